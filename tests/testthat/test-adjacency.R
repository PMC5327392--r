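test_that("descending matrix bins by unsigned distance and sorts columns", {
  # two tiny windows, m = 4, l = 2, b = 2: bin 0 is d < 2, bin 1 is d >= 2.
  # placements start at offsets 0..6; centers offset + 1; d = |offset + 1 - 4|.
  cfg <- scoring_config(m = 4, b = 2, strand = "forward", t_grid = 1)
  M <- apply_pseudocount(freq_matrix("m2", matrix(c(
    0.97, 0.01, 0.01, 0.01,
    0.01, 0.97, 0.01, 0.01), 4, 2)), cfg$pseudocount)
  wins <- data.frame(chrom = "c", peak = 5L, start = 1L, end = 9L,
                     seq = c("ACGTACGT", "TTACTTAC"))
  B <- build_descending_matrix(wins, M, cfg)

  # oracle: scan each window independently, bin and sort by hand
  vals <- list(`0` = numeric(0), `1` = numeric(0))
  for (s in wins$seq) {
    h <- scan_window(s, M, strand_mode = "forward")
    d <- abs(h$offset + 1 - 4)
    for (k in seq_len(nrow(h))) {
      j <- if (d[k] < 2) "0" else "1"
      vals[[j]] <- c(vals[[j]], h$V[k])
    }
  }
  r <- max(lengths(vals))
  expect_equal(B$r, r)
  for (j in 1:2) {
    col <- sort(vals[[j]], decreasing = TRUE)
    expect_equal(B$M[, j], c(col, numeric(r - length(col))))
  }
  expect_true(all(diff(B$M[, 1]) <= 0) && all(diff(B$M[, 2]) <= 0))
  expect_true(all(B$M >= 0 & B$M <= 1))
})

test_that("a motif spanning most of the window leaves remote bins as padding", {
  cfg <- scoring_config(m = 4, b = 2, strand = "forward")
  M <- apply_pseudocount(rand_fm(7), cfg$pseudocount)
  wins <- data.frame(seq = "ACGTACGT")
  B <- build_descending_matrix(wins, M, cfg)
  # placements at offsets 0,1 have centers 3.5, 4.5 -> d = 0.5 -> bin 0 only
  expect_true(all(B$M[, 2] == 0))
  expect_true(any(B$M[, 1] > 0))
})

test_that("first-order differences subtract adjacent sorted columns", {
  expect_equal(first_order_difference(matrix(0.4, 5, 3)),
               matrix(0, 5, 2))
  toy <- matrix(c(3, 1, 2, 1, 1, 0), 2, 3)
  expect_equal(first_order_difference(toy), matrix(c(1, 0, 1, 1), 2, 2))
  set.seed(31)
  for (k in 1:20) {
    Ms <- rand_descending(6, 4)
    f1 <- first_order_difference(Ms)
    # row 0 compares column maxima because columns are descending
    expect_equal(f1[1, ], apply(Ms, 2, max)[-4] - apply(Ms, 2, max)[-1])
  }
})

test_that("gamma weights decay from the peak and match the closed form", {
  w <- gamma_weights(40, shape = 1, scale = 10)
  expect_length(w, 39L)
  expect_true(all(w > 0))
  expect_true(all(diff(w) < 0))  # shape 1: strictly decreasing
  expect_equal(w[1], exp(-0.05) / 10, tolerance = 1e-12)
  set.seed(32)
  for (k in 1:10) {
    sh <- stats::runif(1, 0.5, 5); sc <- stats::runif(1, 1, 20)
    expect_true(all(gamma_weights(12, sh, sc) > 0))
  }
  expect_error(gamma_weights(10, 0, 1), "positive")
})

test_that("S1 truncates rows then gamma-weights column sums", {
  f1 <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_equal(score_S1(f1, c(0.5, 0.25), 2), 1.0)
  expect_equal(score_S1(matrix(0, 4, 3), rep(1, 3), 2), 0)
  set.seed(33)
  F <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(score_S1(F, rep(1, 3), 4), sum(F))  # t = r, unit weights
  expect_error(score_S1(F, rep(1, 3), 0), "must be in")
  expect_error(score_S1(F, rep(1, 3), 5), "must be in")
})

test_that("second-order differences are column-normalized to [-1, 1]", {
  f1 <- matrix(c(2, 1, -1), 3, 1)
  expect_equal(second_order_difference(f1), matrix(c(1, 0.5, -0.5), 3, 1))
  expect_equal(second_order_difference(matrix(0, 3, 2)), matrix(0, 3, 2))
  set.seed(34)
  for (k in 1:20) {
    f1 <- matrix(stats::rnorm(24), 6, 4)
    f2 <- second_order_difference(f1)
    expect_true(all(abs(f2) <= 1 + 1e-12))
    expect_true(any(abs(f2) == 1))  # each column attains its max
  }
})

test_that("S2 is a centered sigmoid of column sums", {
  expect_equal(score_S2(matrix(0, 5, 3)), 0)
  # oddness: mirrored column sums cancel
  f2 <- cbind(rep(0.25, 4), rep(-0.25, 4))
  expect_equal(score_S2(f2), 0)
  # saturation: one strongly positive column contributes ~ +0.5
  expect_equal(score_S2(matrix(1, 50, 1)), 0.5, tolerance = 1e-9)
  expect_equal(score_S2(matrix(-1, 50, 1)), -0.5, tolerance = 1e-9)
  expect_equal(score_S2(matrix(c(1, -1), 2, 1)), 0)
})

test_that("adjacency_score matches a straight-line oracle on random matrices", {
  set.seed(35)
  for (k in 1:60) {
    r <- sample(2:8, 1); b <- sample(2:5, 1)
    Ms <- rand_descending(r, b)
    cfg <- scoring_config(m = 1000, b = b,
                          gamma_scale = stats::runif(1, 0.5, 4),
                          w1 = stats::runif(1), w2 = stats::runif(1))
    got <- adjacency_score(as_binned(Ms), cfg)
    ora <- oracle_adjacency(Ms, cfg)
    expect_equal(got$S, ora$S, tolerance = 1e-9)
    expect_equal(got$S1, ora$S1, tolerance = 1e-9)
    expect_equal(got$S2, ora$S2, tolerance = 1e-9)
    expect_equal(got$t_star, ora$t_star)
    expect_equal(got$f1, ora$f1, tolerance = 1e-12)
    expect_equal(got$S, cfg$w1 * got$S1 + cfg$w2 * got$S2)
  }
})

test_that("degenerate combination weights isolate each component", {
  set.seed(36)
  Ms <- rand_descending(6, 4)
  c1 <- scoring_config(b = 4, w1 = 1, w2 = 0)
  a1 <- adjacency_score(as_binned(Ms), c1)
  expect_equal(a1$S, max(a1$S1_by_t))
  c2 <- scoring_config(b = 4, w1 = 0, w2 = 1)
  a2 <- adjacency_score(as_binned(Ms), c2)
  expect_equal(a2$S, a2$S2)
  expect_true(is.finite(a2$t_star))
})

test_that("scaling all scores by lambda scales f1/S1 and leaves f2/S2 alone", {
  set.seed(37)
  Ms <- rand_descending(7, 5)
  cfg <- scoring_config(b = 5)
  base <- adjacency_score(as_binned(Ms), cfg)
  for (lam in c(0.3, 0.7)) {
    sc <- adjacency_score(as_binned(Ms * lam), cfg)
    expect_equal(sc$f1, base$f1 * lam)
    expect_equal(sc$S1, base$S1 * lam)
    expect_equal(sc$t_star, base$t_star)
    expect_equal(sc$f2, base$f2)
    expect_equal(sc$S2, base$S2)
  }
})

test_that("lifting near-bin scores strictly increases S1 and S", {
  set.seed(38)
  Ms <- rand_descending(8, 4) * 0.5
  cfg <- scoring_config(b = 4)
  S1s <- Ss <- numeric(0)
  for (delta in c(0, 0.1, 0.2, 0.3)) {
    shifted <- Ms
    shifted[, 1] <- shifted[, 1] + delta
    a <- adjacency_score(as_binned(shifted), cfg)
    S1s <- c(S1s, a$S1); Ss <- c(Ss, a$S)
  }
  expect_true(all(diff(S1s) > 0))
  expect_true(all(diff(Ss) > 0))
})

test_that("positionally uniform scores carry no signal at fixed depth", {
  # i.i.d. columns: every f1 entry has mean 0, so S1 at any fixed depth and
  # S2 are mean-zero; check both within 3 standard errors over 300 draws
  set.seed(39)
  n <- 300
  S1f <- S2s <- numeric(n)
  w <- gamma_weights(4, 1, 1)
  for (k in seq_len(n)) {
    Ms <- rand_descending(6, 4)
    f1 <- first_order_difference(Ms)
    S1f[k] <- score_S1(f1, w, 6)
    S2s[k] <- score_S2(second_order_difference(f1))
  }
  expect_lt(abs(mean(S1f)), 3 * stats::sd(S1f) / sqrt(n))
  expect_lt(abs(mean(S2s)), 3 * stats::sd(S2s) / sqrt(n))
})

test_that("bin diagnostics expose per-bin means and difference sums", {
  set.seed(40)
  B <- as_binned(rand_descending(5, 3))
  d <- bin_diagnostics(B, scoring_config(b = 3))
  expect_equal(nrow(d), 3L)
  expect_equal(d$mean_V, colMeans(B$M))
  expect_equal(d$sum_f1[1:2], colSums(first_order_difference(B)))
  expect_true(is.na(d$z[3]))
})
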