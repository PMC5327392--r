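test_that("motif ranking sorts by score with lexicographic tie-break", {
  r <- rank_motifs(data.frame(motif_id = c("A", "B"), S = c(0.2, 0.5)))
  expect_equal(r$motif_id, c("B", "A"))
  expect_equal(r$rank, 1:2)
  tie <- rank_motifs(data.frame(motif_id = c("B", "A"), S = c(0.3, 0.3)))
  expect_equal(tie$motif_id, c("A", "B"))
  expect_error(rank_motifs(data.frame(motif_id = c("A", "A"), S = 1:2)),
               "duplicate")
  set.seed(51)
  tab <- data.frame(motif_id = sprintf("m%03d", 1:100), S = stats::rnorm(100))
  r <- rank_motifs(tab)
  expect_equal(r$motif_id, tab$motif_id[order(-tab$S, tab$motif_id)])
  expect_true(all(diff(r$S) <= 0))
})

test_that("AUC matches closed forms and a pairwise-comparison oracle", {
  lab <- data.frame(motif_id = sprintf("m%d", 1:6),
                    label = rep(c("pos", "neg"), each = 3))
  perfect <- data.frame(motif_id = sprintf("m%d", 1:6), S = 6:1)
  expect_equal(roc_auc(perfect, lab), 1)
  reversed <- data.frame(motif_id = sprintf("m%d", 1:6), S = 1:6)
  expect_equal(roc_auc(reversed, lab), 0)
  tied <- data.frame(motif_id = sprintf("m%d", 1:6), S = rep(1, 6))
  expect_equal(roc_auc(tied, lab), 0.5)
  expect_error(roc_auc(perfect, data.frame(motif_id = sprintf("m%d", 1:6),
                                           label = rep("pos", 6))),
               "undefined")
  set.seed(52)
  for (k in 1:20) {
    n <- 20
    sc <- data.frame(motif_id = sprintf("m%d", 1:n),
                     S = sample(stats::rnorm(12), n, replace = TRUE))
    lb <- data.frame(motif_id = sprintf("m%d", 1:n),
                     label = sample(c("pos", "neg"), n, TRUE,
                                    prob = c(0.4, 0.6)))
    if (!any(lb$label == "pos") || !any(lb$label == "neg")) next
    expect_equal(roc_auc(sc, lb), oracle_auc(sc$S, lb$label == "pos"))
  }
})

test_that("AUC agrees with pROC and with the trapezoidal curve area", {
  skip_if_not_installed("pROC")
  set.seed(53)
  sc <- data.frame(motif_id = sprintf("m%d", 1:30), S = stats::rnorm(30))
  lb <- data.frame(motif_id = sprintf("m%d", 1:30),
                   label = sample(c("pos", "neg"), 30, TRUE))
  got <- roc_auc(sc, lb)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lb$label, predictor = sc$S, levels = c("neg", "pos"),
    direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
  crv <- roc_curve(sc, lb)
  trap <- sum(diff(crv$fpr) * (utils::head(crv$tpr, -1) + utils::tail(crv$tpr, -1)) / 2)
  expect_equal(got, trap, tolerance = 1e-12)
})

test_that("AUC invariances: complement under reversal, monotone transforms", {
  set.seed(54)
  sc <- data.frame(motif_id = sprintf("m%d", 1:15), S = stats::rnorm(15))
  lb <- data.frame(motif_id = sprintf("m%d", 1:15),
                   label = sample(rep(c("pos", "neg"), c(7, 8))))
  a <- roc_auc(sc, lb)
  flipped <- transform(sc, S = -S)
  expect_equal(a + roc_auc(flipped, lb), 1)
  warped <- transform(sc, S = exp(3 * S) + 2)
  expect_equal(roc_auc(warped, lb), a)
})

test_that("family grouping keeps each family's best-ranked motif", {
  rk <- rank_motifs(data.frame(motif_id = c("a1", "a2", "b1", "c1"),
                               S = c(0.9, 0.3, 0.5, 0.1)))
  lab <- data.frame(motif_id = c("a1", "a2", "b1", "c1"),
                    family = c("A", "A", "B", ""),
                    label = c("pos", "pos", "neg", "neg"))
  g <- group_by_family(rk, lab)
  expect_equal(g$family, c("A", "B", "c1"))  # empty family -> singleton
  expect_equal(g$best_rank, c(1L, 2L, 4L))
  expect_equal(g$best_motif, c("a1", "b1", "c1"))
  expect_equal(g$label, c("pos", "neg", "neg"))
  # random input matches a naive group-then-min oracle
  set.seed(55)
  rk2 <- rank_motifs(data.frame(motif_id = sprintf("m%02d", 1:30),
                                S = stats::rnorm(30)))
  fam <- sample(LETTERS[1:6], 30, TRUE)
  lab2 <- data.frame(motif_id = sprintf("m%02d", 1:30), family = fam)
  g2 <- group_by_family(rk2, lab2)
  ora <- tapply(rk2$rank, fam[match(rk2$motif_id, lab2$motif_id)], min)
  expect_equal(g2$best_rank[order(g2$family)],
               as.vector(ora[order(names(ora))]))
})

test_that("label files parse with or without a header", {
  f <- withr::local_tempfile(lines = c("motif_id\tfamily\tlabel",
                                       "m1\tfamA\tpos",
                                       "m2\tfamB\tnegative"),
                             fileext = ".tsv")
  lab <- read_labels(f)
  expect_equal(lab$label, c("pos", "neg"))
  g <- withr::local_tempfile(lines = c("m1\tfamA\tmaybe"), fileext = ".tsv")
  expect_error(read_labels(g), "pos/neg")
})
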