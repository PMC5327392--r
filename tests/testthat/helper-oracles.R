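# Fixtures and independent (straight-line, loop-based) oracles used across
# the suite. Oracles deliberately share no helpers with the package code
# paths they check.

# Random frequency matrix with uniform Dirichlet-ish columns.
rand_fm <- function(l, id = "rand") {
  m <- matrix(stats::runif(4 * l), 4, l)
  freq_matrix(id, m)
}

# Term-by-term log-odds score, the slow way.
oracle_pwm_score <- function(s, M) {
  bases <- strsplit(s, "")[[1]]
  tot <- 0
  for (i in seq_along(bases))
    tot <- tot + log(unname(M$mat[bases[i], i]) / 0.25)
  tot
}

# Exhaustive max/min PWM score over all 4^l sequences.
oracle_score_extremes <- function(M) {
  l <- ncol(M$mat)
  seqs <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), l))
  scores <- apply(seqs, 1L, function(b) {
    tot <- 0
    for (i in seq_len(l)) tot <- tot + log(M$mat[b[i], i] / 0.25)
    tot
  })
  c(min = min(scores), max = max(scores))
}

# Straight-line recomputation of the adjacency score from a descending
# matrix: explicit loops, hand-written sigmoid, no shared package helpers.
oracle_adjacency <- function(Ms, cfg) {
  r <- nrow(Ms); b <- ncol(Ms)
  f1 <- matrix(0, r, b - 1L)
  for (i in seq_len(r))
    for (j in seq_len(b - 1L))
      f1[i, j] <- Ms[i, j] - Ms[i, j + 1L]
  w <- stats::dgamma((seq_len(b - 1L)) - 0.5,
                     shape = cfg$gamma_shape, scale = cfg$gamma_scale)
  depths <- sort(unique(pmin(r, as.integer(ceiling(cfg$t_grid * r)))))
  S1s <- vapply(depths, function(t) {
    tot <- 0
    for (j in seq_len(b - 1L)) {
      cs <- 0
      for (i in seq_len(t)) cs <- cs + f1[i, j]
      tot <- tot + w[j] * cs
    }
    tot
  }, numeric(1))
  k <- which.max(S1s)
  f2 <- matrix(0, r, b - 1L)
  for (j in seq_len(b - 1L)) {
    D <- max(abs(f1[, j]))
    if (D > 0) f2[, j] <- f1[, j] / D
  }
  S2 <- 0
  for (j in seq_len(b - 1L)) {
    z <- sum(f2[, j])
    S2 <- S2 + 1 / (1 + exp(-z)) - 0.5
  }
  list(S1 = S1s[k], t_star = depths[k], S2 = S2,
       S = cfg$w1 * S1s[k] + cfg$w2 * S2, f1 = f1, f2 = f2)
}

# Wrap a bare descending matrix as the object adjacency_score() expects.
as_binned <- function(Ms, m = 1000L) {
  structure(list(M = Ms, r = nrow(Ms), b = ncol(Ms), n = 1L,
                 bin_edges = seq(0, m, length.out = ncol(Ms) + 1L),
                 motif_id = "test"),
            class = "binned_scores")
}

# Random descending matrix: i.i.d. uniform entries, columns sorted.
rand_descending <- function(r, b) {
  apply(matrix(stats::runif(r * b), r, b), 2L, sort, decreasing = TRUE)
}

# Pairwise-comparison AUC oracle: concordant pairs / (P * N), ties 1/2.
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# A consensus DNA string (per-column argmax) for a motif.
consensus_of <- function(M) {
  paste(rownames(M$mat)[apply(M$mat, 2L, which.max)], collapse = "")
}

transfac_two_blocks <- c(
  "AC M00001", "XX", "ID TOY_A", "XX",
  "P0\tA\tC\tG\tT",
  "01\t1\t2\t1\t1",
  "02\t0\t0\t5\t0",
  "XX", "//",
  "AC M00002", "XX", "ID TOY_B", "XX",
  "P0\tA\tC\tG\tT",
  "01\t0.2\t0.3\t0.4\t0.1",
  "02\t0.25\t0.25\t0.25\t0.25",
  "XX", "//")
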