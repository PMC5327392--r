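#' Scoring configuration for adjacency analysis
#'
#' Bundles every tunable parameter of the adjacency-score pipeline.
#'
#' @param m Half-window size in bp around each peak point.
#' @param b Number of distance bins over `[0, m]`; each bin spans `m / b`
#'   bp of unsigned distance from the peak.
#' @param gamma_shape,gamma_scale Shape `c` and scale (in bins) of the
#'   gamma density that down-weights remote bins in the first-order score.
#'   Defaults: shape 1 (exponentially decaying weights, largest at the
#'   peak-proximal bin) and scale `b / 4` (`NULL` means `b / 4`), so the
#'   weight has dropped by ~e^-4 at the window edge.
#' @param w1,w2 Non-negative combination weights of the first- and
#'   second-order scores in the final score `S = w1 * S1 + w2 * S2`.
#'   Defaults: `w1 = 1` and `w2 = 2 / (b - 1)` (`NULL` means `2 / (b - 1)`).
#'   `S2` is a sum of `b - 1` terms each bounded by 1/2, so its natural
#'   scale grows with the bin count while `S1` stays O(1); the default
#'   `w2` rescales the `S2` contribution into `(-1, 1)` so the two
#'   components enter the final score on comparable scales.
#' @param t_grid Candidate row-truncation depths for the first-order
#'   score, as fractions of the matrix depth `r`; the depth maximizing
#'   `S1` is selected per motif.
#' @param pseudocount Pseudocount frequency applied to each motif before
#'   scanning (see [apply_pseudocount()]).
#' @param strand `"both"` (score forward and reverse-complement motif at
#'   each start, keep the larger) or `"forward"`.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(m = 1000L, b = 40L, gamma_shape = 1,
                           gamma_scale = NULL, w1 = 1, w2 = NULL,
                           t_grid = c(0.01, 0.05, 0.10, 0.25, 0.50, 1),
                           pseudocount = 1e-3,
                           strand = c("both", "forward")) {
  strand <- match.arg(strand)
  m <- as.integer(m); b <- as.integer(b)
  if (is.null(gamma_scale)) gamma_scale <- b / 4
  if (is.null(w2)) w2 <- 2 / (b - 1)
  if (b < 2L) stop("`b` must be at least 2 bins")
  if (gamma_shape <= 0 || gamma_scale <= 0)
    stop("gamma shape and scale must be positive")
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0)
    stop("`w1` and `w2` must be non-negative and not both zero")
  if (any(t_grid <= 0) || any(t_grid > 1))
    stop("`t_grid` fractions must lie in (0, 1]")
  structure(list(m = m, b = b, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale, w1 = w1, w2 = w2,
                 t_grid = sort(unique(t_grid)), pseudocount = pseudocount,
                 strand = strand),
            class = "scoring_config")
}

#' Build the descending-order binned score matrix
#'
#' Scans every window with the motif, assigns each placement to a distance
#' bin by the unsigned distance `d` from the placement's center
#' (`offset + l/2`) to the peak point (offset `m`), with bin
#' `j = floor(d / (m / b))` and the outermost bin absorbing `d = m`.
#' Placements left and right of the peak fold into the same bin. Each
#' bin's normalized scores are pooled across windows and sorted in
#' descending order into the columns of an r-by-b matrix, where `r` is
#' the largest bin occupancy; shorter columns are padded at the bottom
#' with 0 so the matrix stays rectangular without inflating top scores.
#'
#' @param windows A `peak_windows` object from [extract_windows()] (or any
#'   data.frame with a `seq` column of equal-length `2 m` windows).
#' @param M A [freq_matrix()]; the config's pseudocount is applied here if
#'   the motif does not carry one yet.
#' @param cfg A [scoring_config()].
#' @return An object of class `binned_scores`: list with `M` (the r-by-b
#'   matrix), `r`, `b`, `n` (windows contributing), `bin_edges` (unsigned
#'   distances in bp, length `b + 1`), `motif_id`.
#' @export
build_descending_matrix <- function(windows, M, cfg = scoring_config()) {
  stopifnot(is.data.frame(windows), nrow(windows) >= 1L,
            inherits(M, "freq_matrix"), inherits(cfg, "scoring_config"))
  L <- unique(nchar(windows$seq))
  if (length(L) != 1L || L != 2L * cfg$m)
    stop("all windows must have length 2 * m = ", 2L * cfg$m, " bp")
  codes <- attr(windows, "codes") %||%
    vapply(windows$seq, encode_dna, integer(L), USE.NAMES = FALSE)
  descending_matrix_from_codes(codes, M, cfg)
}

# Core of build_descending_matrix on pre-encoded windows (L x n matrix of
# base codes); lets score_motifs() encode the window set only once.
descending_matrix_from_codes <- function(codes, M, cfg) {
  L <- nrow(codes)
  if (M$pseudocount == 0) M <- apply_pseudocount(M, cfg$pseudocount)
  l <- motif_length(M)
  if (L < l) stop("windows (", L, " bp) are shorter than the motif (", l, " bp)")

  raw <- scan_raw(codes, M, cfg$strand)$raw     # (L - l + 1) x n
  rng <- c(pwm_score_min(M), pwm_score_max(M))
  denom <- diff(rng)
  V <- if (denom < 1e-12) {
    m0 <- raw; m0[] <- 0.5; m0
  } else (raw - rng[1L]) / denom
  V[is.na(raw)] <- 0

  # identical geometry in every window: bin by placement-center distance
  offs <- seq_len(nrow(V)) - 1L
  d <- abs(offs + l / 2 - cfg$m)
  bin <- pmin(floor(d / (cfg$m / cfg$b)), cfg$b - 1L)

  cols <- lapply(0:(cfg$b - 1L), function(j) {
    sort(V[bin == j, , drop = FALSE], decreasing = TRUE, method = "radix")
  })
  r <- max(lengths(cols))
  if (r == 0L) stop("no motif placement falls in any bin")
  Ms <- vapply(cols, function(x) c(x, numeric(r - length(x))), numeric(r))
  structure(list(M = Ms, r = r, b = cfg$b, n = ncol(V),
                 bin_edges = seq(0, cfg$m, length.out = cfg$b + 1L),
                 motif_id = M$id),
            class = "binned_scores")
}

#' First-order adjacency differences
#'
#' Row-wise differences between adjacent distance-bin columns of the
#' descending-order matrix: `f1[i, j] = M_s[i, j] - M_s[i, j + 1]`. Because
#' every column is sorted descending, row `i` compares the i-th largest
#' score of bin `j` with the i-th largest of bin `j + 1`; positive values
#' mean scores drop moving away from the peak.
#'
#' @param B A `binned_scores` object (or a plain numeric matrix with
#'   descending columns).
#' @return An r-by-(b-1) numeric matrix.
#' @export
first_order_difference <- function(B) {
  Ms <- if (inherits(B, "binned_scores")) B$M else B
  stopifnot(is.matrix(Ms), ncol(Ms) >= 2L)
  Ms[, -ncol(Ms), drop = FALSE] - Ms[, -1L, drop = FALSE]
}

#' Gamma weights over bin boundaries
#'
#' Positional weights for the `b - 1` adjacent-column pairs: the gamma
#' density evaluated at the pair midpoints `j + 0.5` for `j = 0 .. b - 2`.
#' With shape 1 these decay exponentially, so score drops close to the
#' peak count most and remote drops are damped — matching the expectation
#' that co-associated factors bind near the peak point.
#'
#' @param b Number of bins.
#' @param shape,scale Gamma shape and scale (scale in bin units).
#' @return Numeric vector of `b - 1` positive weights.
#' @export
gamma_weights <- function(b, shape = 1, scale = 10) {
  if (shape <= 0 || scale <= 0) stop("gamma shape and scale must be positive")
  stats::dgamma(seq_len(b - 1L) - 0.5, shape = shape, scale = scale)
}

#' First-order adjacency score
#'
#' Sums the top `t` rows of each `f1` column (the rows are aligned order
#' statistics, so the top rows carry the strongest binding scores) and
#' combines the column sums with the gamma weights:
#' `S1(t) = sum_j g_j * sum_{i <= t} f1[i, j]`.
#'
#' @param f1 Matrix from [first_order_difference()].
#' @param weights Vector of `ncol(f1)` positive weights
#'   (see [gamma_weights()]).
#' @param t Row truncation depth, `1 <= t <= nrow(f1)`.
#' @return A single number.
#' @export
score_S1 <- function(f1, weights, t) {
  stopifnot(is.matrix(f1), length(weights) == ncol(f1))
  t <- as.integer(t)
  if (t < 1L || t > nrow(f1)) stop("`t` must be in 1..", nrow(f1))
  sum(weights * colSums(f1[seq_len(t), , drop = FALSE]))
}

#' Second-order adjacency differences
#'
#' Rescales each `f1` column by the largest absolute first-order
#' difference of that column pair, `f2[i, j] = f1[i, j] / max_i |f1[i, j]|`
#' (an all-zero column stays zero), so `|f2| <= 1`. This removes the
#' common scale that base-composition (CG/AT) bias imposes on raw score
#' differences, leaving only the shape of the drop-off.
#'
#' @param f1 Matrix from [first_order_difference()].
#' @return Matrix of the same shape with entries in `[-1, 1]`.
#' @export
second_order_difference <- function(f1) {
  stopifnot(is.matrix(f1))
  D <- apply(abs(f1), 2L, max)
  D[D == 0] <- 1             # all-zero column: keep zeros
  sweep(f1, 2L, D, "/")
}

#' Second-order adjacency score
#'
#' Column sums of `f2` pushed through a centered logistic sigmoid:
#' `S2 = sum_j (sigmoid(z_j) - 1/2)` with `z_j = sum_i f2[i, j]`. The
#' centering makes a null (all-zero) column contribute exactly 0, and the
#' sigmoid caps each bin pair's contribution at +-1/2 so a single extreme
#' region cannot dominate.
#'
#' @param f2 Matrix from [second_order_difference()].
#' @return A single number in `(-(b - 1)/2, (b - 1)/2)`.
#' @export
score_S2 <- function(f2) {
  stopifnot(is.matrix(f2))
  sum(stats::plogis(colSums(f2)) - 0.5)
}

#' Adjacency score of one motif
#'
#' The full per-motif computation: first-order differences `f1`; the
#' truncation depth `t*` maximizing `S1(t)` over the configured grid of
#' depths (fractions of `r`, rounded up; ties broken toward the smallest
#' depth); second-order differences `f2` and `S2`; and the final score
#' `S = w1 * S1(t*) + w2 * S2`.
#'
#' @param B A `binned_scores` object from [build_descending_matrix()].
#' @param cfg A [scoring_config()].
#' @return An object of class `adjacency_result`: list with `motif_id`,
#'   `S`, `S1`, `S2`, `t_star`, `S1_by_t` (named by depth), `f1`, `f2`,
#'   `weights`, `r`, `b`, `n`.
#' @export
adjacency_score <- function(B, cfg = scoring_config()) {
  stopifnot(inherits(B, "binned_scores"), inherits(cfg, "scoring_config"))
  f1 <- first_order_difference(B)
  w <- gamma_weights(B$b, cfg$gamma_shape, cfg$gamma_scale)
  depths <- sort(unique(pmin(B$r, as.integer(ceiling(cfg$t_grid * B$r)))))
  S1_by_t <- vapply(depths, function(t)
    sum(w * colSums(f1[seq_len(t), , drop = FALSE])), numeric(1))
  names(S1_by_t) <- depths
  best <- which.max(S1_by_t)        # first max: ties go to smallest depth
  f2 <- second_order_difference(f1)
  S2 <- score_S2(f2)
  S1 <- unname(S1_by_t[best])
  structure(list(motif_id = B$motif_id, S = cfg$w1 * S1 + cfg$w2 * S2,
                 S1 = S1, S2 = S2, t_star = depths[best],
                 S1_by_t = S1_by_t, f1 = f1, f2 = f2, weights = w,
                 r = B$r, b = B$b, n = B$n),
            class = "adjacency_result")
}

#' @export
print.adjacency_result <- function(x, ...) {
  cat("Adjacency score for motif '", x$motif_id, "'\n",
      "  S = ", format(x$S), "  (S1 = ", format(x$S1), " at t = ", x$t_star,
      ", S2 = ", format(x$S2), ")\n",
      "  matrix: r = ", x$r, ", b = ", x$b, ", windows = ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Per-bin diagnostics of a binned score matrix
#'
#' Summary table used for enrichment plots: per distance bin the mean
#' normalized score, and per adjacent-bin pair the weighted `f1` sum and
#' the `f2` column sum `z_j` (NA in the last bin's row).
#'
#' @param B A `binned_scores` object.
#' @param cfg A [scoring_config()].
#' @return A data.frame with columns `bin`, `d_lo`, `d_hi`, `mean_V`,
#'   `sum_f1`, `z`.
#' @export
bin_diagnostics <- function(B, cfg = scoring_config()) {
  f1 <- first_order_difference(B)
  f2 <- second_order_difference(f1)
  data.frame(bin = 0:(B$b - 1L),
             d_lo = B$bin_edges[-length(B$bin_edges)],
             d_hi = B$bin_edges[-1L],
             mean_V = colMeans(B$M),
             sum_f1 = c(colSums(f1), NA),
             z = c(colSums(f2), NA))
}
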