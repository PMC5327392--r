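#' @useDynLib coTFscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Encode a DNA string as integers 1..4 (A,C,G,T); anything else -> 0.
encode_dna <- function(s) {
  map <- integer(256)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("a")] <- 1L
  map[utf8ToInt("C")] <- 2L; map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("g")] <- 3L
  map[utf8ToInt("T")] <- 4L; map[utf8ToInt("t")] <- 4L
  map[utf8ToInt(s)]
}

# Per-position log-odds terms log(theta / 0.25) of a frequency matrix.
logodds_matrix <- function(M) log(M$mat / 0.25)

#' Log-odds PWM score of a sequence
#'
#' The score of an l-base sequence `s` under motif model `M` is the log
#' likelihood ratio of `s` under the motif's per-position frequencies
#' versus a uniform 0-order background in which every base has probability
#' 0.25: `sum_i log(theta[s_i, i] / 0.25)` (natural log).
#'
#' @param s A DNA string over A/C/G/T, exactly as long as the motif.
#' @param M A [freq_matrix()]; apply a pseudocount first if any frequency
#'   may be zero.
#' @return The raw log-odds score (a single number).
#' @seealso [normalized_score()], [scan_window()]
#' @export
pwm_score <- function(s, M) {
  stopifnot(inherits(M, "freq_matrix"))
  l <- motif_length(M)
  codes <- encode_dna(s)
  if (length(codes) != l)
    stop("sequence length ", length(codes), " != motif length ", l)
  if (any(codes == 0L))
    stop("sequence contains non-ACGT characters")
  W <- logodds_matrix(M)
  sum(W[cbind(codes, seq_len(l))])
}

#' Maximum and minimum attainable PWM scores
#'
#' The analytic extremes of [pwm_score()] over all 4^l sequences: the sum
#' of `log(max_q theta[q, i] / 0.25)` (respectively column minima) across
#' positions. Used to min-max normalize raw scores to `[0, 1]`.
#'
#' @param M A [freq_matrix()].
#' @return A single number.
#' @export
pwm_score_max <- function(M) {
  stopifnot(inherits(M, "freq_matrix"))
  sum(log(apply(M$mat, 2L, max) / 0.25))
}

#' @rdname pwm_score_max
#' @export
pwm_score_min <- function(M) {
  stopifnot(inherits(M, "freq_matrix"))
  sum(log(apply(M$mat, 2L, min) / 0.25))
}

#' Min-max normalized binding score
#'
#' The sequence-specific binding score `V = (score - min) / (max - min)`,
#' a dimensionless affinity in `[0, 1]`: 1 for the per-column consensus
#' sequence, 0 for the per-column worst sequence. A degenerate matrix whose
#' max and min scores coincide (uniform columns) gives `V = 0.5`.
#'
#' @inheritParams pwm_score
#' @return A list with elements `V` (normalized score), `raw` (log-odds).
#' @export
normalized_score <- function(s, M) {
  raw <- pwm_score(s, M)
  rng <- c(pwm_score_min(M), pwm_score_max(M))
  V <- if (diff(rng) < 1e-12) 0.5 else (raw - rng[1L]) / diff(rng)
  list(V = V, raw = raw)
}

#' Scan a sequence window with a motif
#'
#' Scores every full placement of the motif in a window: a window of
#' length `L` admits `L - l + 1` placements. With `strand_mode = "both"`
#' each start is scored with the motif and with its reverse complement and
#' the larger normalized score is kept, together with the winning strand;
#' transcription factor binding is strand-agnostic, so this is the default.
#' Placements overlapping a non-ACGT base (e.g. N) get `V = 0`.
#'
#' @param w DNA string of length `L >= l` (a warning and an empty result
#'   if shorter).
#' @param M A [freq_matrix()] (pseudocount recommended).
#' @param strand_mode `"both"` or `"forward"`.
#' @return A data.frame with one row per placement start: `offset` (0-based
#'   start within the window), `V`, `raw`, `strand`.
#' @export
scan_window <- function(w, M, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(M, "freq_matrix"))
  codes <- matrix(encode_dna(w), ncol = 1L)
  l <- motif_length(M)
  if (nrow(codes) < l) {
    warning("window of length ", nrow(codes), " shorter than motif (", l,
            " bp); no placements scored")
    return(data.frame(offset = integer(0), V = numeric(0),
                      raw = numeric(0), strand = character(0)))
  }
  sc <- scan_raw(codes, M, strand_mode, keep_strand = TRUE)
  rng <- c(pwm_score_min(M), pwm_score_max(M))
  denom <- diff(rng)
  V <- if (denom < 1e-12) rep(0.5, length(sc$raw)) else (sc$raw - rng[1L]) / denom
  V[is.na(sc$raw)] <- 0            # placements overlapping N
  data.frame(offset = seq_along(V) - 1L, V = V,
             raw = as.vector(sc$raw), strand = sc$strand)
}

# Raw scores for all windows in a codes matrix (one column per window).
# Returns list(raw = matrix, strand = "+"/"-" per placement when
# keep_strand). A placement overlapping N is NA on both strands.
scan_raw <- function(codes, M, strand_mode, keep_strand = FALSE) {
  W <- logodds_matrix(M)
  if (strand_mode == "forward") {
    fwd <- scan_codes(codes, W)
    return(list(raw = fwd,
                strand = if (keep_strand) rep("+", length(fwd))))
  }
  Wrc <- logodds_matrix(reverse_complement(M))
  if (!keep_strand)
    return(list(raw = scan_codes_max(codes, W, Wrc), strand = NULL))
  fwd <- scan_codes(codes, W)
  rev <- scan_codes(codes, Wrc)
  raw <- pmax(fwd, rev)
  strand <- ifelse(!is.na(rev) & (is.na(fwd) | rev > fwd), "-", "+")
  list(raw = raw, strand = strand)
}
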