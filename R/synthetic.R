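# Run code under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  force(code)
}

# Derived RNG stream id; double arithmetic so large bases cannot overflow.
derive_seed <- function(seed, offset) (as.numeric(seed) * 1000 + offset) %% 2147483647

#' Random informative motif model
#'
#' Draws a frequency matrix in which each column has one dominant
#' nucleotide (chosen uniformly) with frequency uniform in
#' `[dominant[1], dominant[2]]`; the remainder is split among the other
#' three bases with random proportions. The defaults give per-column
#' information content typical of curated transcription-factor motifs
#' (roughly 0.6-1.6 bits).
#'
#' @param l Motif length in bases.
#' @param id Motif identifier.
#' @param dominant Range of the dominant base's frequency.
#' @param seed Optional integer seed for reproducibility.
#' @return A [freq_matrix()].
#' @export
random_motif <- function(l = 10L, id = "motif", dominant = c(0.7, 0.95),
                         seed = NULL) {
  draw <- function() {
    mat <- vapply(seq_len(l), function(p) {
      f <- stats::runif(1, dominant[1L], dominant[2L])
      rest <- stats::runif(3)
      col <- numeric(4)
      top <- sample.int(4L, 1L)
      col[top] <- f
      col[-top] <- (1 - f) * rest / sum(rest)
      col
    }, numeric(4))
    rownames(mat) <- DNA_BASES
    freq_matrix(id, mat)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Specification of a synthetic co-motif dataset
#'
#' Describes a desk-scale dataset emulating the premise that a
#' co-associated factor's binding sites cluster near another factor's
#' ChIP-seq peak points with a peak-like (decaying) distance
#' distribution: an i.i.d. background contig, evenly spaced peak points,
#' instances of one planted motif written near a subset of peaks at
#' exponentially distributed unsigned distances, and decoy motifs that
#' never get instances and so have no positional preference.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_peaks Number of peak points.
#' @param m Half-window in bp; peaks are spaced `2 m` apart so windows
#'   tile the contig without overlap.
#' @param gc Background GC fraction in (0, 1); default 0.42, a typical
#'   mammalian genome-wide value.
#' @param plant_prob Probability that a peak receives one planted
#'   instance.
#' @param lambda Mean of the exponential unsigned peak-to-instance
#'   distance, in bp (the "peak-like" decay scale).
#' @param planted_motif A [freq_matrix()]; default a random 10-mer drawn
#'   from the seed.
#' @param n_decoys Number of decoy motifs (drawn from the seed with the
#'   same law as the planted motif).
#' @param decoy_length Length of decoy motifs in bases.
#' @param contig_length Contig length in bp; default `2 m * n_peaks + 2 m`,
#'   just enough for non-overlapping windows with margins.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_peaks = 500L, m = 1000L, gc = 0.42,
                           plant_prob = 0.8, lambda = 50, planted_motif = NULL,
                           n_decoys = 20L, decoy_length = 10L,
                           contig_length = NULL) {
  m <- as.integer(m); n_peaks <- as.integer(n_peaks)
  if (is.null(contig_length)) contig_length <- 2L * m * n_peaks + 2L * m
  if (gc <= 0 || gc >= 1) stop("`gc` must be in (0, 1)")
  if (plant_prob < 0 || plant_prob > 1) stop("`plant_prob` must be in [0, 1]")
  if (lambda >= m) stop("`lambda` must be smaller than the half-window `m`")
  if (is.null(planted_motif))
    planted_motif <- random_motif(10L, "PLANTED", seed = derive_seed(seed, 1))
  decoys <- lapply(seq_len(n_decoys), function(k)
    random_motif(decoy_length, sprintf("DECOY_%02d", k),
                 seed = derive_seed(seed, 1 + k)))
  structure(list(seed = as.numeric(seed), n_peaks = n_peaks, m = m, gc = gc,
                 plant_prob = plant_prob, lambda = lambda,
                 planted_motif = planted_motif, decoys = decoys,
                 contig_length = as.integer(contig_length)),
            class = "synthetic_spec")
}

#' Random background contig
#'
#' i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`;
#' deterministic given the seed.
#'
#' @param length Contig length in bp.
#' @param gc GC fraction.
#' @param seed Optional integer seed.
#' @return A single DNA string.
#' @export
generate_background <- function(length, gc = 0.42, seed = NULL) {
  draw <- function() {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# One instance sequence sampled column-wise from the motif's frequencies.
sample_instance <- function(M) {
  paste(vapply(seq_len(motif_length(M)), function(p)
    sample(DNA_BASES, 1L, prob = M$mat[, p]), character(1)), collapse = "")
}

#' Plant motif instances near peak points
#'
#' For each peak, with probability `plant_prob`, writes one instance
#' sampled column-wise from the planted motif's frequencies into the
#' contig. The instance's center sits at unsigned distance
#' `d ~ Exponential(mean = lambda)` from the peak (rounded, capped at
#' `m - l` so the instance stays inside the window), on a uniformly chosen
#' side and strand. An instance overlapping a previously planted one is
#' re-drawn (up to 100 tries, then skipped with a warning).
#'
#' @param contig Background DNA string.
#' @param peaks Integer vector of 1-based peak positions (each at least
#'   `m` from the contig ends).
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed (defaults to the spec's seed).
#' @return A list: `contig` (modified string) and `truth`, a data.frame
#'   with one row per planted instance (`peak`, `d`, `side`, `strand`,
#'   `start`).
#' @export
plant_instances <- function(contig, peaks, spec, seed = spec$seed) {
  run <- function() {
    M <- spec$planted_motif
    l <- motif_length(M)
    half <- floor(l / 2)
    starts <- integer(0)              # occupied instance starts (length l each)
    rows <- list()
    for (p in peaks) {
      if (stats::runif(1) > spec$plant_prob) next
      ok <- FALSE
      for (try in seq_len(100L)) {
        d <- min(round(stats::rexp(1, rate = 1 / spec$lambda)), spec$m - l)
        side <- sample(c(-1L, 1L), 1L)
        start <- p + side * d - half
        if (start < 1L || start + l - 1L > nchar(contig)) next
        if (length(starts) == 0L || all(abs(start - starts) >= l)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        warning("could not place an instance near peak ", p, "; skipped")
        next
      }
      strand <- sample(c("+", "-"), 1L)
      inst <- sample_instance(M)
      if (strand == "-")
        inst <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(inst)))
      starts <- c(starts, start)
      rows[[length(rows) + 1L]] <-
        data.frame(peak = p, d = d, side = side, strand = strand,
                   start = start, instance = inst)
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(peak = integer(0), d = numeric(0), side = integer(0),
                 strand = character(0), start = integer(0),
                 instance = character(0))
    # splice all instances in one pass (repeated substr<- would copy the
    # whole contig per instance)
    if (nrow(truth) > 0L) {
      o <- order(truth$start)
      s <- truth$start[o]; inst <- truth$instance[o]
      gap_from <- c(1L, s + l)
      gap_to <- c(s - 1L, nchar(contig))
      pieces <- character(2L * length(s) + 1L)
      pieces[seq(1L, by = 2L, length.out = length(s) + 1L)] <-
        substring(contig, gap_from, gap_to)
      pieces[seq(2L, by = 2L, length.out = length(s))] <- inst
      contig <- paste(pieces, collapse = "")
    }
    list(contig = contig, truth = truth)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a complete synthetic dataset
#'
#' Builds the background contig, evenly spaced peak points (peak `i` at
#' position `(2 i - 1) m + 1`, so windows tile the contig), plants the
#' co-motif, and assembles ground-truth labels (planted motif positive,
#' decoys negative). Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir If non-`NULL`, a directory into which `genome.fa`,
#'   `peaks.bed`, `motifs.transfac`, `labels.tsv` and `truth.tsv` are
#'   written (created if needed).
#' @return Invisibly when writing, otherwise visibly: a list with
#'   `genome` (named character vector, one contig `chr1`), `peaks`
#'   (data.frame `chrom`, `pos`), `motifs` (planted first, then decoys),
#'   `labels` (data.frame `motif_id`, `family`, `label`), `truth`, `spec`,
#'   and (when writing) `paths`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  contig <- generate_background(spec$contig_length, spec$gc,
                                seed = derive_seed(spec$seed, 0))
  peaks <- (2L * seq_len(spec$n_peaks) - 1L) * spec$m + 1L
  pl <- plant_instances(contig, peaks, spec, seed = derive_seed(spec$seed, 500))
  motifs <- c(list(spec$planted_motif), spec$decoys)
  labels <- data.frame(
    motif_id = vapply(motifs, `[[`, character(1), "id"),
    family = vapply(motifs, `[[`, character(1), "id"),
    label = c("pos", rep("neg", length(spec$decoys))))
  out <- list(genome = c(chr1 = pl$contig),
              peaks = data.frame(chrom = "chr1", pos = peaks),
              motifs = motifs, labels = labels, truth = pl$truth, spec = spec)
  if (is.null(dir)) return(out)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c(genome = "genome.fa", peaks = "peaks.bed",
                            motifs = "motifs.transfac", labels = "labels.tsv",
                            truth = "truth.tsv"))
  names(paths) <- c("genome", "peaks", "motifs", "labels", "truth")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$genome), paths["genome"])
  utils::write.table(out$peaks, paths["peaks"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_transfac(motifs, paths["motifs"])
  utils::write.table(labels, paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(out$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out$paths <- paths
  invisible(out)
}
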