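#' Score a set of motifs against peak windows
#'
#' The main analysis entry point: for every motif, builds the
#' descending-order binned score matrix over the given windows and
#' computes its adjacency score, returning the combined score table.
#'
#' @param windows A `peak_windows` object from [extract_windows()].
#' @param motifs A list of [freq_matrix()] objects (or a single one).
#' @param cfg A [scoring_config()]; its `m` must match the windows.
#' @return A `motif_ranking` data.frame (see [rank_motifs()]) with one row
#'   per motif: `rank`, `motif_id`, `S`, `S1`, `S2`, `t_star`, `r`, `b`,
#'   `n`.
#' @examples
#' spec <- synthetic_spec(seed = 7, n_peaks = 40, n_decoys = 3)
#' ds <- generate_dataset(spec)
#' w <- extract_windows(ds$genome, ds$peaks, m = spec$m)
#' score_motifs(w, ds$motifs, scoring_config(m = spec$m))
#' @export
score_motifs <- function(windows, motifs, cfg = scoring_config()) {
  if (inherits(motifs, "freq_matrix")) motifs <- list(motifs)
  if (length(motifs) == 0L) stop("empty motif set")
  L <- unique(nchar(windows$seq))
  if (length(L) != 1L || L != 2L * cfg$m)
    stop("all windows must have length 2 * m = ", 2L * cfg$m, " bp")
  codes <- vapply(windows$seq, encode_dna, integer(L), USE.NAMES = FALSE)
  results <- lapply(motifs, function(M) {
    B <- descending_matrix_from_codes(codes, M, cfg)
    adjacency_score(B, cfg)
  })
  rank_motifs(results)
}

#' Run the full pipeline on one synthetic dataset
#'
#' Convenience wrapper used in validation: generates the dataset, extracts
#' windows, scores the planted motif and all decoys, and evaluates the
#' recovery.
#'
#' @param spec A [synthetic_spec()].
#' @param cfg A [scoring_config()]; defaults to the spec's `m`.
#' @return A list: `ranking` (score table), `auc` (motif-level AUC of the
#'   planted-vs-decoy labels), `planted_rank` (the planted motif's rank),
#'   `labels`, `truth`.
#' @export
run_synthetic <- function(spec, cfg = scoring_config(m = spec$m)) {
  stopifnot(cfg$m == spec$m)
  ds <- generate_dataset(spec)
  w <- extract_windows(ds$genome, ds$peaks, m = spec$m)
  ranking <- score_motifs(w, ds$motifs, cfg)
  list(ranking = ranking,
       auc = roc_auc(ranking, ds$labels),
       planted_rank = ranking$rank[ranking$motif_id == spec$planted_motif$id],
       labels = ds$labels, truth = ds$truth)
}

#' Pipeline commands
#'
#' File-based entry points mirroring the command-line interface
#' (`inst/cli/cotfscan.R`): `cmd_score` scans a genome/peaks/motifs triple
#' and writes the score table, `cmd_eval` computes AUC and ROC points from
#' a score table and labels, `cmd_simulate` writes a synthetic dataset.
#' All outputs are plain TSV and deterministic given inputs and
#' configuration.
#'
#' @param genome,peaks,motifs Paths to the genome FASTA, peak file and
#'   TRANSFAC motif file.
#' @param out Output path (score TSV for `cmd_score`, ROC TSV for
#'   `cmd_eval`).
#' @param cfg A [scoring_config()].
#' @param scores,labels Paths to a score TSV (from `cmd_score`) and a
#'   label TSV.
#' @param by_family Evaluate at family level (per-family best score)
#'   instead of motif level.
#' @param spec A [synthetic_spec()].
#' @param dir Output directory for `cmd_simulate`.
#' @return `cmd_score` the ranking (invisibly); `cmd_eval` the AUC;
#'   `cmd_simulate` the dataset paths (invisibly).
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_score <- function(genome, peaks, motifs, out, cfg = scoring_config()) {
  for (f in c(genome, peaks, motifs))
    if (!file.exists(f)) stop("input file not found: ", f)
  mot <- read_transfac(motifs)
  if (length(mot) == 0L) stop("no motifs parsed from ", motifs)
  w <- extract_windows(genome, read_peaks(peaks), m = cfg$m)
  ranking <- score_motifs(w, mot, cfg)
  utils::write.table(ranking, out, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", nrow(ranking), " motif scores to ", out)
  invisible(ranking)
}

#' @rdname pipeline-commands
#' @export
cmd_eval <- function(scores, labels, out = NULL, by_family = FALSE) {
  ranking <- utils::read.table(scores, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  lab <- read_labels(labels)
  if (by_family) {
    fam <- group_by_family(ranking, lab)
    ranking <- data.frame(motif_id = fam$family, S = fam$best_score)
    lab <- data.frame(motif_id = fam$family, label = fam$label)
  }
  auc <- roc_auc(ranking, lab)
  if (!is.null(out))
    utils::write.table(roc_curve(ranking, lab), out, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cat(format(auc), "\n")
  invisible(auc)
}

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(spec, dir) {
  ds <- generate_dataset(spec, dir = dir)
  message("wrote synthetic dataset (", spec$n_peaks, " peaks, ",
          length(spec$decoys), " decoys) to ", dir)
  invisible(ds$paths)
}
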