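#' Read ChIP-seq peak points
#'
#' Reads a BED-like tab-separated peak file. Two layouts are accepted per
#' line: `chrom<TAB>position` (a peak point, taken as a 1-based genomic
#' coordinate) or a 3+-column BED interval `chrom<TAB>start<TAB>end`, whose
#' position is the interval midpoint `floor((start + end) / 2)` — this
#' covers both summit files and plain peak intervals. Lines starting with
#' `#` are skipped.
#'
#' @param file Path to the peak file.
#' @return A data.frame with columns `chrom` (character) and `pos`
#'   (integer, 1-based), in file order.
#' @export
read_peaks <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pos <- vapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    if (length(f) < 2L)
      stop("peak file line ", k, ": expected at least 2 tab-separated fields")
    v <- suppressWarnings(as.numeric(f[2:min(3L, length(f))]))
    if (anyNA(v) || any(v != floor(v)))
      stop("peak file line ", k, ": non-integer position")
    if (length(f) >= 3L && !is.na(v[2L])) floor((v[1L] + v[2L]) / 2) else v[1L]
  }, numeric(1))
  if (any(pos < 1))
    stop("peak file line ", which(pos < 1)[1L], ": position must be >= 1")
  data.frame(chrom = vapply(fields, `[`, character(1), 1L),
             pos = as.integer(pos))
}

#' Extract fixed-width sequence windows around peak points
#'
#' For each peak point `p` the window covers the genomic interval
#' `[p - m, p + m)` (half-open, so exactly `2 m` bases, e.g. peak 3053033
#' with `m = 1000` gives start 3052033 and length 2000); the peak point
#' itself sits at 0-based offset `m` inside the window. Peaks whose window
#' would run off the contig, or whose chromosome is absent from the
#' genome, are skipped with a warning rather than truncated or padded, so
#' every window contributes the same number of placements to each distance
#' bin.
#'
#' @param genome A genome as a [Biostrings::DNAStringSet], a named
#'   character vector of contig sequences, or a path to a FASTA file.
#'   FASTA names are truncated at the first whitespace.
#' @param peaks Data.frame with columns `chrom`, `pos` (see [read_peaks()]).
#' @param m Half-window size in bp (default 1000).
#' @return An object of class `peak_windows`: a data.frame with columns
#'   `chrom`, `peak`, `start`, `end` (the `[p - m, p + m)` interval) and
#'   `seq` (upper-case window sequence of length `2 m`), with the
#'   half-window stored in attribute `m`.
#' @export
extract_windows <- function(genome, peaks, m = 1000L) {
  stopifnot(is.data.frame(peaks), all(c("chrom", "pos") %in% names(peaks)))
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be a positive half-window in bp")
  genome <- as_genome(genome)
  clen <- vapply(genome, nchar, integer(1))

  chrom <- as.character(peaks$chrom)
  pos <- as.integer(peaks$pos)
  known <- chrom %in% names(genome)
  if (any(!known))
    warning(sum(!known), " peak(s) on contigs absent from the genome; skipped")
  # window occupies 1-based positions [p - m, p + m - 1]
  inside <- known
  inside[known] <- pos[known] - m >= 1L & pos[known] + m - 1L <= clen[chrom[known]]
  if (any(known & !inside))
    warning(sum(known & !inside), " peak(s) too close to a contig edge; skipped")

  chrom <- chrom[inside]; pos <- pos[inside]
  seqs <- toupper(substring(genome[chrom], pos - m, pos + m - 1L))
  out <- data.frame(chrom = chrom, peak = pos, start = pos - m, end = pos + m,
                    seq = unname(seqs))
  attr(out, "m") <- m
  class(out) <- c("peak_windows", "data.frame")
  out
}

# Normalize the genome argument to a named character vector of contigs.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
             file.exists(genome)) {
    g <- as.character(Biostrings::readDNAStringSet(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    g <- genome
  } else {
    stop("`genome` must be a DNAStringSet, a named character vector, ",
         "or a FASTA file path")
  }
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
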