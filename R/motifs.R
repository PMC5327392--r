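#' Frequency matrix for a DNA binding motif
#'
#' A `freq_matrix` holds a motif's per-position nucleotide frequency table:
#' a 4 x l numeric matrix with rows A, C, G, T whose columns each sum to 1.
#' It is the probabilistic model of a transcription factor's binding
#' preference used throughout the package for log-odds scanning.
#'
#' @param id Motif identifier (e.g. a TRANSFAC accession such as
#'   `"V$MYOD_01"`).
#' @param mat 4 x l numeric matrix of frequencies or counts; rows must be
#'   named (or ordered) A, C, G, T. Columns not summing to 1 are normalized
#'   by their column sum, so count matrices are accepted directly.
#' @return An object of class `freq_matrix`: a list with elements `id`,
#'   `mat` (the normalized 4 x l matrix), and `pseudocount` (the pseudocount
#'   frequency already applied, or 0).
#' @examples
#' m <- freq_matrix("toy", matrix(c(1, 2, 1, 1), 4, 1))
#' m$mat  # column (0.2, 0.4, 0.2, 0.2)
#' @export
freq_matrix <- function(id, mat) {
  if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) != 4L || ncol(mat) < 1L)
    stop("`mat` must be a numeric 4 x l matrix with l >= 1")
  if (anyNA(mat) || any(mat < 0))
    stop("motif '", id, "': matrix entries must be non-negative and non-missing")
  if (is.null(rownames(mat))) {
    rownames(mat) <- DNA_BASES
  } else {
    rn <- toupper(rownames(mat))
    if (!setequal(rn, DNA_BASES))
      stop("motif '", id, "': rownames must be A, C, G, T")
    mat <- mat[match(DNA_BASES, rn), , drop = FALSE]
    rownames(mat) <- DNA_BASES
  }
  cs <- colSums(mat)
  if (any(cs <= 0))
    stop("motif '", id, "': column ", which(cs <= 0)[1L], " sums to zero")
  mat <- sweep(mat, 2L, cs, "/")
  structure(list(id = as.character(id), mat = mat, pseudocount = 0),
            class = "freq_matrix")
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.freq_matrix <- function(x, ...) {
  cat("Motif frequency matrix '", x$id, "' (", ncol(x$mat), " bp",
      if (x$pseudocount > 0) paste0(", pseudocount ", x$pseudocount),
      ")\n", sep = "")
  print(round(x$mat, 3))
  invisible(x)
}

#' Motif length in bases
#' @param M A [freq_matrix()].
#' @return Integer number of motif positions.
#' @export
motif_length <- function(M) ncol(M$mat)

#' Parse TRANSFAC flat-file motif matrices
#'
#' Reads the TRANSFAC matrix dialect: blocks introduced by `AC`/`ID` lines,
#' a `P0` (or `PO`) column header naming the four nucleotides, numbered rows
#' of four numeric cells (an optional trailing consensus letter is ignored),
#' terminated by `//`. Count matrices and frequency matrices are both
#' accepted: each column is normalized by its own sum, which leaves true
#' frequency columns unchanged up to rounding. Columns for ambiguous
#' nucleotides beyond A/C/G/T (some dialects add an `N` column) are dropped
#' with a warning.
#'
#' @param file Path to a TRANSFAC flat file, or its content as a single
#'   string / character vector of lines (anything containing a newline or of
#'   length > 1 is treated as content).
#' @return A list of [freq_matrix()] objects, in file order. Empty input
#'   gives an empty list.
#' @seealso [write_transfac()], [write_motif_tsv()]
#' @examples
#' txt <- c("ID toy", "P0 A C G T", "01 1 2 1 1", "//")
#' read_transfac(txt)[[1]]$mat
#' @export
read_transfac <- function(file) {
  lines <- if (length(file) > 1L || !nzchar(file[1L]) ||
               grepl("\n", file[1L], fixed = TRUE)) {
    unlist(strsplit(paste(file, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    readLines(file, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)

  motifs <- list()
  block <- list(id = NULL, ac = NULL, header = NULL, rows = list(),
                first_line = NA_integer_)
  n_dropped_cols <- 0L

  flush_block <- function(block, lineno) {
    if (is.null(block$header) && length(block$rows) == 0L &&
        is.null(block$id) && is.null(block$ac))
      return(NULL)
    if (is.null(block$header))
      stop("TRANSFAC block starting at line ", block$first_line,
           ": missing P0 header")
    if (length(block$rows) == 0L)
      stop("TRANSFAC block starting at line ", block$first_line,
           ": no matrix rows before line ", lineno)
    mat <- do.call(cbind, block$rows)
    rownames(mat) <- block$header[block$header %in% DNA_BASES]
    id <- block$id %||% block$ac %||% paste0("matrix_", length(motifs) + 1L)
    freq_matrix(id, mat)
  }

  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(trimws(ln))) next
    fields <- strsplit(trimws(ln), "\\s+")[[1L]]
    tag <- fields[1L]
    if (is.na(block$first_line)) block$first_line <- k

    if (tag == "//") {
      m <- flush_block(block, k)
      if (!is.null(m)) motifs[[length(motifs) + 1L]] <- m
      block <- list(id = NULL, ac = NULL, header = NULL, rows = list(),
                    first_line = NA_integer_)
    } else if (tag == "ID") {
      block$id <- fields[2L]
    } else if (tag == "AC") {
      block$ac <- fields[2L]
    } else if (tag %in% c("P0", "PO")) {
      hdr <- toupper(fields[-1L])
      keep <- hdr %in% DNA_BASES
      if (any(!keep)) n_dropped_cols <- n_dropped_cols + sum(!keep)
      if (!setequal(hdr[keep], DNA_BASES))
        stop("TRANSFAC block starting at line ", block$first_line,
             ": P0 header at line ", k, " must name A, C, G and T")
      block$header <- hdr
    } else if (grepl("^[0-9]+$", tag)) {
      if (is.null(block$header))
        stop("TRANSFAC block starting at line ", block$first_line,
             ": matrix row at line ", k, " before P0 header")
      cells <- fields[-1L]
      # trailing consensus letter is optional
      if (length(cells) == length(block$header) + 1L &&
          grepl("^[A-Za-z]$", cells[length(cells)]))
        cells <- cells[-length(cells)]
      if (length(cells) != length(block$header))
        stop("TRANSFAC block starting at line ", block$first_line,
             ": row at line ", k, " has ", length(cells),
             " cells, expected ", length(block$header))
      vals <- suppressWarnings(as.numeric(cells))
      if (anyNA(vals))
        stop("TRANSFAC block starting at line ", block$first_line,
             ": non-numeric cell at line ", k)
      keep <- block$header %in% DNA_BASES
      block$rows[[length(block$rows) + 1L]] <- vals[keep]
    }
    # other tags (XX, NA, DE, BF, CC, ...) are annotation; skipped
  }
  # final block without trailing //
  m <- flush_block(block, length(lines) + 1L)
  if (!is.null(m)) motifs[[length(motifs) + 1L]] <- m
  if (n_dropped_cols > 0L)
    warning("dropped ", n_dropped_cols,
            " non-ACGT nucleotide column(s) from P0 header(s)")
  motifs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write motifs in TRANSFAC flat-file format
#'
#' Serializes frequency matrices back to the TRANSFAC matrix dialect with
#' full numeric precision, so that a parse/write/parse round trip preserves
#' frequencies exactly.
#'
#' @param motifs A [freq_matrix()] or list of them.
#' @param file Output path or connection.
#' @return `file`, invisibly.
#' @export
write_transfac <- function(motifs, file) {
  if (inherits(motifs, "freq_matrix")) motifs <- list(motifs)
  out <- unlist(lapply(motifs, function(M) {
    rows <- vapply(seq_len(ncol(M$mat)), function(p) {
      paste(c(sprintf("%02d", p),
              format(M$mat[, p], digits = 17, scientific = FALSE)),
            collapse = "\t")
    }, character(1))
    c(paste("ID", M$id), "XX", paste("P0", "A", "C", "G", "T", sep = "\t"),
      rows, "XX", "//")
  }))
  writeLines(out, file)
  invisible(file)
}

#' Write a normalized motif table as TSV
#'
#' Long-format inspection output: one row per motif position with columns
#' `motif_id`, `position`, `A`, `C`, `G`, `T`.
#'
#' @inheritParams write_transfac
#' @return `file`, invisibly.
#' @export
write_motif_tsv <- function(motifs, file) {
  if (inherits(motifs, "freq_matrix")) motifs <- list(motifs)
  tabs <- lapply(motifs, function(M) {
    data.frame(motif_id = M$id, position = seq_len(ncol(M$mat)),
               t(M$mat), check.names = FALSE)
  })
  utils::write.table(do.call(rbind, tabs), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Apply a pseudocount to a frequency matrix
#'
#' Mixes each frequency with a small constant, `(f + eps) / (1 + 4 * eps)`,
#' so every entry is strictly positive and the log-odds score is bounded.
#' Columns still sum to 1 and the per-column most frequent nucleotide is
#' unchanged.
#'
#' @param M A [freq_matrix()].
#' @param eps Pseudocount frequency, > 0. Default 0.001: small enough not
#'   to perturb score rankings, large enough to bound `log` terms.
#' @return A new `freq_matrix` with `pseudocount` recorded.
#' @export
apply_pseudocount <- function(M, eps = 1e-3) {
  stopifnot(inherits(M, "freq_matrix"))
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("`eps` must be a positive number")
  M$mat <- (M$mat + eps) / (1 + 4 * eps)
  M$pseudocount <- M$pseudocount + eps
  M
}

#' Reverse complement of a frequency matrix
#'
#' Reverses the column order and swaps the A/T and C/G rows, giving the
#' motif model of the opposite strand. Applying it twice returns the
#' original matrix.
#'
#' @param M A [freq_matrix()].
#' @return The reverse-complement `freq_matrix` (same id).
#' @export
reverse_complement <- function(M) {
  stopifnot(inherits(M, "freq_matrix"))
  M$mat <- M$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(M$mat))), drop = FALSE]
  rownames(M$mat) <- DNA_BASES
  M
}
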