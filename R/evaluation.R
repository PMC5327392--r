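#' Rank motifs by adjacency score
#'
#' Orders motifs by decreasing final score `S`; equal scores are broken
#' lexicographically by motif id so the ranking is deterministic.
#'
#' @param results A list of `adjacency_result` objects, or a data.frame
#'   with columns `motif_id` and `S`.
#' @return A data.frame of class `motif_ranking` with columns `rank`,
#'   `motif_id`, `S` (plus any other score columns present).
#' @export
rank_motifs <- function(results) {
  if (is.data.frame(results)) {
    tab <- results
  } else {
    stopifnot(length(results) >= 1L)
    tab <- do.call(rbind, lapply(results, function(x) {
      data.frame(motif_id = x$motif_id, S = x$S, S1 = x$S1, S2 = x$S2,
                 t_star = x$t_star, r = x$r, b = x$b, n = x$n)
    }))
  }
  stopifnot(all(c("motif_id", "S") %in% names(tab)))
  if (anyDuplicated(tab$motif_id))
    stop("duplicate motif_id in results: ",
         tab$motif_id[duplicated(tab$motif_id)][1L])
  tab <- tab[order(-tab$S, tab$motif_id), , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  class(tab) <- c("motif_ranking", "data.frame")
  tab
}

#' Read a motif label table
#'
#' Tab-separated file with columns `motif_id`, `family`, `label`
#' (`pos`/`neg`, `positive`/`negative` also accepted), with or without a
#' header line.
#'
#' @param file Path to the label TSV.
#' @return Data.frame with columns `motif_id`, `family`, `label` where
#'   `label` is `"pos"` or `"neg"`.
#' @export
read_labels <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) stop("label file needs 3 columns: motif_id, family, label")
  if (tolower(tab[1L, 3L]) %in% c("label", "class")) tab <- tab[-1L, , drop = FALSE]
  names(tab)[1:3] <- c("motif_id", "family", "label")
  lab <- tolower(tab$label)
  lab[lab %in% c("positive", "1", "true")] <- "pos"
  lab[lab %in% c("negative", "0", "false")] <- "neg"
  if (!all(lab %in% c("pos", "neg")))
    stop("labels must be pos/neg; got: ",
         paste(unique(tab$label[!lab %in% c("pos", "neg")]), collapse = ", "))
  tab$label <- lab
  if (anyDuplicated(tab$motif_id))
    stop("duplicate motif_id in label file")
  tab[, c("motif_id", "family", "label")]
}

#' Area under the ROC curve of a motif ranking
#'
#' Computes AUC by the rank-sum (Mann-Whitney) formulation: the
#' probability that a randomly chosen positive motif outscores a randomly
#' chosen negative one, with ties counted 1/2. This equals the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param ranking A `motif_ranking` (or any data.frame with `motif_id`,
#'   `S`).
#' @param labels Data.frame with `motif_id` and `label` (`"pos"`/`"neg"`),
#'   see [read_labels()]. Motifs missing from either side are dropped with
#'   a warning.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(ranking, labels) {
  j <- match(ranking$motif_id, labels$motif_id)
  if (anyNA(j) || !all(labels$motif_id %in% ranking$motif_id)) {
    miss <- c(ranking$motif_id[is.na(j)],
              setdiff(labels$motif_id, ranking$motif_id))
    warning("excluding ", length(miss), " motif(s) without both score and ",
            "label: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  keep <- !is.na(j)
  if (!any(keep)) stop("no motif has both a score and a label")
  s <- ranking$S[keep]
  pos <- labels$label[j[keep]] == "pos"
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L)
    stop("AUC undefined: need at least one positive and one negative motif")
  rk <- rank(s)  # ascending midranks; ties get the average rank
  (sum(rk[pos]) - P * (P + 1) / 2) / (P * N)
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data.frame with columns `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1), suitable for plotting or TSV export.
#' @export
roc_curve <- function(ranking, labels) {
  j <- match(ranking$motif_id, labels$motif_id)
  keep <- !is.na(j)
  s <- ranking$S[keep]
  pos <- labels$label[j[keep]] == "pos"
  o <- order(-s)
  s <- s[o]; pos <- pos[o]
  # one ROC point per distinct threshold (scores >= threshold are called)
  last <- c(s[-1L] != s[-length(s)], TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cumsum(!pos)[last] / sum(!pos)),
             tpr = c(0, cumsum(pos)[last] / sum(pos)))
}

#' Best rank and score per motif family
#'
#' Collapses a motif-level ranking to families: each family is represented
#' by its best-ranked member. Motifs without a family annotation form
#' singleton families named by their motif id.
#'
#' @inheritParams roc_auc
#' @param labels Data.frame with `motif_id` and `family` (and optionally
#'   `label`).
#' @return Data.frame with columns `family`, `best_rank`, `best_score`,
#'   `best_motif`, and `label` when available, sorted by `best_rank`.
#' @export
group_by_family <- function(ranking, labels) {
  fam <- labels$family[match(ranking$motif_id, labels$motif_id)]
  fam[is.na(fam) | !nzchar(fam)] <- ranking$motif_id[is.na(fam) | !nzchar(fam)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(ranking)), fam), function(ix) {
    best <- ix[which.min(ranking$rank[ix])]
    data.frame(family = fam[best], best_rank = ranking$rank[best],
               best_score = ranking$S[best], best_motif = ranking$motif_id[best])
  }))
  if ("label" %in% names(labels)) {
    out$label <- labels$label[match(out$best_motif, labels$motif_id)]
  }
  out <- out[order(out$best_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
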