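#' Pairwise Pearson correlation between replicate LFC vectors
#'
#' @param lfc Numeric matrix (guides x replicates), e.g. from
#'   [lfc_matrix()]. Guides missing in either member of a pair are dropped
#'   for that pair (pairwise-complete).
#' @return Data frame with columns \code{replicate_a}, \code{replicate_b},
#'   \code{pearson_r}, one row per unordered replicate pair. A
#'   zero-variance vector yields \code{NA} with a warning.
#' @export
replicate_correlation <- function(lfc) {
  stopifnot(is.matrix(lfc))
  reps <- colnames(lfc)
  if (length(reps) < 2L) stop("need >= 2 replicates", call. = FALSE)
  pairs <- utils::combn(reps, 2L)
  r <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- lfc[, pairs[1L, i]]
    b <- lfc[, pairs[2L, i]]
    ok <- !is.na(a) & !is.na(b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      warning(sprintf("zero-variance LFC vector in pair (%s, %s); r is NA",
                      pairs[1L, i], pairs[2L, i]), call. = FALSE)
      r[i] <- NA_real_
    } else {
      r[i] <- stats::cor(a[ok], b[ok])
    }
  }
  data.frame(replicate_a = pairs[1L, ], replicate_b = pairs[2L, ],
             pearson_r = r, stringsAsFactors = FALSE)
}

#' Essential-gene dropout AUC-ROC
#'
#' Quantifies how well known essential genes drop out of a screen: genes
#' are ranked by dropout score (negative mean LFC; stronger dropout ranks
#' higher) and the area under the ROC curve against the essential/
#' non-essential labels is computed with the rank (Mann-Whitney) formula,
#' using midranks for ties. An AUC near 1 means essential genes dominate
#' the strongest dropouts; 0.5 is chance.
#'
#' @param gene_lfc Named numeric vector of per-gene mean LFCs.
#' @param essential_genes Character vector of essential gene ids (the
#'   standard); ids absent from \code{gene_lfc} are ignored and counted.
#' @return List with \code{auc}, \code{n_essential} and
#'   \code{n_nonessential} (genes of each label present in the screen) and
#'   \code{n_standard_missing} (standard genes not in the screen).
#' @export
essential_auc <- function(gene_lfc, essential_genes) {
  stopifnot(!is.null(names(gene_lfc)))
  gene_lfc <- gene_lfc[!is.na(gene_lfc)]
  present <- intersect(essential_genes, names(gene_lfc))
  n_missing <- length(setdiff(essential_genes, names(gene_lfc)))
  if (length(present) == 0L) {
    stop("essential standard is disjoint from the screened genes",
         call. = FALSE)
  }
  labels <- names(gene_lfc) %in% present
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_neg == 0L) {
    stop("no non-essential genes present; AUC undefined", call. = FALSE)
  }
  score <- -gene_lfc                       # stronger dropout = higher score
  rk <- rank(score, ties.method = "average")
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(auc = auc, n_essential = n_pos, n_nonessential = n_neg,
       n_standard_missing = n_missing)
}

#' Screen quality-control report
#'
#' Combines the two screen diagnostics: pairwise replicate Pearson
#' correlations of guide-level LFC vectors (per context) and the
#' essential-gene dropout AUC-ROC on gene-level mean LFCs (per context).
#'
#' @param lfc Long LFC data frame from [guide_lfc()].
#' @param library A \code{guide_library}.
#' @param essential_genes Character vector: the essential-gene standard.
#' @param aggregate Gene-level aggregation of guide LFCs for the AUC:
#'   \code{"mean"} (default) or \code{"median"}.
#' @return List of class \code{qc_report}: \code{replicate_correlation}
#'   (data frame with a \code{context} column) and \code{essential_auc}
#'   (per-context list from [essential_auc()]).
#' @export
qc_report <- function(lfc, library, essential_genes, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  contexts <- unique(lfc$context)
  cors <- list()
  aucs <- list()
  for (ctx in contexts) {
    m <- lfc_matrix(lfc, ctx)
    cc <- replicate_correlation(m)
    cc$context <- ctx
    cors[[ctx]] <- cc
    guide_mean <- rowMeans(m, na.rm = TRUE)
    gene <- stats::setNames(library$gene_id, library$guide_id)[names(guide_mean)]
    gene_lfc <- tapply(guide_mean, gene, agg_fun)
    aucs[[ctx]] <- essential_auc(
      stats::setNames(as.numeric(gene_lfc), names(gene_lfc)),
      essential_genes)
  }
  rc <- do.call(rbind, cors)
  row.names(rc) <- NULL
  out <- list(replicate_correlation = rc, essential_auc = aucs)
  class(out) <- "qc_report"
  out
}
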