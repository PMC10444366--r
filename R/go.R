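#' Build a gene-set index restricted to the screened library
#'
#' Intersects every term's member list with the library gene set and drops
#' terms left with fewer than \code{min_genes} members, mirroring the
#' minimum-representation filter applied before gene-set summarization.
#'
#' @param annotations Data frame with columns \code{term_id},
#'   \code{gene_id} and optional \code{term_name} (one row per pair).
#' @param library_genes Character vector of library gene ids.
#' @param min_genes Minimum library members per retained term (default 3).
#' @return A list of class \code{term_index}: \code{members} (named list,
#'   term id -> character vector of library genes) and \code{names}
#'   (named character vector of term names, \code{NA} when absent), with
#'   attributes \code{n_input_terms} and \code{n_retained}.
#' @export
build_term_index <- function(annotations, library_genes, min_genes = 3) {
  if (nrow(annotations) == 0L) {
    stop("empty annotation table", call. = FALSE)
  }
  ann <- annotations[annotations$gene_id %in% library_genes, , drop = FALSE]
  all_terms <- unique(annotations$term_id)
  members <- lapply(split(ann$gene_id, ann$term_id), unique)
  members <- members[vapply(members, length, integer(1L)) >= min_genes]
  nm <- stats::setNames(rep(NA_character_, length(members)), names(members))
  if (!is.null(annotations$term_name)) {
    lut <- annotations[!duplicated(annotations$term_id),
                       c("term_id", "term_name")]
    hit <- match(names(members), lut$term_id)
    nm[] <- lut$term_name[hit]
  }
  out <- list(members = members, names = nm)
  attr(out, "n_input_terms") <- length(all_terms)
  attr(out, "n_retained") <- length(members)
  class(out) <- "term_index"
  out
}

#' Gene-set z-scores over gene-level GI scores
#'
#' Summarizes the direction and strength of genetic interactions within
#' each gene set with
#' \deqn{z = \frac{\bar{x} - \mu}{\sigma / \sqrt{n}},}
#' where \eqn{\bar{x}} is the mean GI score of the term's member genes,
#' \eqn{\mu} and \eqn{\sigma} are the mean and sample standard deviation of
#' GI scores across all scored library genes, and \eqn{n} is the number of
#' member genes with a score. Two-tailed p-values come from the standard
#' normal distribution and are BH-adjusted.
#'
#' @param gi Named numeric vector: gene-level GI scores (names = gene ids);
#'   only genes with non-\code{NA} scores enter the background and terms.
#' @param index A \code{term_index} from [build_term_index()].
#' @return Data frame sorted by p-value with columns \code{term_id},
#'   \code{term_name}, \code{n}, \code{x_bar}, \code{mu}, \code{sigma},
#'   \code{z}, \code{p}, \code{fdr}.
#' @export
term_zscores <- function(gi, index) {
  stopifnot(inherits(index, "term_index"), !is.null(names(gi)))
  gi <- gi[!is.na(gi)]
  mu <- mean(gi)
  sigma <- stats::sd(gi)
  if (!is.finite(sigma) || sigma == 0) {
    stop("standard deviation of GI scores is zero; z undefined",
         call. = FALSE)
  }
  terms <- names(index$members)
  n <- integer(length(terms))
  x_bar <- numeric(length(terms))
  for (i in seq_along(terms)) {
    mem <- intersect(index$members[[i]], names(gi))
    n[i] <- length(mem)
    x_bar[i] <- if (n[i] > 0L) mean(gi[mem]) else NA_real_
  }
  keep <- n > 0L
  z <- (x_bar - mu) / (sigma / sqrt(n))
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(term_id = terms, term_name = as.character(index$names),
                    n = n, x_bar = x_bar, mu = mu, sigma = sigma,
                    z = z, p = p, stringsAsFactors = FALSE,
                    row.names = NULL)[keep, , drop = FALSE]
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  row.names(out) <- NULL
  out
}
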