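#' Guide-level genetic-interaction scores
#'
#' The GI score of a guide is the difference between its replicate-averaged
#' normalized LFC in the mutant context and in the control context.
#' Negative scores mean the knockout drops out faster in the mutant
#' (synthetic sick/lethal); positive scores mean loss of the gene buffers
#' the mutant's fitness defect.
#'
#' @param averaged Long data frame from [average_replicates()] (columns
#'   \code{guide_id}, \code{context}, \code{lfc}).
#' @param library A \code{guide_library} mapping guides to genes.
#' @return A data frame with columns \code{guide_id}, \code{gene_id},
#'   \code{gi}. Guides present in only one context are excluded with a
#'   warning.
#' @export
guide_gi_scores <- function(averaged, library) {
  ctrl <- averaged[averaged$context == "control", ]
  mut <- averaged[averaged$context == "mutant", ]
  common <- intersect(ctrl$guide_id, mut$guide_id)
  only_one <- setdiff(union(ctrl$guide_id, mut$guide_id), common)
  if (length(only_one) > 0L) {
    warning(length(only_one),
            " guide(s) present in one context only were excluded",
            call. = FALSE)
  }
  gi <- stats::setNames(mut$lfc, mut$guide_id)[common] -
    stats::setNames(ctrl$lfc, ctrl$guide_id)[common]
  gene <- stats::setNames(library$gene_id, library$guide_id)[common]
  if (any(is.na(gene))) {
    stop("guide(s) missing from the library: ",
         paste(common[is.na(gene)][1:min(5, sum(is.na(gene)))],
               collapse = ", "), call. = FALSE)
  }
  data.frame(guide_id = common, gene_id = as.character(gene),
             gi = as.numeric(gi), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Empirical-Bayes moderated one-sample t-test on guide GI scores
#'
#' Tests, per gene, whether the mean of its guide-level GI scores differs
#' from zero. Per-gene sample variances are shrunk toward a common prior
#' variance \code{s0^2} with prior degrees of freedom \code{d0}, both
#' estimated across all genes by matching moments of the log sample
#' variances to a log scaled-F distribution (digamma/trigamma matching).
#' The moderated statistic is
#' \deqn{t = \bar{g} / \sqrt{s^2_{post}/k}, \quad
#'       s^2_{post} = \frac{d_0 s_0^2 + (k-1) s^2}{d_0 + k - 1},}
#' with \eqn{d_0 + k - 1} degrees of freedom, where \eqn{k} is the number
#' of guides for the gene. With \code{prior_df = 0} this reduces exactly to
#' the classical one-sample t; with \code{prior_df = Inf} every gene uses
#' the common prior variance.
#'
#' @param scores Data frame from [guide_gi_scores()] (columns
#'   \code{gene_id}, \code{gi}).
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (e.g. \code{0} for the classical t). Default \code{NULL}:
#'   estimate from the data.
#' @return A list of class \code{moderated_fit} with elements
#'   \code{prior_df}, \code{prior_var}, and \code{table}: a data frame with
#'   one row per gene (\code{gene_id}, \code{n_guides}, \code{gi_score},
#'   \code{s2}, \code{s2_post}, \code{t}, \code{df}, \code{p}). Genes with
#'   a single guide keep their \code{gi_score} but get \code{NA} statistics.
#' @export
fit_moderated_test <- function(scores, prior_df = NULL) {
  genes <- unique(scores$gene_id)
  k <- as.integer(table(scores$gene_id)[genes])
  mean_gi <- as.numeric(tapply(scores$gi, scores$gene_id, mean)[genes])
  s2 <- as.numeric(tapply(scores$gi, scores$gene_id, stats::var)[genes])
  testable <- k >= 2L
  if (!any(testable)) {
    stop("no gene has >= 2 guides; cannot estimate variances", call. = FALSE)
  }
  if (all(s2[testable] == 0)) {
    stop("all per-gene variances are zero; degenerate moment fit",
         call. = FALSE)
  }
  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2[testable], k[testable] - 1L)
    d0 <- fit$prior_df
    s02 <- fit$prior_var
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) {
      fit_variance_prior(s2[testable], k[testable] - 1L)$prior_var
    } else NA_real_
  }
  s2_post <- rep(NA_real_, length(genes))
  t_mod <- rep(NA_real_, length(genes))
  df_total <- rep(NA_real_, length(genes))
  p <- rep(NA_real_, length(genes))
  i <- which(testable)
  if (is.infinite(d0)) {
    s2_post[i] <- s02
    df_total[i] <- Inf
  } else if (d0 == 0) {
    s2_post[i] <- s2[i]
    df_total[i] <- k[i] - 1
  } else {
    s2_post[i] <- (d0 * s02 + (k[i] - 1) * s2[i]) / (d0 + k[i] - 1)
    df_total[i] <- d0 + k[i] - 1
  }
  t_mod[i] <- mean_gi[i] / sqrt(s2_post[i] / k[i])
  p[i] <- 2 * stats::pt(-abs(t_mod[i]), df = df_total[i])
  out <- list(prior_df = d0, prior_var = s02,
              table = data.frame(gene_id = genes, n_guides = k,
                                 gi_score = mean_gi, s2 = s2,
                                 s2_post = s2_post, t = t_mod,
                                 df = df_total, p = p,
                                 stringsAsFactors = FALSE,
                                 row.names = NULL))
  class(out) <- "moderated_fit"
  out
}

#' Estimate the variance prior (d0, s0^2) across genes
#'
#' Matches the first two moments of \code{log(s2)} to those of a log
#' scaled-F distribution: with \eqn{e_g = \log s^2_g - \psi(d_g/2) +
#' \log(d_g/2)}, the prior satisfies \eqn{E[e] = \log s_0^2 + \psi(d_0/2) -
#' \log(d_0/2)} and \eqn{Var[e] = \psi'(d_g/2) + \psi'(d_0/2)}. If the
#' observed spread of \code{e} does not exceed its sampling component the
#' prior degrees of freedom are infinite (all variances shrink to the
#' common value).
#'
#' @param s2 Per-gene sample variances (all with \code{df >= 1}).
#' @param df Per-gene residual degrees of freedom (k - 1).
#' @return List with \code{prior_df} and \code{prior_var}.
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(length(s2) == length(df), all(df >= 1))
  ok <- s2 > 0
  if (sum(ok) < 2L) stop("too few positive variances", call. = FALSE)
  s2 <- s2[ok]; df <- df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(prior_df = d0, prior_var = s02)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1L, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment: along ascending p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, with the
#' original order restored. \code{NA} p-values propagate as \code{NA}.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-value(s) outside [0, 1]: ",
         paste(format(p[bad][1:min(3, sum(bad))]), collapse = ", "),
         call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call genetic interactors at score and FDR thresholds
#'
#' A gene is a positive interactor when \code{fdr < fdr_threshold} and
#' \code{gi_score > gi_threshold}, a negative interactor when
#' \code{fdr < fdr_threshold} and \code{gi_score < -gi_threshold}
#' (inequalities strict), and otherwise not called. Positive means loss of
#' the gene promoted growth in the mutant relative to control; negative
#' means it reduced growth.
#'
#' @param table Data frame with columns \code{gi_score} and \code{fdr}
#'   (e.g. the moderated-fit table after [bh_adjust()]).
#' @param fdr_threshold FDR cutoff (default 0.2).
#' @param gi_threshold Absolute GI score cutoff (default 0.5).
#' @return The input with a \code{call} column added (\code{"positive"},
#'   \code{"negative"} or \code{"none"}); \code{NA} FDR yields
#'   \code{"none"}.
#' @export
call_interactors <- function(table, fdr_threshold = 0.2, gi_threshold = 0.5) {
  stopifnot(all(c("gi_score", "fdr") %in% colnames(table)))
  sig <- !is.na(table$fdr) & table$fdr < fdr_threshold
  call <- rep("none", nrow(table))
  call[sig & table$gi_score > gi_threshold] <- "positive"
  call[sig & table$gi_score < -gi_threshold] <- "negative"
  table$call <- call
  table
}
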