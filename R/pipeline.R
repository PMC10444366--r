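#' Score genetic interactions from raw counts
#'
#' Runs the full scoring pipeline: guides are filtered on their raw T0
#' abundance in every context (a guide excluded in either screen is
#' excluded from both), counts are depth-normalized, per-guide LFCs are
#' computed between the endpoint and the replicate-matched T0, mutant LFCs
#' are MA/loess-normalized against control per replicate pair, replicates
#' are averaged, guide-level GI scores are formed as normalized mutant
#' minus control LFC, gene-level scores are the mean of guide scores, and
#' genes are tested with the empirical-Bayes moderated one-sample t-test,
#' BH-corrected and called at the score/FDR thresholds.
#'
#' @param counts Integer count matrix (guides x samples) covering both
#'   contexts.
#' @param samples A \code{sample_sheet}.
#' @param library A \code{guide_library}.
#' @param endpoint_days Endpoint timepoint (default 18).
#' @param low,high Raw-count filter bounds applied to T0 samples
#'   (defaults 30 and 10000).
#' @param pseudocount Pseudocount for depth normalization (default 1).
#' @param span,bins Loess parameters (defaults 0.3 and 20).
#' @param loess Apply the MA/loess step (default \code{TRUE}); with
#'   \code{FALSE} the mutant LFCs are used untransformed (for diagnosing
#'   abundance-dependent bias).
#' @param fdr_threshold,gi_threshold Interactor call thresholds
#'   (defaults 0.2 and 0.5).
#' @param prior_df Optional moderated-test prior df override.
#' @return List of class \code{gi_screen}: \code{gene} (per-gene GIResult
#'   table with columns \code{gene_id}, \code{n_guides}, \code{gi_score},
#'   \code{t}, \code{df}, \code{p}, \code{fdr}, \code{call}), \code{guide}
#'   (per-guide GI scores), \code{fitness} (per-replicate fitness table),
#'   \code{lfc} (per-replicate raw LFC long table), \code{filter} (the
#'   guide filter mask), and \code{prior} (fitted \code{d0}, \code{s0^2}).
#' @export
score_gi_screen <- function(counts, samples, library, endpoint_days = 18,
                            low = 30, high = 10000, pseudocount = 1,
                            span = 0.3, bins = 20, loess = TRUE,
                            fdr_threshold = 0.2, gi_threshold = 0.5,
                            prior_df = NULL) {
  t0_samples <- samples$sample_id[samples$timepoint_days == 0L]
  mask <- filter_guides(counts, t0_samples, low = low, high = high)
  kept <- mask$guide_id[mask$kept]
  if (length(kept) == 0L) stop("no guides pass the abundance filter",
                               call. = FALSE)
  norm <- depth_normalize(counts, pseudocount = pseudocount)
  lfc <- guide_lfc(norm, samples, endpoint_days, guides = kept)
  lm_mut <- lfc_matrix(lfc, "mutant")
  lm_ctrl <- lfc_matrix(lfc, "control")
  if (loess) {
    fitness <- ma_loess_normalize(lm_mut, lm_ctrl, span = span, bins = bins)
  } else {
    common <- intersect(rownames(lm_mut), rownames(lm_ctrl))
    reps <- intersect(colnames(lm_mut), colnames(lm_ctrl))
    fitness <- do.call(rbind, lapply(reps, function(r) {
      M <- lm_mut[common, r] - lm_ctrl[common, r]
      data.frame(guide_id = common, replicate = r,
                 lfc_control = lm_ctrl[common, r],
                 lfc_mutant = lm_mut[common, r],
                 A = (lm_mut[common, r] + lm_ctrl[common, r]) / 2,
                 M = M, m_normalized = M,
                 lfc_mutant_normalized = lm_mut[common, r],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    class(fitness) <- c("fitness_table", "data.frame")
  }
  averaged <- average_replicates(fitness)
  guide_scores <- guide_gi_scores(averaged, library)
  fit <- fit_moderated_test(guide_scores, prior_df = prior_df)
  gene <- fit$table
  gene$fdr <- bh_adjust(gene$p)
  gene <- call_interactors(gene, fdr_threshold = fdr_threshold,
                           gi_threshold = gi_threshold)
  gene <- gene[, c("gene_id", "n_guides", "gi_score", "t", "df", "p",
                   "fdr", "call")]
  out <- list(gene = gene, guide = guide_scores, fitness = fitness,
              lfc = lfc, filter = mask,
              prior = list(prior_df = fit$prior_df,
                           prior_var = fit$prior_var))
  class(out) <- "gi_screen"
  out
}

#' @export
print.gi_screen <- function(x, ...) {
  n_pos <- sum(x$gene$call == "positive")
  n_neg <- sum(x$gene$call == "negative")
  cat("Genetic-interaction screen result\n")
  cat(sprintf("  guides kept: %d of %d\n", sum(x$filter$kept),
              nrow(x$filter)))
  cat(sprintf("  genes tested: %d\n", sum(!is.na(x$gene$p))))
  cat(sprintf("  moderated-t prior: d0 = %.3g, s0^2 = %.3g\n",
              x$prior$prior_df, x$prior$prior_var))
  cat(sprintf("  interactors called: %d positive, %d negative\n",
              n_pos, n_neg))
  invisible(x)
}
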