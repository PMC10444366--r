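#' Depth-normalize a count matrix to log2 reads per million
#'
#' Adds a pseudocount to every raw count, scales each sample column to
#' reads per million, and takes log2. The pseudocount makes fold changes
#' defined for guides that drop to zero reads.
#'
#' @param counts Integer count matrix (guides x samples).
#' @param pseudocount Positive number added to every count before scaling
#'   (default 1).
#' @return Numeric matrix of log2 pseudocounted reads-per-million, same
#'   dimnames as \code{counts}, with attributes \code{lib_size} (per-sample
#'   pseudocounted totals) and \code{pseudocount}.
#' @export
depth_normalize <- function(counts, pseudocount = 1) {
  stopifnot(is.matrix(counts), pseudocount > 0)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  pc <- counts + pseudocount
  totals <- colSums(pc)
  norm <- log2(sweep(pc, 2L, totals, "/") * 1e6)
  attr(norm, "lib_size") <- totals
  attr(norm, "pseudocount") <- pseudocount
  norm
}

#' Flag guides with out-of-range reference abundance
#'
#' Guides whose raw read count in any reference (T0) sample is below
#' \code{low} or above \code{high} are excluded from scoring. Bounds are
#' strict: counts equal to \code{low} or \code{high} are kept.
#'
#' @param counts Integer count matrix (guides x samples).
#' @param reference_samples Character vector of T0 sample ids (columns of
#'   \code{counts}) used as the abundance reference.
#' @param low Lower raw-count threshold (default 30); a guide with a count
#'   strictly below this in any reference sample is excluded.
#' @param high Upper raw-count threshold (default 10000); a guide with a
#'   count strictly above this in any reference sample is excluded.
#' @return A data frame (class \code{guide_filter_mask}) with columns
#'   \code{guide_id}, \code{kept} (logical) and \code{reason} (one of
#'   \code{"kept"}, \code{"low"}, \code{"high"}; a guide failing both
#'   bounds in different samples is reported as \code{"low"}).
#' @export
filter_guides <- function(counts, reference_samples, low = 30, high = 10000) {
  if (length(reference_samples) == 0L) {
    stop("empty reference sample set", call. = FALSE)
  }
  missing <- setdiff(reference_samples, colnames(counts))
  if (length(missing) > 0L) {
    stop("reference sample(s) not in count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref <- counts[, reference_samples, drop = FALSE]
  low_fail <- apply(ref < low, 1L, any)
  high_fail <- apply(ref > high, 1L, any)
  reason <- ifelse(low_fail, "low", ifelse(high_fail, "high", "kept"))
  out <- data.frame(guide_id = rownames(counts),
                    kept = reason == "kept",
                    reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("guide_filter_mask", "data.frame")
  out
}

#' Per-guide log2 fold change between an endpoint and T0
#'
#' Computes, for every (context, replicate), the difference in normalized
#' log2 abundance between the sample at \code{endpoint_days} and the
#' replicate-matched T0 sample. This is the guide's fitness readout: guides
#' targeting fitness genes drop out and get negative LFCs.
#'
#' @param norm Normalized matrix from [depth_normalize()].
#' @param sheet A \code{sample_sheet}.
#' @param endpoint_days Integer timepoint to compare against T0 (any
#'   sampled timepoint, e.g. 6, 12 or 18).
#' @param guides Optional character vector restricting the output to these
#'   guide ids (typically the kept guides from [filter_guides()]).
#' @return A long data frame with columns \code{guide_id}, \code{context},
#'   \code{replicate}, \code{lfc}.
#' @export
guide_lfc <- function(norm, sheet, endpoint_days, guides = NULL) {
  if (is.null(guides)) guides <- rownames(norm)
  guides <- intersect(guides, rownames(norm))
  combos <- unique(sheet[, c("context", "replicate")])
  pieces <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ctx <- combos$context[i]
    rep <- combos$replicate[i]
    t0 <- sheet$sample_id[sheet$context == ctx & sheet$replicate == rep &
                            sheet$timepoint_days == 0L]
    end <- sheet$sample_id[sheet$context == ctx & sheet$replicate == rep &
                             sheet$timepoint_days == endpoint_days]
    if (length(t0) != 1L) {
      stop(sprintf("missing T0 sample for (context '%s', replicate '%s')",
                   ctx, rep), call. = FALSE)
    }
    if (length(end) != 1L) {
      stop(sprintf("missing day-%d sample for (context '%s', replicate '%s')",
                   endpoint_days, ctx, rep), call. = FALSE)
    }
    pieces[[i]] <- data.frame(guide_id = guides,
                              context = ctx,
                              replicate = rep,
                              lfc = norm[guides, end] - norm[guides, t0],
                              stringsAsFactors = FALSE,
                              row.names = NULL)
  }
  do.call(rbind, pieces)
}

#' Reshape a long LFC table to a guides-by-replicates matrix
#'
#' @param lfc Long data frame from [guide_lfc()].
#' @param context Which context to extract (\code{"control"} or
#'   \code{"mutant"}).
#' @return Numeric matrix, guides x replicates.
#' @export
lfc_matrix <- function(lfc, context) {
  sub <- lfc[lfc$context == context, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no LFC rows for context ", context, call. = FALSE)
  reps <- sort(unique(sub$replicate))
  guides <- unique(sub$guide_id)
  out <- matrix(NA_real_, nrow = length(guides), ncol = length(reps),
                dimnames = list(guides, reps))
  for (r in reps) {
    ri <- sub[sub$replicate == r, ]
    out[ri$guide_id, r] <- ri$lfc
  }
  out
}

#' MA-transform and loess-normalize mutant against control fitness
#'
#' Per replicate pair, re-expresses the mutant and control LFCs of every
#' guide as a difference M = LFC_mutant - LFC_control and an average
#' A = (LFC_mutant + LFC_control)/2, fits a smooth trend f(A) through the
#' (A, M) cloud by locally weighted linear regression on equal-count bins
#' along A, and subtracts the trend: the normalized mutant LFC is
#' \code{lfc_control + (M - f(A))}. Control LFCs pass through unchanged.
#' This removes abundance-dependent bias between the two screens so that
#' differential fitness reflects genotype, not intensity.
#'
#' @param lfc_mutant,lfc_control Numeric matrices (guides x replicates)
#'   over the same kept guides; replicate columns are paired by label.
#' @param span Fraction of bins entering each local fit (default 0.3).
#' @param bins Number of equal-count bins along A (default 20). If fewer
#'   guides than bins are supplied, a single global median fit is used with
#'   a warning.
#' @return A long data frame (class \code{fitness_table}) with columns
#'   \code{guide_id}, \code{replicate}, \code{lfc_control},
#'   \code{lfc_mutant}, \code{A}, \code{M}, \code{m_normalized},
#'   \code{lfc_mutant_normalized}.
#' @export
ma_loess_normalize <- function(lfc_mutant, lfc_control, span = 0.3,
                               bins = 20) {
  common <- intersect(rownames(lfc_mutant), rownames(lfc_control))
  reps <- intersect(colnames(lfc_mutant), colnames(lfc_control))
  if (length(common) == 0L || length(reps) == 0L) {
    stop("mutant and control LFC matrices share no guides/replicates",
         call. = FALSE)
  }
  pieces <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    r <- reps[i]
    lm_ <- lfc_mutant[common, r]
    lc <- lfc_control[common, r]
    M <- lm_ - lc
    A <- (lm_ + lc) / 2
    f <- loess_fit_binned(A, M, span = span, bins = bins)
    m_norm <- M - f
    pieces[[i]] <- data.frame(guide_id = common,
                              replicate = r,
                              lfc_control = lc,
                              lfc_mutant = lm_,
                              A = A,
                              M = M,
                              m_normalized = m_norm,
                              lfc_mutant_normalized = lc + m_norm,
                              stringsAsFactors = FALSE,
                              row.names = NULL)
  }
  out <- do.call(rbind, pieces)
  class(out) <- c("fitness_table", "data.frame")
  out
}

#' Binned tricube local-linear trend fit
#'
#' The smoother behind [ma_loess_normalize()]: guides are sorted along A
#' and split into \code{bins} equal-count bins; each bin is summarized by
#' its median (A, M) — the median, rather than the mean, keeps the trend
#' estimate from chasing genuine interactors that form a minority within a
#' bin; the trend at every query A is then a tricube-weighted
#' linear regression over the nearest \code{ceiling(span * bins)} bin
#' summaries. Local linear fits reproduce constant and linear trends
#' exactly, so a flat or linear M-vs-A relationship is removed completely.
#'
#' @param A,M Numeric vectors of equal length.
#' @param span Fraction of bins in each local window (default 0.3).
#' @param bins Number of equal-count bins (default 20).
#' @return Numeric vector: fitted trend at each input A.
#' @export
loess_fit_binned <- function(A, M, span = 0.3, bins = 20) {
  stopifnot(length(A) == length(M), span > 0, span <= 1, bins >= 2)
  n <- length(A)
  if (n < bins) {
    warning(sprintf(
      "fewer guides (%d) than bins (%d); falling back to a global median fit",
      n, bins), call. = FALSE)
    return(rep(stats::median(M), n))
  }
  ord <- order(A)
  bin_id <- ceiling(seq_len(n) / (n / bins))
  bin_id[bin_id > bins] <- bins
  bin_a <- as.numeric(tapply(A[ord], bin_id, stats::median))
  bin_m <- as.numeric(tapply(M[ord], bin_id, stats::median))
  k <- max(2L, ceiling(span * bins))
  vapply(A, local_linear_predict, numeric(1L),
         xs = bin_a, ys = bin_m, k = k)
}

# Tricube-weighted linear regression over the k nearest anchor points,
# evaluated at x0. Falls back to a weighted mean when the local design is
# degenerate (all anchors at the same A).
local_linear_predict <- function(x0, xs, ys, k) {
  d <- abs(xs - x0)
  sel <- order(d)[seq_len(min(k, length(xs)))]
  dk <- d[sel]
  h <- max(dk)
  w <- if (h > 0) (1 - pmin(dk / h, 1)^3)^3 else rep(1, length(sel))
  w[w <= 0] <- 1e-8                       # keep the boundary anchor in play
  x <- xs[sel]
  y <- ys[sel]
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx < 1e-12) return(ybar)
  beta <- sum(w * (x - xbar) * (y - ybar)) / sxx
  ybar + beta * (x0 - xbar)
}

#' Average normalized fitness over replicates
#'
#' @param fitness A \code{fitness_table} from [ma_loess_normalize()].
#' @return A long data frame with columns \code{guide_id}, \code{context},
#'   \code{lfc}: the replicate-mean control LFC and replicate-mean
#'   normalized mutant LFC per guide. Replicates missing a guide are
#'   skipped; a guide with no value in any replicate of a context is
#'   dropped with a warning.
#' @export
average_replicates <- function(fitness) {
  mean_by_guide <- function(values, guides) {
    ok <- !is.na(values)
    if (!any(ok)) return(NULL)
    tapply(values[ok], guides[ok], mean)
  }
  ctrl <- mean_by_guide(fitness$lfc_control, fitness$guide_id)
  mut <- mean_by_guide(fitness$lfc_mutant_normalized, fitness$guide_id)
  all_guides <- unique(fitness$guide_id)
  dropped <- setdiff(all_guides, intersect(names(ctrl), names(mut)))
  if (length(dropped) > 0L) {
    warning(length(dropped),
            " guide(s) with no replicate value in a context were dropped",
            call. = FALSE)
  }
  out <- rbind(
    data.frame(guide_id = names(ctrl), context = "control",
               lfc = as.numeric(ctrl), stringsAsFactors = FALSE),
    data.frame(guide_id = names(mut), context = "mutant",
               lfc = as.numeric(mut), stringsAsFactors = FALSE))
  row.names(out) <- NULL
  out
}
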