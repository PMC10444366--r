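# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles are deliberately naive re-derivations, not calls into
# the code paths they check.

# Step-up BH by direct evaluation of q(i) = min_{j>=i} p(j)*m/j on the
# sorted p-values.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# AUC by counting wins + half-ties over all (positive, negative) pairs.
auc_bruteforce <- function(score, is_positive) {
  pos <- score[is_positive]
  neg <- score[!is_positive]
  total <- 0
  for (a in pos) {
    total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  }
  total / (length(pos) * length(neg))
}

# Tricube local-linear prediction recomputed from first principles with
# lm(); anchors are the same equal-count bin medians the implementation
# uses, so any disagreement isolates the regression arithmetic.
loess_bruteforce <- function(A, M, span, bins, query) {
  n <- length(A)
  ord <- order(A)
  bin_id <- ceiling(seq_len(n) / (n / bins))
  bin_id[bin_id > bins] <- bins
  xs <- as.numeric(tapply(A[ord], bin_id, median))
  ys <- as.numeric(tapply(M[ord], bin_id, median))
  k <- max(2L, ceiling(span * bins))
  vapply(query, function(x0) {
    d <- abs(xs - x0)
    sel <- order(d)[seq_len(min(k, length(xs)))]
    h <- max(d[sel])
    w <- if (h > 0) (1 - pmin(d[sel] / h, 1)^3)^3 else rep(1, length(sel))
    w[w <= 0] <- 1e-8
    fit <- stats::lm(y ~ x, data = data.frame(x = xs[sel], y = ys[sel]),
                     weights = w)
    unname(stats::predict(fit, newdata = data.frame(x = x0)))
  }, numeric(1L))
}

# Classical one-sample t against zero.
classical_t <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))

# Minimal two-context sample sheet: one T0 + one endpoint sample per
# context and replicate.
make_sheet <- function(contexts = c("control", "mutant"),
                       timepoints = c(0L, 18L), replicates = "A") {
  grid <- expand.grid(context = contexts, timepoint_days = timepoints,
                      replicate = replicates, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_T%02d_%s", grid$context,
                            grid$timepoint_days, grid$replicate)
  validate_sample_sheet(grid[, c("sample_id", "context", "timepoint_days",
                                 "replicate")])
}

# Small deterministic library without sequences.
make_library <- function(n_genes = 2, guides_per_gene = 3) {
  genes <- sprintf("gene%02d", seq_len(n_genes))
  validate_guide_library(data.frame(
    guide_id = as.vector(t(outer(genes, seq_len(guides_per_gene),
                                 function(g, i) paste0(g, "_g", i)))),
    gene_id = rep(genes, each = guides_per_gene),
    stringsAsFactors = FALSE))
}
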