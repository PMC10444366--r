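test_that("guide GI scores are mutant-minus-control with the screen's sign convention", {
  lib <- make_library(n_genes = 1, guides_per_gene = 3)
  avg <- data.frame(
    guide_id = rep(lib$guide_id, 2),
    context = rep(c("control", "mutant"), each = 3),
    lfc = c(-0.5, 0, -0.2,       # control
            -1.5, 0, 0.6),       # mutant
    stringsAsFactors = FALSE)
  gi <- guide_gi_scores(avg, lib)
  # stronger dropout in the mutant => negative interaction
  expect_equal(gi$gi, c(-1.0, 0, 0.8))
  expect_identical(gi$gene_id, lib$gene_id)

  # a guide present in only one context is excluded with a warning
  expect_warning(gi2 <- guide_gi_scores(avg[-1, ], lib), "one context")
  expect_identical(nrow(gi2), 2L)
})

test_that("moderated t reduces to the classical one-sample t at d0 = 0", {
  scores <- data.frame(gene_id = rep("geneA", 3),
                       gi = c(-1.0, -1.2, -0.8), stringsAsFactors = FALSE)
  # lone gene: augment with a second gene so the prior fit has >= 2 genes
  scores <- rbind(scores, data.frame(gene_id = rep("geneB", 3),
                                     gi = c(0.1, 0.3, 0.2)))
  fit <- fit_moderated_test(scores, prior_df = 0)
  row <- fit$table[fit$table$gene_id == "geneA", ]
  expect_equal(row$gi_score, -1.0)
  expect_equal(row$t, -8.6602540, tolerance = 1e-6)
  expect_equal(row$df, 2)
  expect_equal(row$p, 2 * pt(-8.6602540, df = 2), tolerance = 1e-6)

  # property: d0 = 0 equals mean/(sd/sqrt(k)) on random data
  set.seed(9)
  rnd <- data.frame(gene_id = rep(sprintf("g%03d", 1:50), each = 4),
                    gi = rnorm(200), stringsAsFactors = FALSE)
  f0 <- fit_moderated_test(rnd, prior_df = 0)
  tc <- tapply(rnd$gi, rnd$gene_id, classical_t)[f0$table$gene_id]
  expect_lt(max(abs(f0$table$t - tc)), 1e-10)
})

test_that("a zero-mean gene is never significant, whatever the shrinkage", {
  scores <- data.frame(gene_id = rep(c("g0", "g1"), each = 4),
                       gi = c(-1, 1, -2, 2, 5, 6, 7, 8),
                       stringsAsFactors = FALSE)
  for (d0 in list(NULL, 0, 5, Inf)) {
    fit <- fit_moderated_test(scores, prior_df = d0)
    row <- fit$table[fit$table$gene_id == "g0", ]
    expect_equal(row$t, 0)
    expect_equal(row$p, 1)
  }
})

test_that("posterior variances follow the shrinkage identity and limits", {
  set.seed(10)
  scores <- data.frame(gene_id = rep(sprintf("g%03d", 1:100), each = 3),
                       gi = rnorm(300, 0, rep(sqrt(0.04 * 4 / rchisq(100, 4)),
                                              each = 3)),
                       stringsAsFactors = FALSE)
  fit <- fit_moderated_test(scores)
  tb <- fit$table
  d0 <- fit$prior_df
  s02 <- fit$prior_var
  expect_true(is.finite(d0) && d0 > 0)
  expect_equal(tb$s2_post,
               (d0 * s02 + (tb$n_guides - 1) * tb$s2) / (d0 + tb$n_guides - 1))
  expect_equal(tb$df, d0 + tb$n_guides - 1)
  # d0 = Inf: every gene at the prior variance
  finf <- fit_moderated_test(scores, prior_df = Inf)
  expect_true(all(finf$table$s2_post == finf$prior_var))
})

test_that("the variance prior is recovered from simulated scaled-inv-chisq variances", {
  set.seed(11)
  d0_true <- 4
  s02_true <- 0.04
  n_genes <- 2000
  sigma2 <- d0_true * s02_true / rchisq(n_genes, d0_true)
  scores <- data.frame(
    gene_id = rep(sprintf("g%04d", seq_len(n_genes)), each = 3),
    gi = rnorm(3 * n_genes, 0, sqrt(rep(sigma2, each = 3))),
    stringsAsFactors = FALSE)
  fit <- fit_moderated_test(scores)
  expect_lt(abs(fit$prior_df - d0_true) / d0_true, 0.15)
  expect_lt(abs(fit$prior_var - s02_true) / s02_true, 0.15)
})

test_that("moderated fit agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(12)
  n_genes <- 300
  k <- 3
  sigma2 <- 0.05 * 6 / rchisq(n_genes, 6)
  mat <- matrix(rnorm(n_genes * k, 0, sqrt(rep(sigma2, k))), ncol = k)
  rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
  scores <- data.frame(gene_id = rep(rownames(mat), k),
                       gi = as.vector(mat), stringsAsFactors = FALSE)
  fit <- fit_moderated_test(scores)
  lf <- limma::eBayes(limma::lmFit(mat))
  expect_equal(fit$prior_df, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior_var, lf$s2.prior, tolerance = 1e-6)
  ord <- match(fit$table$gene_id, rownames(mat))
  expect_equal(fit$table$t, lf$t[ord, 1], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$table$p, lf$p.value[ord, 1], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("single-guide genes get a score but no p-value", {
  scores <- data.frame(gene_id = c("g1", "g1", "g1", "solo", "g2", "g2"),
                       gi = c(1, 2, 3, -0.7, 0.1, 0.4),
                       stringsAsFactors = FALSE)
  fit <- fit_moderated_test(scores)
  solo <- fit$table[fit$table$gene_id == "solo", ]
  expect_equal(solo$gi_score, -0.7)
  expect_true(is.na(solo$p))
  tbl <- call_interactors(transform(fit$table, fdr = bh_adjust(p)))
  expect_identical(tbl$call[tbl$gene_id == "solo"], "none")
})

test_that("degenerate variance structures are handled", {
  all_zero <- data.frame(gene_id = rep(c("a", "b"), each = 3),
                         gi = rep(c(1, 2), each = 3),
                         stringsAsFactors = FALSE)
  expect_error(fit_moderated_test(all_zero), "zero")

  # equal nonzero variances: infinite prior df, not an error
  eq <- data.frame(gene_id = rep(c("a", "b", "c"), each = 2),
                   gi = c(0, 1, 2, 3, 5, 6), stringsAsFactors = FALSE)
  fit <- fit_moderated_test(eq)
  expect_true(is.infinite(fit$prior_df))
  expect_true(all(is.finite(fit$table$t)))
})

test_that("BH adjustment matches brute-force step-up evaluation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }

  # monotone along ascending p, invariant to permutation
  p <- sort(runif(30))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= 0))
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), q[perm])

  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  expect_error(bh_adjust(c(-0.1, 0.5)), "outside")
})

test_that("interactor calls apply strict FDR and score thresholds", {
  tbl <- data.frame(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    gi_score = c(0.51, 0.40, -2.0, -0.6, 0.5, -0.5),
    fdr = c(0.19, 0.19, 0.25, 0.10, 0.10, 0.10),
    stringsAsFactors = FALSE)
  out <- call_interactors(tbl)
  expect_identical(out$call,
                   c("positive",  # fdr 0.19, gi 0.51
                     "none",      # gi below threshold
                     "none",      # fails the FDR gate
                     "negative",  # fdr 0.10, gi -0.6
                     "none",      # gi == threshold: strict
                     "none"))     # gi == -threshold: strict
  # fdr == threshold is strict too
  expect_identical(call_interactors(data.frame(gi_score = 2, fdr = 0.2))$call,
                   "none")
})
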