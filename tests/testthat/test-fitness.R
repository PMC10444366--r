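test_that("depth normalization is log2 RPM with a pseudocount", {
  counts <- matrix(c(3L, 1L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  norm <- depth_normalize(counts, pseudocount = 1)
  # pseudocounts (4, 2): exactly one log2 unit apart
  expect_equal(norm["g1", "s1"] - norm["g2", "s1"], 1.0)
  expect_equal(norm["g1", "s1"], log2(4 / 6 * 1e6))

  # invariant: 2^value scaled back by the sample total gives count + pc
  back <- 2^norm * attr(norm, "lib_size")["s1"] / 1e6
  expect_equal(unname(back[, 1]), c(4, 2))

  eq <- matrix(rep(10L, 6), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  neq <- depth_normalize(eq)
  expect_true(all(abs(neq - neq[1, 1]) < 1e-12))

  zero <- matrix(c(1L, 2L, 0L, 0L), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("ok", "dead")))
  expect_error(depth_normalize(zero), "dead")
})

test_that("depth normalization is invariant to sequencing depth", {
  set.seed(42)
  x <- matrix(rpois(40, 200), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
  x[, "b"] <- x[, "a"] * 7L
  norm <- depth_normalize(x, pseudocount = 1e-9)  # no-pseudocount limit
  expect_equal(norm[, "a"], norm[, "b"], tolerance = 1e-6)
})

test_that("guide filter applies strict bounds to every reference sample", {
  counts <- matrix(c(29L, 30L, 10000L, 10001L, 500L,
                     500L, 500L, 500L, 500L, 29L),
                   nrow = 5,
                   dimnames = list(paste0("g", 1:5), c("t0a", "t0b")))
  mask <- filter_guides(counts, c("t0a", "t0b"))
  expect_identical(mask$reason, c("low", "kept", "kept", "high", "low"))
  expect_identical(mask$kept, mask$reason == "kept")

  # failing in any single reference sample excludes the guide (g5)
  expect_false(mask$kept[5])
  expect_error(filter_guides(counts, character(0)), "empty")

  ok <- matrix(rep(100L, 4), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_true(all(filter_guides(ok, c("a", "b"))$kept))
})

test_that("guide filter is monotone in its thresholds", {
  set.seed(7)
  counts <- matrix(as.integer(rlnorm(300, log(500), 1.5)), ncol = 3,
                   dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  kept_n <- function(low, high) {
    sum(filter_guides(counts, c("a", "b", "c"), low, high)$kept)
  }
  for (low in c(10, 30, 100)) {
    expect_gte(kept_n(low, 10000), kept_n(low + 20, 10000))
  }
  for (high in c(20000, 10000, 2000)) {
    expect_gte(kept_n(30, high), kept_n(30, high / 2))
  }
})

test_that("guide LFC is the endpoint-minus-T0 normalized difference", {
  sheet <- make_sheet(contexts = "control", timepoints = c(0L, 6L, 18L))
  norm <- matrix(c(5, 5, 5, 7, 5, 6), nrow = 2,
                 dimnames = list(c("g1", "g2"), sheet$sample_id))
  lfc <- guide_lfc(norm, sheet, endpoint_days = 18L)
  expect_equal(lfc$lfc[lfc$guide_id == "g1"], 0)      # unchanged abundance
  expect_equal(lfc$lfc[lfc$guide_id == "g2"], 1)

  # endpoint RPM exactly 4x the T0 RPM -> LFC 2
  norm4 <- matrix(c(3, log2(4 * 2^3)), nrow = 1,
                  dimnames = list("g1", sheet$sample_id[c(1, 3)]))
  lfc4 <- guide_lfc(norm4, sheet[c(1, 3), ], endpoint_days = 18L)
  expect_equal(lfc4$lfc, 2)

  # intermediate timepoints are valid endpoints
  lfc6 <- guide_lfc(norm, sheet, endpoint_days = 6L)
  expect_equal(lfc6$lfc[lfc6$guide_id == "g2"], 2)

  expect_error(guide_lfc(norm, sheet, endpoint_days = 9L), "day-9")
  no_t0 <- sheet[sheet$timepoint_days != 0L, ]
  class(no_t0) <- c("sample_sheet", "data.frame")
  expect_error(guide_lfc(norm, no_t0, endpoint_days = 18L),
               "T0.*control.*A|missing T0")
})

test_that("MA transform is exact and a constant offset is removed", {
  set.seed(1)
  n <- 200
  a_base <- rnorm(n, 0, 2)
  lfc_ctrl <- matrix(a_base, ncol = 1,
                     dimnames = list(sprintf("g%03d", 1:n), "A"))
  lfc_mut <- lfc_ctrl + 0.7                     # global shift only
  ft <- ma_loess_normalize(lfc_mut, lfc_ctrl)
  expect_equal(ft$M, ft$lfc_mutant - ft$lfc_control)
  expect_equal(ft$A, (ft$lfc_mutant + ft$lfc_control) / 2)
  expect_true(all(abs(ft$m_normalized) < 1e-10))
  expect_equal(ft$lfc_mutant_normalized, ft$lfc_control, tolerance = 1e-10)

  # M identically zero: normalization is the identity
  ft0 <- ma_loess_normalize(lfc_ctrl, lfc_ctrl)
  expect_equal(ft0$lfc_mutant_normalized, ft0$lfc_mutant)
})

test_that("loess recovers an injected linear trend and matches the oracle", {
  set.seed(2)
  n <- 500
  A <- rnorm(n, 0, 2)
  M <- 0.1 * A + rnorm(n, 0, 0.01)
  fit <- loess_fit_binned(A, M, span = 0.3, bins = 20)
  oracle <- loess_bruteforce(A, M, span = 0.3, bins = 20, query = A)
  expect_equal(fit, oracle, tolerance = 1e-8)
  expect_lt(max(abs(fit - 0.1 * A)), 0.02)

  # a pure linear trend is removed exactly (local linear reproduces lines)
  M_lin <- -0.3 + 0.25 * A
  fit_lin <- loess_fit_binned(A, M_lin)
  expect_equal(fit_lin, M_lin, tolerance = 1e-10)

  # nonlinear trend: still matches the oracle
  M_nl <- sin(A) + rnorm(n, 0, 0.05)
  expect_equal(loess_fit_binned(A, M_nl, span = 0.4, bins = 15),
               loess_bruteforce(A, M_nl, 0.4, 15, A), tolerance = 1e-8)
})

test_that("loess normalization is idempotent on trend-free data", {
  set.seed(3)
  n <- 300
  A <- rnorm(n, 0, 1.5)
  for (M in list(rep(0.4, n), 0.2 - 0.5 * A)) {   # constant / linear trends
    r1 <- M - loess_fit_binned(A, M)
    r2 <- r1 - loess_fit_binned(A, r1)
    expect_lt(max(abs(r2 - r1)), 1e-6)
  }
})

test_that("loess falls back to a global median below the bin count", {
  A <- 1:5
  M <- c(1, 2, 3, 4, 100)
  expect_warning(f <- loess_fit_binned(A, M, bins = 20), "median")
  expect_equal(f, rep(3, 5))
})

test_that("replicate averaging is the mean over available replicates", {
  ft <- data.frame(
    guide_id = rep(c("g1", "g2"), each = 3),
    replicate = rep(c("A", "B", "C"), 2),
    lfc_control = c(1, 2, 3, 0, 0, 0),
    lfc_mutant = 0, A = 0, M = 0, m_normalized = 0,
    lfc_mutant_normalized = c(2, 2, 2, 1, NA, 4),
    stringsAsFactors = FALSE)
  out <- average_replicates(ft)
  expect_equal(out$lfc[out$guide_id == "g1" & out$context == "control"], 2)
  expect_equal(out$lfc[out$guide_id == "g1" & out$context == "mutant"], 2)
  # one replicate missing: mean of the remaining two
  expect_equal(out$lfc[out$guide_id == "g2" & out$context == "mutant"], 2.5)

  single <- ft[ft$replicate == "A", ]
  out1 <- average_replicates(single)
  expect_equal(out1$lfc[out1$context == "control"], c(1, 0))
})
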