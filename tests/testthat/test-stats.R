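# Inferential machinery: equalization, sign-flip nulls, FDR, clusters,
# rm ANOVA, metric group tests.

test_that("equalize_trials subsamples the larger set deterministically", {
  eq <- equalize_trials(1:40, 101:125, seed = 9)
  expect_length(eq$a, 25)
  expect_identical(eq$b, 101:125)            # smaller set unchanged
  expect_true(all(eq$a %in% 1:40) && !anyDuplicated(eq$a))
  # equal sizes: both unchanged
  eq2 <- equalize_trials(1:7, 11:17, seed = 9)
  expect_identical(eq2$a, 1:7)
  expect_identical(eq2$b, 11:17)
  # determinism
  expect_identical(equalize_trials(1:40, 101:125, seed = 9), eq)
  expect_error(equalize_trials(integer(0), 1:3), "non-empty")
})

# enumerate_signflip_p (exact oracle) comes from helper-oracles.R

test_that("sign-flip Monte Carlo agrees with exact enumeration", {
  # all diffs positive: two-tailed p ~ 2/2^8
  d <- rep(0.7, 8)
  r <- signflip_monte_carlo(d, n = 20000, seed = 10)
  expect_true(r$mask)
  expect_equal(r$p_two, 2 / 256, tolerance = 0.5)   # ~0.0078
  # symmetric diffs: p ~ 1
  d2 <- rep(c(0.5, -0.5), 4)
  r2 <- signflip_monte_carlo(d2, n = 5000, seed = 10)
  expect_false(r2$mask)
  expect_gt(r2$p_two, 0.5)
  # random case: MC within +-0.003 of the exact tail probabilities
  set.seed(12)
  d3 <- stats::rnorm(8, mean = 0.55)
  ex <- enumerate_signflip_p(d3)
  r3 <- signflip_monte_carlo(d3, n = 20000, seed = 13)
  expect_lt(abs(r3$p_hi - ex["hi"]), 0.003)
  expect_lt(abs(r3$p_lo - ex["lo"]), 0.003)
  expect_error(signflip_monte_carlo(3), "2 subjects")
})

test_that("BH step-up matches the hand example and the reference", {
  # hand step-up with thresholds 0.01 0.02 0.03 0.04 0.05
  p <- c(0.001, 0.012, 0.03, 0.04, 0.8)
  expect_identical(bh_fdr(p, 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_identical(bh_fdr(0.04, 0.05), TRUE)   # m = 1 reduces to p <= q
  # dual route: exact mask agreement with stats::p.adjust on 1000 vectors
  set.seed(14)
  for (i in 1:1000) {
    m <- sample(1:30, 1)
    pv <- stats::runif(m)^sample(1:3, 1)
    q <- stats::runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(pv, q),
                     unname(stats::p.adjust(pv, "BH") <= q))
  }
})

test_that("cluster permutation: null case is empty, injection is recovered", {
  set.seed(15)
  # A == B: no suprathreshold elements at all
  a <- array(stats::rnorm(8 * 3 * 20), c(8, 3, 20))
  r0 <- cluster_permutation(a, a, n_perm = 100, seed = 1)
  expect_equal(nrow(r0$clusters), 0)
  # constant offset in band 2 over a contiguous span, high SNR
  b <- array(stats::rnorm(8 * 3 * 20, sd = 0.3), c(8, 3, 20))
  a2 <- b + stats::rnorm(length(b), sd = 0.3)
  a2[, 2, 6:12] <- a2[, 2, 6:12] + 3
  r1 <- cluster_permutation(a2, b, n_perm = 500, seed = 2)
  sig <- r1$clusters[r1$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(abs(sig$t_sum)), ]
  expect_equal(main$band, 2)
  expect_lte(main$start, 7)
  expect_gte(main$end, 11)
  expect_equal(main$sign, 1)
  expect_error(cluster_permutation(a2[1, , , drop = FALSE],
                                   b[1, , , drop = FALSE]), "2 animals")
})

test_that("cluster permutation is reproducible under its seed", {
  set.seed(16)
  a <- array(stats::rnorm(6 * 2 * 15), c(6, 2, 15))
  b <- array(stats::rnorm(6 * 2 * 15), c(6, 2, 15))
  r1 <- cluster_permutation(a, b, n_perm = 200, seed = 42)
  r2 <- cluster_permutation(a, b, n_perm = 200, seed = 42)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$clusters, r2$clusters)
})

test_that("two-way rm ANOVA matches a hand partition and handles edge cases", {
  # all cells equal: F = 0 everywhere
  v0 <- array(5, c(4, 2, 2))
  a0 <- rm_anova_roi(v0)
  expect_true(all(a0$F == 0))
  # additive construction: value = 2 * I(CR) + subject offset, no noise:
  # factor A is infinitely strong, interaction flat
  v1 <- array(0, c(6, 2, 2))
  for (s in 1:6) v1[s, , ] <- s / 10
  v1[, 2, ] <- v1[, 2, ] + 2
  a1 <- rm_anova_roi(v1)
  expect_true(is.infinite(a1$F[1]) || a1$p[1] < 1e-12)
  expect_equal(a1$F[3], 0)
  # random 8 x 2 x 2 table against an independently coded partition
  set.seed(17)
  v2 <- array(stats::rnorm(32), c(8, 2, 2))
  a2 <- rm_anova_roi(v2, factor_names = c("cr", "rank"))
  d <- data.frame(y = as.vector(v2),
                  s = factor(rep(1:8, 4)),
                  A = factor(rep(rep(1:2, each = 8), 2)),
                  B = factor(rep(1:2, each = 16)))
  ref <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = d))
  expect_equal(a2$F[1], ref[["Error: s:A"]][[1]]["A", "F value"],
               tolerance = 1e-10)
  expect_equal(a2$F[2], ref[["Error: s:B"]][[1]]["B", "F value"],
               tolerance = 1e-10)
  expect_equal(a2$F[3], ref[["Error: s:A:B"]][[1]]["A:B", "F value"],
               tolerance = 1e-10)
  expect_equal(a2$p[1], ref[["Error: s:A"]][[1]]["A", "Pr(>F)"],
               tolerance = 1e-10)
  # missing cells error (no imputation)
  v3 <- v2; v3[2, 1, 2] <- NA
  expect_error(rm_anova_roi(v3), "missing cells")
})

test_that("pac_group_test: null, forced effect, and skipped cells", {
  set.seed(18)
  post <- matrix(stats::runif(40 * 6, 0.2, 0.4), 40, 6)
  # post == pre: nothing significant
  r0 <- pac_group_test(post, post)
  expect_true(all(!r0$mask))
  # uniform +0.2 shift with negligible variance: everything significant
  r1 <- pac_group_test(post + 0.2 + stats::rnorm(length(post), sd = 1e-4),
                       post)
  expect_true(all(r1$mask))
  # a cell with < 3 observations is skipped
  post2 <- post; post2[3:40, 3] <- NA
  r2 <- pac_group_test(post2, post)
  expect_true(is.na(r2$p[3]))
  expect_false(r2$mask[3])
})

test_that("pte_shuffle_test flags the lagged band and is antisymmetric", {
  cfg <- null_config(seed = 20)
  cfg$n_trials <- 25L
  cfg$lag_spec <- list(freq = 9, lag = 11, source = "hilus",
                       target = "fissure", amplitude = 40,
                       window = c(0, 0.6))
  exp <- simulate_experiment(cfg)
  bank <- test_bank()
  tfrs <- decompose(exp$recordings[[1]][[1]], bank)
  dte <- dte_spectrum(tfrs$hilus, tfrs$fissure, n_bins = 4)
  r <- pte_shuffle_test(dte, n_shuffles = 200, seed = 21)
  b9 <- which.min(abs(r$freq - 9))
  expect_true(r$significant[b9])
  expect_gt(r$dte[b9], 0)
  # swapped labels: dTE negated, same null geometry
  dte_sw <- dte_spectrum(tfrs$fissure, tfrs$hilus, n_bins = 4)
  expect_equal(dte_sw$dte, -dte$dte, tolerance = 1e-12)
  r_sw <- pte_shuffle_test(dte_sw, n_shuffles = 200, seed = 21)
  expect_equal(r_sw$p[b9], r$p[b9], tolerance = 0.05)
})
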