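test_that("pairwise correlations recover exact linear dependence", {
  x <- c(0.1, 0.2, 0.4, 0.3)
  m <- cbind(t1 = x, t2 = 2 * x, t3 = 0.5 - x)
  rownames(m) <- paste0("s", 1:4)
  cc <- pairwise_correlations(m)
  expect_equal(cc["t1", "t2"], 1)
  expect_equal(cc["t1", "t3"], -1)
  expect_equal(diag(cc), c(t1 = 0, t2 = 0, t3 = 0))
  expect_equal(cc, t(cc))
})

test_that("pairwise correlations match the direct product-moment formula", {
  m <- matrix(c(0.10, 0.30, 0.60,
                0.25, 0.25, 0.50,
                0.40, 0.10, 0.50,
                0.20, 0.20, 0.60), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  cc <- pairwise_correlations(m)
  ## oracle: covariance / sd product, written out
  pm <- function(a, b) {
    n <- length(a)
    co <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
    co / (sd(a) * sd(b))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(cc[i, j], pm(m[, i], m[, j]), tolerance = 1e-12)
  }
})

test_that("zero-variance taxa are flagged and contribute zero correlations", {
  m <- cbind(t1 = c(0.2, 0.4, 0.3, 0.1), t2 = rep(0.25, 4),
             t3 = c(0.55, 0.35, 0.45, 0.65))
  rownames(m) <- paste0("s", 1:4)
  cc <- pairwise_correlations(m)
  expect_identical(attr(cc, "zero_variance"), "t2")
  expect_equal(unname(cc["t2", ]), c(0, 0, 0))
  expect_error(pairwise_correlations(m[1:2, ]), "3 samples")
})

test_that("Monte-Carlo null agrees with exhaustive permutation enumeration", {
  m <- commcoal:::with_seed(7, matrix(runif(4 * 5), 4, 5,
    dimnames = list(paste0("s", 1:4), paste0("t", 1:5))))
  ex <- null_expected_correlations(m, method = "exhaustive")
  mc <- null_expected_correlations(m, n_iter = 4000, seed = 2)
  expect_lt(max(abs(ex - mc)), 0.02)
  ## the exhaustive null is itself symmetric with zero diagonal
  expect_equal(ex, t(ex))
  expect_equal(unname(diag(ex)), rep(0, 5))
})

test_that("the null model is seeded and destroys real alignment", {
  m <- commcoal:::with_seed(3, matrix(runif(8 * 6), 8, 6,
    dimnames = list(paste0("s", 1:8), paste0("t", 1:6))))
  n1 <- null_expected_correlations(m, n_iter = 50, seed = 9)
  n2 <- null_expected_correlations(m, n_iter = 50, seed = 9)
  expect_identical(n1, n2)
  ## two identical taxa: observed correlation 1, null far below
  m2 <- cbind(m, t7 = m[, "t1"])
  obs <- pairwise_correlations(m2)
  nul <- null_expected_correlations(m2, n_iter = 200, seed = 1)
  expect_equal(obs["t1", "t7"], 1)
  expect_lt(nul["t1", "t7"], 0.5)
  expect_error(null_expected_correlations(m, n_iter = 0), "n_iter")
})

test_that("connectedness averages strictly positive and negative entries", {
  taxa <- c("t1", "t2", "t3")
  corr <- matrix(0, 3, 3, dimnames = list(taxa, taxa))
  corr["t1", "t2"] <- corr["t2", "t1"] <- 0.6
  corr["t1", "t3"] <- corr["t3", "t1"] <- -0.2
  corr["t2", "t3"] <- corr["t3", "t2"] <- 0.4
  cs <- correlation_set(corr, matrix(0, 3, 3, dimnames = dimnames(corr)))
  cn <- connectedness(cs)
  expect_equal(cn$connectedness_pos, c(0.6, 0.5, 0.4))
  expect_equal(cn$connectedness_neg, c(-0.2, 0, -0.2))

  ## all-zero corrected matrix: both vectors zero
  cs0 <- correlation_set(matrix(0, 3, 3, dimnames = dimnames(corr)),
                         matrix(0, 3, 3, dimnames = dimnames(corr)))
  cn0 <- connectedness(cs0)
  expect_equal(cn0$connectedness_pos, rep(0, 3))
  expect_equal(cn0$connectedness_neg, rep(0, 3))

  ## label invariance: permuting taxa permutes connectedness identically
  perm <- c(3, 1, 2)
  csp <- correlation_set(corr[perm, perm],
                         matrix(0, 3, 3,
                                dimnames = list(taxa[perm], taxa[perm])))
  cnp <- connectedness(csp)
  expect_equal(cnp$connectedness_pos,
               cn$connectedness_pos[perm])
  expect_error(connectedness(correlation_set(
    matrix(0, 1, 1, dimnames = list("t1", "t1")),
    matrix(0, 1, 1, dimnames = list("t1", "t1")))), "two taxa")
})

test_that("cohesion is the abundance-weighted sum of connectedness", {
  conn <- data.frame(taxon_id = c("t1", "t2", "t3"),
                     connectedness_pos = c(0.6, 0.5, 0.4),
                     connectedness_neg = c(-0.2, 0, -0.2))
  a <- matrix(c(0.5, 0.3, 0.2,
                0.1, 0.1, 0.8), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  coh <- cohesion(make_cm(a, "relative", samples = c("s1", "s2"),
                          taxa = c("t1", "t2", "t3")), conn)
  expect_equal(coh$cohesion_pos,
               c(0.5 * 0.6 + 0.3 * 0.5 + 0.2 * 0.4,
                 0.1 * 0.6 + 0.1 * 0.5 + 0.8 * 0.4))
  expect_equal(coh$cohesion_neg,
               c(0.5 * -0.2 + 0.2 * -0.2, 0.1 * -0.2 + 0.8 * -0.2))
  ## single sample fully on one taxon
  b <- matrix(c(1, 0, 0), 1, 3,
              dimnames = list("s1", c("t1", "t2", "t3")))
  expect_equal(cohesion(b, conn)$cohesion_pos, 0.6)
  ## taxon mismatch is an error
  conn2 <- conn[1:2, ]
  expect_error(cohesion(b, conn2), "taxa")
})

test_that("stability ratio handles the boundary and undefined cases", {
  expect_equal(stability_ratio(0.2, -0.1), 0.5)
  expect_equal(stability_ratio(0.1, -0.1), 1.0)
  expect_warning(out <- stability_ratio(c(0, 0.2), c(-0.1, -0.1)),
                 "undefined")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 0.5)
})

test_that("stability comparisons use exact rank-sum p-values and BH", {
  ## complete separation of two groups of five: two-sided exact p is
  ## 2 / choose(10, 5) = 2/252
  vals <- c(1:5 / 10, 6:10 / 10)
  grp <- rep(c("a", "b"), each = 5)
  tab <- compare_stability(vals, grp)
  expect_equal(tab$p_raw, 2 / 252, tolerance = 1e-12)
  ## identical groups: adjusted p = 1
  tab2 <- compare_stability(rep(c(0.4, 0.5, 0.6), 2),
                            rep(c("a", "b"), each = 3))
  expect_equal(tab2$p_adj, 1)
  ## three groups: three pairwise tests, BH over m = 3
  v3 <- c(1:4, 11:14, 21:24) / 30
  g3 <- rep(c("a", "b", "c"), each = 4)
  tab3 <- compare_stability(v3, g3)
  expect_equal(nrow(tab3), 3)
  expect_equal(tab3$p_adj, bh_adjust(tab3$p_raw))
  ## too-small groups are excluded with a warning
  expect_warning(compare_stability(c(vals, 0.2), c(grp, "c")),
                 "fewer than 2")
})

test_that("planted positive blocks surface in connectedness", {
  sim <- simulate_coupled_taxa(30, 40, block = 1:8, block_loading = 0.8,
                               sync_loading = 0.2, noise_sd = 0.3, seed = 42)
  m <- as.matrix(sim$matrix)
  cs <- correlation_set(pairwise_correlations(m),
                        null_expected_correlations(m, n_iter = 100,
                                                   seed = 43))
  cn <- connectedness(cs)
  expect_gt(mean(cn$connectedness_pos[sim$block]),
            mean(cn$connectedness_pos[-sim$block]))
})

test_that("community_cohesion wires filter, null model and weighting together", {
  cm <- random_counts(12, 25, lambda = 15, seed = 5)
  res <- community_cohesion(cm, n_iter = 50, seed = 2,
                            prevalence_threshold = 0.1)
  expect_s3_class(res$correlations, "correlation_set")
  expect_true(all(res$samples$cohesion_pos >= 0))
  expect_true(all(res$samples$cohesion_neg <= 0))
  defined <- !is.na(res$samples$stability)
  expect_equal(res$samples$stability[defined],
               abs(res$samples$cohesion_neg[defined] /
                     res$samples$cohesion_pos[defined]))
  ## deterministic under the seed
  res2 <- community_cohesion(cm, n_iter = 50, seed = 2,
                             prevalence_threshold = 0.1)
  expect_identical(res$samples, res2$samples)
})
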