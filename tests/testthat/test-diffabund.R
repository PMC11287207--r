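test_that("bh_adjust reproduces the step-up definition", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # step-up monotone
  }
})

test_that("the permutation test tracks the exhaustive label-split null", {
  ## 3 vs 3 samples: 20 ordered splits; the implementation samples splits
  ## other than the observed partition, so the expected exceedance rate per
  ## taxon is k/18 with k counted over the 18 non-observed ordered splits
  set.seed(70)
  a <- matrix(abs(rnorm(3 * 6)), 3, 6,
              dimnames = list(paste0("a", 1:3), paste0("t", 1:6)))
  b <- matrix(abs(rnorm(3 * 6)), 3, 6,
              dimnames = list(paste0("b", 1:3), paste0("t", 1:6)))
  pooled <- rbind(a, b)
  obs <- colMeans(b) - colMeans(a)
  splits <- combn(6, 3)
  k <- sapply(seq_len(ncol(pooled)), function(j) {
    stats <- apply(splits, 2, function(idx_a) {
      mean(pooled[-idx_a, j]) - mean(pooled[idx_a, j])
    })
    drop <- apply(splits, 2, function(idx_a)
      identical(sort(idx_a), 1:3) || identical(sort(idx_a), 4:6))
    sum(abs(stats[!drop]) >= abs(obs[j]))
  })
  oracle_p <- (1 + 999 * k / 18) / 1000
  da <- permutation_da_test(a, b, n_perm = 999, seed = 5)
  expect_lt(max(abs(da$p_raw - oracle_p)), 0.06)
})

test_that("a copied group gives near-one p-values and no direction calls", {
  set.seed(71)
  a <- matrix(abs(rnorm(3 * 5)) + 0.1, 3, 5,
              dimnames = list(paste0("a", 1:3), paste0("t", 1:5)))
  b <- a
  rownames(b) <- paste0("b", 1:3)
  da <- permutation_da_test(a, b, n_perm = 999, seed = 6)
  expect_true(all(da$p_raw > 0.5))
  expect_true(all(da$direction == "none"))
})

test_that("complete separation attains the minimal p of 1/(n_perm + 1)", {
  set.seed(72)
  base <- rdirichlet_rows(10, rep(1, 30))
  dimnames(base) <- list(paste0("s", 1:10), paste0("t", 1:30))
  shifted <- base
  shifted[6:10, 1] <- shifted[6:10, 1] * 10 # ten-fold planted increase
  a <- base[1:5, ]
  b <- prop.table(shifted[6:10, ], 1)
  da <- permutation_da_test(a, b, n_perm = 999, seed = 7)
  expect_equal(da$p_raw[da$taxon_id == "t1"], 1 / 1000)
  expect_identical(da$direction[da$taxon_id == "t1"], "increase")
  expect_true(attr(da, "n_permutations") == 999)
  ## determinism and the min-p formula
  da2 <- permutation_da_test(a, b, n_perm = 999, seed = 7)
  expect_identical(da$p_raw, da2$p_raw)
  expect_true(all(da$p_raw >= 1 / 1000))
  expect_error(permutation_da_test(a[1, , drop = FALSE], b), "2 samples")
})

test_that("the environmental screen retains exactly the non-decreasing present taxa", {
  set.seed(73)
  p <- 40
  base <- prop.table(rgamma(p, 0.6))
  names(base) <- paste0("t", 1:p)
  parent <- rdirichlet_rows(5, base * 300)
  dimnames(parent) <- list(paste0("p", 1:5), names(base))
  treated_base <- base
  treated_base[1:4] <- treated_base[1:4] * 0.02  # crash four taxa
  treated_base[5:6] <- treated_base[5:6] * 8     # boost two taxa
  env <- rdirichlet_rows(5, prop.table(treated_base) * 300)
  dimnames(env) <- list(paste0("e", 1:5), names(base))
  ## a taxon absent from the treated group is excluded by presence alone
  parent2 <- cbind(parent, ghost = rep(0.0, 5))
  env2 <- cbind(env, ghost = rep(0, 5))
  parent2[, "ghost"] <- 0.01
  parent2 <- prop.table(parent2, 1)
  env2 <- prop.table(env2, 1)
  sc <- environmental_screen(parent2, env2, n_perm = 999, seed = 8)
  da <- attr(sc, "da")
  expect_false("ghost" %in% sc)
  crashed <- paste0("t", 1:4)
  expect_true(all(!(crashed %in% sc)))
  ## significantly increased taxa are retained
  boosted <- paste0("t", 5:6)
  boosted_sig <- da$taxon_id[da$direction == "increase"]
  expect_true(all(intersect(boosted, boosted_sig) %in% sc))
  ## every retained taxon is present in both groups and not a significant
  ## decrease - and vice versa
  dec <- da$taxon_id[da$direction == "decrease"]
  present <- colnames(parent2)[colSums(parent2) > 0 & colSums(env2) > 0]
  expect_setequal(sc, setdiff(present, dec))
})

test_that("biotic response recovers planted fold changes on screened taxa", {
  set.seed(74)
  p <- 50
  base <- prop.table(rgamma(p, 0.6) + 0.02)
  names(base) <- paste0("t", 1:p)
  up <- names(sort(base, decreasing = TRUE))[4:6]
  ref <- rdirichlet_rows(5, base * 400)
  dimnames(ref) <- list(paste0("r", 1:5), names(base))
  shifted <- base
  shifted[up] <- shifted[up] * 5
  coal <- rdirichlet_rows(5, prop.table(shifted) * 400)
  dimnames(coal) <- list(paste0("c", 1:5), names(base))
  br <- biotic_response(coal, ref, screen = names(base), n_perm = 999,
                        seed = 9)
  expect_true(all(up %in% br$increased))
  ## taxa outside the screen can never be reported
  br2 <- biotic_response(coal, ref, screen = setdiff(names(base), up[1]),
                         n_perm = 999, seed = 9)
  expect_false(up[1] %in% c(br2$increased, br2$decreased))
  expect_false(up[1] %in% br2$table$taxon_id)
  ## identical groups produce empty sets
  br3 <- biotic_response(ref, ref[c(3:5, 1:2), ], screen = names(base),
                         n_perm = 999, seed = 10)
  expect_length(br3$increased, 0)
  expect_length(br3$decreased, 0)
  expect_error(biotic_response(coal, ref, screen = character(0)), "empty")
})

test_that("low-prevalence taxa never enter the biotic response", {
  set.seed(75)
  base <- prop.table(rep(1, 20))
  names(base) <- paste0("t", 1:20)
  ref <- rdirichlet_rows(5, base * 200)
  coal <- rdirichlet_rows(5, base * 200)
  dimnames(ref) <- list(paste0("r", 1:5), names(base))
  dimnames(coal) <- list(paste0("c", 1:5), names(base))
  ref[, "t20"] <- 0
  coal[, "t20"] <- 0
  coal[1, "t20"] <- 1e-4 # prevalence 1/10: fails the strict 10% filter
  ref <- prop.table(ref, 1)
  coal <- prop.table(coal, 1)
  br <- biotic_response(coal, ref, screen = names(base), n_perm = 99,
                        seed = 11)
  expect_false("t20" %in% br$table$taxon_id)
})

test_that("aggregate response totals and Kruskal-Wallis match direct computation", {
  g1 <- make_cm(matrix(c(0.1, 0.9, 0.2, 0.8, 0.15, 0.85), 3, 2,
                       byrow = TRUE), "relative",
                samples = paste0("x", 1:3), taxa = c("t1", "t2"))
  g2 <- make_cm(matrix(c(0.6, 0.4, 0.7, 0.3, 0.65, 0.35), 3, 2,
                       byrow = TRUE), "relative",
                samples = paste0("y", 1:3), taxa = c("t1", "t2"))
  res <- aggregate_response(list(a = g1, b = g2), "t1")
  ## disjoint totals (0.1, 0.2, 0.15) vs (0.6, 0.7, 0.65): hand-ranked
  ## Kruskal-Wallis H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  expect_equal(res$test$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(res$totals$total, c(0.1, 0.2, 0.15, 0.6, 0.7, 0.65))

  ## response set covering everything: totals 1, degenerate test, p = 1
  res2 <- aggregate_response(list(a = g1, b = g2), c("t1", "t2"))
  expect_true(res2$test$degenerate)
  expect_equal(res2$test$p, 1)
  expect_equal(res2$totals$total, rep(1, 6))

  ## empty response set: flagged, no test
  res3 <- aggregate_response(list(a = g1, b = g2), character(0))
  expect_true(res3$empty_set)
  expect_null(res3$test)
  expect_equal(res3$totals$total, rep(0, 6))
})
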