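test_that("the spec validates its fields and names the offender", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(n_shared = 100), "n_shared")
  expect_error(synthetic_spec(exchange_fraction = 1), "exchange_fraction")
  expect_error(synthetic_spec(env_decline_river = 0), "env_decline_river")
  expect_error(synthetic_spec(n_positive_block = 30, n_negative_pairs = 10),
               "n_positive_block")
  expect_error(synthetic_spec(fitness_river = rep(1, 3)), "fitness_river")
})

test_that("parent generation is deterministic with the declared supports", {
  spec <- synthetic_spec(seed = 5)
  p1 <- generate_parents(spec)
  p2 <- generate_parents(spec)
  expect_identical(p1$latent, p2$latent)
  expect_identical(as.matrix(p1$counts$R), as.matrix(p2$counts$R))
  ## river parent holds no sea-exclusive taxa and vice versa
  sea_excl <- spec$taxa$taxon_id[spec$taxa$origin == "sea"]
  riv_excl <- spec$taxa$taxon_id[spec$taxa$origin == "river"]
  expect_true(all(p1$latent$R[, sea_excl] == 0))
  expect_true(all(p1$latent$S[, riv_excl] == 0))
  ## no shared taxa at all gives disjoint supports
  p0 <- generate_parents(synthetic_spec(n_shared = 0, n_positive_block = 0,
                                        n_negative_pairs = 0, seed = 2))
  expect_length(intersect(colnames(p0$latent$R)[colSums(p0$latent$R) > 0],
                          colnames(p0$latent$S)[colSums(p0$latent$S) > 0]),
                0)
})

test_that("counts sum to the sequencing depth and stay non-negative", {
  ex <- simulate_experiment(synthetic_spec(seed = 3))
  m <- as.matrix(ex$counts)
  expect_true(all(rowSums(m) == ex$spec$sequencing_depth))
  expect_true(all(m >= 0))
  expect_true(all(ex$truth$latent_day16 >= 0))
})

test_that("the environmental filter scales sensitive taxa and nothing else", {
  spec <- synthetic_spec(seed = 11)
  par <- generate_parents(spec)
  env <- apply_environmental_filter(par)
  sens <- par$truth$env_sensitive_river
  before <- par$latent$R
  after <- env$latent$Rx
  ## ratios of unaffected taxa are preserved within each replicate
  keep <- setdiff(colnames(before)[colSums(before) > 0], sens)
  k2 <- keep[1:5]
  for (r in 1:nrow(before)) {
    expect_equal(after[r, k2] / after[r, k2[1]],
                 before[r, k2] / before[r, k2[1]], tolerance = 1e-12)
  }
  ## multiplier 1 leaves the latent composition untouched
  env1 <- apply_environmental_filter(par, decline_river = 1,
                                     decline_sea = 1)
  expect_equal(unname(env1$latent$Rx), unname(before), tolerance = 1e-12)
  expect_error(apply_environmental_filter(par, decline_river = 1.2),
               "0, 1")
})

test_that("coalescence dynamics honour their fixed points and contraction", {
  spec <- synthetic_spec(
    mixing_ratios = list(c(1, 0), c(1, 1)),
    fitness_river = rep(1, 120), fitness_sea = rep(1, 120),
    env_decline_river = 1, env_decline_sea = 1, seed = 13)
  par <- generate_parents(spec)
  ## ratio 1:0 with unit fitness: RC latent equals parent R at every day
  rc <- simulate_coalescence(spec, par, "RC", c(1, 0), seed = 1)
  for (d in names(rc$latent)) {
    expect_equal(unname(rc$latent[[d]]), unname(par$latent$R),
                 tolerance = 1e-12)
  }
  ## zero exchange: OC and RC coincide latently and in seeded counts
  spec0 <- synthetic_spec(fitness_river = rep(1, 120),
                          fitness_sea = rep(1, 120), seed = 13)
  spec0$exchange_fraction <- 0
  par0 <- generate_parents(spec0)
  oc0 <- simulate_coalescence(spec0, par0, "OC", c(1, 2), seed = 4)
  rc0 <- simulate_coalescence(spec0, par0, "RC", c(1, 2), seed = 4)
  expect_equal(lapply(oc0$latent, unname), lapply(rc0$latent, unname),
               tolerance = 1e-12)
  expect_identical(lapply(oc0$counts, function(x) unname(as.matrix(x))),
                   lapply(rc0$counts, function(x) unname(as.matrix(x))))
  ## with uniform fitness the parent mixture is a fixed point of the RC
  ## update, so the trajectory never leaves it
  spec1 <- synthetic_spec(fitness_river = rep(1, 120),
                          fitness_sea = rep(1, 120),
                          env_decline_river = 1, env_decline_sea = 1,
                          seed = 17)
  par1 <- generate_parents(spec1)
  rc1 <- simulate_coalescence(spec1, par1, "RC", c(1, 1), seed = 5)
  mix <- 0.5 * par1$latent$R + 0.5 * par1$latent$S
  dist <- sapply(rc1$latent, function(l) max(abs(unname(l) - unname(mix))))
  expect_true(all(dist <= 1e-12))
  ## with selection pushing the community away, the repeated top-ups keep
  ## RC closer to the (filtered) parent mixture than OC at every day
  spec2 <- synthetic_spec(seed = 17)
  par2 <- generate_parents(spec2)
  oc2 <- simulate_coalescence(spec2, par2, "OC", c(1, 1), seed = 6)
  rc2 <- simulate_coalescence(spec2, par2, "RC", c(1, 1), seed = 6)
  mix2 <- rc2$latent[["0"]] # day-0 filtered mixture
  d_oc <- sapply(oc2$latent, function(l) mean(abs(unname(l) - unname(mix2))))
  d_rc <- sapply(rc2$latent, function(l) mean(abs(unname(l) - unname(mix2))))
  expect_true(all(d_rc[-1] <= d_oc[-1] + 1e-12))
  expect_error(simulate_coalescence(spec1, par1, "XX", c(1, 1)), "mode")
})

test_that("planted positive blocks correlate across parent replicates", {
  hits <- sapply(1:20, function(s) {
    spec <- synthetic_spec(n_replicates = 10L, seed = 100 + s)
    par <- generate_parents(spec)
    m <- rbind(par$latent$R, par$latent$S)
    block <- par$truth$positive_block
    cc <- pairwise_correlations(m[, colSums(m) > 0])
    within <- cc[block, block]
    within <- within[upper.tri(within)]
    mean(within) > median(cc[upper.tri(cc)])
  })
  expect_gte(sum(hits), 19)
})

test_that("the default experiment matches the design layout and is seeded", {
  ex <- simulate_experiment(synthetic_spec(seed = 21))
  ex2 <- simulate_experiment(synthetic_spec(seed = 21))
  expect_identical(as.matrix(ex$counts), as.matrix(ex2$counts))
  d <- ex$design
  expect_equal(nrow(d), 60)
  expect_true(all(d$day == 16))
  expect_equal(sum(d$sequenced), 50)
  expect_equal(nrow(as.matrix(ex$counts)), 50)
  tab <- table(d$source[d$sequenced])
  expect_equal(unname(tab[c("R", "S", "Rx", "Sx")]), rep(5L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(tab[c("OC", "RC")]), rep(15L, 2), ignore_attr = TRUE)
  ## the expected day-16 mixtures satisfy the convex-combination identity
  for (nm in names(ex$truth$expected_day16_mixture)) {
    r <- as.numeric(strsplit(nm, "")[[1]])
    rho <- r[1] / sum(r)
    manual <- rho * ex$truth$parent_day16_latent$R +
      (1 - rho) * ex$truth$parent_day16_latent$S
    expect_equal(unname(ex$truth$expected_day16_mixture[[nm]]),
                 unname(manual), tolerance = 1e-12)
  }
})

test_that("emitted datasets round-trip through the readers", {
  ex <- simulate_experiment(synthetic_spec(seed = 31))
  out <- withr::local_tempdir()
  paths <- emit_dataset(ex, out)
  cm <- read_community_table(paths[["otu_table"]])
  expect_identical(as.matrix(cm)[rownames(as.matrix(ex$counts)), ],
                   as.matrix(ex$counts))
  d <- read_experiment_design(paths[["metadata"]])
  expect_equal(nrow(d), 60)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(sort(unlist(truth$positive_block)),
               sort(ex$truth$positive_block))
  expect_equal(unlist(truth$seed), 31)
})

test_that("simulate_coupled_taxa plants the requested coupling structure", {
  sim <- simulate_coupled_taxa(40, 30, neg_fraction = 0.4, neg_loading = 1.2,
                               sync_loading = 0.2, noise_sd = 0.2, seed = 8)
  m <- as.matrix(sim$matrix)
  expect_equal(nrow(sim$negative_pairs), 6)
  cc <- pairwise_correlations(m)
  pair_cors <- cc[sim$negative_pairs]
  expect_true(all(pair_cors < 0))
  ## closed output sums to one; unclosed output does not
  expect_equal(unname(rowSums(m)), rep(1, 40))
  sim_open <- simulate_coupled_taxa(10, 8, close = FALSE, seed = 8)
  expect_false(inherits(sim_open$matrix, "community_matrix"))
  ## counts mode respects the depth
  simc <- simulate_coupled_taxa(6, 8, depth = 500, seed = 2)
  expect_true(all(rowSums(as.matrix(simc$matrix)) == 500))
  ## determinism
  expect_identical(simulate_coupled_taxa(6, 8, seed = 4)$matrix,
                   simulate_coupled_taxa(6, 8, seed = 4)$matrix)
})
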