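## Synthetic coalescence-experiment generator: two parent communities with
## partially overlapping taxa, planted correlation blocks, environmentally
## sensitive taxa, serial-transfer dynamics with one-time (OC) and repeated
## (RC) mixing, and multinomial sequencing noise, with full ground truth.

#' Specification of a synthetic coalescence experiment
#'
#' Defaults emulate the study design the package targets: two parent
#' communities (river and sea) with partially overlapping taxon pools, five
#' replicates, environmental-coalescence treatments, and one-time (OC) and
#' repeated (RC) coalescence at river:sea ratios 1:1, 1:2 and 2:1, with 20%
#' volume exchange every 4 days over 16 days and multinomial sequencing
#' depth noise.
#'
#' Taxon identifiers are deterministic (`Riv*` river-exclusive, `Shr*`
#' shared, `Sea*` sea-exclusive), so per-taxon fitness can be supplied by
#' name. Default per-4-day fitness factors treat each parent community as
#' near equilibrium in its native medium and penalise freshwater taxa
#' sharply in sea-influenced medium, giving sea-origin taxa the planted
#' advantage after mixing (river-exclusive: 1.0 in river medium, 0.45 in
#' sea medium; shared: 1.0/1.0; sea-exclusive: 0.85/1.05).
#'
#' @param n_taxa_river,n_taxa_sea Sizes of the parent taxon pools.
#' @param n_shared Number of taxa present in both pools
#'   (`<= min(n_taxa_river, n_taxa_sea)`).
#' @param base_concentration Dirichlet concentration of the base community
#'   draw (small values give realistic, skewed abundance distributions).
#' @param replicate_theta Concentration of the replicate-level Dirichlet
#'   resampling around the base composition (larger = tighter replicates).
#' @param n_replicates Replicates per treatment (default 5).
#' @param mixing_ratios List of `c(river_parts, sea_parts)` pairs.
#' @param days Sampling days; exchanges happen every 4 days.
#' @param exchange_fraction Volume fraction exchanged at each transfer,
#'   in (0, 1).
#' @param n_positive_block Number of shared taxa coupled through a common
#'   positive latent factor.
#' @param positive_loading Loading of the positive block factor.
#' @param n_negative_pairs Number of shared taxon pairs coupled through
#'   opposite-sign latent factors.
#' @param negative_loading Loading of the negative pair factors.
#' @param n_env_sensitive Number of environmentally sensitive taxa per
#'   parent. On the river side these are the most abundant river-exclusive
#'   taxa (the dominant freshwater groups are the ones hit by brackish
#'   admixture); on the sea side the next abundance tier of sea-exclusive
#'   taxa (the sea community is less impacted by environmental coalescence,
#'   and its dominant taxa respond to biotic rather than environmental
#'   effects).
#' @param env_decline_river,env_decline_sea Decline multipliers in (0, 1]
#'   applied to the sensitive taxa of each parent on exposure to mixed
#'   medium (river taxa crash hard, sea taxa decline mildly).
#' @param fitness_river,fitness_sea Optional named per-taxon growth factors
#'   per 4-day step in river and sea medium; defaults by taxon origin as
#'   above.
#' @param sequencing_depth Reads per sample for the multinomial observation.
#' @param seed Integer master seed.
#' @return A `synthetic_spec` list (validated).
#' @export
synthetic_spec <- function(n_taxa_river = 80L, n_taxa_sea = 80L,
                           n_shared = 40L, base_concentration = 0.4,
                           replicate_theta = 400, n_replicates = 5L,
                           mixing_ratios = list(c(1, 1), c(1, 2), c(2, 1)),
                           days = c(0L, 4L, 8L, 12L, 16L),
                           exchange_fraction = 0.2,
                           n_positive_block = 8L, positive_loading = 0.8,
                           n_negative_pairs = 4L, negative_loading = 0.8,
                           n_env_sensitive = 10L,
                           env_decline_river = 0.05, env_decline_sea = 0.4,
                           fitness_river = NULL, fitness_sea = NULL,
                           sequencing_depth = 5000L, seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  if (n_taxa_river < 1L) fail("n_taxa_river", "must be positive")
  if (n_taxa_sea < 1L) fail("n_taxa_sea", "must be positive")
  if (n_shared < 0L || n_shared > min(n_taxa_river, n_taxa_sea)) {
    fail("n_shared", "must satisfy 0 <= n_shared <= min(pool sizes)")
  }
  if (base_concentration <= 0) fail("base_concentration", "must be > 0")
  if (replicate_theta <= 0) fail("replicate_theta", "must be > 0")
  if (n_replicates < 1L) fail("n_replicates", "must be >= 1")
  if (exchange_fraction <= 0 || exchange_fraction >= 1) {
    fail("exchange_fraction", "must lie in (0, 1)")
  }
  if (env_decline_river <= 0 || env_decline_river > 1) {
    fail("env_decline_river", "must lie in (0, 1]")
  }
  if (env_decline_sea <= 0 || env_decline_sea > 1) {
    fail("env_decline_sea", "must lie in (0, 1]")
  }
  if (sequencing_depth < 1L) fail("sequencing_depth", "must be >= 1")
  if (!is.list(mixing_ratios) || !length(mixing_ratios) ||
      !all(vapply(mixing_ratios, function(r)
        is.numeric(r) && length(r) == 2L && all(r >= 0) && sum(r) > 0,
        logical(1L)))) {
    fail("mixing_ratios", "must be pairs of non-negative parts, not both zero")
  }
  if (n_positive_block + 2L * n_negative_pairs > n_shared) {
    fail("n_positive_block", "block and pair taxa exceed the shared pool")
  }
  if (n_env_sensitive > min(n_taxa_river, n_taxa_sea) - n_shared) {
    fail("n_env_sensitive", "exceeds the parent-exclusive pool")
  }

  riv <- sprintf("Riv%03d", seq_len(n_taxa_river - n_shared))
  shr <- sprintf("Shr%03d", seq_len(n_shared))
  sea <- sprintf("Sea%03d", seq_len(n_taxa_sea - n_shared))
  taxa <- c(riv, shr, sea)
  origin <- rep(c("river", "shared", "sea"),
                c(length(riv), length(shr), length(sea)))
  def_fr <- c(river = 1.00, shared = 1.00, sea = 0.85)
  def_fs <- c(river = 0.45, shared = 1.00, sea = 1.05)
  norm_fitness <- function(v, field) {
    if (!is.null(names(v))) {
      if (!setequal(names(v), taxa)) {
        fail(field, "names must match the taxon identifiers")
      }
      v <- v[taxa]
    }
    if (length(v) != length(taxa) || !is.numeric(v) || any(v <= 0)) {
      fail(field, "must be one positive value per taxon")
    }
    unname(v)
  }
  f_river <- norm_fitness(fitness_river %||% unname(def_fr[origin]),
                          "fitness_river")
  f_sea <- norm_fitness(fitness_sea %||% unname(def_fs[origin]),
                        "fitness_sea")
  structure(list(n_taxa_river = n_taxa_river, n_taxa_sea = n_taxa_sea,
                 n_shared = n_shared,
                 base_concentration = base_concentration,
                 replicate_theta = replicate_theta,
                 n_replicates = n_replicates,
                 mixing_ratios = mixing_ratios, days = sort(unique(days)),
                 exchange_fraction = exchange_fraction,
                 n_positive_block = n_positive_block,
                 positive_loading = positive_loading,
                 n_negative_pairs = n_negative_pairs,
                 negative_loading = negative_loading,
                 n_env_sensitive = n_env_sensitive,
                 env_decline_river = env_decline_river,
                 env_decline_sea = env_decline_sea,
                 taxa = data.frame(taxon_id = taxa, origin = origin,
                                   f_river = f_river, f_sea = f_sea,
                                   stringsAsFactors = FALSE),
                 sequencing_depth = as.integer(sequencing_depth),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

replicate_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else sprintf("r%02d", seq_len(n))
}

observe_counts <- function(latent, depth) {
  counts <- t(apply(latent, 1L, function(p)
    stats::rmultinom(1L, depth, p)[, 1L]))
  dimnames(counts) <- dimnames(latent)
  community_matrix(counts, "counts")
}

normalise_rows <- function(m) m / rowSums(m)

## per-step growth factor blended by the medium's river fraction rho
growth_factors <- function(spec, rho) {
  spec$taxa$f_river^rho * spec$taxa$f_sea^(1 - rho)
}

grow <- function(latent, spec, rho, steps = 1L) {
  g <- growth_factors(spec, rho)
  for (i in seq_len(steps)) {
    latent <- normalise_rows(latent * rep(g, each = nrow(latent)))
  }
  latent
}

## one-shot environmental-filter multiplier for material entering mixed
## medium: sensitive taxa are knocked down by the decline factor
env_filter_composition <- function(latent, spec, truth) {
  sr <- truth$env_sensitive_river
  ss <- truth$env_sensitive_sea
  latent[, sr] <- latent[, sr, drop = FALSE] * spec$env_decline_river
  latent[, ss] <- latent[, ss, drop = FALSE] * spec$env_decline_sea
  normalise_rows(latent)
}

#' Generate the two parent communities
#'
#' Draws base compositions for the river (R) and sea (S) parent communities
#' over partially overlapping taxon pools, adds replicate-level Dirichlet
#' variation, plants the positive-block and negative-pair correlation
#' structure through shared latent factors, and observes day-0 counts by
#' multinomial sampling at the sequencing depth. Deterministic under `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return List with `latent` (day-0 latent compositions, replicate x taxon,
#'   for `R` and `S`), `counts` (day-0 [community_matrix()] objects),
#'   `truth` (base compositions, planted block/pair memberships, sensitive
#'   sets, fitness table, seed) and `spec`.
#' @export
generate_parents <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  taxa <- spec$taxa$taxon_id
  p <- length(taxa)
  reps <- replicate_labels(spec$n_replicates)
  with_seed(seed, {
    support <- list(
      R = spec$taxa$origin %in% c("river", "shared"),
      S = spec$taxa$origin %in% c("sea", "shared"))
    base <- lapply(support, function(s) {
      g <- numeric(p)
      g[s] <- stats::rgamma(sum(s), shape = spec$base_concentration)
      stats::setNames(g / sum(g), taxa)
    })
    excl_r <- spec$taxa$taxon_id[spec$taxa$origin == "river"]
    excl_s <- spec$taxa$taxon_id[spec$taxa$origin == "sea"]
    n_sens <- spec$n_env_sensitive
    sens_r <- excl_r[order(-base$R[excl_r])][seq_len(n_sens)]
    ## sea side: next abundance tier (its dominants are biotically, not
    ## environmentally, sensitive), clipped to the available pool
    rank_s <- excl_s[order(-base$S[excl_s])]
    pick_s <- seq.int(min(n_sens + 1L, length(rank_s)),
                      min(2L * n_sens, length(rank_s)))
    sens_s <- rank_s[pick_s]
    shr <- spec$taxa$taxon_id[spec$taxa$origin == "shared"]
    pool <- sample(shr)
    block <- sort(pool[seq_len(spec$n_positive_block)])
    pair_pool <- pool[spec$n_positive_block +
                        seq_len(2L * spec$n_negative_pairs)]
    pairs <- if (spec$n_negative_pairs > 0L) {
      matrix(pair_pool, ncol = 2L, byrow = TRUE,
             dimnames = list(NULL, c("up", "down")))
    } else {
      matrix(character(0L), 0L, 2L, dimnames = list(NULL, c("up", "down")))
    }
    latent <- lapply(names(base), function(pn) {
      b <- base[[pn]]
      m <- matrix(0, spec$n_replicates, p,
                  dimnames = list(paste0(pn, "_", reps), taxa))
      on <- b > 0
      for (k in seq_len(spec$n_replicates)) {
        w <- numeric(p)
        w[on] <- stats::rgamma(sum(on), shape = b[on] * spec$replicate_theta)
        zb <- stats::rnorm(1L)
        w[taxa %in% block] <- w[taxa %in% block] *
          exp(spec$positive_loading * zb)
        if (nrow(pairs)) {
          zk <- stats::rnorm(nrow(pairs))
          w[match(pairs[, "up"], taxa)] <-
            w[match(pairs[, "up"], taxa)] * exp(spec$negative_loading * zk)
          w[match(pairs[, "down"], taxa)] <-
            w[match(pairs[, "down"], taxa)] * exp(-spec$negative_loading * zk)
        }
        m[k, ] <- w / sum(w)
      }
      m
    })
    names(latent) <- names(base)
    truth <- list(base_r = base$R, base_s = base$S,
                  positive_block = block, negative_pairs = pairs,
                  env_sensitive_river = sens_r, env_sensitive_sea = sens_s,
                  fitness = spec$taxa, seed = as.integer(seed))
    counts <- lapply(latent, observe_counts, depth = spec$sequencing_depth)
    list(latent = latent, counts = counts, truth = truth, spec = spec)
  })
}

#' Apply the environmental filter to the parent communities
#'
#' Models environmental coalescence (incubation of an unmixed community in
#' 1:1 blended media): the latent abundances of the environmentally
#' sensitive taxa are multiplied by their decline factor and the composition
#' renormalised, then observed as multinomial counts.
#'
#' @param parents Output of [generate_parents()].
#' @param decline_river,decline_sea Decline multipliers in (0, 1];
#'   default to the spec values.
#' @param seed Seed for the count observation.
#' @return List with `latent` and `counts` for `Rx` and `Sx`.
#' @export
apply_environmental_filter <- function(parents,
                                       decline_river =
                                         parents$spec$env_decline_river,
                                       decline_sea =
                                         parents$spec$env_decline_sea,
                                       seed = parents$spec$seed + 1L) {
  spec <- parents$spec
  for (d in c(decline_river, decline_sea)) {
    if (d <= 0 || d > 1) {
      stop("decline multiplier must lie in (0, 1]", call. = FALSE)
    }
  }
  filt <- function(pn, sens, decline) {
    m <- parents$latent[[pn]]
    m[, sens] <- m[, sens, drop = FALSE] * decline
    out <- normalise_rows(m)
    rownames(out) <- sub(paste0("^", pn, "_"), paste0(pn, "x_"),
                         rownames(m))
    out
  }
  latent <- list(Rx = filt("R", parents$truth$env_sensitive_river,
                           decline_river),
                 Sx = filt("S", parents$truth$env_sensitive_sea,
                           decline_sea))
  counts <- with_seed(seed,
    lapply(latent, observe_counts, depth = spec$sequencing_depth))
  list(latent = latent, counts = counts)
}

## deterministic latent trajectory of an unmixed parent culture in its own
## medium (medium exchanges with sterile filtrate leave proportions alone)
parent_latent_at <- function(parents, parent = c("R", "S"), day) {
  parent <- match.arg(parent)
  spec <- parents$spec
  rho <- if (parent == "R") 1 else 0
  steps <- as.integer(day %/% 4L)
  grow(parents$latent[[parent]], spec, rho, steps)
}

#' Simulate one coalescence treatment
#'
#' Day-0 composition is the ratio-weighted convex mixture of the paired
#' parent replicates, passed through the environmental filter (the mixed
#' medium knocks sensitive taxa down). Each 4-day interval applies one
#' growth step with fitness blended by the medium's river fraction, then the
#' volume exchange: one-time coalescence (OC) exchanges against cell-free
#' medium - a pure dilution that leaves proportions unchanged - while
#' repeated coalescence (RC) replaces `exchange_fraction` of the volume with
#' the fresh parent mixture at the treatment ratio (itself environmentally
#' filtered on entry). Sampling happens before the exchange, as in a
#' serial-transfer design. Counts are multinomial at the sequencing depth.
#'
#' @param spec A [synthetic_spec()].
#' @param parents Output of [generate_parents()].
#' @param mode `"OC"` (one-time) or `"RC"` (repeated).
#' @param ratio `c(river_parts, sea_parts)`.
#' @param seed Seed for the count observations.
#' @return List with `mode`, `ratio`, `latent` (list per sampled day of
#'   replicate x taxon compositions) and `counts` (list per sampled day of
#'   [community_matrix()] objects).
#' @export
simulate_coalescence <- function(spec, parents, mode = c("OC", "RC"),
                                 ratio, seed = spec$seed + 2L) {
  if (!is.character(mode) || !all(mode %in% c("OC", "RC"))) {
    stop("unknown coalescence mode: ", paste(mode, collapse = ", "),
         call. = FALSE)
  }
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.numeric(ratio) || length(ratio) != 2L || any(ratio < 0) ||
      sum(ratio) == 0) {
    stop("`ratio` must be two non-negative parts, not both zero",
         call. = FALSE)
  }
  rho <- ratio[1L] / sum(ratio)
  f <- spec$exchange_fraction
  lab <- sprintf("%s_%d%d_", mode, ratio[1L], ratio[2L])
  mixture_at <- function(day) {
    mR <- parent_latent_at(parents, "R", day)
    mS <- parent_latent_at(parents, "S", day)
    mix <- rho * mR + (1 - rho) * mS
    env_filter_composition(mix, spec, parents$truth)
  }
  days <- spec$days
  latent <- mixture_at(0)
  rownames(latent) <- sub("^R_", lab, rownames(parents$latent$R))
  series <- list(`0` = latent)
  for (i in seq_along(days)[-1L]) {
    steps <- as.integer((days[i] - days[i - 1L]) %/% 4L)
    latent <- grow(latent, spec, rho, steps)
    series[[as.character(days[i])]] <- latent
    if (i < length(days) && mode == "RC" && f > 0) {
      top_up <- mixture_at(days[i])
      rownames(top_up) <- rownames(latent)
      latent <- normalise_rows((1 - f) * latent + f * top_up)
    }
  }
  counts <- with_seed(seed,
    lapply(series, observe_counts, depth = spec$sequencing_depth))
  list(mode = mode, ratio = ratio, latent = series, counts = counts)
}

#' Simulate a complete coalescence experiment
#'
#' Generates the parents, the environmental-coalescence treatments and all
#' OC/RC x ratio treatments, observes day-16 (final day) counts for every
#' sequenced community, and assembles the experiment design covering all
#' cultures - including the ten cell-free medium flasks (Rm, Sm), which
#' carry no community and are not sequenced. Fully deterministic under the
#' spec seed via fixed per-stage seed offsets.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_experiment`: `counts` (day-16 counts,
#'   sequenced samples x taxa), `design` ([experiment_design()] of all
#'   cultures, with a `sequenced` column), `truth` (ground truth including
#'   the exact expected day-16 mixtures per ratio), `series` (latent
#'   trajectories) and `spec`.
#' @export
simulate_experiment <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- spec$seed
  parents <- generate_parents(spec, seed)
  env <- apply_environmental_filter(parents, seed = seed + 1L)
  final_day <- max(spec$days)
  steps <- as.integer(final_day %/% 4L)

  ## parents and environmental treatments grown to the final day
  lat16 <- list(
    R = grow(parents$latent$R, spec, 1, steps),
    S = grow(parents$latent$S, spec, 0, steps),
    Rx = grow(env$latent$Rx, spec, 0.5, steps),
    Sx = grow(env$latent$Sx, spec, 0.5, steps))
  co <- list()
  k <- 0L
  for (mode in c("OC", "RC")) {
    for (r in spec$mixing_ratios) {
      k <- k + 1L
      sim <- simulate_coalescence(spec, parents, mode, r,
                                  seed = seed + 10L + k)
      nm <- sprintf("%s_%d%d", mode, r[1L], r[2L])
      co[[nm]] <- sim
      lat16[[nm]] <- sim$latent[[as.character(final_day)]]
    }
  }
  all_latent <- do.call(rbind, lat16)
  counts <- with_seed(seed + 100L,
                      observe_counts(all_latent, spec$sequencing_depth))

  reps <- replicate_labels(spec$n_replicates)
  rows <- list()
  for (src in c("R", "S", "Rx", "Sx")) {
    rows[[src]] <- data.frame(
      sample_id = paste0(src, "_", reps), source = src,
      river_parts = NA_real_, sea_parts = NA_real_, replicate = reps,
      day = final_day, sequenced = TRUE, stringsAsFactors = FALSE)
  }
  for (mode in c("OC", "RC")) {
    for (r in spec$mixing_ratios) {
      nm <- sprintf("%s_%d%d", mode, r[1L], r[2L])
      rows[[nm]] <- data.frame(
        sample_id = paste0(nm, "_", reps), source = mode,
        river_parts = r[1L], sea_parts = r[2L], replicate = reps,
        day = final_day, sequenced = TRUE, stringsAsFactors = FALSE)
    }
  }
  for (src in c("Rm", "Sm")) { # cell-free medium flasks, not sequenced
    rows[[src]] <- data.frame(
      sample_id = paste0(src, "_", reps), source = src,
      river_parts = NA_real_, sea_parts = NA_real_, replicate = reps,
      day = final_day, sequenced = FALSE, stringsAsFactors = FALSE)
  }
  design <- experiment_design(do.call(rbind, c(rows, make.row.names = FALSE)))

  expected <- lapply(spec$mixing_ratios, function(r) {
    rho <- r[1L] / sum(r)
    e <- rho * lat16$R + (1 - rho) * lat16$S
    rownames(e) <- paste0(sprintf("EXP_%d%d_", r[1L], r[2L]), reps)
    e
  })
  names(expected) <- vapply(spec$mixing_ratios, function(r)
    sprintf("%d%d", r[1L], r[2L]), character(1L))

  truth <- c(parents$truth,
             list(parent_day16_latent = lat16[c("R", "S")],
                  expected_day16_mixture = expected,
                  latent_day16 = all_latent))
  structure(list(counts = counts, design = design, truth = truth,
                 series = c(list(parents = parents$latent,
                                 env = env$latent), co),
                 spec = spec),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment to disk
#'
#' Emits `otu_table.tsv` (taxa as rows), `metadata.tsv` and `truth.json`
#' into `out_dir`; the table and metadata round-trip through
#' [read_community_table()] and [read_experiment_design()].
#'
#' @param experiment Output of [simulate_experiment()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_dataset <- function(experiment, out_dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(otu_table = file.path(out_dir, "otu_table.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_community_table(experiment$counts, paths[["otu_table"]])
  write_experiment_design(experiment$design, paths[["metadata"]])
  tr <- experiment$truth
  json <- list(base_r = as.list(tr$base_r), base_s = as.list(tr$base_s),
               positive_block = tr$positive_block,
               negative_pairs = apply(tr$negative_pairs, 1L, as.list),
               env_sensitive_river = tr$env_sensitive_river,
               env_sensitive_sea = tr$env_sensitive_sea,
               fitness = tr$fitness,
               expected_day16_mixture = lapply(tr$expected_day16_mixture,
                                               function(m) {
                 stats::setNames(lapply(seq_len(nrow(m)), function(i)
                   as.list(m[i, ])), rownames(m))
               }),
               seed = tr$seed)
  jsonlite::write_json(json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Simulate taxa with planted coupling structure
#'
#' Lightweight community simulator for calibrating and validating the
#' cohesion chain: taxa respond to a heterogeneous environmental-synchrony
#' factor (per-taxon loadings uniform on `[0, 2 * sync_loading]`), an
#' optional block shares a positive latent factor, and a fraction of taxon
#' pairs is coupled with opposite signs; multiplicative lognormal noise is
#' added and rows are closed to relative abundances (or multinomial counts
#' when `depth` is given).
#'
#' @param n_samples,n_taxa Dimensions.
#' @param block Integer indices of the positively coupled block (may be
#'   empty).
#' @param block_loading Loading of the shared block factor.
#' @param neg_fraction Fraction of taxa tied up in negatively coupled pairs
#'   (pairs drawn outside `block`).
#' @param neg_loading Loading of the pair factors.
#' @param sync_loading Scale of the heterogeneous synchrony loadings.
#' @param noise_sd Lognormal noise standard deviation.
#' @param depth Optional multinomial sequencing depth (counts output;
#'   implies closure).
#' @param close Close rows to relative abundances (default). With
#'   `close = FALSE` the raw latent abundances are returned, which keeps
#'   planted positive and negative couplings separable: closure itself ties
#'   the two together (a compositional artefact discussed in the vignette).
#' @param seed Integer seed.
#' @return List with `matrix` (a [community_matrix()], or a plain abundance
#'   matrix when `close = FALSE`), `block` (indices) and `negative_pairs`
#'   (two-column index matrix).
#' @export
simulate_coupled_taxa <- function(n_samples, n_taxa, block = integer(0L),
                                  block_loading = 0.8, neg_fraction = 0,
                                  neg_loading = 1, sync_loading = 0.3,
                                  noise_sd = 0.3, depth = NULL,
                                  close = TRUE, seed = 1L) {
  stopifnot(n_samples >= 3L, n_taxa >= 2L,
            neg_fraction >= 0, neg_fraction <= 1)
  with_seed(seed, {
    base <- exp(stats::rnorm(n_taxa, 0, 1))
    sync <- stats::runif(n_taxa, 0, 2 * sync_loading)
    n_pairs <- floor(neg_fraction * n_taxa / 2)
    candidates <- setdiff(seq_len(n_taxa), block)
    if (2L * n_pairs > length(candidates)) {
      stop("not enough taxa outside the block for the requested pairs",
           call. = FALSE)
    }
    pair_idx <- if (n_pairs > 0L) {
      matrix(sample(candidates, 2L * n_pairs), ncol = 2L)
    } else {
      matrix(integer(0L), 0L, 2L)
    }
    m <- matrix(0, n_samples, n_taxa,
                dimnames = list(sprintf("sample%03d", seq_len(n_samples)),
                                sprintf("taxon%03d", seq_len(n_taxa))))
    for (s in seq_len(n_samples)) {
      w <- base * exp(sync * stats::rnorm(1L))
      if (length(block)) {
        w[block] <- w[block] * exp(block_loading * stats::rnorm(1L))
      }
      if (n_pairs > 0L) {
        zk <- stats::rnorm(n_pairs)
        w[pair_idx[, 1L]] <- w[pair_idx[, 1L]] * exp(neg_loading * zk)
        w[pair_idx[, 2L]] <- w[pair_idx[, 2L]] * exp(-neg_loading * zk)
      }
      w <- w * exp(stats::rnorm(n_taxa, 0, noise_sd))
      m[s, ] <- if (close || !is.null(depth)) w / sum(w) else w
    }
    cm <- if (!is.null(depth)) {
      observe_counts(m, depth)
    } else if (close) {
      community_matrix(m, "relative")
    } else {
      m
    }
    list(matrix = cm, block = block, negative_pairs = pair_idx)
  })
}
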