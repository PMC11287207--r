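#' Pipeline configuration
#'
#' Exactly one input source: either paths to an OTU table and metadata (and
#' optionally a taxonomy table), or a [synthetic_spec()] to simulate.
#'
#' @param otu_table,metadata,taxonomy Input file paths, or `NULL`.
#' @param synthetic A [synthetic_spec()], or `NULL`.
#' @param rarefaction_depth Reads per sample for rarefaction; diversity and
#'   mixing-model stages consume the rarefied table, the cohesion stage the
#'   non-rarefied one.
#' @param prevalence_threshold Strict prevalence filter fraction.
#' @param alpha Significance / FDR cutoff used throughout.
#' @param n_perm Permutations for differential abundance.
#' @param n_null_iter Null-model iterations for cohesion.
#' @param seed Master seed; stage seeds are derived as fixed small offsets.
#' @param out_dir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(otu_table = NULL, metadata = NULL,
                            taxonomy = NULL, synthetic = NULL,
                            rarefaction_depth = 4752L,
                            prevalence_threshold = 0.1, alpha = 0.05,
                            n_perm = 999L, n_null_iter = 200L, seed = 1L,
                            out_dir = tempfile("commcoal_run_")) {
  have_files <- !is.null(otu_table) || !is.null(metadata)
  have_synth <- !is.null(synthetic)
  if (have_files == have_synth) {
    stop("provide exactly one of {otu_table+metadata, synthetic}",
         call. = FALSE)
  }
  if (have_files && (is.null(otu_table) || is.null(metadata))) {
    stop("file input needs both `otu_table` and `metadata`", call. = FALSE)
  }
  if (have_synth && !inherits(synthetic, "synthetic_spec")) {
    stop("`synthetic` must be a synthetic_spec", call. = FALSE)
  }
  stopifnot(rarefaction_depth >= 1, prevalence_threshold >= 0,
            prevalence_threshold < 1, alpha > 0, alpha < 1, n_perm >= 1,
            n_null_iter >= 1)
  structure(list(otu_table = otu_table, metadata = metadata,
                 taxonomy = taxonomy, synthetic = synthetic,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 prevalence_threshold = prevalence_threshold, alpha = alpha,
                 n_perm = as.integer(n_perm),
                 n_null_iter = as.integer(n_null_iter),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

samples_of <- function(design, source, ratio = NULL) {
  sel <- design$source == source & design$sequenced %||% TRUE
  if (!is.null(ratio)) {
    sel <- sel & design$river_parts == ratio[1L] &
      design$sea_parts == ratio[2L]
  }
  design$sample_id[sel & !is.na(design$sample_id)]
}

subset_cm <- function(cm, samples) {
  m <- as.matrix(cm)[samples, , drop = FALSE]
  community_matrix(m, cm_kind(cm))
}

write_stage <- function(out_dir, stage, name, df) {
  dir.create(file.path(out_dir, stage), recursive = TRUE,
             showWarnings = FALSE)
  path <- file.path(out_dir, stage, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full coalescence-analysis pipeline
#'
#' Orchestrates the analysis in the order the design calls for: input
#' validation, rarefaction, alpha diversity (on the rarefied table),
#' cohesion and stability (on the non-rarefied table, as the cohesion metric
#' recommends), the environmental screen (parent vs environmental
#' coalescence), the biotic response of screened taxa against the expected
#' parent mixture, aggregate response abundances, and the mixing-model
#' predictability and parent-convergence analysis (on the rarefied table).
#' Every stage's tables are written under `out_dir/<stage>/` together with a
#' JSON manifest of parameters, seeds and input checksums. Deterministic
#' under the config seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- list()
  manifest <- list(package = "commcoal",
                   version = as.character(utils::packageVersion("commcoal")),
                   parameters = config[c("rarefaction_depth",
                                         "prevalence_threshold", "alpha",
                                         "n_perm", "n_null_iter", "seed")],
                   stages = list())
  run_stage <- function(name, code) {
    stage <<- name
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  ## ---- input -------------------------------------------------------------
  inp <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      ex <- simulate_experiment(config$synthetic)
      list(counts = ex$counts, design = ex$design, experiment = ex)
    } else {
      design <- read_experiment_design(config$metadata)
      counts <- read_community_table(config$otu_table)
      missing_meta <- setdiff(sample_ids(counts), design$sample_id)
      if (length(missing_meta)) {
        stop("samples without metadata: ",
             paste(missing_meta, collapse = ", "))
      }
      list(counts = counts, design = design,
           checksums = as.list(tools::md5sum(c(config$otu_table,
                                               config$metadata))))
    }
  })
  counts <- inp$counts
  design <- inp$design
  if (is.null(design$sequenced)) design$sequenced <- TRUE
  manifest$input_checksums <- inp$checksums %||% list()
  manifest$stages$input <- write_stage(out_dir, "input", "metadata.tsv",
                                       as.data.frame(design))
  write_community_table(counts, file.path(out_dir, "input",
                                          "otu_table.tsv"))

  ## ---- rarefaction -------------------------------------------------------
  rare <- run_stage("rarefy", {
    rarefy(counts, config$rarefaction_depth, seed = config$seed + 1L)
  })
  manifest$stages$rarefy <-
    write_stage(out_dir, "rarefy", "rarefied_counts.tsv",
                data.frame(taxon_id = taxon_ids(rare),
                           t(as.matrix(rare)), check.names = FALSE))
  rare_rel <- to_relative(rare)

  ## ---- diversity ---------------------------------------------------------
  diversity <- run_stage("diversity", {
    div <- alpha_diversity(rare)
    grp <- design$source[match(div$sample_id, design$sample_id)]
    tests <- compare_alpha(div, grp, alpha = config$alpha)
    list(per_sample = div, groups = grp, tests = tests)
  })
  manifest$stages$diversity <-
    write_stage(out_dir, "diversity", "alpha_diversity.tsv",
                diversity$per_sample)

  ## ---- cohesion (non-rarefied, as the metric recommends) -----------------
  coh <- run_stage("cohesion", {
    cc <- community_cohesion(counts, n_iter = config$n_null_iter,
                             seed = config$seed + 2L,
                             prevalence_threshold =
                               config$prevalence_threshold)
    grp <- design$source[match(cc$samples$sample_id, design$sample_id)]
    cc$comparison <- compare_stability(cc$samples$stability, grp,
                                       alpha = config$alpha)
    cc$groups <- grp
    cc
  })
  manifest$stages$cohesion <-
    write_stage(out_dir, "cohesion", "cohesion.tsv", coh$samples)
  write_stage(out_dir, "cohesion", "connectedness.tsv", coh$connectedness)
  write_stage(out_dir, "cohesion", "stability_tests.tsv", coh$comparison)

  rel_all <- to_relative(counts)
  get_group <- function(src, ratio = NULL, cm = rare_rel) {
    ids <- intersect(samples_of(design, src, ratio), sample_ids(cm))
    subset_cm(cm, ids)
  }

  ## ---- environmental screen ----------------------------------------------
  screen <- run_stage("screen", {
    sc <- list()
    for (p in c("R", "S")) {
      px <- paste0(p, "x")
      sc[[p]] <- environmental_screen(get_group(p), get_group(px),
                                      alpha = config$alpha,
                                      n_perm = config$n_perm,
                                      seed = config$seed + 3L)
    }
    sc$retained <- union(sc$R, sc$S)
    sc
  })
  manifest$stages$screen <-
    write_stage(out_dir, "screen", "screened_taxa.tsv",
                data.frame(taxon_id = screen$retained))

  ## ---- biotic response ----------------------------------------------------
  respond <- run_stage("respond", {
    out <- list()
    ratios <- unique(stats::na.omit(
      design[design$source %in% c("OC", "RC"), c("river_parts", "sea_parts")]))
    for (mode in c("OC", "RC")) {
      for (i in seq_len(nrow(ratios))) {
        r <- as.numeric(ratios[i, ])
        coal <- get_group(mode, r)
        if (!nrow(coal)) next
        ## reference: ratio-weighted expected mixture of the paired parents
        pr <- as.matrix(get_group("R"))
        ps <- as.matrix(get_group("S"))
        stopifnot(nrow(pr) == nrow(coal))
        expd <- (r[1L] * pr + r[2L] * ps) / sum(r)
        rownames(expd) <- rownames(as.matrix(coal))
        nm <- sprintf("%s_%d%d", mode, r[1L], r[2L])
        out[[nm]] <- biotic_response(
          coal, expd, screen$retained, n_perm = config$n_perm,
          seed = config$seed + 4L, alpha = config$alpha,
          prevalence_threshold = config$prevalence_threshold)
      }
    }
    treatments <- names(out)
    out$increased <- sort(unique(unlist(
      lapply(out[treatments], `[[`, "increased"))))
    out$decreased <- sort(unique(unlist(
      lapply(out[treatments], `[[`, "decreased"))))
    treat_groups <- lapply(stats::setNames(nm = treatments),
                           function(nm) {
      mode <- sub("_.*$", "", nm)
      r <- as.numeric(strsplit(sub("^[A-Z]+_", "", nm), "")[[1L]])
      get_group(mode, r)
    })
    out$aggregate_decreased <- aggregate_response(treat_groups,
                                                  out$decreased)
    out$aggregate_increased <- aggregate_response(treat_groups,
                                                  out$increased)
    out
  })
  manifest$stages$respond <-
    write_stage(out_dir, "respond", "response_sets.tsv",
                data.frame(taxon_id = c(respond$increased,
                                        respond$decreased),
                           direction = rep(c("increase", "decrease"),
                                           c(length(respond$increased),
                                             length(respond$decreased)))))

  ## ---- mixing model --------------------------------------------------------
  mix <- run_stage("mix_expect", {
    pr <- as.matrix(get_group("R"))
    ps <- as.matrix(get_group("S"))
    obs_all <- NULL
    exp_all <- NULL
    treat <- character(0L)
    ratios <- unique(stats::na.omit(
      design[design$source %in% c("OC", "RC"), c("river_parts", "sea_parts")]))
    for (mode in c("OC", "RC")) {
      for (i in seq_len(nrow(ratios))) {
        r <- as.numeric(ratios[i, ])
        coal <- as.matrix(get_group(mode, r))
        if (!nrow(coal)) next
        expd <- (r[1L] * pr + r[2L] * ps) / sum(r)
        rownames(expd) <- rownames(coal)
        obs_all <- rbind(obs_all, coal)
        exp_all <- rbind(exp_all, expd)
        treat <- c(treat, rep(sprintf("%s_%d%d", mode, r[1L], r[2L]),
                              nrow(coal)))
      }
    }
    pred <- predictability(obs_all, exp_all, treatment = treat,
                           alpha = config$alpha)
    conv <- parent_convergence(obs_all, exp_all,
                               parent_r = colMeans(pr),
                               parent_s = colMeans(ps),
                               alpha = config$alpha)
    list(predictability = pred, convergence = conv)
  })
  manifest$stages$mix_expect <-
    write_stage(out_dir, "mix_expect", "predictability.tsv",
                mix$predictability$replicates)
  write_stage(out_dir, "mix_expect", "convergence.tsv", mix$convergence)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  res <- list(counts = counts, design = design, rarefied = rare,
              diversity = diversity, cohesion = coh, screen = screen,
              respond = respond, mixing = mix, manifest = manifest,
              manifest_path = manifest_path, out_dir = out_dir)
  invisible(res)
}
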