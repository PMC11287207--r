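## Conservative mixing model: expected coalesced communities, Bray-Curtis
## predictability and convergence toward the parent communities.

align_compositions <- function(...) {
  vs <- list(...)
  nm <- sort(unique(unlist(lapply(vs, names))))
  if (is.null(nm) || !length(nm)) {
    ## unnamed vectors: require equal lengths
    len <- unique(vapply(vs, length, integer(1L)))
    if (length(len) != 1L) stop("unnamed compositions must share length",
                                call. = FALSE)
    return(vs)
  }
  lapply(vs, function(v) {
    out <- stats::setNames(numeric(length(nm)), nm)
    out[names(v)] <- v
    out
  })
}

#' Expected coalesced community under the conservative mixing model
#'
#' The expected composition of a coalesced microcosm is the ratio-weighted
#' convex combination of the two parent compositions, assuming no species
#' interactions or selection: `E = (r * R + s * S) / (r + s)` over the union
#' taxon set (taxa absent from a parent count as zero).
#'
#' @param parent_r,parent_s Named relative-abundance vectors of the river
#'   and sea parent communities (each summing to 1).
#' @param ratio Numeric pair `c(river_parts, sea_parts)`, non-negative and
#'   not both zero.
#' @return Named relative composition over the union taxon set, summing to 1.
#' @examples
#' expected_community(c(a = 0.8, b = 0.2), c(a = 0.2, b = 0.8), c(1, 1))
#' @export
expected_community <- function(parent_r, parent_s, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 2L || any(ratio < 0)) {
    stop("`ratio` must be two non-negative numbers", call. = FALSE)
  }
  if (sum(ratio) == 0) stop("ratio parts must not both be zero", call. = FALSE)
  for (v in list(parent_r, parent_s)) {
    if (abs(sum(v) - 1) > 1e-6) {
      stop("parent compositions must sum to 1", call. = FALSE)
    }
  }
  al <- align_compositions(parent_r, parent_s)
  (ratio[1L] * al[[1L]] + ratio[2L] * al[[2L]]) / sum(ratio)
}

#' Bray-Curtis similarity of two compositions
#'
#' Defined as 1 minus the Bray-Curtis dissimilarity,
#' `1 - sum(|x - y|) / sum(x + y)`; symmetric, in `[0, 1]`, and 1 exactly
#' when the compositions coincide.
#'
#' @param x,y Non-negative abundance vectors; named vectors are aligned on
#'   the union of their names (absent taxa zero-filled).
#' @return Similarity in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(x, y) {
  al <- align_compositions(x, y)
  x <- al[[1L]]
  y <- al[[2L]]
  if (sum(x) == 0 && sum(y) == 0) {
    stop("both compositions are all-zero", call. = FALSE)
  }
  d <- as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
  1 - d
}

rowwise_bc_similarity <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    bray_curtis_similarity(a[i, ], b[i, ])
  }, numeric(1L))
}

align_replicate_matrices <- function(observed, expected,
                                     arg = c("observed", "expected")) {
  if (is.null(rownames(observed)) || is.null(rownames(expected))) {
    stop("replicate row names are required on both matrices", call. = FALSE)
  }
  orph_o <- setdiff(rownames(observed), rownames(expected))
  orph_e <- setdiff(rownames(expected), rownames(observed))
  if (length(orph_o) || length(orph_e)) {
    stop("unpaired replicates - only in ", arg[1L], ": [",
         paste(orph_o, collapse = ", "), "]; only in ", arg[2L], ": [",
         paste(orph_e, collapse = ", "), "]", call. = FALSE)
  }
  nm <- sort(unique(c(colnames(observed), colnames(expected))))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(nm),
                  dimnames = list(rownames(m), nm))
    out[, colnames(m)] <- m
    out[rownames(observed), , drop = FALSE]
  }
  list(observed = pad(observed), expected = pad(expected))
}

## one-sample t of the deviations (1 - similarity) against 0; degenerate
## (constant) deviations are resolved by their value rather than an error
deviation_test <- function(sims) {
  dev <- 1 - sims
  if (length(dev) < 2L || stats::sd(dev) == 0) {
    if (isTRUE(all.equal(mean(dev), 0))) {
      return(c(statistic = 0, p = 1))
    }
    return(c(statistic = Inf, p = 0))
  }
  tt <- stats::t.test(dev, mu = 0)
  c(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Predictability of coalescence outcomes
#'
#' Bray-Curtis similarity between each observed coalesced replicate and its
#' model-expected counterpart, summarised per treatment. Higher mean
#' similarity means a more predictable coalescence outcome. Per treatment a
#' one-sample t-test of the deviations (1 - similarity) against zero asks
#' whether observed communities differ from the expected ones at all; across
#' treatments a one-way ANOVA with Tukey HSD post-hoc compares mean
#' predictability.
#'
#' @param observed,expected Replicate x taxon relative-abundance matrices
#'   with matching replicate row names (taxa aligned on the union,
#'   zero-filled).
#' @param treatment Optional factor of treatment labels per replicate row;
#'   default a single treatment.
#' @param alpha Significance level used in the summaries.
#' @return List of class `predictability`: `replicates` (per-replicate
#'   similarities), `treatments` (mean, sd, deviation-test statistic and p),
#'   and for two or more treatments `anova` (`F`, `p`) and `tukey`
#'   (all-pairs comparisons).
#' @export
predictability <- function(observed, expected, treatment = NULL,
                           alpha = 0.05) {
  al <- align_replicate_matrices(observed, expected)
  sims <- rowwise_bc_similarity(al$observed, al$expected)
  treatment <- if (is.null(treatment)) {
    factor(rep("all", length(sims)))
  } else {
    factor(treatment)
  }
  if (length(treatment) != length(sims)) {
    stop("`treatment` must have one label per replicate", call. = FALSE)
  }
  reps <- data.frame(replicate = rownames(al$observed),
                     treatment = treatment, similarity = sims,
                     stringsAsFactors = FALSE)
  tr <- do.call(rbind, lapply(split(reps$similarity, reps$treatment),
                              function(s) {
    dt <- deviation_test(s)
    data.frame(n = length(s), mean_similarity = mean(s),
               sd_similarity = stats::sd(s),
               deviation_statistic = dt[["statistic"]],
               deviation_p = dt[["p"]])
  }))
  tr <- data.frame(treatment = rownames(tr), tr, row.names = NULL,
                   stringsAsFactors = FALSE)
  out <- list(replicates = reps, treatments = tr, alpha = alpha)
  if (nlevels(treatment) >= 2L && all(table(treatment) >= 2L) &&
      stats::var(sims) > 0) {
    fit <- stats::aov(similarity ~ treatment, data = reps)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$treatment
    out$anova <- c(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L])
    out$tukey <- data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], p_adj = tk[, "p adj"],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  class(out) <- "predictability"
  out
}

#' @export
print.predictability <- function(x, ...) {
  cat("Predictability of coalescence outcomes (Bray-Curtis obs vs expected)\n")
  print(x$treatments, digits = 4)
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA across treatments: F = %.3f, p = %.4g\n",
                x$anova[["F"]], x$anova[["p"]]))
  }
  invisible(x)
}

#' Convergence toward the parent communities
#'
#' For each parent, the Bray-Curtis similarity of every observed coalesced
#' replicate to that parent is compared with the similarity of the matching
#' expected community to the same parent (paired t-test across replicates).
#' Observed communities significantly *more* similar than expected converge
#' toward that parent (asymmetric coalescence); significantly *less* similar
#' communities diverge; otherwise no deviation.
#'
#' @inheritParams predictability
#' @param parent_r,parent_s Parent compositions: either a replicate x taxon
#'   matrix paired with `observed` by row name, or a single named
#'   composition used for every replicate.
#' @return Data frame with one row per parent: mean observed and expected
#'   similarity, paired-t statistic and p, and a classification in
#'   `c("convergence", "divergence", "none")`.
#' @export
parent_convergence <- function(observed, expected, parent_r, parent_s,
                               alpha = 0.05) {
  al <- align_replicate_matrices(observed, expected)
  as_mat <- function(p) {
    if (is.matrix(p)) {
      p[rownames(al$observed), , drop = FALSE]
    } else {
      matrix(rep(p, each = nrow(al$observed)), nrow(al$observed),
             dimnames = list(rownames(al$observed), names(p)))
    }
  }
  one <- function(parent, label) {
    pm <- as_mat(parent)
    apm <- align_replicate_matrices(al$observed, pm)
    sim_obs <- rowwise_bc_similarity(apm$observed, apm$expected)
    apm <- align_replicate_matrices(al$expected, pm)
    sim_exp <- rowwise_bc_similarity(apm$observed, apm$expected)
    d <- sim_obs - sim_exp
    if (stats::sd(d) == 0) {
      stat <- if (isTRUE(all.equal(mean(d), 0))) 0 else Inf * sign(mean(d))
      p <- if (stat == 0) 1 else 0
    } else {
      tt <- stats::t.test(d, mu = 0)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    cls <- if (p < alpha && mean(d) > 0) {
      "convergence"
    } else if (p < alpha && mean(d) < 0) {
      "divergence"
    } else {
      "none"
    }
    data.frame(parent = label, mean_sim_observed = mean(sim_obs),
               mean_sim_expected = mean(sim_exp), statistic = stat,
               p = p, classification = cls, stringsAsFactors = FALSE)
  }
  rbind(one(parent_r, "R"), one(parent_s, "S"))
}
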