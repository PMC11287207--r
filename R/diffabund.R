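#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`p_adj[i] = min over k >= i of m * p(k) / k`
#' after sorting, capped at 1), returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

## random label split distinct from the observed partition; identity and,
## for equal group sizes, the group-swapped labelling are excluded so that
## complete separation can attain the minimal p of 1/(n_perm + 1)
draw_split <- function(n, n_a) {
  id <- seq_len(n_a)
  mirror <- if (2L * n_a == n) seq.int(n_a + 1L, n) else NULL
  repeat {
    idx_a <- sort(sample.int(n, n_a))
    if (!identical(idx_a, id) &&
        (is.null(mirror) || !identical(idx_a, mirror))) {
      return(idx_a)
    }
  }
}

#' Permutation differential-abundance test
#'
#' Per-taxon two-group test on relative abundances. The statistic is the
#' difference of group means (group B minus group A); its null distribution
#' is generated by randomly re-assigning sample labels, and the two-sided
#' p-value is `(1 + #{|stat*| >= |stat|}) / (1 + n_perm)`, so the smallest
#' attainable raw p is `1/(n_perm + 1)`. P-values are BH-adjusted across
#' taxa and a direction (`increase`/`decrease` in B relative to A) is called
#' only for taxa significant after adjustment.
#'
#' @param group_a,group_b [community_matrix()] objects (counts are converted
#'   to relative abundances) or plain sample x taxon matrices sharing the
#'   same taxon set; at least two samples each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param alpha FDR cutoff used for the direction call.
#' @param statistic `"mean"` (difference of group means) or `"rank"`
#'   (difference of mean ranks).
#' @return A `da_result` data frame with per-taxon `statistic`, `p_raw`,
#'   `p_adj`, `direction` and `prevalence`; attributes `n_permutations`,
#'   `seed` and `alpha`.
#' @export
permutation_da_test <- function(group_a, group_b, n_perm = 999L, seed = 1L,
                                alpha = 0.05,
                                statistic = c("mean", "rank")) {
  statistic <- match.arg(statistic)
  rel <- function(g, arg) {
    if (inherits(g, "community_matrix")) as.matrix(to_relative(g))
    else as_abundance_matrix(g, arg)
  }
  a <- rel(group_a, "group_a")
  b <- rel(group_b, "group_b")
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (!setequal(colnames(a), colnames(b))) {
    stop("groups must share the same taxon set", call. = FALSE)
  }
  b <- b[, colnames(a), drop = FALSE]
  if (!is.numeric(n_perm) || n_perm < 1L) {
    stop("`n_perm` must be >= 1", call. = FALSE)
  }
  pooled <- rbind(a, b)
  if (statistic == "rank") {
    pooled <- apply(pooled, 2L, rank)
  }
  n <- nrow(pooled)
  n_a <- nrow(a)
  n_b <- nrow(b)
  obs <- colMeans(pooled[seq.int(n_a + 1L, n), , drop = FALSE]) -
    colMeans(pooled[seq_len(n_a), , drop = FALSE])
  ## weight matrix: one row per permutation, stats via a single matmul
  W <- with_seed(seed, {
    w <- matrix(-1 / n_a, n_perm, n)
    for (r in seq_len(n_perm)) {
      idx_a <- draw_split(n, n_a)
      w[r, -idx_a] <- 1 / n_b
    }
    w
  })
  null_stats <- W %*% pooled
  exceed <- colSums(abs(null_stats) >= matrix(abs(obs), n_perm,
                                              ncol(pooled), byrow = TRUE))
  p_raw <- (1 + exceed) / (1 + n_perm)
  p_adj <- bh_adjust(p_raw)
  direction <- ifelse(p_adj < alpha,
                      ifelse(obs > 0, "increase", "decrease"), "none")
  out <- data.frame(taxon_id = colnames(pooled), statistic = unname(obs),
                    p_raw = unname(p_raw), p_adj = unname(p_adj),
                    direction = direction,
                    prevalence = unname(colMeans(rbind(a, b) > 0)),
                    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  class(out) <- c("da_result", class(out))
  out
}

#' Environmental-coalescence taxon screen
#'
#' Selects the taxa usable for assessing the biotic component of
#' coalescence: taxa present (nonzero in at least one replicate) in both the
#' parent community and its environmental-coalescence treatment, excluding
#' those that significantly *decreased* under the mixed medium
#' (`p_adj < alpha` with a negative statistic). Significant increases are
#' retained.
#'
#' @param parent,env_treated Parent and environmentally coalesced community
#'   matrices (replicates of one treatment each).
#' @param da Optional precomputed [permutation_da_test()] of parent (group A)
#'   versus env_treated (group B); computed if `NULL`.
#' @param alpha FDR cutoff for the decrease call.
#' @param n_perm,seed Passed to [permutation_da_test()] when `da` is `NULL`.
#' @return Character vector of retained taxon ids, with the differential
#'   abundance table in attribute `da`.
#' @export
environmental_screen <- function(parent, env_treated, da = NULL,
                                 alpha = 0.05, n_perm = 999L, seed = 1L) {
  rel <- function(g, arg) {
    if (inherits(g, "community_matrix")) as.matrix(g)
    else as_abundance_matrix(g, arg)
  }
  pm <- rel(parent, "parent")
  em <- rel(env_treated, "env_treated")
  if (is.null(da)) {
    da <- permutation_da_test(parent, env_treated, n_perm = n_perm,
                              seed = seed, alpha = alpha)
  }
  common <- intersect(colnames(pm), colnames(em))
  present <- common[colSums(pm[, common, drop = FALSE]) > 0 &
                      colSums(em[, common, drop = FALSE]) > 0]
  dec <- da$taxon_id[da$p_adj < alpha & da$statistic < 0]
  retained <- setdiff(present, dec)
  attr(retained, "da") <- da
  retained
}

#' Biotic response of screened taxa to community coalescence
#'
#' Runs the permutation differential-abundance test of coalesced communities
#' against a parent reference, restricted to screened taxa with prevalence
#' strictly above `prevalence_threshold` (computed over the pooled samples
#' of the two groups), and returns the significantly increased and decreased
#' taxon sets.
#'
#' @param coalesced Coalesced community matrix (replicates).
#' @param parent_reference Reference community matrix, typically the
#'   ratio-weighted expected parent mixture (see [expected_community()]) or
#'   a single parent.
#' @param screen Character vector of screened taxon ids
#'   ([environmental_screen()]).
#' @param n_perm,seed,alpha Passed to [permutation_da_test()].
#' @param prevalence_threshold Prevalence filter (strict), default 0.1.
#' @return List with `increased`, `decreased` (character vectors) and
#'   `table` (the full `da_result` on the analysed taxa).
#' @export
biotic_response <- function(coalesced, parent_reference, screen,
                            n_perm = 999L, seed = 1L, alpha = 0.05,
                            prevalence_threshold = 0.1) {
  rel <- function(g, arg) {
    if (inherits(g, "community_matrix")) as.matrix(to_relative(g))
    else as_abundance_matrix(g, arg)
  }
  cm <- rel(coalesced, "coalesced")
  pm <- rel(parent_reference, "parent_reference")
  if (!length(screen)) stop("empty screened taxon set", call. = FALSE)
  common <- intersect(intersect(colnames(cm), colnames(pm)), screen)
  pooled <- rbind(cm[, common, drop = FALSE], pm[, common, drop = FALSE])
  keep <- common[colMeans(pooled > 0) > prevalence_threshold]
  if (!length(keep)) stop("no screened taxon passes the prevalence filter",
                          call. = FALSE)
  da <- permutation_da_test(pm[, keep, drop = FALSE],
                            cm[, keep, drop = FALSE],
                            n_perm = n_perm, seed = seed, alpha = alpha)
  list(increased = da$taxon_id[da$direction == "increase"],
       decreased = da$taxon_id[da$direction == "decrease"],
       table = da)
}

#' Aggregate abundance of a response set across treatments
#'
#' Sums, per sample, the relative abundance over a set of responding taxa
#' (e.g. the significantly decreased OTUs) and compares the totals across
#' treatment groups with a Kruskal-Wallis test.
#'
#' @param groups Named list of community matrices (counts converted to
#'   relative), one per treatment group.
#' @param response_set Character vector of taxon ids (may be empty, in which
#'   case totals are 0, the result is flagged and no test is run).
#' @return List with `totals` (data frame sample/group/total), `empty_set`
#'   flag, and unless empty or degenerate a `test` with the Kruskal-Wallis
#'   `statistic`, `df` and `p`.
#' @export
aggregate_response <- function(groups, response_set) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2L) {
    stop("`groups` must be a named list of at least two matrices",
         call. = FALSE)
  }
  rel <- function(g) {
    if (inherits(g, "community_matrix")) as.matrix(to_relative(g))
    else as_abundance_matrix(g, "group")
  }
  tot <- do.call(rbind, lapply(names(groups), function(g) {
    m <- rel(groups[[g]])
    sel <- intersect(colnames(m), response_set)
    data.frame(sample_id = rownames(m), group = g,
               total = if (length(sel)) {
                 rowSums(m[, sel, drop = FALSE])
               } else {
                 rep(0, nrow(m))
               },
               stringsAsFactors = FALSE)
  }))
  out <- list(totals = tot, empty_set = length(response_set) == 0L)
  if (out$empty_set) return(out)
  if (stats::var(tot$total) == 0) {
    out$test <- list(statistic = 0, df = length(groups) - 1L, p = 1,
                     degenerate = TRUE)
  } else {
    kw <- stats::kruskal.test(tot$total, factor(tot$group))
    out$test <- list(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p = kw$p.value,
                     degenerate = FALSE)
  }
  out
}
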