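#' Pairwise taxon correlations across samples
#'
#' Product-moment (or rank) correlation of every taxon pair across samples.
#' Pairs involving a zero-variance taxon are set to 0 and the taxa recorded
#' in the `zero_variance` attribute; the diagonal is set to 0 and ignored
#' downstream.
#'
#' Correlations are computed on whatever abundance scale is supplied; the
#' cohesion workflow uses relative abundances of the non-rarefied table.
#' Note that row-normalising a table of genuinely independent taxa induces a
#' small spurious negative correlation (closure effect of magnitude about
#' 1/(number of taxa - 1)); calibration checks of the null model therefore
#' use unclosed abundance matrices.
#'
#' @param cm A [community_matrix()] (counts are converted to relative) or a
#'   plain sample x taxon abundance matrix used as-is.
#' @param method `"pearson"` (default, the cohesion metric's choice) or
#'   `"spearman"`.
#' @return Symmetric taxon x taxon correlation matrix with zero diagonal.
#' @export
pairwise_correlations <- function(cm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (inherits(cm, "community_matrix")) {
    as.matrix(to_relative(cm))
  } else {
    as_abundance_matrix(cm, "cm")
  }
  if (nrow(m) < 3L) stop("need at least 3 samples to correlate", call. = FALSE)
  if (ncol(m) < 2L) stop("need at least 2 taxa", call. = FALSE)
  cc <- suppressWarnings(stats::cor(m, method = method))
  zv <- colnames(m)[apply(m, 2L, stats::sd) == 0]
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  attr(cc, "zero_variance") <- zv
  cc
}

#' Null-model expected correlations by taxon shuffling
#'
#' For each ordered taxon pair (i, j), taxon j's abundance vector is permuted
#' across samples and re-correlated with taxon i; the average over
#' permutations estimates the correlation expected when the pairing of
#' abundances across samples is broken while each taxon's abundance
#' distribution is kept intact. The (i, j) and (j, i) estimates are averaged
#' to give a symmetric matrix. With `method = "exhaustive"` (samples <= 8)
#' the average runs over all n! permutations instead of Monte-Carlo draws.
#'
#' @inheritParams pairwise_correlations
#' @param n_iter Number of Monte-Carlo permutations (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param method `"sample"` (Monte-Carlo) or `"exhaustive"`.
#' @param cor_method Correlation type, as in [pairwise_correlations()].
#' @return Symmetric taxon x taxon matrix of null-expected correlations.
#' @export
null_expected_correlations <- function(cm, n_iter = 200L, seed = 1L,
                                       method = c("sample", "exhaustive"),
                                       cor_method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cor_method <- match.arg(cor_method)
  m <- if (inherits(cm, "community_matrix")) {
    as.matrix(to_relative(cm))
  } else {
    as_abundance_matrix(cm, "cm")
  }
  n <- nrow(m)
  p <- ncol(m)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (method == "sample" && (!is.numeric(n_iter) || n_iter < 1L)) {
    stop("`n_iter` must be >= 1", call. = FALSE)
  }
  acc <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  if (method == "exhaustive") {
    if (n > 8L) stop("exhaustive enumeration limited to 8 samples",
                     call. = FALSE)
    perms <- all_permutations(n)
    for (r in seq_len(nrow(perms))) {
      cc <- suppressWarnings(stats::cor(m, m[perms[r, ], , drop = FALSE],
                                        method = cor_method))
      cc[is.na(cc)] <- 0
      acc <- acc + cc
    }
    acc <- acc / nrow(perms)
  } else {
    acc <- with_seed(seed, {
      a <- acc
      for (r in seq_len(n_iter)) {
        shuffled <- apply(m, 2L, sample) # independent permutation per taxon
        cc <- suppressWarnings(stats::cor(m, shuffled, method = cor_method))
        cc[is.na(cc)] <- 0
        a <- a + cc
      }
      a / n_iter
    })
  }
  out <- (acc + t(acc)) / 2
  diag(out) <- 0
  out
}

#' Bundle observed and null-expected correlations
#'
#' @param observed Symmetric observed correlation matrix
#'   ([pairwise_correlations()]).
#' @param null_expected Symmetric null matrix of the same shape
#'   ([null_expected_correlations()]).
#' @param n_null_iterations Number of null permutations used.
#' @param seed Seed used for the null model.
#' @return A `correlation_set`: list with `taxon_ids`, `observed`,
#'   `null_expected`, `corrected` (observed minus null), `n_null_iterations`
#'   and `seed`.
#' @export
correlation_set <- function(observed, null_expected,
                            n_null_iterations = NA_integer_,
                            seed = NA_integer_) {
  stopifnot(is.matrix(observed), is.matrix(null_expected),
            all(dim(observed) == dim(null_expected)))
  if (max(abs(observed - t(observed))) > 1e-12 ||
      max(abs(null_expected - t(null_expected))) > 1e-12) {
    stop("correlation matrices must be symmetric", call. = FALSE)
  }
  if (max(abs(observed)) > 1 + 1e-12) {
    stop("observed correlations must lie in [-1, 1]", call. = FALSE)
  }
  diag(observed) <- 0
  diag(null_expected) <- 0
  structure(list(taxon_ids = colnames(observed),
                 observed = observed,
                 null_expected = null_expected,
                 corrected = observed - null_expected,
                 n_null_iterations = n_null_iterations,
                 seed = seed),
            class = "correlation_set")
}

#' Per-taxon connectedness
#'
#' A taxon's positive (negative) connectedness is the mean of the strictly
#' positive (negative) null-corrected correlations between it and all other
#' taxa, or 0 when there are none. Zero-variance taxa carry corrected
#' correlations of exactly 0 and so never contribute.
#'
#' @param cs A [correlation_set()].
#' @return Data frame with `taxon_id`, `connectedness_pos` (>= 0) and
#'   `connectedness_neg` (<= 0).
#' @export
connectedness <- function(cs) {
  stopifnot(inherits(cs, "correlation_set"))
  cc <- cs$corrected
  p <- ncol(cc)
  if (p < 2L) stop("connectedness needs at least two taxa", call. = FALSE)
  pos <- numeric(p)
  neg <- numeric(p)
  for (j in seq_len(p)) {
    v <- cc[j, -j]
    up <- v[v > 0]
    dn <- v[v < 0]
    pos[j] <- if (length(up)) mean(up) else 0
    neg[j] <- if (length(dn)) mean(dn) else 0
  }
  data.frame(taxon_id = cs$taxon_ids, connectedness_pos = pos,
             connectedness_neg = neg, stringsAsFactors = FALSE)
}

#' Per-sample community cohesion
#'
#' Positive (negative) cohesion of a sample is the abundance-weighted sum of
#' the taxa's positive (negative) connectedness: the degree of connectivity
#' of the realised community.
#'
#' @param cm A [community_matrix()] (counts converted to relative) whose taxa
#'   match `conn`.
#' @param conn Output of [connectedness()].
#' @return Data frame with `sample_id`, `cohesion_pos` and `cohesion_neg`.
#' @export
cohesion <- function(cm, conn) {
  m <- if (inherits(cm, "community_matrix")) {
    as.matrix(to_relative(cm))
  } else {
    as_abundance_matrix(cm, "cm")
  }
  if (!setequal(colnames(m), conn$taxon_id)) {
    stop("taxa of the community matrix and connectedness table differ",
         call. = FALSE)
  }
  idx <- match(colnames(m), conn$taxon_id)
  data.frame(sample_id = rownames(m),
             cohesion_pos = as.numeric(m %*% conn$connectedness_pos[idx]),
             cohesion_neg = as.numeric(m %*% conn$connectedness_neg[idx]),
             stringsAsFactors = FALSE)
}

#' Community stability ratio
#'
#' Stability is inferred from `|cohesion_neg / cohesion_pos|`: values below 1
#' indicate dominance of facilitation/synchrony (positive-feedback loops, low
#' stability), values above 1 competition dominance (negative feedback,
#' higher stability). Samples with zero positive cohesion get `NA` with a
#' warning rather than an infinity.
#'
#' @param cohesion_pos,cohesion_neg Paired per-sample cohesion values, or a
#'   data frame from [cohesion()] as the first argument.
#' @return Numeric vector of stability ratios (NA where undefined).
#' @export
stability_ratio <- function(cohesion_pos, cohesion_neg = NULL) {
  if (is.data.frame(cohesion_pos)) {
    df <- cohesion_pos
    cohesion_neg <- df$cohesion_neg
    cohesion_pos <- df$cohesion_pos
  }
  stopifnot(length(cohesion_pos) == length(cohesion_neg))
  out <- abs(cohesion_neg / cohesion_pos)
  undef <- cohesion_pos <= 0
  if (any(undef)) {
    warning(sprintf("%d sample(s) with non-positive cohesion_pos: stability undefined",
                    sum(undef)), call. = FALSE)
    out[undef] <- NA_real_
  }
  out
}

#' Compare stability across groups
#'
#' All pairwise Wilcoxon rank-sum tests on per-sample stability values, with
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @param values Numeric per-sample stability values (NA dropped).
#' @param groups Factor or character vector of group labels, same length.
#' @param alpha Significance cutoff applied to the adjusted p-values.
#' @return Data frame with one row per group pair: group sizes, rank-sum
#'   statistic `W`, `p_raw`, `p_adj` and `significant`.
#' @export
compare_stability <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 defined values: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
  }
  levs <- sort(unique(groups))
  if (length(levs) < 2L) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(levs, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    w <- suppressWarnings(stats::wilcox.test(x, y))
    c(n1 = length(x), n2 = length(y), W = unname(w$statistic),
      p_raw = w$p.value)
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    t(res), stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out
}

#' One-shot cohesion analysis of a community table
#'
#' Convenience wrapper chaining prevalence filtering, observed and
#' null-expected correlations, connectedness, per-sample cohesion and the
#' stability ratio. Following the metric's recommendation the input should
#' be the non-rarefied table; counts are converted to relative abundances.
#'
#' @param cm A [community_matrix()].
#' @param n_iter Null-model permutations per ordered taxon pair.
#' @param seed Integer seed for the null model.
#' @param prevalence_threshold Persistence pre-filter: only taxa with
#'   prevalence strictly above this fraction enter the correlation analysis.
#' @param samples Optional subset of sample ids over which correlations and
#'   connectedness are estimated (default: all samples jointly).
#' @param cor_method Correlation type.
#' @return List with `correlations` (a [correlation_set()]),
#'   `connectedness`, and `samples`: a data frame of per-sample
#'   `cohesion_pos`, `cohesion_neg` and `stability`.
#' @export
community_cohesion <- function(cm, n_iter = 200L, seed = 1L,
                               prevalence_threshold = 0.1,
                               samples = NULL,
                               cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  rel <- to_relative(cm)
  keep <- prevalence_filter(rel, prevalence_threshold)
  if (length(keep) < 2L) {
    stop("fewer than two taxa pass the prevalence filter", call. = FALSE)
  }
  sub <- as.matrix(rel)[, keep, drop = FALSE]
  est <- if (is.null(samples)) sub else sub[samples, , drop = FALSE]
  obs <- pairwise_correlations(est, method = cor_method)
  nul <- null_expected_correlations(est, n_iter = n_iter, seed = seed,
                                    cor_method = cor_method)
  cs <- correlation_set(obs, nul, n_null_iterations = n_iter, seed = seed)
  conn <- connectedness(cs)
  coh <- cohesion(sub, conn)
  coh$stability <- suppressWarnings(
    stability_ratio(coh$cohesion_pos, coh$cohesion_neg))
  list(correlations = cs, connectedness = conn, samples = coh)
}
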