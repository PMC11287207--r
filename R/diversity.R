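#' Alpha diversity per sample
#'
#' Richness (count of nonzero taxa), Shannon entropy (natural log) and
#' inverse Simpson index. Empty samples get `NA` diversity values with a
#' warning.
#'
#' @param cm A [community_matrix()] (counts or relative) or abundance
#'   matrix.
#' @return Data frame with `sample_id`, `richness`, `shannon`,
#'   `inverse_simpson`.
#' @export
alpha_diversity <- function(cm) {
  m <- as_abundance_matrix(cm, "cm")
  tot <- rowSums(m)
  empty <- tot == 0
  if (any(empty)) {
    warning("empty sample(s): ", paste(rownames(m)[empty], collapse = ", "),
            call. = FALSE)
  }
  sh <- suppressWarnings(vegan::diversity(m, index = "shannon"))
  is <- suppressWarnings(vegan::diversity(m, index = "invsimpson"))
  sh[empty] <- NA_real_
  is[empty] <- NA_real_
  data.frame(sample_id = rownames(m), richness = rowSums(m > 0),
             shannon = unname(sh), inverse_simpson = unname(is),
             row.names = NULL, stringsAsFactors = FALSE)
}

## compact letter display from a logical "significantly different" matrix
## (insert-and-absorb): groups sharing a letter are not significantly
## different
letter_display <- function(levels, sig_pairs, order_by = NULL) {
  sets <- list(levels)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[r, 1L]
      j <- sig_pairs[r, 2L]
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      ## absorb sets contained in another
      keep <- rep(TRUE, length(new_sets))
      for (x in seq_along(new_sets)) {
        for (y in seq_along(new_sets)) {
          if (x != y && keep[x] &&
              all(new_sets[[x]] %in% new_sets[[y]]) &&
              (length(new_sets[[x]]) < length(new_sets[[y]]) || x > y)) {
            keep[x] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  if (!is.null(order_by)) {
    sets <- sets[order(-vapply(sets, function(s)
      max(order_by[s]), numeric(1L)))]
  }
  letts <- vapply(levels, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1L)))],
          collapse = "")
  }, character(1L))
  stats::setNames(letts, levels)
}

#' Compare alpha diversity across groups
#'
#' One-way ANOVA per metric with Tukey HSD all-pairs post-hoc and a compact
#' letter display (groups sharing a letter do not differ significantly).
#'
#' @param div Output of [alpha_diversity()].
#' @param groups Group label per sample (same order as `div`).
#' @param metrics Which metric columns to test.
#' @param alpha Significance level.
#' @return Named list per metric: `F`, `p`, `tukey` (comparison table) and
#'   `letters`.
#' @export
compare_alpha <- function(div, groups,
                          metrics = c("richness", "shannon",
                                      "inverse_simpson"),
                          alpha = 0.05) {
  stopifnot(nrow(div) == length(groups))
  groups <- as.character(groups)
  out <- list()
  for (met in metrics) {
    val <- div[[met]]
    keep <- !is.na(val)
    v <- val[keep]
    g <- groups[keep]
    sizes <- table(g)
    small <- names(sizes)[sizes < 2L]
    if (length(small)) {
      warning("excluding degenerate group(s) for ", met, ": ",
              paste(small, collapse = ", "), call. = FALSE)
      sel <- !(g %in% small)
      v <- v[sel]
      g <- g[sel]
    }
    if (length(unique(g)) < 2L) {
      stop("need at least two groups with two samples each", call. = FALSE)
    }
    df <- data.frame(value = v, group = factor(g))
    means <- tapply(df$value, df$group, mean)
    if (stats::var(v) == 0) {
      out[[met]] <- list(F = 0, p = 1,
                         tukey = data.frame(comparison = character(0L),
                                            diff = numeric(0L),
                                            p_adj = numeric(0L)),
                         letters = letter_display(levels(df$group),
                                                  matrix(character(0L), 0L, 2L),
                                                  order_by = means))
      next
    }
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$group
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
    sig <- tukey[tukey$p_adj < alpha, , drop = FALSE]
    sig_pairs <- if (nrow(sig)) {
      do.call(rbind, strsplit(sig$comparison, "-", fixed = TRUE))
    } else {
      matrix(character(0L), 0L, 2L)
    }
    out[[met]] <- list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                       tukey = tukey,
                       letters = letter_display(levels(df$group), sig_pairs,
                                                order_by = means))
  }
  out
}
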