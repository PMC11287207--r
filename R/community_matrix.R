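#' Construct a community matrix
#'
#' The universal data container of the package: a numeric sample x taxon
#' abundance matrix carrying either sequencing counts (`kind = "counts"`,
#' all values integral) or relative abundances (`kind = "relative"`, every
#' sample row sums to 1). Row names are sample identifiers, column names are
#' taxon identifiers; both must be unique and all values non-negative.
#'
#' @param values Numeric matrix, samples in rows and taxa in columns, with
#'   complete `dimnames`.
#' @param kind Either `"counts"` or `"relative"`.
#' @return A `community_matrix` object (a classed numeric matrix with a
#'   `kind` attribute).
#' @examples
#' m <- matrix(c(3, 1, 2, 4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' community_matrix(m, "counts")
#' @export
community_matrix <- function(values, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and taxon column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated sample identifier: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated taxon identifier: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  if (kind == "counts") {
    if (any(abs(values - round(values)) > 1e-9)) {
      bad <- which(abs(values - round(values)) > 1e-9, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-integral count at sample '%s', taxon '%s'",
                   rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
           call. = FALSE)
    }
    values <- round(values)
  } else {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) {
      bad <- which(abs(rs - 1) > 1e-9)[1L]
      stop(sprintf("relative abundances of sample '%s' sum to %.12g, not 1",
                   rownames(values)[bad], rs[bad]), call. = FALSE)
    }
  }
  structure(values, kind = kind, class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix (%s): %d samples x %d taxa\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  m <- as.matrix(x)
  utils::str(m, give.attr = FALSE)
  invisible(x)
}

#' @export
as.matrix.community_matrix <- function(x, ...) {
  attr(x, "kind") <- NULL
  class(x) <- NULL
  x
}

#' Abundance kind of a community matrix
#' @param x A `community_matrix`.
#' @return `"counts"` or `"relative"`.
#' @export
cm_kind <- function(x) {
  stopifnot(inherits(x, "community_matrix"))
  attr(x, "kind")
}

#' Sample and taxon identifiers
#' @param x A `community_matrix`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(x)

## accept either a community_matrix or a plain sample x taxon matrix;
## used by operations (correlations, DA) whose arithmetic is agnostic
as_abundance_matrix <- function(x, arg = "x") {
  if (inherits(x, "community_matrix")) {
    return(as.matrix(x))
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a community_matrix or numeric matrix", arg),
         call. = FALSE)
  }
  x
}

#' Read an OTU table from a tab-separated file
#'
#' On disk the conventional dialect stores taxa as rows and samples as
#' columns, first header cell `taxon_id`; in memory the canonical orientation
#' is samples x taxa. Tables of counts and of relative abundances are
#' recognised automatically; anything else is rejected.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param orientation `"taxa_as_rows"` (default, first column taxon ids) or
#'   `"samples_as_rows"`.
#' @return A validated [community_matrix()].
#' @export
read_community_table <- function(path,
                                 orientation = c("taxa_as_rows",
                                                 "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table needs an id column plus data columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  num <- df[-1L]
  not_num <- !vapply(num, is.numeric, logical(1L))
  if (any(not_num)) {
    stop("non-numeric column(s): ",
         paste(names(num)[not_num], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  if (anyNA(m)) stop("missing values in table", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at row '%s', column '%s'",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  kind <- if (all(abs(m - round(m)) <= 1e-9)) {
    "counts"
  } else if (all(abs(rowSums(m) - 1) <= 1e-9)) {
    "relative"
  } else {
    stop("table is neither integral counts nor rows summing to 1",
         call. = FALSE)
  }
  community_matrix(m, kind)
}

#' Write a community matrix to a tab-separated file
#'
#' Inverse of [read_community_table()]; round-trips valid tables losslessly
#' (counts exactly; relative abundances to double-precision printing).
#'
#' @param cm A [community_matrix()].
#' @param path Output path.
#' @param orientation Disk dialect, as in [read_community_table()].
#' @return `path`, invisibly.
#' @export
write_community_table <- function(cm, path,
                                  orientation = c("taxa_as_rows",
                                                  "samples_as_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(cm, "community_matrix"))
  m <- as.matrix(cm)
  if (orientation == "taxa_as_rows") {
    df <- data.frame(taxon_id = colnames(m), t(m), check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param cm A [community_matrix()]. Relative input is returned unchanged.
#' @return A `community_matrix` of kind `"relative"`.
#' @export
to_relative <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  if (cm_kind(cm) == "relative") return(cm)
  m <- as.matrix(cm)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total: ",
         paste(rownames(m)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  community_matrix(m / tot, "relative")
}

#' Rarefy a count table to a common sequencing depth
#'
#' Each sample is subsampled uniformly at random, without replacement, to
#' exactly `depth` reads. Samples with fewer than `depth` total reads are
#' dropped with a warning. The draw is deterministic for a fixed `seed`.
#'
#' @param cm A counts [community_matrix()].
#' @param depth Positive integer target depth per sample.
#' @param seed Integer seed for the subsampling.
#' @return A counts `community_matrix` in which every row sums to `depth`.
#' @export
rarefy <- function(cm, depth, seed = 1L) {
  stopifnot(inherits(cm, "community_matrix"))
  if (cm_kind(cm) != "counts") stop("rarefaction needs a counts matrix",
                                    call. = FALSE)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0 ||
      depth != round(depth)) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  m <- as.matrix(cm)
  tot <- rowSums(m)
  drop <- tot < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(rownames(m)[drop], collapse = ", ")), call. = FALSE)
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no sample reaches the requested depth",
                          call. = FALSE)
  r <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      ## vegan flags large smallest counts as possibly pre-scaled data;
      ## inputs here are validated integer counts
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  community_matrix(r, "counts")
}

#' Per-taxon prevalence
#'
#' @param cm A [community_matrix()] or plain abundance matrix.
#' @return Named numeric vector: fraction of samples in which each taxon has
#'   nonzero abundance.
#' @export
prevalence <- function(cm) {
  m <- as_abundance_matrix(cm, "cm")
  colMeans(m > 0)
}

#' Prevalence filter
#'
#' Returns the taxa whose prevalence is strictly greater than `threshold`
#' (a taxon present in exactly 10% of samples is excluded at
#' `threshold = 0.1`).
#'
#' @param cm A [community_matrix()] or abundance matrix.
#' @param threshold Fraction in `[0, 1)`.
#' @return Character vector of retained taxon identifiers.
#' @export
prevalence_filter <- function(cm, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  }
  p <- prevalence(cm)
  names(p)[p > threshold]
}

#' Shared and group-unique taxa
#'
#' @param groups Named list (length >= 2) of [community_matrix()] objects or
#'   abundance matrices, one per group of samples.
#' @return List with `shared` (taxa with nonzero abundance in every group)
#'   and `unique` (named list: taxa with nonzero abundance only in that
#'   group).
#' @export
shared_and_unique_taxa <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups))) {
    stop("`groups` must be a named list of at least two matrices",
         call. = FALSE)
  }
  present <- lapply(groups, function(g) {
    m <- as_abundance_matrix(g, "group")
    colnames(m)[colSums(m) > 0]
  })
  shared <- Reduce(intersect, present)
  uniq <- lapply(seq_along(present), function(i) {
    setdiff(present[[i]], unique(unlist(present[-i])))
  })
  names(uniq) <- names(groups)
  list(shared = shared, unique = uniq)
}
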