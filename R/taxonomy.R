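#' Consensus taxonomy by the 2-out-of-3 rule
#'
#' Given the ranked lineages assigned to one OTU by three reference
#' databases, walk the rank ladder from the root and keep, at each rank, the
#' name supported by at least two of the lineages that are still consistent
#' with the consensus built so far; stop at the first rank without a two-way
#' agreement. Name comparison is case-insensitive exact matching. An empty
#' lineage simply never votes, so the result is invariant under permutation
#' of the three inputs.
#'
#' @param a,b,c Character vectors, ranked lineages from root to tip (e.g.
#'   domain, phylum, class, order, family, genus, species). May be empty.
#' @return Character vector: the consensus lineage prefix (possibly empty).
#' @examples
#' consensus_taxonomy(c("Eukaryota", "Ochrophyta"),
#'                    c("Eukaryota", "Ochrophyta"),
#'                    c("Eukaryota", "Chlorophyta"))
#' @export
consensus_taxonomy <- function(a, b, c) {
  lins <- list(as.character(a), as.character(b), as.character(c))
  lins <- lapply(lins, function(x) x[!is.na(x) & nzchar(x)])
  consensus <- character(0L)
  alive <- rep(TRUE, 3L) # lineages whose prefix still matches the consensus
  k <- 1L
  repeat {
    votes <- character(0L)
    voters <- integer(0L)
    for (i in which(alive)) {
      if (length(lins[[i]]) >= k) {
        votes <- c(votes, lins[[i]][k])
        voters <- c(voters, i)
      }
    }
    if (length(votes) < 2L) break
    tab <- table(tolower(votes))
    if (max(tab) < 2L) break
    win <- names(tab)[which.max(tab)]
    consensus <- c(consensus, votes[match(win, tolower(votes))])
    alive[] <- FALSE
    alive[voters[tolower(votes) == win]] <- TRUE
    k <- k + 1L
  }
  consensus
}

#' Consensus taxonomy for a whole assignment table
#'
#' @param df Data frame with a `taxon_id` column and three columns of
#'   semicolon-delimited lineages (named by `lineage_cols`), one per
#'   reference database.
#' @param lineage_cols Names of the three lineage columns.
#' @param sep Rank separator inside a lineage string.
#' @return `df` with an added `consensus` column (semicolon-delimited).
#' @export
consensus_taxonomy_table <- function(df,
                                     lineage_cols = c("pr2", "silva", "unite"),
                                     sep = ";") {
  miss <- setdiff(c("taxon_id", lineage_cols), names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  split1 <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0L)
    else trimws(strsplit(x, sep, fixed = TRUE)[[1L]])
  }
  df$consensus <- vapply(seq_len(nrow(df)), function(i) {
    cons <- consensus_taxonomy(split1(df[[lineage_cols[1L]]][i]),
                               split1(df[[lineage_cols[2L]]][i]),
                               split1(df[[lineage_cols[3L]]][i]))
    paste(cons, collapse = sep)
  }, character(1L))
  df
}

#' Read or write a taxonomy assignment table
#'
#' @param path TSV with `taxon_id` plus three semicolon-delimited lineage
#'   columns (and optionally a `consensus` column).
#' @return The reader returns a data frame; the writer returns `path`
#'   invisibly.
#' @export
read_taxonomy_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_taxonomy_table
#' @param df Taxonomy data frame.
#' @export
write_taxonomy_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
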