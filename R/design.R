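#' Validate an experiment design table
#'
#' The per-sample metadata of a coalescence experiment: treatment source,
#' river:sea mixing ratio for coalesced samples, replicate label and sampling
#' day. Sources are the two parent communities (`R`, `S`), the environmental
#' coalescence treatments (`Rx`, `Sx`), one-time and repeated community
#' coalescence (`OC`, `RC`), and the cell-free medium controls (`Rm`, `Sm`).
#'
#' @param df Data frame with columns `sample_id`, `source`, `river_parts`,
#'   `sea_parts`, `replicate`, `day`. Ratio parts may be `NA` for
#'   non-coalesced samples but must be present, and not both zero, for
#'   `OC`/`RC` samples.
#' @return The validated data frame, with class `experiment_design` prepended.
#' @export
experiment_design <- function(df) {
  req <- c("sample_id", "source", "river_parts", "sea_parts",
           "replicate", "day")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing metadata column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in design", call. = FALSE)
  }
  ok_src <- c("R", "S", "Rx", "Sx", "OC", "RC", "Rm", "Sm")
  bad <- setdiff(unique(df$source), ok_src)
  if (length(bad)) {
    stop("unknown source value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$day < 0 | df$day != round(df$day))) {
    stop("`day` must be a non-negative integer", call. = FALSE)
  }
  co <- df$source %in% c("OC", "RC")
  if (any(co)) {
    rp <- df$river_parts[co]
    sp <- df$sea_parts[co]
    if (anyNA(rp) || anyNA(sp) || any(rp < 0) || any(sp < 0) ||
        any(rp + sp == 0)) {
      stop("OC/RC samples need a river:sea ratio with parts not both zero",
           call. = FALSE)
    }
  }
  ## replicate pairing: each treatment should carry the same label set
  labs <- split(df$replicate, df$source)
  ref <- sort(unique(df$replicate))
  uneven <- names(labs)[!vapply(labs, function(x)
    setequal(unique(x), ref), logical(1L))]
  if (length(uneven)) {
    warning("replicate labels differ across treatments: ",
            paste(uneven, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("experiment_design", class(df))
  df
}

#' Read or write experiment metadata
#'
#' @param path TSV file with the columns listed in [experiment_design()].
#' @return For the reader, a validated `experiment_design`; the writer
#'   returns `path` invisibly.
#' @export
read_experiment_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  experiment_design(df)
}

#' @rdname read_experiment_design
#' @param design An `experiment_design` data frame.
#' @export
write_experiment_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
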