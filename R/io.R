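#' Read a cohort of stress-stretch curves from a delimited file
#'
#' The curve table format is CSV with header
#' `specimen_id,region,direction,stretch,stress_MPa`, one row per sample
#' point; `region` is one of `PA|PP|DA|DP` and `direction` is `C|L`. Stretch
#' must be strictly increasing within each specimen. Validation errors name
#' the offending file row.
#'
#' @param path file path.
#' @return A named list of [specimen_set()] objects (one per region present).
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "region", "direction", "stretch", "stress_MPa")
  if (!identical(colnames(df), need))
    stop("header must be exactly: ", paste(need, collapse = ","))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  bad_region <- which(!df$region %in% c("PA", "PP", "DA", "DP"))
  if (length(bad_region))
    stop(sprintf("unknown region code '%s' at file row %d",
                 df$region[bad_region[1]], bad_region[1] + 1L))
  bad_dir <- which(!df$direction %in% c("C", "L"))
  if (length(bad_dir))
    stop(sprintf("unknown direction code '%s' at file row %d",
                 df$direction[bad_dir[1]], bad_dir[1] + 1L))
  if (any(!is.finite(df$stretch)) || any(!is.finite(df$stress_MPa)))
    stop("non-numeric stretch/stress values")

  # preserve file order of specimens within each set
  df$.row <- seq_len(nrow(df))
  sets <- list()
  for (rg in intersect(c("PA", "PP", "DA", "DP"), unique(df$region))) {
    per_dir <- list(C = list(), L = list())
    sub <- df[df$region == rg, ]
    for (id in unique(sub$specimen_id)) {
      rows <- sub[sub$specimen_id == id, ]
      d <- unique(rows$direction)
      if (length(d) != 1L)
        stop("specimen ", id, " appears with multiple directions")
      nonmono <- which(diff(rows$stretch) <= 0)
      if (length(nonmono))
        stop(sprintf(
          "non-increasing stretch for specimen %s at file row %d", id,
          rows$.row[nonmono[1] + 1L] + 1L))
      per_dir[[d]][[length(per_dir[[d]]) + 1L]] <-
        ss_curve(rows$stretch, rows$stress_MPa, rg, d, id)
    }
    if (!length(per_dir$C) || !length(per_dir$L))
      stop("region ", rg, " is missing one loading direction")
    sets[[rg]] <- specimen_set(rg, per_dir$C, per_dir$L)
  }
  sets
}

#' Write a cohort of curves to the delimited curve-table format
#'
#' Deterministic output (fixed column order, 10 significant digits) so that a
#' fixed-seed cohort round-trips byte-for-byte.
#'
#' @param sets named list of [specimen_set()]s (e.g. `generate_cohort()$sets`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(sets, path) {
  # canonical region order so that write -> read -> write is byte-stable
  regions <- vapply(sets, `[[`, character(1), "region")
  sets <- sets[order(match(regions, c("PA", "PP", "DA", "DP")))]
  rows <- lapply(sets, function(s)
    lapply(c(s$circumferential, s$longitudinal), as.data.frame))
  df <- do.call(rbind, unlist(rows, recursive = FALSE))
  df$stretch <- signif(df$stretch, 10)
  df$stress_MPa <- signif(df$stress_MPa, 10)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tidy results table
#'
#' Shared writer for slope tables, pair manifests, fit summaries and
#' statistical outputs: plain CSV, deterministic formatting.
#'
#' @param df a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 10)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
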