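#' Five-number summaries of fitted parameter distributions
#'
#' Aggregates a list of [hyperfit()] results into per-parameter distribution
#' summaries (minimum, first quartile, median, third quartile, maximum;
#' quartiles by linear interpolation, i.e. `stats::quantile` type 7), the
#' layout used to report virtual-pair parameter populations per region and
#' model. Non-converged fits are excluded and counted.
#'
#' @param fits list of `"hyperfit"` objects (one model).
#' @param region optional region label recorded in the output; defaults to the
#'   fits' region when unique.
#' @param model optional model label; defaults to the fits' model (must be
#'   unique).
#' @return A data frame with one row per parameter: `model`, `region`,
#'   `parameter`, `min`, `q1`, `median`, `q3`, `max`, `iqr`, `n`,
#'   `n_excluded`.
#' @export
summarize_distribution <- function(fits, region = NULL, model = NULL) {
  stopifnot(length(fits) >= 1L)
  models <- unique(vapply(fits, `[[`, character(1), "model"))
  if (is.null(model)) {
    if (length(models) != 1L) stop("fits mix models; pass `model` subsets")
    model <- models
  }
  fits <- Filter(function(f) f$model == model, fits)
  if (is.null(region)) {
    regions <- unique(vapply(fits, `[[`, character(1), "region"))
    region <- if (length(regions) == 1L) regions else NA_character_
  }
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(ok)) stop("zero converged fits: nothing to summarize")
  mat <- do.call(rbind, lapply(fits[ok], coef))
  out <- do.call(rbind, lapply(colnames(mat), function(nm) {
    q <- stats::quantile(mat[, nm], c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                         type = 7)
    data.frame(model = model, region = region, parameter = nm,
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               iqr = q[4] - q[2], n = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit one model to every virtual pair of a cohort
#'
#' Convenience driver: cross-maps each region's specimen set and fits the
#' requested model(s) to every pair (optionally a seeded subsample per region
#' for runtime control), returning the flat list of fits.
#'
#' @param sets list of [specimen_set()] objects.
#' @param model `"fung"`, `"holzapfel"`, `"cmm"` or `"all"`.
#' @param subsample optional per-region cap on the number of pairs (seeded,
#'   without replacement); `NULL` fits every pair.
#' @param seed base seed; each fit derives its multistart seed from it.
#' @param ... passed to [hyperfit()].
#' @return A list of `"hyperfit"` objects with an attribute `n_attempted`,
#'   the number of fit cases attempted (pairs x models).
#' @export
fit_cohort <- function(sets, model = c("fung", "holzapfel", "cmm", "all"),
                       subsample = NULL, seed = 1L, ...) {
  model <- match.arg(model)
  models <- if (model == "all") model_names else model
  fits <- list()
  attempted <- 0L
  for (s in sets) {
    pairs <- cross_map_pairs(s, subsample = subsample, seed = seed)
    for (m in models) {
      for (p in pairs) {
        attempted <- attempted + 1L
        fits[[length(fits) + 1L]] <-
          hyperfit(p, m, seed = seed + attempted, ...)
      }
    }
  }
  attr(fits, "n_attempted") <- attempted
  fits
}
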