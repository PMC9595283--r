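#' Specimen set for one aortic region
#'
#' Groups all circumferential and longitudinal specimens of one test region;
#' the unit on which virtual biaxial cross-mapping operates.
#'
#' @param region `"PA"`, `"PP"`, `"DA"` or `"DP"`.
#' @param circumferential,longitudinal non-empty lists of [ss_curve()]s, all
#'   tagged with `region` and the matching direction.
#' @return An object of class `"specimen_set"`.
#' @export
specimen_set <- function(region, circumferential, longitudinal) {
  region <- match.arg(region, c("PA", "PP", "DA", "DP"))
  if (!length(circumferential) || !length(longitudinal))
    stop("both direction lists must be non-empty")
  for (crv in circumferential) {
    stopifnot(inherits(crv, "ss_curve"))
    if (crv$region != region || crv$direction != "circumferential")
      stop("curve ", crv$specimen_id, " does not match set tags")
  }
  for (crv in longitudinal) {
    stopifnot(inherits(crv, "ss_curve"))
    if (crv$region != region || crv$direction != "longitudinal")
      stop("curve ", crv$specimen_id, " does not match set tags")
  }
  structure(list(region = region, circumferential = circumferential,
                 longitudinal = longitudinal), class = "specimen_set")
}

#' @export
print.specimen_set <- function(x, ...) {
  cat(sprintf("<specimen_set> %s: %d circumferential x %d longitudinal\n",
              x$region, length(x$circumferential), length(x$longitudinal)))
  invisible(x)
}

#' One-to-many cross-mapping into virtual biaxial pairs
#'
#' Pairs every circumferential specimen of a region with every longitudinal
#' specimen of the same region (the full Cartesian product), so each pair
#' stands in for a true biaxial test. The ordering is deterministic:
#' circumferential-major, then longitudinal. With the cohort sizes of the
#' porcine thoracic aorta study design this yields 1,015 / 625 / 728 / 784
#' pairs for PA / PP / DA / DP.
#'
#' @param set a [specimen_set()].
#' @param subsample optional integer: seeded subsample (without replacement) of
#'   that many pairs for runtime control; default `NULL` keeps all pairs.
#' @param seed seed used only when `subsample` is given.
#' @return A list of `"virtual_pair"` objects, each a list with `circ_curve`,
#'   `long_curve`, `region` and `pair_index = c(i, j)`.
#' @export
cross_map_pairs <- function(set, subsample = NULL, seed = 1L) {
  stopifnot(inherits(set, "specimen_set"))
  nc <- length(set$circumferential)
  nl <- length(set$longitudinal)
  pairs <- vector("list", nc * nl)
  k <- 0L
  for (i in seq_len(nc)) {
    for (j in seq_len(nl)) {
      k <- k + 1L
      pairs[[k]] <- structure(
        list(circ_curve = set$circumferential[[i]],
             long_curve = set$longitudinal[[j]],
             region = set$region, pair_index = c(i, j)),
        class = "virtual_pair")
    }
  }
  if (!is.null(subsample) && subsample < length(pairs)) {
    keep <- local_seed(seed, sort(sample.int(length(pairs), subsample)))
    pairs <- pairs[keep]
  }
  pairs
}

#' @export
print.virtual_pair <- function(x, ...) {
  cat(sprintf("<virtual_pair> %s: %s (C) x %s (L)  [i = %d, j = %d]\n",
              x$region, x$circ_curve$specimen_id, x$long_curve$specimen_id,
              x$pair_index[1], x$pair_index[2]))
  invisible(x)
}

#' Total number of fitting cases across regions and models
#'
#' Sum over regions of |circumferential| x |longitudinal|, multiplied by the
#' number of constitutive models. With the study-design specimen counts
#' (35, 29), (25, 25), (26, 28), (28, 28) and three models the total is 9,456.
#'
#' @param sets list of [specimen_set()] objects.
#' @param n_models number of constitutive models fitted to each pair.
#' @return Integer case count.
#' @examples
#' # counts only, no curves needed:
#' count_cases_from_counts(list(c(35, 29), c(25, 25), c(26, 28), c(28, 28)), 3)
#' @export
count_cases <- function(sets, n_models = 1L) {
  stopifnot(n_models >= 1L)
  count_cases_from_counts(lapply(sets, function(s)
    c(length(s$circumferential), length(s$longitudinal))), n_models)
}

#' @rdname count_cases
#' @param counts list of length-2 integer vectors `(n_circ, n_long)`.
#' @export
count_cases_from_counts <- function(counts, n_models = 1L) {
  stopifnot(n_models >= 1L)
  as.integer(sum(vapply(counts, function(ct) ct[1] * ct[2], numeric(1))) *
               n_models)
}

#' Pair manifest table
#'
#' @param pairs list of virtual pairs from [cross_map_pairs()].
#' @return Data frame with `region`, `i`, `j`, `circ_specimen_id`,
#'   `long_specimen_id`.
#' @export
pair_manifest <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p)
    data.frame(region = p$region, i = p$pair_index[1], j = p$pair_index[2],
               circ_specimen_id = p$circ_curve$specimen_id,
               long_specimen_id = p$long_curve$specimen_id,
               stringsAsFactors = FALSE)))
}

# evaluate expr under a local RNG seed without disturbing the global stream
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
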