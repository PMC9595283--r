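#' Uniaxial stress-stretch curve
#'
#' Container for one specimen's uniaxial tensile record: a strictly increasing
#' stretch sequence with the matching Cauchy stress sequence (MPa), tagged with
#' the aortic test region and the loading direction.
#'
#' @param stretch numeric, strictly increasing, first value near 1.
#' @param stress numeric Cauchy stress in MPa, same length as `stretch`,
#'   non-negative after baseline correction.
#' @param region one of `"PA"`, `"PP"`, `"DA"`, `"DP"` (proximal/distal x
#'   anterior/posterior).
#' @param direction `"circumferential"` or `"longitudinal"` (abbreviations and
#'   the single-letter file codes `"C"`/`"L"` are accepted).
#' @param specimen_id character identifier.
#' @param validate logical; skip checks when building internally.
#' @return An object of class `"ss_curve"`: a list with elements `stretch`,
#'   `stress`, `region`, `direction`, `specimen_id`.
#' @examples
#' lam <- seq(1, 1.4, length.out = 40)
#' crv <- ss_curve(lam, 0.2 * (lam^2 - 1 / lam), "PA", "circumferential", "demo")
#' print(crv)
#' @export
ss_curve <- function(stretch, stress, region, direction, specimen_id = "s1",
                     validate = TRUE) {
  direction <- match_direction(direction)
  region <- match.arg(region, c("PA", "PP", "DA", "DP"))
  if (validate) {
    stopifnot(is.numeric(stretch), is.numeric(stress),
              length(stretch) == length(stress))
    if (length(stretch) < 10L)
      stop("a stress-stretch curve needs at least 10 points")
    if (any(diff(stretch) <= 0))
      stop("stretch must be strictly increasing")
    if (any(!is.finite(stretch)) || any(!is.finite(stress)))
      stop("non-finite values in curve")
    if (any(stretch <= 0)) stop("stretch must be positive")
    if (any(stress < -sqrt(.Machine$double.eps)))
      stop("stress must be non-negative after baseline correction")
  }
  structure(list(stretch = as.numeric(stretch), stress = as.numeric(stress),
                 region = region, direction = direction,
                 specimen_id = as.character(specimen_id)),
            class = "ss_curve")
}

# canonical direction names; accepts C/L file codes
match_direction <- function(direction) {
  if (length(direction) != 1L) stop("direction must be length 1")
  d <- as.character(direction)
  if (toupper(d) %in% c("C", "CIRC")) return("circumferential")
  if (toupper(d) %in% c("L", "LONG")) return("longitudinal")
  match.arg(d, c("circumferential", "longitudinal"))
}

#' @export
print.ss_curve <- function(x, ...) {
  cat(sprintf("<ss_curve> %s  region %s, %s\n", x$specimen_id, x$region,
              x$direction))
  cat(sprintf("  %d points, stretch [%.3f, %.3f], peak stress %.4g MPa\n",
              length(x$stretch), min(x$stretch), max(x$stretch),
              max(x$stress)))
  invisible(x)
}

#' @export
plot.ss_curve <- function(x, ...) {
  graphics::plot(x$stretch, x$stress, type = "l",
                 xlab = expression(lambda),
                 ylab = "Cauchy stress (MPa)",
                 main = sprintf("%s (%s, %s)", x$specimen_id, x$region,
                                x$direction), ...)
  invisible(x)
}

#' @export
as.data.frame.ss_curve <- function(x, ...) {
  data.frame(specimen_id = x$specimen_id, region = x$region,
             direction = ifelse(x$direction == "circumferential", "C", "L"),
             stretch = x$stretch, stress_MPa = x$stress,
             stringsAsFactors = FALSE)
}
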