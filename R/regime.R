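#' Truncate a curve at the fiber-breakage point
#'
#' Keeps the prefix of a stress-stretch curve up to the point where it deviates
#' from the high-stiffness trend. Deviation is the first index at or after the
#' global stress maximum, or where a running windowed least-squares tangent
#' drops below `slope_frac` of its running maximum, whichever comes first.
#'
#' @param curve an [ss_curve()].
#' @param slope_frac running-tangent collapse threshold as a fraction of the
#'   running maximum tangent (default 0.5).
#' @param window window length (points) for the running tangent (default 5).
#' @return The truncated [ss_curve()].
#' @export
truncate_at_fiber_breakage <- function(curve, slope_frac = 0.5, window = 5L) {
  stopifnot(inherits(curve, "ss_curve"))
  n <- length(curve$stretch)
  i_peak <- which.max(curve$stress)
  if (max(curve$stress) <= min(curve$stress) + .Machine$double.eps)
    stop("degenerate curve: constant stress, no identifiable high-stiffness regime")
  # running windowed OLS tangent; collapse marks softening before the peak
  i_collapse <- n
  if (n >= 2L * window) {
    sl <- vapply(seq_len(n - window + 1L), function(i) {
      idx <- i:(i + window - 1L)
      ols_slope(curve$stretch[idx], curve$stress[idx])
    }, numeric(1))
    runmax <- cummax(sl)
    drop <- which(sl < slope_frac * runmax & runmax > 0)
    if (length(drop)) i_collapse <- drop[1L] + window - 1L
  }
  cut <- min(i_peak, i_collapse)
  if (cut < 10L)
    stop("curve too short after fiber-breakage truncation (< 10 points)")
  ss_curve(curve$stretch[1:cut], curve$stress[1:cut], curve$region,
           curve$direction, curve$specimen_id, validate = FALSE)
}

ols_slope <- function(x, y) {
  xm <- x - mean(x)
  sum(xm * (y - mean(y))) / sum(xm^2)
}

#' R-squared-optimal linear range anchored at one end of the curve
#'
#' Scans every candidate window anchored at the stated end (the curve's first
#' point for the low-stiffness regime, its last point for the high-stiffness
#' regime), fits ordinary least squares to each, and returns the window that
#' maximizes the coefficient of determination. Ties are broken toward the
#' longer window.
#'
#' @param curve an [ss_curve()] with at least 10 points.
#' @param anchor `"first_point"` or `"last_point"`.
#' @param min_len minimum window length in points (default 5).
#' @return A list with `range` (integer index interval), `slope`, `intercept`
#'   and `r_squared`.
#' @export
optimal_linear_range <- function(curve, anchor = c("first_point",
                                                   "last_point"),
                                 min_len = 5L) {
  stopifnot(inherits(curve, "ss_curve"))
  anchor <- match.arg(anchor)
  x <- curve$stretch
  y <- curve$stress
  n <- length(x)
  if (n < min_len) stop("all candidate windows shorter than the minimum length")
  if (anchor == "last_point") {
    x <- rev(x); y <- rev(y)
  }
  # cumulative-moment OLS over windows [1, m], m = min_len..n
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  m <- seq.int(min_len, n)
  sxx <- cxx[m] - cx[m]^2 / m
  sxy <- cxy[m] - cx[m] * cy[m] / m
  syy <- cyy[m] - cy[m]^2 / m
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, pmin(1, pmax(0, sxy^2 / (sxx * syy))), NA_real_)
  if (all(is.na(r2)))
    stop("degenerate curve: zero stress variance in every candidate window")
  # ties toward the longer window (lower-variance slope)
  best <- which(r2 >= max(r2, na.rm = TRUE) - 1e-12)
  best <- best[length(best)]
  mlen <- m[best]
  b <- slope[best]
  a <- (cy[mlen] - b * cx[mlen]) / mlen
  range <- if (anchor == "first_point") c(1L, mlen) else c(n - mlen + 1L, n)
  list(range = range, slope = unname(b), intercept = unname(a),
       r_squared = unname(r2[best]))
}

#' Two-regime tangent slopes of a stress-stretch curve
#'
#' Quantifies the J-shaped nonlinearity of arterial tissue by the tangent
#' slopes of the low-stiffness (elastin-dominated) and high-stiffness
#' (collagen-recruited) regimes. The curve is approximated as a two-piece
#' linear function: each regime's optimal range is found by
#' [optimal_linear_range()] (anchored at the first point for the low regime,
#' at the last point for the high regime); a fitting equation over that range
#' is then differentiated at the range midpoint. The default fitting equation
#' is the range's linear fit itself (derivative = its slope);
#' `fit = "quadratic"` uses a local second-order polynomial for sensitivity
#' checks.
#'
#' @param curve a truncated [ss_curve()] (see [truncate_at_fiber_breakage()]).
#' @param min_len minimum range length in points (default 5).
#' @param fit `"linear"` (default) or `"quadratic"` fitting equation for the
#'   tangent.
#' @return An object of class `"regime_slopes"`: list with `low_slope`,
#'   `high_slope` (MPa per unit stretch), `low_range`, `high_range`,
#'   `low_r2`, `high_r2`, `transition_stretch`, and `degenerate` (`TRUE` when
#'   the two segments are statistically indistinguishable or overlap, i.e.
#'   the curve has a single regime).
#' @examples
#' lam <- seq(1, 1.4, length.out = 60)
#' p <- holzapfel_params(0.05, 0.06, 2.5, 0.5)
#' crv <- ss_curve(lam, uniaxial_stress(p, lam, "circumferential"), "DP",
#'                 "circumferential")
#' regime_slopes(crv)
#' @export
regime_slopes <- function(curve, min_len = 5L, fit = c("linear", "quadratic")) {
  fit <- match.arg(fit)
  x <- curve$stretch
  y <- curve$stress
  n <- length(x)
  if (n < 2L * min_len)
    stop("curve too short for a two-regime split")
  lo_r <- optimal_linear_range(curve, "first_point", min_len)
  hi_r <- optimal_linear_range(curve, "last_point", min_len)
  sp <- list(m = lo_r$range[2], k = hi_r$range[1])
  lin_stats <- function(idx) {
    xm <- x[idx] - mean(x[idx])
    ym <- y[idx] - mean(y[idx])
    sxx <- sum(xm^2)
    sxy <- sum(xm * ym)
    syy <- sum(ym^2)
    b <- sxy / sxx
    sse <- max(0, syy - sxy^2 / sxx)
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
    se <- if (length(idx) > 2L) sqrt(sse / (length(idx) - 2L) / sxx) else Inf
    list(slope = b, r2 = r2, se = se)
  }
  lo_idx <- 1L:sp$m
  hi_idx <- sp$k:n
  lo <- lin_stats(lo_idx)
  hi <- lin_stats(hi_idx)
  tangent_at <- function(idx, lin) {
    if (fit == "linear" || length(idx) < 3L) return(lin$slope)
    mid <- x[idx[ceiling(length(idx) / 2)]]
    co <- stats::coef(stats::lm(y[idx] ~ stats::poly(x[idx], 2,
                                                     raw = TRUE)))
    unname(co[2] + 2 * co[3] * mid)
  }
  # a single-regime curve: segments overlap beyond a shared endpoint, or the
  # two slopes are indistinguishable given their standard errors
  degenerate <- sp$m > sp$k ||
    (hi$slope - lo$slope) <= 2 * (lo$se + hi$se)
  if (degenerate)
    warning("no identifiable transition between regimes ",
            "(single-regime curve)")
  transition <- if (sp$m > sp$k) NA_real_ else (x[sp$m] + x[sp$k]) / 2
  structure(list(low_slope = tangent_at(lo_idx, lo),
                 high_slope = tangent_at(hi_idx, hi),
                 low_range = c(1L, sp$m), high_range = c(sp$k, n),
                 low_r2 = lo$r2, high_r2 = hi$r2,
                 transition_stretch = transition,
                 degenerate = degenerate,
                 specimen_id = curve$specimen_id, region = curve$region,
                 direction = curve$direction),
            class = "regime_slopes")
}

#' @export
print.regime_slopes <- function(x, ...) {
  cat(sprintf("<regime_slopes> %s (%s, %s)\n", x$specimen_id, x$region,
              x$direction))
  cat(sprintf("  low  slope %.4g MPa (R2 = %.4f, points %d-%d)\n",
              x$low_slope, x$low_r2, x$low_range[1], x$low_range[2]))
  cat(sprintf("  high slope %.4g MPa (R2 = %.4f, points %d-%d)\n",
              x$high_slope, x$high_r2, x$high_range[1], x$high_range[2]))
  if (!x$degenerate)
    cat(sprintf("  transition stretch %.4f\n", x$transition_stretch))
  else cat("  degenerate: single-regime curve\n")
  invisible(x)
}

#' Per-specimen regime-slope table for a cohort
#'
#' Applies [truncate_at_fiber_breakage()] and [regime_slopes()] to every curve
#' of a list of [specimen_set()]s and assembles the tidy per-specimen table.
#'
#' @param sets list of [specimen_set()] objects.
#' @param ... passed to [regime_slopes()].
#' @return A data frame with one row per specimen: `specimen_id`, `region`,
#'   `direction`, `low_slope`, `high_slope`, `transition_stretch`, `low_r2`,
#'   `high_r2`.
#' @export
slope_table <- function(sets, ...) {
  rows <- lapply(sets, function(s) {
    lapply(c(s$circumferential, s$longitudinal), function(crv) {
      rs <- regime_slopes(truncate_at_fiber_breakage(crv), ...)
      data.frame(specimen_id = rs$specimen_id, region = rs$region,
                 direction = ifelse(rs$direction == "circumferential", "C",
                                    "L"),
                 low_slope = rs$low_slope, high_slope = rs$high_slope,
                 transition_stretch = rs$transition_stretch,
                 low_r2 = rs$low_r2, high_r2 = rs$high_r2,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}
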