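#' Shapiro-Wilk normality gate
#'
#' Gate used throughout the statistical pipeline: a sample is treated as
#' normally distributed when the Shapiro-Wilk p-value is at least `alpha`.
#' Samples larger than 5000 are thinned to 5000 evenly spaced order statistics
#' (the test is defined for 3-5000 observations).
#'
#' @param values numeric sample, n >= 3, non-constant.
#' @param alpha gate level (default 0.05).
#' @return List with `is_normal`, `p_value`, `statistic`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("normality gate needs at least 3 values")
  if (diff(range(values)) == 0) stop("constant sample: normality undefined")
  if (length(values) > 5000L) {
    values <- sort(values)[round(seq(1, length(values), length.out = 5000L))]
  }
  sw <- stats::shapiro.test(values)
  list(is_normal = sw$p.value >= alpha, p_value = sw$p.value,
       statistic = unname(sw$statistic))
}

#' Box-Cox transformation with maximum-likelihood lambda
#'
#' Profiles the Box-Cox likelihood on a fine lambda grid (via
#' [MASS::boxcox()]) and applies \eqn{y = (x^\lambda - 1)/\lambda}
#' (\eqn{\log x} at \eqn{\lambda = 0}) at the optimum.
#'
#' @param values strictly positive numeric sample.
#' @param lambda_grid grid searched for the optimum.
#' @return List with `transformed` and `lambda`.
#' @export
boxcox_optimal <- function(values,
                           lambda_grid = seq(-5, 5, by = 0.01)) {
  if (any(!is.finite(values))) stop("non-finite values")
  if (any(values <= 0)) stop("Box-Cox requires strictly positive values")
  if (diff(range(values)) == 0)
    return(list(transformed = values, lambda = 1, degenerate = TRUE))
  bc <- MASS::boxcox(values ~ 1, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  transformed <- if (abs(lambda) < 1e-12) log(values)
                 else (values^lambda - 1) / lambda
  list(transformed = transformed, lambda = lambda, degenerate = FALSE)
}

#' Regional difference tests with normality gating
#'
#' Implements the two-branch difference-examination flow: each group is first
#' checked with the Shapiro-Wilk gate; if any group fails, all groups are
#' Box-Cox transformed with a common maximum-likelihood lambda before testing.
#' Both pairwise two-sample t-tests (Welch by default) over all region pairs
#' and a one-way ANOVA with Bonferroni-corrected pairwise post-hoc tests are
#' then reported, labeled by `test`.
#'
#' @param values numeric vector of the variable under study.
#' @param region factor/character vector of region labels, same length.
#' @param alpha significance level (default 0.05).
#' @param var_equal `FALSE` (default) for Welch t-tests, `TRUE` for pooled.
#' @return A data frame of class `"region_comparison"`, one row per test and
#'   region pair: `test` (`"t_test"` or `"anova_bonferroni"`, plus one
#'   `"anova"` omnibus row), `region_a`, `region_b`, `statistic`, `p_value`,
#'   `transformed`, `significant`. The gate decisions are attached as
#'   attribute `"audit"`.
#' @export
compare_regions <- function(values, region, alpha = 0.05,
                            var_equal = FALSE) {
  stopifnot(length(values) == length(region))
  region <- as.character(region)
  keep <- is.finite(values)
  values <- values[keep]
  region <- region[keep]
  groups <- split(values, region)
  if (length(groups) < 2L) stop("need at least two regions")
  ns <- lengths(groups)
  if (any(ns < 3L)) stop("every region needs at least 3 observations")
  if (any(vapply(groups, function(g) diff(range(g)) == 0, logical(1))))
    stop("constant group: tests undefined")

  gate <- lapply(groups, normality_gate, alpha = alpha)
  all_normal <- all(vapply(gate, `[[`, logical(1), "is_normal"))
  audit <- data.frame(region = names(groups),
                      shapiro_p = vapply(gate, `[[`, numeric(1), "p_value"),
                      is_normal = vapply(gate, `[[`, logical(1),
                                         "is_normal"),
                      stringsAsFactors = FALSE)
  transformed <- FALSE
  if (!all_normal) {
    if (all(values > 0)) {
      bc <- boxcox_optimal(values)
      values <- bc$transformed
      groups <- split(values, region)
      transformed <- TRUE
      attr(audit, "boxcox_lambda") <- bc$lambda
    } else {
      warning("normality gate failed but values are not all positive; ",
              "proceeding without Box-Cox transformation")
    }
  }
  attr(audit, "transformed") <- transformed

  regs <- names(groups)
  pairs <- utils::combn(regs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- groups[[pairs[1, k]]]
    b <- groups[[pairs[2, k]]]
    tt <- if (isTRUE(all.equal(sort(a), sort(b)))) {
      list(statistic = 0, p.value = 1)       # identical groups: no difference
    } else {
      stats::t.test(a, b, var.equal = var_equal)
    }
    data.frame(test = "t_test", region_a = pairs[1, k],
               region_b = pairs[2, k],
               statistic = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })

  fit <- stats::aov(values ~ factor(region))
  an <- summary(fit)[[1]]
  rows[[length(rows) + 1L]] <- data.frame(
    test = "anova", region_a = NA_character_, region_b = NA_character_,
    statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
    stringsAsFactors = FALSE)
  ph <- stats::pairwise.t.test(values, factor(region),
                               p.adjust.method = "bonferroni",
                               pool.sd = var_equal)
  pm <- ph$p.value
  for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm))) {
    if (!is.na(pm[i, j])) {
      rows[[length(rows) + 1L]] <- data.frame(
        test = "anova_bonferroni", region_a = colnames(pm)[j],
        region_b = rownames(pm)[i], statistic = NA_real_,
        p_value = min(1, pm[i, j]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$transformed <- transformed
  out$significant <- out$p_value < alpha
  attr(out, "audit") <- audit
  class(out) <- c("region_comparison", "data.frame")
  out
}

#' Region-wise correlation analysis with coefficient averaging
#'
#' For every variable pair, computes the correlation coefficient and p-value
#' in each of the four test regions (PA, PP, DA, DP), averages the
#' coefficients over the regions, and flags a pair as `reported` only when it
#' is significantly correlated (p < `alpha`, r != 0) in *all four* regions.
#' `uniform_sign` records whether the four coefficients share one sign.
#'
#' @param tables named list of data frames, one per region (names must cover
#'   PA, PP, DA, DP), columns = variables, rows = fits/specimens.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha per-region significance level.
#' @return A data frame, one row per variable pair: `var_a`, `var_b`,
#'   `method`, `r_PA`, `r_PP`, `r_DA`, `r_DP`, `p_PA` ... `p_DP`, `mean_r`,
#'   `reported`, `uniform_sign`.
#' @export
correlation_matrix <- function(tables, method = c("spearman", "pearson"),
                               alpha = 0.05) {
  method <- match.arg(method)
  regions <- c("PA", "PP", "DA", "DP")
  if (!all(regions %in% names(tables)))
    stop("missing region(s): ",
         paste(setdiff(regions, names(tables)), collapse = ", "))
  tables <- tables[regions]
  vars <- Reduce(intersect, lapply(tables, colnames))
  if (length(vars) < 2L) stop("need at least two shared variables")
  for (tb in tables) if (nrow(tb) < 3L)
    stop("need at least 3 paired observations per region")
  pairs <- utils::combn(vars, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    va <- pairs[1, k]
    vb <- pairs[2, k]
    r <- p <- stats::setNames(numeric(4), regions)
    for (rg in regions) {
      ct <- suppressWarnings(
        stats::cor.test(tables[[rg]][[va]], tables[[rg]][[vb]],
                        method = method, exact = FALSE))
      r[rg] <- unname(ct$estimate)
      p[rg] <- ct$p.value
    }
    data.frame(var_a = va, var_b = vb, method = method,
               r_PA = r["PA"], r_PP = r["PP"], r_DA = r["DA"],
               r_DP = r["DP"], p_PA = p["PA"], p_PP = p["PP"],
               p_DA = p["DA"], p_DP = p["DP"],
               mean_r = mean(r),
               reported = all(p < alpha & r != 0),
               uniform_sign = all(r > 0) || all(r < 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
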