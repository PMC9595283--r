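test_that("the normality gate accepts normal and rejects lognormal samples", {
  set.seed(23)
  hits_norm <- sum(vapply(1:100, function(i)
    normality_gate(stats::rnorm(500))$is_normal, logical(1)))
  expect_gte(hits_norm, 90)
  hits_lnorm <- sum(vapply(1:100, function(i)
    normality_gate(stats::rlnorm(500))$is_normal, logical(1)))
  expect_lte(hits_lnorm, 1)
  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("Box-Cox finds lambda near zero for lognormal data and normalizes it", {
  set.seed(29)
  x <- stats::rlnorm(1000)
  bc <- boxcox_optimal(x)
  expect_lt(abs(bc$lambda), 0.15)
  expect_true(normality_gate(bc$transformed)$is_normal)
  # a shifted already-normal positive sample stays normal after transform
  y <- stats::rnorm(500, mean = 20, sd = 1)
  bcy <- boxcox_optimal(y)
  expect_true(normality_gate(bcy$transformed)$is_normal)
  expect_error(boxcox_optimal(c(-1, 2, 3)), "positive")
  deg <- boxcox_optimal(c(1, 1, 1))
  expect_true(deg$degenerate)
})

test_that("null region comparisons keep the nominal type-I error", {
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    v <- stats::rnorm(100)
    rg <- rep(c("PA", "DP"), each = 50)
    cmp <- suppressWarnings(compare_regions(v, rg))
    cmp$significant[cmp$test == "t_test"][1]
  }, logical(1))
  expect_gte(mean(hits), 0.005)
  expect_lte(mean(hits), 0.12)
})

test_that("a one-standard-deviation shift is detected almost always", {
  set.seed(37)
  hits <- vapply(1:50, function(i) {
    v <- c(stats::rnorm(50), stats::rnorm(50, mean = 1))
    cmp <- suppressWarnings(compare_regions(v, rep(c("PA", "DP"), each = 50)))
    cmp$significant[cmp$test == "t_test"][1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("identical groups give p = 1 and non-normal groups get transformed", {
  x <- stats::rlnorm(40, 0, 1)
  cmp <- compare_regions(c(x, x), rep(c("PA", "DP"), each = 40))
  t_row <- cmp[cmp$test == "t_test", ]
  expect_equal(t_row$p_value, 1)
  expect_false(t_row$significant)
  # lognormal input fails the gate, so the audit must show a Box-Cox pass
  expect_true(unique(cmp$transformed))
  audit <- attr(cmp, "audit")
  expect_false(all(audit$is_normal))
  expect_false(is.null(attr(audit, "boxcox_lambda")))
})

test_that("the normality gate is honored before any t-test", {
  set.seed(41)
  v <- c(stats::rnorm(50, 10), stats::rnorm(50, 10.5))
  cmp <- compare_regions(v, rep(c("PA", "DP"), each = 50))
  audit <- attr(cmp, "audit")
  # when every group passes the gate no transformation may be applied
  if (all(audit$is_normal)) expect_false(unique(cmp$transformed))
  expect_identical(attr(audit, "transformed"), unique(cmp$transformed))
})

test_that("ANOVA post-hoc p-values dominate the raw pairwise p-values", {
  set.seed(43)
  v <- c(stats::rnorm(30, 0), stats::rnorm(30, 0.4), stats::rnorm(30, 0.8),
         stats::rnorm(30, 0.1))
  rg <- rep(c("PA", "PP", "DA", "DP"), each = 30)
  cmp <- compare_regions(v, rg)
  raw <- cmp[cmp$test == "t_test", ]
  post <- cmp[cmp$test == "anova_bonferroni", ]
  key <- function(d) paste(pmin(d$region_a, d$region_b),
                           pmax(d$region_a, d$region_b))
  m <- match(key(raw), key(post))
  # Bonferroni-corrected pooled tests are conservative relative to raw tests
  expect_lte(sum(post$significant[m]), sum(raw$significant))
  expect_true(all(post$p_value <= 1))
  expect_equal(nrow(raw), 6)   # all six region pairs
})

test_that("correlations are exact on monotone pairs and averaged over regions", {
  set.seed(47)
  tables <- lapply(stats::setNames(nm = c("PA", "PP", "DA", "DP")),
                   function(rg) {
    x <- stats::runif(20)
    data.frame(x = x, y = x^3, z = -x^5)
  })
  sp <- correlation_matrix(tables, "spearman")
  xy <- sp[sp$var_a == "x" & sp$var_b == "y", ]
  expect_equal(unlist(xy[c("r_PA", "r_PP", "r_DA", "r_DP")]),
               c(r_PA = 1, r_PP = 1, r_DA = 1, r_DP = 1))
  expect_equal(xy$mean_r, 1)
  expect_true(xy$reported)
  expect_true(xy$uniform_sign)
  xz <- sp[sp$var_a == "x" & sp$var_b == "z", ]
  expect_equal(xz$mean_r, -1)
  expect_error(correlation_matrix(tables[c("PA", "PP")]), "missing region")
})

test_that("Spearman correlation is invariant under strictly monotone transforms", {
  set.seed(53)
  tables <- lapply(stats::setNames(nm = c("PA", "PP", "DA", "DP")),
                   function(rg) {
    x <- stats::rnorm(15)
    data.frame(x = x, y = stats::rnorm(15))
  })
  warped <- lapply(tables, function(tb)
    data.frame(x = exp(tb$x), y = tb$y^3 + 5 * tb$y))
  r1 <- correlation_matrix(tables, "spearman")
  r2 <- correlation_matrix(warped, "spearman")
  expect_equal(r1$mean_r, r2$mean_r, tolerance = 1e-12)
})

test_that("independent pairs are almost never reported in all four regions", {
  set.seed(59)
  n_reported <- sum(vapply(1:400, function(i) {
    tables <- lapply(stats::setNames(nm = c("PA", "PP", "DA", "DP")),
                     function(rg)
      data.frame(x = stats::rnorm(20), y = stats::rnorm(20)))
    correlation_matrix(tables, "spearman")$reported
  }, logical(1)))
  expect_lte(n_reported / 400, 0.01)
})
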