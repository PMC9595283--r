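# shared fixtures, built in code at test time

# exact two-piece linear stress-stretch curve: slope s1 over n1 points, then
# s2 over n2 points, continuous at the knee
two_piece_curve <- function(s1 = 0.1, s2 = 2, n1 = 50, n2 = 50,
                            lam0 = 1, dlam = 0.005, noise_sd = 0,
                            seed = NULL, region = "PA",
                            direction = "circumferential") {
  lam <- lam0 + dlam * seq_len(n1 + n2)
  knee <- lam[n1]
  stress <- ifelse(lam <= knee, s1 * (lam - lam0),
                   s1 * (knee - lam0) + s2 * (lam - knee))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    stress <- stress * (1 + stats::rnorm(length(stress), 0, noise_sd))
  }
  ss_curve(lam, pmax(0, stress), region, direction, "twopiece",
           validate = FALSE)
}

# curve evaluated from a model's closed form, optionally with seeded noise
model_curve <- function(params, direction, lam_max = 1.5, n = 60,
                        noise_sd_fraction = 0, seed = NULL, region = "PA",
                        specimen_id = "gen") {
  lam <- seq(1, lam_max, length.out = n)
  mu <- uniaxial_stress(params, lam, direction)
  if (noise_sd_fraction > 0) {
    if (!is.null(seed)) set.seed(seed)
    mu <- pmax(0, mu * (1 + stats::rnorm(n, 0, noise_sd_fraction)))
  }
  ss_curve(lam, mu, region, direction, specimen_id, validate = FALSE)
}

# a virtual pair whose two curves come from one shared ground truth
shared_truth_pair <- function(params, region = "PA", lam_c = 1.45,
                              lam_l = 1.7, n = 60) {
  structure(list(
    circ_curve = model_curve(params, "circumferential", lam_c, n,
                             region = region, specimen_id = "C1"),
    long_curve = model_curve(params, "longitudinal", lam_l, n,
                             region = region, specimen_id = "L1"),
    region = region, pair_index = c(1L, 1L)), class = "virtual_pair")
}

# random valid parameter draws for property-style loops
random_fung <- function() fung_params(runif(1, 0.02, 0.3), runif(1, 0.5, 3),
                                      runif(1, 0.5, 3), runif(1, 0.2, 2),
                                      runif(1, 0, 1), runif(1, 0, 1),
                                      runif(1, 0, 1))
random_holzapfel <- function() holzapfel_params(runif(1, 0.01, 0.2),
                                                runif(1, 0.01, 0.3),
                                                runif(1, 0.2, 5),
                                                runif(1, 0, pi / 2))
random_cmm <- function(unit_prestretch = FALSE) {
  g <- if (unit_prestretch) c(1, 1, 1) else runif(3, 0.9, 1.3)
  cmm_params(runif(1, 0.005, 0.05), runif(1, 0.05, 0.4),
             runif(1, 0.05, 0.4), runif(1, 0.5, 3), runif(1, 0.5, 3),
             g[1], g[2], g[3], runif(1, 0, pi / 2))
}

# tiny specimen set with n_c x n_l minimal curves (for pairing tests)
tiny_set <- function(region = "PA", n_c = 3, n_l = 4) {
  lam <- seq(1, 1.2, length.out = 10)
  mk <- function(d, i) ss_curve(lam, 0.1 * (lam^2 - 1 / lam), region, d,
                                sprintf("%s%s%d", region,
                                        ifelse(d == "circumferential", "C",
                                               "L"), i))
  specimen_set(region,
               lapply(seq_len(n_c), function(i) mk("circumferential", i)),
               lapply(seq_len(n_l), function(i) mk("longitudinal", i)))
}
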