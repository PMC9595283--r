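test_that("uniaxial stress vanishes exactly at the identity stretch", {
  set.seed(11)
  for (rep in 1:25) {
    fp <- random_fung()
    hp <- random_holzapfel()
    cpu <- random_cmm(unit_prestretch = TRUE)
    for (d in c("circumferential", "longitudinal")) {
      expect_identical(uniaxial_stress(fp, 1, d), 0)
      expect_identical(uniaxial_stress(fp, 1, d, form = "literal"), 0)
      expect_identical(uniaxial_stress(hp, 1, d), 0)
      expect_identical(uniaxial_stress(hp, 1, d, form = "literal"), 0)
      expect_identical(uniaxial_stress(cpu, 1, d), 0)
      expect_identical(strain_energy(fp, 1, d), 0)
      expect_identical(strain_energy(hp, 1, d), 0)
      expect_identical(strain_energy(cpu, 1, d), 0)
    }
  }
})

test_that("CMM stores pre-stretch energy at the identity state", {
  p <- cmm_params(0.02, 0.1, 0.1, 2, 1, 1.1, 1.1, 1.05, 0.6)
  expect_gt(strain_energy(p, 1, "circumferential"), 0)
})

test_that("closed forms reproduce frozen energy-derivative reference values", {
  # central-difference reference computed independently of the closed forms
  fp <- fung_params(0.1, 2, 1, 0.5, 0.5, 0.5, 0.5)
  expect_equal(uniaxial_stress(fp, 1.3, "circumferential"),
               0.114998117720, tolerance = 1e-8)
  hp <- holzapfel_params(0.05, 0.1, 1, 0)
  expect_equal(uniaxial_stress(hp, 1.2, "circumferential"),
               0.337910839674, tolerance = 1e-8)
  cp <- cmm_params(0.02, 0.05, 0, 2, 1, 1.2, 1.2, 1.1, pi / 4)
  expect_equal(uniaxial_stress(cp, 1.15, "longitudinal"),
               0.032209691354, tolerance = 1e-8)
})

test_that("neo-Hookean limit of the Holzapfel model is exact", {
  p <- holzapfel_params(0.05, 0, 1, 0.7)
  lam <- seq(1.05, 1.6, by = 0.05)
  for (d in c("circumferential", "longitudinal")) {
    expect_equal(uniaxial_stress(p, lam, d), 0.05 * (lam^2 - 1 / lam),
                 tolerance = 1e-14)
    expect_equal(uniaxial_stress(p, lam, d, form = "literal"),
                 0.05 * (lam^2 - 1 / lam), tolerance = 1e-14)
  }
  expect_equal(uniaxial_stress(p, 1.2, "circumferential"),
               0.05 * (1.2^2 - 1 / 1.2), tolerance = 1e-14)
})

test_that("CMM with unit pre-stretches and no collagen is neo-Hookean elastin", {
  p <- cmm_params(0.03, 0, 0, 2, 1, 1, 1, 1, 0.5)
  lam <- c(1.1, 1.2, 1.4)
  for (d in c("circumferential", "longitudinal"))
    expect_equal(uniaxial_stress(p, lam, d), 0.03 * (lam^2 - 1 / lam),
                 tolerance = 1e-12)
})

test_that("Fung index exchange maps the two loading directions onto each other", {
  # swapping b1<->b2 and b5<->b6 (b4 fixed) exchanges the roles of the
  # circumferential and longitudinal closed forms
  set.seed(21)
  for (rep in 1:10) {
    b <- runif(6, 0.2, 2)
    c1 <- runif(1, 0.05, 0.2)
    p <- fung_params(c1, b[1], b[2], b[3], b[4], b[5], b[6])
    q <- fung_params(c1, b[2], b[1], b[3], b[4], b[6], b[5])
    lam <- seq(1.05, 1.5, by = 0.05)
    for (form in c("consistent", "literal")) {
      expect_equal(uniaxial_stress(p, lam, "circumferential", form),
                   uniaxial_stress(q, lam, "longitudinal", form),
                   tolerance = 1e-13)
    }
  }
})

test_that("closed-form stress matches the numeric oracle on random parameters", {
  set.seed(31)
  lam <- seq(1.05, 1.6, by = 0.05)
  for (rep in 1:20) {
    for (p in list(random_fung(), random_holzapfel(), random_cmm())) {
      for (d in c("circumferential", "longitudinal")) {
        cf <- uniaxial_stress(p, lam, d)
        or <- numeric_stress_oracle(p, lam, d)
        expect_lt(max(abs(cf - or) / pmax(abs(or), 1e-10)), 1e-6)
      }
    }
  }
})

test_that("oracle central difference converges at second order", {
  p <- random_holzapfel()
  exact <- uniaxial_stress(p, 1.3, "circumferential")
  e1 <- abs(numeric_stress_oracle(p, 1.3, "circumferential", h = 1e-2) -
              exact)
  e2 <- abs(numeric_stress_oracle(p, 1.3, "circumferential", h = 1e-3) -
              exact)
  expect_lt(e2, e1 / 50)   # ~h^2: a decade in h gains ~two decades in error
})

test_that("oracle flags a step too large for the requested accuracy", {
  p <- holzapfel_params(0.05, 0.2, 8, 0.3)
  expect_error(numeric_stress_oracle(p, 1.5, "circumferential", h = 0.2,
                                     check_step = TRUE, step_tol = 1e-10),
               "step too large")
  expect_silent(numeric_stress_oracle(p, 1.5, "circumferential", h = 1e-5,
                                      check_step = TRUE))
})

test_that("literal forms equal the energy-consistent forms on the symmetric subspace", {
  # the radial-face multiplier elimination is exact when the two transverse
  # directions respond identically
  set.seed(41)
  lam <- seq(1.05, 1.5, by = 0.05)
  for (rep in 1:10) {
    b <- runif(4, 0.2, 2)
    c1 <- runif(1, 0.05, 0.2)
    # circumferential loading: b2 = b3 and b4 = b5
    p <- fung_params(c1, b[1], b[2], b[2], b[3], b[3], b[4])
    expect_equal(uniaxial_stress(p, lam, "circumferential", "literal"),
                 uniaxial_stress(p, lam, "circumferential", "consistent"),
                 tolerance = 1e-12)
    # longitudinal loading: b1 = b3 and b4 = b6
    q <- fung_params(c1, b[1], b[2], b[1], b[3], b[4], b[3])
    expect_equal(uniaxial_stress(q, lam, "longitudinal", "literal"),
                 uniaxial_stress(q, lam, "longitudinal", "consistent"),
                 tolerance = 1e-12)
    # Holzapfel: fibers aligned with the loaded axis
    h1 <- holzapfel_params(runif(1, 0.01, 0.1), runif(1, 0.01, 0.2),
                           runif(1, 0.5, 3), 0)
    expect_equal(uniaxial_stress(h1, lam, "circumferential", "literal"),
                 uniaxial_stress(h1, lam, "circumferential", "consistent"),
                 tolerance = 1e-12)
    h2 <- holzapfel_params(runif(1, 0.01, 0.1), runif(1, 0.01, 0.2),
                           runif(1, 0.5, 3), pi / 2)
    expect_equal(uniaxial_stress(h2, lam, "longitudinal", "literal"),
                 uniaxial_stress(h2, lam, "longitudinal", "consistent"),
                 tolerance = 1e-12)
  }
})

test_that("off the symmetric subspace the literal form departs from the oracle", {
  # the discrepancy is half the residual transverse stress; it is real and
  # measurable, which is why both forms are exposed
  fp <- fung_params(0.1, 2, 1, 0.5, 0.5, 0.5, 0.5)   # b2 != b3
  lit <- uniaxial_stress(fp, 1.3, "circumferential", "literal")
  or <- numeric_stress_oracle(fp, 1.3, "circumferential")
  expect_gt(abs(lit - or) / abs(or), 0.01)
  hp <- holzapfel_params(0.05, 0.1, 1, pi / 6)
  lit_h <- uniaxial_stress(hp, 1.2, "circumferential", "literal")
  or_h <- numeric_stress_oracle(hp, 1.2, "circumferential")
  expect_gt(abs(lit_h - or_h) / abs(or_h), 0.01)
  # CMM literal transcription departs as well (duplicated stretch factors)
  cp <- cmm_params(0.02, 0.05, 0.03, 2, 1, 1.1, 1.1, 1.05, 0.6)
  lit_c <- uniaxial_stress(cp, 1.2, "circumferential", "literal")
  or_c <- numeric_stress_oracle(cp, 1.2, "circumferential")
  expect_gt(abs(lit_c - or_c), 1e-4)
})

test_that("Holzapfel anisotropic term grows as fibers align with the loaded axis", {
  # swept over the fiber-tension range (invariant >= 1); beyond it the term
  # changes sign and monotonicity provably fails for these equations
  lam <- 1.25
  iso <- 0.05 * (lam^2 - 1 / lam)
  for (form in c("consistent", "literal")) {
    gam <- seq(0, pi / 2, length.out = 200)
    keep <- (lam^2 - 1) * cos(gam)^2 + (1 / lam - 1) * sin(gam)^2 >= 0
    aniso <- vapply(gam[keep], function(g)
      uniaxial_stress(holzapfel_params(0.05, 0.1, 2, g), lam,
                      "circumferential", form) - iso, numeric(1))
    expect_true(all(diff(aniso) <= 1e-12))
  }
})

test_that("exponent overflow is signalled, not silently saturated", {
  p <- holzapfel_params(0.05, 0.1, 50, 0)
  expect_error(uniaxial_stress(p, 3.5, "circumferential"),
               "non-finite stress")
  expect_error(uniaxial_stress(p, 3.5, "circumferential"),
               class = "virtbiax_nonfinite_stress")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(fung_params(-0.1, 1, 1, 1, 1, 1, 1), "c1")
  expect_error(holzapfel_params(0.05, 0.1, -1, 0.3), "k2")
  expect_error(holzapfel_params(0.05, 0.1, 1, 2), "gamma")
  expect_error(cmm_params(0.02, 0.1, 0.1, 2, 1, 0, 1, 1, 0.5),
               "pre-stretches")
  expect_error(cmm_params(-0.02, 0.1, 0.1, 2, 1, 1, 1, 1, 0.5))
})
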