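Package: virtbiax
Title: Virtual Biaxial Characterization of Arterial Tissue from Uniaxial Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-dependent mechanical characterization of arterial tissue from
    uniaxial tensile tests. Pairs of circumferential and longitudinal stress-stretch
    curves from the same aortic region are cross-mapped one-to-many into virtual
    biaxial datasets, and three anisotropic hyperelastic constitutive models (the
    Fung orthotropic exponential model, the Holzapfel two-fiber-family model, and a
    constrained mixture model with constituent pre-stretches) are fitted to each
    virtual pair by bounded multistart nonlinear least squares with per-direction
    plausible-interval integration. Includes two-regime tangent-stiffness estimation
    via R-squared-optimal piecewise-linear ranges, a normality-gated statistical
    pipeline (Shapiro-Wilk, Box-Cox, t-tests, ANOVA with Bonferroni correction,
    Pearson and Spearman correlations averaged over regions), and a seeded synthetic
    cohort generator with region-structured ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    MASS,
    minpack.lm,
    lhs
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
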