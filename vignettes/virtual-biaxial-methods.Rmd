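---
title: "Virtual biaxial characterization: models, estimator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual biaxial characterization: models, estimator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(virtbiax)
```

## The problem and the device

Anisotropic hyperelastic models of the arterial wall need paired information
from two loading directions, but uniaxial tensile campaigns — the practical
way to map regional heterogeneity — test each specimen in one direction only.
`virtbiax` pairs every circumferential specimen of an aortic region with every
longitudinal specimen of the same region (the full Cartesian product; with
the default cohort design that is 1,015 + 625 + 728 + 784 = 3,152 virtual
pairs, 9,456 fit cases over three models). Each *virtual pair* stands in for
a biaxial test of one region, and the population of fits over all pairs
carries the between-specimen variability into the parameter distributions.
Cross-region pairing is deliberately not offered, and subsampling of pairs is
available only as an explicit, seeded runtime control — never the default.

## Kinematics and the two stress forms

All three models are evaluated on the incompressible uniaxial path
F = diag(λ, λ^−1/2, λ^−1/2), with the loaded axis mapped onto the specimen's
material direction, the Cauchy stress obtained from the strain energy W and a
pressure-like multiplier enforced by traction-free lateral faces.

For an *anisotropic* material this classical setup hides a subtlety: with
both lateral stretches pinned at λ^−1/2, the two transverse faces can only be
simultaneously traction-free when the transverse response is symmetric. The
textbook closed forms eliminate the multiplier through the radial face alone,
which leaves a residual in-plane transverse stress whenever symmetry fails —
for the Fung model whenever b₂ ≠ b₃ or b₄ ≠ b₅ under circumferential loading
(b₁ ≠ b₃ or b₄ ≠ b₆ under longitudinal), for the Holzapfel model whenever the
fibers are neither loading-aligned nor absent. The exact uniaxial stress along
this kinematic path is instead the total energy derivative

  T = λ · dŴ/dλ,  Ŵ(λ) = W evaluated along the path,

which equals the tensor expression with the multiplier chosen as the *mean*
transverse stress. The two results differ by half the residual transverse
stress — around 2% for a representative asymmetric Fung set, up to tens of
percent for strongly inclined Holzapfel fibers.

`virtbiax` therefore exposes both closed forms for every model:

* `form = "consistent"` (default): the analytic λ·dŴ/dλ. It agrees with the
  central-difference oracle `numeric_stress_oracle()` to near machine
  precision for arbitrary parameters, which is what the test suite asserts.
* `form = "literal"`: the radial-face elimination in its classical
  transcription. On the transversely-symmetric parameter subspace the two
  forms coincide identically (also a tested property). For the constrained
  mixture model the literal transcription additionally carries the
  duplicated stretch factors of its published uniaxial form, so it departs
  from the energy derivative even at symmetric configurations; it is kept
  strictly for diffing, with the grouping of the (G_h λₙ)² factor read
  literally.

The oracle itself is a second-order central difference, λ(Ŵ(λ+h) − Ŵ(λ−h))/2h
with h = 10⁻⁵ by default, an optional step check (re-evaluation at h/2), and
observed second-order convergence. Exponent arguments above 700 raise a
classed non-finite-stress error rather than saturating silently.

Angles are radians internally (degrees only in printed output); stresses are
MPa throughout — the literature rarely states units, so the file format fixes
them in the column name (`stress_MPa`).

## The models

* **Fung**: c₁ (MPa) scales an exponential of the quadratic form Q in
  Green–Lagrange strains; b₁ and b₂ multiply the squared in-plane normal
  strains and dominate directional stiffness; b₃–b₆ couple the out-of-plane
  strain, which under this kinematics equals the in-plane transverse strain —
  the root of the well-known non-identifiability of some b-combinations from
  uniaxial data. Swapping (b₁↔b₂, b₅↔b₆) exchanges the two loading
  directions' responses exactly.
* **Holzapfel**: neo-Hookean matrix c (MPa) plus two symmetric collagen
  families with stress scale k₁ (MPa), exponent k₂ and angle γ. No
  tension-only switch is applied — the equations are used literally; fitted
  stretch ranges start at λ = 1 and the fiber invariant stays ≥ 1 except for
  strongly inclined fibers, which is also why the monotone-anisotropy
  property (circumferential stress non-decreasing as fibers align with the
  load) is asserted over the fiber-tension sub-range of γ only: beyond it the
  anisotropic term changes sign and monotonicity genuinely fails.
* **Constrained mixture**: elastin with in-plane pre-stretch tensor
  diag(G₁, G₂) (its energy includes the −3 offset so the energy vanishes at
  the natural state; the offset carries no stress), plus two grouped collagen
  families at ±α from the axial direction with deposition pre-stretch G_h.
  Constituent mass densities are absorbed into the stress-like coefficients.
  With pre-stretches present the stress at λ = 1 is legitimately nonzero —
  the tissue's reference configuration is not the constituents' natural
  state; with unit pre-stretches the model collapses to neo-Hookean elastin
  and zero stress at identity (both tested).

## The estimator

`hyperfit()` is bounded multistart nonlinear least squares
(Levenberg–Marquardt with box constraints via `minpack.lm`), unweighted
residuals in stress units.

Default bounds: stress-like parameters [10⁻⁶, 10] MPa, dimensionless
exponents [10⁻⁴, 50] (Fung b's [0, 50]), angles [0, π/2], pre-stretches
[0.8, 2] — wide enough to cover reported healthy-aorta magnitudes (k₂ medians
near 3.3, G_h near 1.34) with headroom. Starts are one field-typical
heuristic vector plus Latin-hypercube draws; the draws are taken log-uniform
(for magnitude-type parameters) from a *physiologic sub-box* rather than the
full bounds, because full-box draws overwhelmingly land in the
exponential-overflow plateau where the residual surface is flat and the
optimizer learns nothing. Budgets are model-dependent — 8 starts for the
four-parameter Holzapfel model, 16 for Fung, 24 for the nine-parameter
mixture — and the best solution gets up to two polish restarts (restarting
resets the LM damping, which frees plateau stalls on ridged landscapes). The
mixture model additionally contributes a staged start: pre-stretches pinned
at mid-range values, the remaining six parameters fitted, then everything
released — the classical two-step estimation of mixture models, used here
purely as an initialization. All draws are seeded; a fixed seed gives
bitwise-identical fits.

For a virtual pair the sequence is:

1. **Per-direction fits** on each curve.
2. **Plausible intervals**: per parameter, the contiguous region around the
   best fit whose *profiled* residual sum of squares (others re-optimized,
   warm-started sweep over a grid clustered cubically around the optimum,
   threshold crossing interpolated under a locally-quadratic assumption)
   stays within a residual factor of the minimum. The factor starts at 1.05.
   An absolute SSR floor at (10⁻⁴ × stress scale)² per point keeps noiseless
   fits from collapsing to zero-width intervals. Conditional profiles (other
   parameters held fixed) were evaluated and rejected: they are far too
   narrow to ever intersect across directions.
3. **Common range**: the per-parameter intersection of the two directions'
   intervals.
4. **Joint refit** on the concatenated two-direction residual, constrained to
   the common range, started from the two direction solutions and their
   midpoint. The refit is *accepted* only if its SSR stays within the current
   factor of the summed per-direction minima (and both R² ≥ 0.9) — a single
   parameter set should describe both curves nearly as well as two free ones
   did. Otherwise the factor is relaxed through 1.05, 1.1, 1.25, 1.5.
5. **Fallback**: if no level yields an acceptable constrained fit, an
   unconstrained joint fit is run and the result flagged (`fallback = TRUE`,
   with a warning). This is common and expected for pairs whose two specimens
   are mechanically far apart; the `converged` flag tracks fit quality
   (R² floor, non-degenerate data) independently of the path taken, so
   fallback fits still enter distribution summaries.

The alternative semantics — accepting the interval intersection without a
refit — is available in effect through the reported `common` interval; the
refit is the default because a concatenated-residual optimum is a sharper
single-vector summary than a box. On curve-recovery: for the Holzapfel model
the four parameters are identifiable from a noiseless pair and are recovered
to well under 5% (tested); for Fung and the mixture model only reproduction
of the stress–stretch curves is asserted, since their parameter vectors are
structurally non-identifiable from two uniaxial directions.

## Regime analysis

Curves are truncated at fiber breakage: the prefix up to the global stress
maximum, or to the point where a running windowed least-squares tangent drops
below half its running maximum, whichever comes first (the source literature
states the concept but no formula; this rule is the package's own). Each
regime's optimal linear range is the R²-maximizing window anchored at the
curve's first point (low-stiffness) or last point (high-stiffness), minimum
window five points, ties broken toward the longer window — longer windows give
lower-variance slopes. The tangent is the window's OLS slope evaluated at the
window midpoint (a local quadratic is available for sensitivity checks). The
transition stretch is the midpoint between the two ranges' inner ends. A
degeneracy flag is raised when the ranges overlap beyond a shared endpoint or
when the two slopes are indistinguishable at two combined standard errors —
on an exactly piecewise-linear curve the knee belongs to both segments, so
sharing one point is not overlap.

A joint two-segment selector (minimizing pooled residual mean square over
both windows) was prototyped and rejected: under the multiplicative noise
that load cells actually produce it prefers lucky short windows, whereas the
per-window R² scan is robust precisely because multiplicative noise keeps the
relative noise level comparable across windows.

## Statistical pipeline

The difference-examination flow gates each group with the Shapiro–Wilk test
at α = 0.05; if any group fails, all values are Box–Cox transformed with a
common maximum-likelihood λ (profiled on a 0.01-step grid via `MASS::boxcox`)
before testing, and the gate decisions plus λ are kept in an audit attribute.
Then both pairwise two-sample t-tests over all region pairs and a one-way
ANOVA with Bonferroni-corrected pairwise post-hoc tests are reported, labeled
separately — which of the two produced a given published significance is not
always distinguishable, so both are emitted. The t-tests are Welch by default
(group variances differ regionally; a pooled-variance switch exists).
Correlation analysis computes r and p per region for every variable pair
(Spearman with average ranks for ties, or Pearson), averages r over the four
regions, and marks a pair `reported` only when it is significant with nonzero
r in *all four* regions; `uniform_sign` records sign consistency, since
mixed-sign correlations across regions do occur and are worth flagging.
Calibration is verified by simulation: type-I error within [2%, 10%] at
nominal 5%, near-total power at a one-standard-deviation shift, Spearman
exactness on monotone pairs, |λ̂| < 0.15 on lognormal samples, and a ≤ 1%
all-four-regions false-report rate on independent pairs.

## Synthetic cohorts

The generator emulates the study conditions of a porcine descending thoracic
aorta campaign: eight direction sets with specimen counts 35, 29, 26, 28, 25,
25, 28, 28 (PAC, PAL, DAC, DAL, PPC, PPL, DPC, DPL), J-shaped curves with a
compliant and a stiff regime, circumferential specimens stiffer than
longitudinal, and the distal posterior region stiffest. Defaults, chosen once
from curve-shape physics and reported parameter magnitudes: Holzapfel
generator with c ∈ [0.04, 0.06] MPa, k₁ ∈ [0.04, 0.08] MPa, region-graded
k₂ (PA 1.8–2.4, DA 2.0–2.6, PP 2.2–2.8, DP 3.0–3.6), γ ∈ [0.60, 0.70] rad;
80 points per curve; stretch endpoints 1.45 (circumferential) and 1.70
(longitudinal) — the longer longitudinal run is needed for the fiber
invariant to grow appreciably against transverse contraction, i.e. for the
longitudinal J-shape to appear; 2% multiplicative Gaussian noise (load-cell
noise scales with signal, and multiplicative noise leaves the zero-stress
identity point exactly zero); per-specimen lognormal jitter (sd 0.15 on the
log scale) on stress-like parameters to create realistic between-specimen
spread. Fung and mixture generators exist with analogous region grading; the
mixture ranges keep pre-stretches mild (G ≈ 1.05–1.15, G_h ≈ 1.02–1.08) so
the traction-free reference state carries only a small residual stress, as an
excised specimen must.

What the generator does *not* emulate: image-based stretch measurement,
force-to-stress conversion through measured thickness, rupture behavior,
specimen-level fiber-architecture variation beyond scalar jitter, or any
departure of real tissue from the generating constitutive family. Passing
recovery tests therefore demonstrates the estimator's correctness and the
pipeline's calibration under the stated conditions — not that any particular
model is the right description of real aortic tissue.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately scaled sizes:
oracle grids of 100 random parameter sets × 12 stretches, 20 noiseless
Holzapfel pairs plus two pairs each for Fung and the mixture model, 200-run
null simulations, and small (1–3 specimens per direction) cohorts for
end-to-end determinism — full 3,152-pair campaigns use identical code paths
and are enumerated exactly but not fitted in the default runs. Every source
of randomness (cohort generation, multistart, simulations) descends from an
explicit seed, and a fixed seed reproduces every output file byte-for-byte.

## Known limitations

The kinematic assumption of equal lateral stretches is itself an
approximation for anisotropic tissue; the consistent form is exact for the
assumed path, not for the fully traction-free boundary-value problem. Shear
deformation and a possible fifth-invariant dependence are out of scope, as
are layered-wall models, growth and remodeling dynamics, and rupture-strength
analysis. Parameter distributions inherit the non-identifiability of the
Fung and mixture parameterizations: individual coordinates of those fits
should be interpreted through their plausible intervals and
inter-correlations, not as point estimates.
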