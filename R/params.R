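#' Fung orthotropic exponential model parameters
#'
#' The Fung-type strain energy is \eqn{W = c_1/2 [\exp(Q) - 1]} with
#' \eqn{Q = b_1 E_{11}^2 + b_2 E_{22}^2 + b_3 E_{33}^2 + 2 b_4 E_{11}E_{22} +
#' 2 b_5 E_{11}E_{33} + 2 b_6 E_{22}E_{33}} in Green-Lagrange strain components
#' (1 = circumferential, 2 = longitudinal, 3 = radial).
#'
#' @param c1 stress-like elastic constant (MPa), > 0.
#' @param b1,b2,b3,b4,b5,b6 dimensionless exponent coefficients.
#' @return A named numeric vector of class `"fung_params"`.
#' @examples
#' fung_params(0.1, 2, 1, 0.5, 0.5, 0.5, 0.5)
#' @export
fung_params <- function(c1, b1, b2, b3, b4, b5, b6) {
  p <- c(c1 = c1, b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5, b6 = b6)
  if (any(!is.finite(p))) stop("Fung parameters must be finite")
  if (c1 <= 0) stop("c1 must be > 0")
  structure(p, class = "fung_params")
}

#' Holzapfel two-fiber-family model parameters
#'
#' Strain energy \eqn{W = c/2 (I_1 - 3) + k_1/(2 k_2) \sum_{i=4,6}
#' [\exp(k_2 (I_i - 1)^2) - 1]} with two symmetric collagen fiber families; the
#' fiber angle \eqn{\gamma} is measured from the longitudinal direction and is
#' stored in radians.
#'
#' @param c neo-Hookean stress-like parameter (MPa), > 0.
#' @param k1 fiber stress-like parameter (MPa), >= 0 (0 gives the neo-Hookean
#'   limit).
#' @param k2 dimensionless fiber exponent, > 0.
#' @param gamma fiber angle in radians, in \eqn{[0, \pi/2]}.
#' @return A named numeric vector of class `"holzapfel_params"`.
#' @examples
#' holzapfel_params(0.05, 0.1, 1, pi / 6)
#' @export
holzapfel_params <- function(c, k1, k2, gamma) {
  p <- c(c = c, k1 = k1, k2 = k2, gamma = gamma)
  if (any(!is.finite(p))) stop("Holzapfel parameters must be finite")
  if (c <= 0) stop("c must be > 0")
  if (k1 < 0) stop("k1 must be >= 0")
  if (k2 <= 0) stop("k2 must be > 0")
  if (gamma < 0 || gamma > pi / 2) stop("gamma must lie in [0, pi/2]")
  structure(p, class = "holzapfel_params")
}

#' Constrained mixture model parameters
#'
#' Elastin with an in-plane pre-stretch tensor diag(G1, G2) plus two grouped
#' collagen fiber families at \eqn{\pm\alpha} from the axial direction, each
#' deposited with pre-stretch `Gh` relative to the tissue reference
#' configuration. Constituent mass densities are absorbed into the stress-like
#' coefficients.
#'
#' @param c1 elastin stress-like parameter (MPa), >= 0.
#' @param c2_1,c2_2 collagen stress-like parameters for the two family groups
#'   (MPa), >= 0.
#' @param c3_1,c3_2 dimensionless collagen exponents, >= 0.
#' @param G1,G2 elastin pre-stretches (circumferential, longitudinal), > 0.
#' @param Gh collagen deposition pre-stretch, > 0.
#' @param alpha fiber angle in radians from the axial (longitudinal) direction,
#'   in \eqn{[0, \pi/2]}.
#' @return A named numeric vector of class `"cmm_params"`.
#' @examples
#' cmm_params(0.02, 0.05, 0.03, 2, 1, 1.2, 1.2, 1.1, pi / 4)
#' @export
cmm_params <- function(c1, c2_1, c2_2, c3_1, c3_2, G1, G2, Gh, alpha) {
  p <- c(c1 = c1, c2_1 = c2_1, c2_2 = c2_2, c3_1 = c3_1, c3_2 = c3_2,
         G1 = G1, G2 = G2, Gh = Gh, alpha = alpha)
  if (any(!is.finite(p))) stop("CMM parameters must be finite")
  if (any(p[c("c1", "c2_1", "c2_2", "c3_1", "c3_2")] < 0))
    stop("stress-like parameters and exponents must be >= 0")
  if (any(p[c("G1", "G2", "Gh")] <= 0)) stop("pre-stretches must be > 0")
  if (alpha < 0 || alpha > pi / 2) stop("alpha must lie in [0, pi/2]")
  structure(p, class = "cmm_params")
}

#' @export
print.fung_params <- function(x, ...) {
  cat("<fung_params>\n"); print(unclass(x)); invisible(x)
}
#' @export
print.holzapfel_params <- function(x, ...) {
  cat(sprintf("<holzapfel_params> (gamma = %.1f deg)\n",
              x[["gamma"]] * 180 / pi))
  print(unclass(x)); invisible(x)
}
#' @export
print.cmm_params <- function(x, ...) {
  cat(sprintf("<cmm_params> (alpha = %.1f deg)\n", x[["alpha"]] * 180 / pi))
  print(unclass(x)); invisible(x)
}

# model registry -------------------------------------------------------------

model_names <- c("fung", "holzapfel", "cmm")

param_names <- function(model) {
  switch(match.arg(model, model_names),
         fung = c("c1", "b1", "b2", "b3", "b4", "b5", "b6"),
         holzapfel = c("c", "k1", "k2", "gamma"),
         cmm = c("c1", "c2_1", "c2_2", "c3_1", "c3_2", "G1", "G2", "Gh",
                 "alpha"))
}

# named vector -> classed params object (no validation; optimizer-internal)
as_params <- function(model, x) {
  model <- match.arg(model, model_names)
  x <- stats::setNames(as.numeric(x), param_names(model))
  structure(x, class = paste0(ifelse(model == "cmm", "cmm",
                                     ifelse(model == "fung", "fung",
                                            "holzapfel")), "_params"))
}

model_of <- function(params) {
  if (inherits(params, "fung_params")) return("fung")
  if (inherits(params, "holzapfel_params")) return("holzapfel")
  if (inherits(params, "cmm_params")) return("cmm")
  stop("unknown model parameter class: ", paste(class(params), collapse = "/"))
}

#' Default parameter bounds for fitting
#'
#' Box bounds used by [hyperfit()]: stress-like parameters in `[1e-6, 10]` MPa,
#' dimensionless exponents in `[1e-4, 50]` (Fung `b` coefficients in
#' `[0, 50]`), angles in `[0, pi/2]`, pre-stretches in `[0.8, 2]`. The ranges
#' comfortably cover the magnitudes reported for healthy porcine aorta
#' (e.g. `k2` medians around 3.3, `Gh` around 1.34).
#'
#' @param model `"fung"`, `"holzapfel"` or `"cmm"`.
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
default_bounds <- function(model) {
  model <- match.arg(model, model_names)
  nm <- param_names(model)
  switch(model,
    fung = list(lower = stats::setNames(c(1e-6, rep(0, 6)), nm),
                upper = stats::setNames(c(10, rep(50, 6)), nm)),
    holzapfel = list(lower = stats::setNames(c(1e-6, 1e-6, 1e-4, 0), nm),
                     upper = stats::setNames(c(10, 10, 50, pi / 2), nm)),
    cmm = list(lower = stats::setNames(c(rep(1e-6, 3), rep(1e-4, 2),
                                         rep(0.8, 3), 0), nm),
               upper = stats::setNames(c(rep(10, 3), rep(50, 2),
                                         rep(2, 3), pi / 2), nm)))
}
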