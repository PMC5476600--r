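# Named tissue models used throughout the package's validation study:
# generic layered skin/fat/muscle parameter sets.

#' Two-layer generic tissue model
#'
#' Upper layer (skin including subcutaneous fat, adjustable thickness):
#' `mu_a = 0.02 /mm`, `mu_s' = 2.0 /mm`; lower semi-infinite layer
#' (muscle): `mu_a = 0.03 /mm`, `mu_s' = 0.5 /mm`. Henyey-Greenstein
#' `g = 0.8`, `n = 1.4` in both layers, air above.
#'
#' @param l1_thickness upper-layer thickness \[mm\].
#' @param g anisotropy factor.
#' @return a `lux_medium`.
#' @export
model_skin_two_layer <- function(l1_thickness = 2, g = 0.8) {
  ph <- phase_hg(g)
  layered_medium(list(
    layer_optics(0.02, 2.0 / (1 - g), ph, 1.4, l1_thickness),
    layer_optics(0.03, 0.5 / (1 - g), ph, 1.4, Inf)),
    n_external_top = 1.0)
}

#' Three-layer generic tissue model (skin / subcutaneous fat / muscle)
#'
#' `mu_a = (0.02, 0.003, 0.02) /mm`, `mu_s' = (2.0, 1.0, 0.5) /mm`,
#' thicknesses 1 and 2 mm over a semi-infinite base; HG `g = 0.8`,
#' `n = 1.4`, air above.
#'
#' @param phases a single phase spec or list of three (per layer); numeric
#'   is interpreted as an HG anisotropy factor. The scattering coefficient
#'   is always derived from the fixed `mu_s'` values and the phase
#'   function's true first Legendre moment, so different phase functions
#'   share identical reduced scattering.
#' @param swap_scattering if `TRUE`, interchange `mu_s'` of the first and
#'   third layers (0.5 and 2.0), the regime where the top-layer transport
#'   length exceeds its thickness and diffusion theory collapses.
#' @return a `lux_medium`.
#' @export
model_skin_three_layer <- function(phases = 0.8, swap_scattering = FALSE) {
  if (inherits(phases, "lux_phase") || is.numeric(phases))
    phases <- list(phases, phases, phases)
  phases <- lapply(phases, function(p)
    if (is.numeric(p)) phase_hg(p) else p)
  musp <- c(2.0, 1.0, 0.5)
  if (swap_scattering) musp <- c(0.5, 1.0, 2.0)
  mua <- c(0.02, 0.003, 0.02)
  th <- c(1, 2, Inf)
  layered_medium(lapply(1:3, function(k) {
    g <- phase_g(phases[[k]])
    layer_optics(mua[k], musp[k] / (1 - g), phases[[k]], 1.4, th[k])
  }), n_external_top = 1.0)
}

#' Two-layer fluorescence model
#'
#' Excitation properties of [model_skin_two_layer()] (upper thickness 2 mm);
#' emission-wavelength absorption and scattering 20% below their excitation
#' counterparts; identical phase function and refractive index at both
#' wavelengths. Only the upper layer fluoresces (`quantum_yield = 1`).
#'
#' @param yields per-layer quantum yields.
#' @return a `lux_fluor_problem`.
#' @export
model_fluorescence_two_layer <- function(yields = c(1, 0)) {
  ph <- phase_hg(0.8)
  mk <- function(mu_a, mu_s, th) layer_optics(mu_a, mu_s, ph, 1.4, th)
  layers <- list(
    fluorescent_layer(mk(0.02, 10, 2),   mk(0.8 * 0.02, 0.8 * 10, 2),   yields[1]),
    fluorescent_layer(mk(0.03, 2.5, Inf), mk(0.8 * 0.03, 0.8 * 2.5, Inf), yields[2]))
  fluorescence_problem(layers, n_external_top = 1.0)
}

#' Default incident beam of the validation study
#'
#' Gaussian profile with 1/e^2 radius 0.5 mm, unit power, perpendicular
#' incidence.
#' @export
default_beam <- function() beam("gaussian", rho_w = 0.5)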