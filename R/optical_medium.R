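#' @useDynLib layerlux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx integrate spline splinefun optimize uniroot runif
#' @importFrom utils modifyList write.table
NULL

#' Physical constants and unit conventions
#'
#' All lengths are millimetres, all times picoseconds, package-wide.
#' The in-medium speed of light in layer k is `c_mm_ps / n_k`.
#'
#' @format `c_mm_ps` is the vacuum speed of light in mm/ps.
#' @export
c_mm_ps <- 0.299792458

#' Define the optical properties of one layer at one wavelength
#'
#' @param mu_a absorption coefficient \[1/mm\], >= 0.
#' @param mu_s scattering coefficient \[1/mm\], >= 0.
#' @param phase a phase-function specification from [phase_hg()],
#'   [phase_rmcc()], [phase_rayleigh()] or [phase_table()]. A bare number is
#'   interpreted as a Henyey-Greenstein anisotropy factor `g`.
#' @param n refractive index (> 0).
#' @param thickness layer thickness \[mm\] or `Inf` (allowed for the last
#'   layer of a medium only).
#' @return an object of class `lux_layer`.
#' @examples
#' layer_optics(mu_a = 0.02, mu_s = 10, phase = phase_hg(0.8), n = 1.4,
#'              thickness = 2)
#' @export
layer_optics <- function(mu_a, mu_s, phase, n = 1.4, thickness = Inf) {
  if (is.numeric(phase) && length(phase) == 1L) phase <- phase_hg(phase)
  stopifnot(inherits(phase, "lux_phase"))
  if (!is.numeric(mu_a) || length(mu_a) != 1L || is.na(mu_a) || mu_a < 0)
    stop("mu_a must be a single number >= 0")
  if (!is.numeric(mu_s) || length(mu_s) != 1L || is.na(mu_s) || mu_s < 0)
    stop("mu_s must be a single number >= 0")
  if (!is.numeric(n) || n <= 0) stop("refractive index must be > 0")
  if (!is.numeric(thickness) || thickness <= 0)
    stop("thickness must be > 0 (Inf allowed for the last layer)")
  structure(list(mu_a = mu_a, mu_s = mu_s, phase = phase, n = n,
                 thickness = thickness),
            class = "lux_layer")
}

#' Anisotropy factor of a layer
#' @param layer a `lux_layer`.
#' @return the first Legendre moment g of its phase function.
#' @export
layer_g <- function(layer) phase_g(layer$phase)

#' Reduced scattering coefficient mu_s' = mu_s (1 - g)
#' @param layer a `lux_layer`.
#' @export
layer_musp <- function(layer) layer$mu_s * (1 - layer_g(layer))

#' Total attenuation coefficient mu_t = mu_a + mu_s
#' @param layer a `lux_layer`.
#' @export
layer_mut <- function(layer) layer$mu_a + layer$mu_s

#' Pair excitation and emission optical properties for a fluorescent layer
#'
#' The geometry (thickness) and refractive index must agree between the two
#' wavelengths; the index is taken as wavelength independent.
#'
#' @param excitation,emission `lux_layer` objects for the two wavelengths.
#' @param quantum_yield probability in \[0, 1\] that an absorbed excitation
#'   photon is re-emitted as a fluorescence photon.
#' @return an object of class `lux_fluor_layer`.
#' @export
fluorescent_layer <- function(excitation, emission, quantum_yield = 0) {
  stopifnot(inherits(excitation, "lux_layer"), inherits(emission, "lux_layer"))
  if (!isTRUE(all.equal(excitation$thickness, emission$thickness)))
    stop("excitation and emission thicknesses must agree")
  if (!isTRUE(all.equal(excitation$n, emission$n)))
    stop("refractive index must be identical at both wavelengths")
  if (quantum_yield < 0 || quantum_yield > 1)
    stop("quantum_yield must lie in [0, 1]")
  structure(list(excitation = excitation, emission = emission,
                 quantum_yield = quantum_yield),
            class = "lux_fluor_layer")
}

#' Stack layers into a plane-parallel layered medium
#'
#' The first layer is illuminated at `z = 0`; `z` grows into the medium.
#' Only the last layer may be semi-infinite.
#'
#' @param layers list of `lux_layer` objects, top to bottom.
#' @param n_external_top refractive index of the non-scattering half-space
#'   above `z = 0` (air: 1.0).
#' @param n_external_bottom index below the last boundary; used only when the
#'   last layer has finite thickness.
#' @return an object of class `lux_medium` with element `interface_depths`,
#'   the cumulative boundary positions \[mm\].
#' @export
layered_medium <- function(layers, n_external_top = 1.0,
                           n_external_bottom = 1.0) {
  if (inherits(layers, "lux_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "lux_layer")))
  th <- vapply(layers, function(l) l$thickness, 0)
  k <- length(layers)
  if (k > 1L && any(!is.finite(th[-k])))
    stop("only the last layer may be semi-infinite")
  depths <- cumsum(th)
  m <- structure(list(layers = layers,
                      n_external_top = n_external_top,
                      n_external_bottom = n_external_bottom,
                      interface_depths = depths,
                      semi_infinite = !is.finite(th[k])),
                 class = "lux_medium")
  m
}

#' @export
print.lux_medium <- function(x, ...) {
  cat(sprintf("Layered medium: %d layer(s), n_ext = %.3g / %.3g\n",
              length(x$layers), x$n_external_top, x$n_external_bottom))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] mu_a=%.4g mu_s=%.4g g=%.4g n=%.3g L=%s mm\n",
                i, l$mu_a, l$mu_s, layer_g(l), l$n,
                if (is.finite(l$thickness)) format(l$thickness) else "Inf"))
  }
  invisible(x)
}

#' Axisymmetric incident beams of unit power
#'
#' @param profile `"gaussian"`, `"pencil"` or `"flat_disc"`.
#' @param rho_w 1/e^2 Gaussian beam radius \[mm\] (gaussian profile).
#' @param radius disc radius \[mm\] (flat_disc profile).
#' @return object of class `lux_beam`. The lateral profile S(rho) integrates
#'   to 1 over the plane; incidence is perpendicular (+z).
#' @details The Gaussian profile is
#'   \deqn{S(\rho) = \frac{2}{\pi \rho_w^2} e^{-2\rho^2/\rho_w^2}}
#'   with transverse-frequency spectrum \eqn{\tilde S(q) = e^{-q^2\rho_w^2/8}}.
#' @export
beam <- function(profile = c("gaussian", "pencil", "flat_disc"),
                 rho_w = 0.5, radius = 1) {
  profile <- match.arg(profile)
  if (profile == "gaussian" && rho_w <= 0) stop("rho_w must be > 0")
  if (profile == "flat_disc" && radius <= 0) stop("radius must be > 0")
  structure(list(profile = profile, rho_w = rho_w, radius = radius),
            class = "lux_beam")
}

#' Transverse-frequency spectrum of a beam
#' @param bm a `lux_beam`.
#' @param q spatial frequency \[1/mm\], vectorized.
#' @return \eqn{\tilde S(q)}, the 2-D Fourier transform of the lateral profile.
#' @export
beam_spectrum <- function(bm, q) {
  switch(bm$profile,
         gaussian = exp(-q^2 * bm$rho_w^2 / 8),
         pencil = rep(1, length(q)),
         flat_disc = ifelse(q == 0, 1, 2 * besselJ(q * bm$radius, 1) /
                              (q * bm$radius)))
}

#' Evaluate the lateral beam profile S(rho)
#' @param bm a `lux_beam`.
#' @param rho radius \[mm\], vectorized.
#' @export
beam_profile <- function(bm, rho) {
  switch(bm$profile,
         gaussian = 2 / (pi * bm$rho_w^2) * exp(-2 * rho^2 / bm$rho_w^2),
         pencil = ifelse(rho == 0, Inf, 0),
         flat_disc = ifelse(rho <= bm$radius, 1 / (pi * bm$radius^2), 0))
}

#' Unpolarized Fresnel reflection probability at an index step
#'
#' Arithmetic mean of the squared s- and p-polarized amplitude reflection
#' coefficients; returns exactly 1 under total internal reflection.
#'
#' @param n_from,n_to refractive indices on the incidence and transmission
#'   sides.
#' @param mu cosine of the polar angle of incidence, in (0, 1\]. Vectorized.
#' @return reflection probability in \[0, 1\].
#' @examples
#' fresnel_unpolarized_reflectance(1.4, 1.0, 1.0)  # normal incidence: 1/36
#' @export
fresnel_unpolarized_reflectance <- function(n_from, n_to, mu) {
  if (any(mu <= 0 | mu > 1)) stop("mu must lie in (0, 1]")
  if (n_from <= 0 || n_to <= 0) stop("indices must be > 0")
  arg <- 1 - (n_from / n_to)^2 * (1 - mu^2)
  r <- numeric(length(mu))
  tir <- arg < 0
  r[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    mt <- sqrt(arg[ok])           # transmitted cosine
    mi <- mu[ok]
    rs <- (n_from * mi - n_to * mt) / (n_from * mi + n_to * mt)
    rp <- (n_to * mi - n_from * mt) / (n_to * mi + n_from * mt)
    r[ok] <- 0.5 * (rs^2 + rp^2)
  }
  pmin(pmax(r, 0), 1)
}

#' Critical direction cosine for total internal reflection
#'
#' @inheritParams fresnel_unpolarized_reflectance
#' @return `sqrt(1 - (n_to/n_from)^2)` when `n_from > n_to`, else 0. Incident
#'   cosines below this value are totally reflected.
#' @export
critical_cosine <- function(n_from, n_to) {
  if (n_from <= n_to) return(0)
  sqrt(1 - (n_to / n_from)^2)
}

#' Snell-refracted polar direction cosine
#'
#' @inheritParams fresnel_unpolarized_reflectance
#' @return cosine of the refracted polar angle (azimuth is preserved).
#' @export
refracted_cosine <- function(n_from, n_to, mu) {
  arg <- 1 - (n_from / n_to)^2 * (1 - mu^2)
  if (any(arg < 0))
    stop("refracted_cosine called below the critical cosine")
  sqrt(arg)
}

#' Ballistic (unscattered) transmitted fraction down to depth z
#'
#' Beer-Lambert attenuation through every layer above `z` multiplied by the
#' normal-incidence Fresnel transmission of every interface crossed,
#' including the top surface.
#'
#' @param medium a `lux_medium`.
#' @param z depth \[mm\], vectorized, >= 0.
#' @param s optional Laplace variable \[1/ps\]; shifts every mu_a by s n/c.
#' @return transmitted fraction(s) of the incident collimated power.
#' @export
ballistic_attenuation <- function(medium, z, s = 0) {
  if (any(z < 0)) stop("z must be >= 0")
  bd <- c(0, medium$interface_depths)
  K <- length(medium$layers)
  out <- rep(1 + 0i, length(z))
  # top-surface Fresnel transmission
  out <- out * (1 - fresnel_unpolarized_reflectance(
    medium$n_external_top, medium$layers[[1]]$n, 1))
  for (k in seq_len(K)) {
    lay <- medium$layers[[k]]
    mut <- layer_mut(lay) + s * lay$n / c_mm_ps
    z0 <- bd[k]
    z1 <- if (k < K) bd[k + 1] else Inf
    path <- pmin(pmax(z - z0, 0), z1 - z0)
    out <- out * exp(-mut * path)
    if (k < K) {
      crossed <- z > z1
      tf <- 1 - fresnel_unpolarized_reflectance(lay$n,
                                                medium$layers[[k + 1]]$n, 1)
      out[crossed] <- out[crossed] * tf
    }
  }
  if (all(Im(out) == 0)) Re(out) else out
}

#' Validate a layered medium and warn about diffusion-hostile regimes
#'
#' Checks the structural invariants of a `lux_medium` and issues a warning
#' when a layer's transport length `1/(mu_a + mu_s')` exceeds its thickness,
#' the regime in which diffusion theory is known to fail badly.
#'
#' @param medium a `lux_medium`.
#' @return invisibly, a list of diagnostic messages (also warned about).
#' @export
validate_medium <- function(medium) {
  stopifnot(inherits(medium, "lux_medium"))
  errs <- character(0)
  K <- length(medium$layers)
  for (k in seq_len(K)) {
    l <- medium$layers[[k]]
    if (l$mu_a < 0) errs <- c(errs, sprintf("layer %d: mu_a < 0", k))
    if (l$mu_s < 0) errs <- c(errs, sprintf("layer %d: mu_s < 0", k))
    if (l$n <= 0) errs <- c(errs, sprintf("layer %d: n <= 0", k))
    if (l$thickness <= 0) errs <- c(errs, sprintf("layer %d: thickness <= 0", k))
    if (k < K && !is.finite(l$thickness))
      errs <- c(errs, sprintf("layer %d: only the last layer may be semi-infinite", k))
  }
  if (length(errs)) stop("invalid medium:\n  ", paste(errs, collapse = "\n  "))
  notes <- character(0)
  for (k in seq_len(K)) {
    l <- medium$layers[[k]]
    lt <- 1 / (l$mu_a + layer_musp(l))
    if (is.finite(l$thickness) && lt > l$thickness) {
      msg <- sprintf(
        "layer %d: transport length %.3g mm exceeds layer thickness %.3g mm; diffusion-theory results for this medium are unreliable",
        k, lt, l$thickness)
      notes <- c(notes, msg)
      warning(msg, call. = FALSE)
    }
  }
  invisible(list(ok = TRUE, notes = notes))
}

#' Shift a layer's absorption for the Laplace/time domain
#'
#' Implements the substitution `mu_a -> mu_a + s n / c` that carries a
#' steady-state frequency solution to the Laplace (or, for imaginary `s`,
#' temporal-frequency) domain. `s = 0` is the identity.
#'
#' @param layer a `lux_layer`.
#' @param s Laplace variable \[1/ps\], possibly complex.
#' @return the layer with shifted `mu_a` (complex when `s` is complex).
#' @export
time_domain_shift <- function(layer, s) {
  if (identical(s, 0) || identical(s, 0 + 0i)) return(layer)
  layer$mu_a <- layer$mu_a + s * layer$n / c_mm_ps
  layer
}
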