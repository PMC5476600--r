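# Analog Monte Carlo photon transport -- the package's validation oracle.

#' Monte Carlo run configuration
#'
#' @param n_photons number of launched photons.
#' @param seed RNG seed; together with the photon index it keys a
#'   counter-based substream per photon, so a run is exactly reproducible.
#' @param r_edges radial tally bin edges \[mm\].
#' @param t_edges time tally bin edges \[ps\] (time-resolved reflectance).
#' @param fl_z_edges,fl_r_edges optional depth/radius voxel edges for the
#'   track-length fluence estimator (disabled when `NULL`).
#' @param abs_z_edges optional depth histogram edges for absorption sites.
#' @param max_events guard on the number of transport events per photon;
#'   guard-terminated photons are counted and reported.
#' @return a `lux_mc_config` list.
#' @export
mc_config <- function(n_photons = 1e6, seed = 1,
                      r_edges = seq(0, 10, by = 0.5),
                      t_edges = numeric(0),
                      fl_z_edges = NULL, fl_r_edges = NULL,
                      abs_z_edges = NULL, max_events = 1e7) {
  stopifnot(n_photons >= 1, !is.unsorted(r_edges))
  if (length(t_edges) && is.unsorted(t_edges)) stop("t_edges must be ascending")
  structure(list(n_photons = n_photons, seed = seed, r_edges = r_edges,
                 t_edges = t_edges,
                 fl_z_edges = fl_z_edges %||% numeric(0),
                 fl_r_edges = fl_r_edges %||% numeric(0),
                 abs_z_edges = abs_z_edges %||% numeric(0),
                 max_events = max_events),
            class = "lux_mc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mc_layer_spec <- function(medium) {
  K <- length(medium$layers)
  z_top <- c(0, medium$interface_depths[-K])
  z_bot <- medium$interface_depths
  if (medium$semi_infinite) z_bot[K] <- 1e300
  ptype <- integer(K); pg <- numeric(K); palpha <- numeric(K)
  icdf <- vector("list", K)
  for (k in seq_len(K)) {
    ph <- medium$layers[[k]]$phase
    if (ph$family == "hg") { ptype[k] <- 0L; pg[k] <- ph$g }
    else if (ph$family == "rmcc") { ptype[k] <- 1L; pg[k] <- ph$g; palpha[k] <- ph$alpha }
    else { ptype[k] <- 2L; icdf[[k]] <- phase_icdf_table(ph) }
  }
  list(mu_a = vapply(medium$layers, function(l) l$mu_a, 0),
       mu_s = vapply(medium$layers, function(l) l$mu_s, 0),
       n = vapply(medium$layers, function(l) l$n, 0),
       z_top = z_top, z_bot = z_bot,
       ptype = ptype, pg = pg, palpha = palpha, icdf = icdf,
       n_ext_top = medium$n_external_top,
       n_ext_bot = medium$n_external_bottom,
       semi_inf = medium$semi_infinite)
}

mc_beam_code <- function(bm) {
  switch(bm$profile,
         gaussian = list(type = 0L, param = bm$rho_w),
         pencil = list(type = 1L, param = 0),
         flat_disc = list(type = 2L, param = bm$radius))
}

mc_postprocess <- function(raw, cfg, K, fluor = FALSE) {
  n <- cfg$n_photons
  re <- cfg$r_edges
  area <- pi * diff(re^2)
  res <- list(
    n_photons = n, seed = cfg$seed,
    counts = list(specular = raw$specular, reflected = raw$reflected,
                  transmitted = raw$transmitted, absorbed = raw$absorbed,
                  guard = raw$guard),
    specular_fraction = raw$specular / n,
    total_diffuse_reflectance = raw$reflected / n,
    total_transmittance = raw$transmitted / n,
    absorbed_fraction = raw$absorbed / n,
    r_edges = re, t_edges = cfg$t_edges)
  res$accounting_ok <- (raw$specular + raw$reflected + raw$transmitted +
                          sum(raw$absorbed) + raw$guard) == n
  res$Rr <- data.frame(
    r_lo = re[-length(re)], r_hi = re[-1],
    counts = raw$r_counts,
    estimate = raw$r_counts / (n * area),
    se = sqrt(raw$r_counts) / (n * area))
  if (length(cfg$t_edges) >= 2) {
    nt <- length(cfg$t_edges) - 1
    cnt <- matrix(raw$rt_counts, ncol = nt, byrow = TRUE)
    dt <- diff(cfg$t_edges)
    norm <- outer(n * area, dt)
    res$Rrt <- list(counts = cnt, estimate = cnt / norm,
                    se = sqrt(cnt) / norm)
  }
  res$Tr <- data.frame(r_lo = re[-length(re)], r_hi = re[-1],
                       counts = raw$trans_r_counts,
                       estimate = raw$trans_r_counts / (n * area),
                       se = sqrt(raw$trans_r_counts) / (n * area))
  if (length(cfg$fl_z_edges) >= 2 && length(cfg$fl_r_edges) >= 2) {
    nzv <- length(cfg$fl_z_edges) - 1; nrv <- length(cfg$fl_r_edges) - 1
    vol <- outer(diff(cfg$fl_z_edges), pi * diff(cfg$fl_r_edges^2))
    len <- matrix(raw$fluence_len, nzv, nrv, byrow = TRUE)
    res$fluence <- list(z_edges = cfg$fl_z_edges, r_edges = cfg$fl_r_edges,
                        estimate = len / (n * vol))
  }
  if (length(cfg$abs_z_edges) >= 2)
    res$abs_z <- data.frame(z_lo = cfg$abs_z_edges[-length(cfg$abs_z_edges)],
                            z_hi = cfg$abs_z_edges[-1],
                            counts = raw$abs_z_counts)
  if (fluor) {
    res$emission <- list(
      launched = raw$em_launched, reflected = raw$em_reflected,
      transmitted = raw$em_transmitted, absorbed = raw$em_absorbed,
      guard = raw$em_guard,
      Rr = data.frame(r_lo = re[-length(re)], r_hi = re[-1],
                      counts = raw$em_r_counts,
                      estimate = raw$em_r_counts / (n * area),
                      se = sqrt(raw$em_r_counts) / (n * area)))
    if (length(cfg$t_edges) >= 2) {
      nt <- length(cfg$t_edges) - 1
      cnt <- matrix(raw$em_rt_counts, ncol = nt, byrow = TRUE)
      norm <- outer(n * area, diff(cfg$t_edges))
      res$emission$Rrt <- list(counts = cnt, estimate = cnt / norm,
                               se = sqrt(cnt) / norm)
    }
    res$emission$accounting_ok <-
      (raw$em_reflected + raw$em_transmitted + sum(raw$em_absorbed) +
         raw$em_guard) == raw$em_launched
  }
  class(res) <- "lux_mc_result"
  res
}

#' @export
print.lux_mc_result <- function(x, ...) {
  cat(sprintf("Analog MC: %g photons (seed %g)\n", x$n_photons, x$seed))
  cat(sprintf("  specular %.5f | diffuse R %.5f | T %.5f | absorbed %.5f | guard %g\n",
              x$specular_fraction, x$total_diffuse_reflectance,
              x$total_transmittance, sum(x$absorbed_fraction),
              x$counts$guard))
  cat(sprintf("  exact accounting: %s\n", x$accounting_ok))
  invisible(x)
}

#' Run an analog Monte Carlo simulation of elastic light transport
#'
#' Unweighted photon-by-photon transport: exponential free paths, analog
#' absorption/scattering decisions, Fresnel reflection/refraction at every
#' index-mismatched boundary, escape tallies binned in exit radius and in
#' optical path time `sum n_k l_k / c`.
#'
#' @param medium a `lux_medium`.
#' @param bm a `lux_beam` (photons are launched from its lateral profile).
#' @param cfg a [mc_config()].
#' @return a `lux_mc_result`: bin estimates with standard errors,
#'   per-layer absorption, specular fraction, exact integer accounting.
#' @export
run_elastic <- function(medium, bm, cfg) {
  validate_medium_quiet(medium)
  b <- mc_beam_code(bm)
  raw <- .mc_run_cpp(mc_layer_spec(medium), NULL,
                     numeric(length(medium$layers)),
                     cfg$n_photons, cfg$seed, b$type, b$param,
                     cfg$r_edges, cfg$t_edges,
                     cfg$fl_z_edges, cfg$fl_r_edges, cfg$abs_z_edges,
                     cfg$max_events, c_mm_ps)
  mc_postprocess(raw, cfg, length(medium$layers))
}

validate_medium_quiet <- function(medium)
  suppressWarnings(validate_medium(medium))

#' Run a direct fluorescence Monte Carlo simulation
#'
#' Excitation photons are transported with the excitation-wavelength
#' properties; at every absorption event in a fluorescent layer an emission
#' photon is launched isotropically from the absorption site (with the
#' layer's quantum yield) and transported with the emission-wavelength
#' properties. No convolution or weighting is used.
#'
#' @param problem a [fluorescence_problem()].
#' @param bm a `lux_beam`.
#' @param cfg a [mc_config()].
#' @return a `lux_mc_result` with an `emission` component.
#' @export
run_fluorescence <- function(problem, bm, cfg) {
  b <- mc_beam_code(bm)
  raw <- .mc_run_cpp(mc_layer_spec(problem$medium_x),
                     mc_layer_spec(problem$medium_m),
                     problem$yields,
                     cfg$n_photons, cfg$seed, b$type, b$param,
                     cfg$r_edges, cfg$t_edges,
                     cfg$fl_z_edges, cfg$fl_r_edges, cfg$abs_z_edges,
                     cfg$max_events, c_mm_ps)
  mc_postprocess(raw, cfg, length(problem$medium_x$layers), fluor = TRUE)
}

#' Track-length fluence tally
#'
#' Convenience wrapper around [run_elastic()] with the fluence voxel grid
#' enabled; returns fluence per unit volume per incident photon.
#'
#' @inheritParams run_elastic
#' @param z_edges,r_edges voxel edges \[mm\].
#' @return the `lux_mc_result` with its `fluence` component filled.
#' @export
fluence_tally <- function(medium, bm, cfg, z_edges, r_edges) {
  cfg$fl_z_edges <- z_edges
  cfg$fl_r_edges <- r_edges
  run_elastic(medium, bm, cfg)
}

#' Average an analytic radial curve over Monte Carlo tally bins
#'
#' Evaluates `f(r)` on each annular bin with the area weight `2 pi r dr`,
#' so analytic curves and bin estimates are compared like for like.
#' @param f vectorized function of radius.
#' @param r_edges bin edges \[mm\].
#' @param n_sub sub-divisions per bin.
#' @export
bin_average_radial <- function(f, r_edges, n_sub = 8) {
  vapply(seq_len(length(r_edges) - 1), function(i) {
    g <- pracma::gaussLegendre(n_sub, r_edges[i], r_edges[i + 1])
    sum(g$w * g$x * f(g$x)) / sum(g$w * g$x)
  }, 0)
}
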