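# Coupled excitation/emission transport for fluorescent layered media.
#
# The excitation field is solved first; its depth-resolved fluence (a sum
# of exponentials per layer, including the unscattered beam) multiplied by
# the layer's quantum yield and excitation absorption coefficient forms the
# isotropic emission source, which drives a second transport solve at the
# emission wavelength. Re-absorption cascades (emission re-exciting
# fluorophores) are not modelled.

#' Define a coupled excitation/emission problem for a fluorescent medium
#'
#' @param layers list of [fluorescent_layer()] objects, top to bottom.
#' @param n_external_top,n_external_bottom external refractive indices.
#' @return a `lux_fluor_problem` with media `medium_x` (excitation),
#'   `medium_m` (emission) and per-layer quantum `yields`.
#' @export
fluorescence_problem <- function(layers, n_external_top = 1.0,
                                 n_external_bottom = 1.0) {
  stopifnot(all(vapply(layers, inherits, TRUE, "lux_fluor_layer")))
  mx <- layered_medium(lapply(layers, `[[`, "excitation"),
                       n_external_top, n_external_bottom)
  mm <- layered_medium(lapply(layers, `[[`, "emission"),
                       n_external_top, n_external_bottom)
  structure(list(medium_x = mx, medium_m = mm,
                 yields = vapply(layers, `[[`, 0, "quantum_yield")),
            class = "lux_fluor_problem")
}

#' Per-layer emission source amplitudes from an excitation solution
#'
#' Returns, for every layer, the exponential-in-depth components of the
#' isotropic emission source
#' \eqn{Q_m(q, z) = \Phi_e \mu_{ax} \tilde\Phi_x(q, z) / 4\pi}:
#' amplitudes `coef` (the 1/4pi is applied in the emission solve) and decay
#' constants `gamma`, both measured from the layer top.
#'
#' @param excitation a `lux_freq_solution` of the excitation medium.
#' @param problem a `lux_fluor_problem`.
#' @return list per layer of data frames with columns `coef`, `gamma`.
#' @export
emission_source_profile <- function(excitation, problem) {
  K <- length(problem$yields)
  L <- vapply(problem$medium_x$layers, function(l) l$thickness, 0)
  lapply(seq_len(K), function(k) {
    yl <- problem$yields[k]
    mu_ax <- problem$medium_x$layers[[k]]$mu_a
    if (yl == 0 || mu_ax == 0)
      return(data.frame(coef = complex(0), gamma = complex(0)))
    ft <- excitation$fluence_terms[[k]]
    Lk <- if (is.finite(L[k])) L[k] else 0
    coefs <- ft$top$coef
    gammas <- ft$top$gamma
    coefs_bot <- ft$top$coef * exp(-ft$top$gamma * Lk)
    if (length(ft$bottom$coef)) {
      # bottom-anchored terms c e^{-g (L - zeta)}: expressed from the top
      # as (c e^{-gL}) e^{+g zeta}, with the bottom value kept exactly to
      # avoid overflow of the re-anchoring factor
      coefs <- c(coefs, ft$bottom$coef * exp(-ft$bottom$gamma * Lk))
      coefs_bot <- c(coefs_bot, ft$bottom$coef)
      gammas <- c(gammas, -ft$bottom$gamma)
    }
    coefs <- c(coefs, ft$ballistic$coef)
    coefs_bot <- c(coefs_bot, ft$ballistic$coef * exp(-ft$ballistic$gamma * Lk))
    gammas <- c(gammas, ft$ballistic$gamma)
    keep <- pmax(abs(coefs), abs(coefs_bot)) > 0
    data.frame(coef = yl * mu_ax * coefs[keep],
               coef_bot = yl * mu_ax * coefs_bot[keep],
               gamma = gammas[keep])
  })
}

#' Solve the coupled fluorescence problem at one (q, s) point
#'
#' @param problem a [fluorescence_problem()].
#' @param bm a `lux_beam`.
#' @param config a [pn_config()].
#' @param q transverse spatial frequency \[1/mm\].
#' @param s Laplace variable \[1/ps\].
#' @param pre_x,pre_m optional precomputes for the two media (reused across
#'   sweeps).
#' @return a `lux_freq_solution` for the emission field (reflectance `R` is
#'   the escaping fluorescence amplitude).
#' @export
solve_fluorescence_frequency <- function(problem, bm, config, q, s = 0,
                                         pre_x = NULL, pre_m = NULL) {
  if (is.null(pre_x)) pre_x <- pn_precompute(problem$medium_x, config, s)
  if (is.null(pre_m)) pre_m <- pn_precompute(problem$medium_m, config, s)
  sol_x <- freq_solution_from(pre_x, pn_solve_q_fast(pre_x, q,
                                                     beam_spectrum(bm, q)))
  src <- emission_source_profile(sol_x, problem)
  parts_fn <- fluor_parts_fn(pre_m, src)
  sol <- pn_solve_q_fast(pre_m, q, beam_spectrum(bm, q), parts_fn = parts_fn)
  out <- freq_solution_from(pre_m, sol)
  out$excitation <- sol_x
  out
}

# particular-source builder for the emission solve: one isotropic
# lab-frame particular per excitation fluence exponential
fluor_parts_fn <- function(pre_m, src) {
  function(k, q) {
    e <- pre_m$eigs[[k]]
    terms <- src[[k]]
    n_t <- nrow(terms)
    mu_nodes <- pre_m$eval_sets[[k]]$mu
    if (n_t == 0) {
      # inert zero source term
      p0 <- pn_particular_lab(e, q, e$mut_eff, "isotropic")
      return(list(comp = 0i * pn_particular_components(p0, mu_nodes),
                  amp_top = as.complex(0), amp_bot = as.complex(0),
                  gamma = as.complex(e$mut_eff), w00 = 0i,
                  ballistic = list(coef = 0i, gamma = 0i)))
    }
    comps <- vector("list", n_t)
    w00 <- gam <- amp_t <- amp_b <- complex(n_t)
    for (t in seq_len(n_t)) {
      p <- pn_particular_lab(e, q, terms$gamma[t], "isotropic")
      comps[[t]] <- pn_particular_components(p, mu_nodes)
      w00[t] <- p$w00
      gam[t] <- p$gamma
      amp_t[t] <- terms$coef[t]
      amp_b[t] <- terms$coef_bot[t]
    }
    list(comp = array(unlist(comps),
                      dim = c(length(mu_nodes), pre_m$N + 1, n_t)),
         amp_top = as.complex(amp_t), amp_bot = as.complex(amp_b),
         gamma = as.complex(gam), w00 = w00,
         ballistic = list(coef = 0i, gamma = 0i))
  }
}

#' Steady-state spatially resolved fluorescence
#'
#' Hankel inversion of the emission reflectance amplitude at `s = 0`.
#'
#' @inheritParams solve_fluorescence_frequency
#' @param r_grid radii \[mm\].
#' @param pts Gauss-Legendre points per Hankel panel.
#' @return data frame (`lux_spatial_result`) with columns `r`, `R`.
#' @export
fluorescence_spatial_curve <- function(problem, bm, config, r_grid, pts = 6) {
  pre_x <- pn_precompute(problem$medium_x, config, 0)
  pre_m <- pn_precompute(problem$medium_m, config, 0)
  plan <- hankel_plan(max(r_grid), config$q_max %||% pn_qmax(bm), pts)
  Rq <- vapply(plan$q, function(q)
    Re(solve_fluorescence_frequency(problem, bm, config, q,
                                    pre_x = pre_x, pre_m = pre_m)$R), 0)
  base <- plan$w * plan$q * Rq
  R <- vapply(r_grid, function(r)
    sum(base * besselJ(plan$q * r, 0)) / (2 * pi), 0)
  out <- data.frame(r = r_grid, R = R)
  class(out) <- c("lux_spatial_result", "data.frame")
  attr(out, "N") <- config$N
  attr(out, "solver") <- "pn_fluorescence"
  out
}

#' Diffusion-backend fluorescence at one (q, s) point
#'
#' Same two-stage structure with the layered diffusion solver: the
#' excitation DE fluence drives per-layer exponential sources in the
#' emission DE. The emission field uses its own extrapolated boundary;
#' sources act only in the physical region.
#'
#' @inheritParams solve_fluorescence_frequency
#' @param opts convention options from [de_options()].
#' @return list with emission reflectance `R`.
#' @export
de_solve_fluorescence <- function(problem, bm, q, s = 0, opts = de_options()) {
  dx <- de_solve_frequency(problem$medium_x, bm, q, s, opts)
  mm <- problem$medium_m
  K <- length(mm$layers)
  semi <- mm$semi_infinite
  musp_m <- vapply(mm$layers, layer_musp, 0)
  mua_m <- vapply(mm$layers, function(l) l$mu_a, 0)
  D_m <- if (opts$D_mode == "musp") 1 / (3 * musp_m) else 1 / (3 * (mua_m + musp_m))
  alp_m <- sqrt((mua_m + s * vapply(mm$layers, function(l) l$n, 0) / c_mm_ps) /
                  D_m + q^2 + 0i)
  n_m <- vapply(mm$layers, function(l) l$n, 0)
  ebc <- opts$boundary == "ebc"

  sub <- list()
  if (ebc) {
    zb_m <- 2 * de_boundary_A(n_m[1], mm$n_external_top) * D_m[1]
    sub[[1]] <- list(L = zb_m, D = D_m[1], alpha = alp_m[1], n = n_m[1],
                     coef_top = complex(0), coef_bot = complex(0),
                     gamma = complex(0), jump = 0i)
  }
  for (k in seq_len(K)) for (tt in dx$terms[[k]]) {
    yl <- problem$yields[k]
    mu_ax <- problem$medium_x$layers[[k]]$mu_a
    # physical portion of this excitation sublayer
    off <- max(0, -tt$z_top)
    Lp <- (if (is.finite(tt$L)) tt$L else Inf) - off
    cf <- complex(0); cb <- complex(0); gm <- complex(0)
    if (yl > 0 && mu_ax > 0) {
      if (abs(tt$p) > 0) {
        cf <- c(cf, yl * mu_ax * tt$p * exp(-tt$alpha * off)); cb <- c(cb, 0i)
        gm <- c(gm, tt$alpha)
      }
      if (abs(tt$m) > 0) {
        cf <- c(cf, 0i); cb <- c(cb, yl * mu_ax * tt$m); gm <- c(gm, tt$alpha)
      }
    }
    sub[[length(sub) + 1]] <- list(L = Lp, D = D_m[k], alpha = alp_m[k],
                                   n = n_m[k], coef_top = cf, coef_bot = cb,
                                   gamma = gm, jump = 0i)
  }
  top <- if (ebc) list(type = "dirichlet")
         else list(type = "robin",
                   A = de_boundary_A(n_m[1], mm$n_external_top))
  bot <- if (semi) NULL
         else if (ebc) list(type = "dirichlet")
         else list(type = "robin",
                   A = de_boundary_A(n_m[K], mm$n_external_bottom))
  sol <- de_core_solve(sub, top, bot)
  jsurf <- if (ebc) 2L else 1L
  ph0 <- sol$phi(jsurf, 0); dph0 <- sol$dphi(jsurf, 0)
  Rq <- if (opts$R_mode == "flux") D_m[1] * dph0
  else {
    ec <- de_exit_coefs(n_m[1], mm$n_external_top)
    ec$C_phi / 4 * ph0 + ec$C_j / 2 * D_m[1] * dph0
  }
  list(q = q, s = s, R = Rq, excitation = dx)
}

#' Diffusion-backend spatially resolved fluorescence
#' @inheritParams fluorescence_spatial_curve
#' @export
de_fluorescence_spatial_curve <- function(problem, bm, r_grid,
                                          opts = de_options()) {
  Fq <- function(q) vapply(q, function(qq)
    Re(de_solve_fluorescence(problem, bm, qq, 0, opts)$R), 0)
  R <- inverse_hankel0(Fq, r_grid, q_max = de_qmax(problem$medium_x, bm))
  out <- data.frame(r = r_grid, R = as.numeric(R))
  class(out) <- c("lux_spatial_result", "data.frame")
  attr(out, "solver") <- "de_fluorescence"
  out
}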