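# Spatial- and time-domain reflectance curves: composition of the PN
# frequency solver with the inverse Hankel and Laplace transforms.

# reflectance-only sweep over q nodes, reusing a precompute
pn_sweep_R <- function(pre, bm, qs) {
  if (pre$config$backend == "cpp")
    return(vapply(qs, function(q)
      pn_solve_q_fast(pre, q, beam_spectrum(bm, q))$R, 0i))
  vapply(qs, function(q) {
    sol <- pn_solve_q(pre, q, beam_spectrum(bm, q))
    ev1 <- sol$evals[[1]]
    Fd <- flux_integrals(pre$surface, sol$cmp(1, "surf", +1, "dec"),
                         sol$cmp(1, "surf", -1, "dec"))
    Fp <- flux_integrals(pre$surface, sol$cmp(1, "surf", +1, "par"),
                         sol$cmp(1, "surf", -1, "par"))
    x1 <- sol$x[sol$offs[1] + seq_len(ev1$n_dec + ev1$n_gro)]
    Rq <- -(sum(x1[seq_len(ev1$n_dec)] * Fd) + sol$A[1] * sum(Fp))
    if (ev1$n_gro) {
      Fg <- flux_integrals(pre$surface, sol$cmp(1, "surf", +1, "gro"),
                           sol$cmp(1, "surf", -1, "gro"))
      zb <- exp(-sol$lams[[1]] * pre$L[1])
      Rq <- Rq - sum(x1[ev1$n_dec + seq_len(ev1$n_gro)] * zb * Fg)
    }
    Rq
  }, 0i)
}

pn_qmax <- function(bm) {
  if (bm$profile == "gaussian") sqrt(8 * log(1e12)) / bm$rho_w else 60
}

#' Steady-state spatially resolved reflectance (PN solver)
#'
#' Composes the PN frequency solution at `s = 0` with the order-zero
#' inverse Hankel transform: `R_s(r)` equals the steady-state limit of the
#' Laplace-domain solution.
#'
#' @inheritParams solve_frequency
#' @param r_grid radii \[mm\].
#' @param pts Gauss-Legendre points per Hankel panel.
#' @return data frame (`lux_spatial_result`) with columns `r`, `R`
#'   \[1/mm^2\]; metadata in attributes (`N`, `n_q`).
#' @export
steady_state_curve <- function(medium, bm, config, r_grid, pts = 6,
                               q_max = NULL) {
  pre <- pn_precompute(medium, config, 0)
  if (is.null(q_max)) q_max <- config$q_max %||% pn_qmax(bm)
  plan <- hankel_plan(max(r_grid), q_max, pts)
  Rq <- Re(pn_sweep_R(pre, bm, plan$q))
  base <- plan$w * plan$q * Rq
  R <- vapply(r_grid, function(r)
    sum(base * besselJ(plan$q * r, 0)) / (2 * pi), 0)
  out <- data.frame(r = r_grid, R = R)
  class(out) <- c("lux_spatial_result", "data.frame")
  attr(out, "N") <- config$N
  attr(out, "n_q") <- length(plan$q)
  attr(out, "solver") <- "pn"
  out
}

#' Time-resolved reflectance at fixed radii (PN solver)
#'
#' For every Laplace-contour node `s_j` the layered problem is solved over
#' the transverse-frequency grid and Hankel-inverted to `R(r, s_j)`; the
#' contour sum then yields `R_t(r, t)` for the whole time grid from one
#' node set per window. The default contour is the flattened
#' transport-safe one.
#'
#' @inheritParams steady_state_curve
#' @param r radius (scalar or vector) \[mm\].
#' @param t_grid times \[ps\], > 0.
#' @param type inversion scheme. `"auto"` (default) uses vertical
#'   Bromwich-Fourier windows for early times (`t < t_switch`), where the
#'   signal is broadband and the transport dispersion carries branch
#'   structure off the negative real axis, and the flattened `"two_part"`
#'   contour for later windows, whose leftward reach then stays inside the
#'   cut-free gap next to the imaginary axis.
#' @param M contour nodes per window (contour windows).
#' @param window_ratio maximal time dynamic range per window.
#' @param neg_tol fail if `R_t` undershoots below `-neg_tol * max(R_t)`
#'   (numerical-quality guard; negative values are reported, never clipped).
#' @param t_switch time \[ps\] separating vertical from contour windows in
#'   `"auto"` mode.
#' @param vert_cap maximal number of frequency nodes per vertical window.
#' @return data frame (`lux_time_result`) with columns `r`, `t`, `R`
#'   \[1/(mm^2 ps)\].
#' @export
time_resolved_curve <- function(medium, bm, config, r, t_grid,
                                type = c("auto", "two_part", "hyperbolic",
                                         "vertical"),
                                M = 64, window_ratio = 12, pts = 6,
                                neg_tol = 1e-4, t_switch = 1000,
                                vert_cap = 360) {
  type <- match.arg(type)
  o <- order(t_grid)
  ts <- t_grid[o]
  plan <- hankel_plan(max(r), config$q_max %||% pn_qmax(bm), pts)
  sweep_at <- function(s) {
    pre <- pn_precompute(medium, config, s)
    Rq <- pn_sweep_R(pre, bm, plan$q)
    base <- plan$w * plan$q * Rq
    vapply(r, function(rr)
      sum(base * besselJ(plan$q * rr, 0)) / (2 * pi), 0i)
  }
  out_t <- matrix(0, length(ts), length(r))
  i0 <- 1
  while (i0 <= length(ts)) {
    t1w <- ts[i0]
    lim <- t1w * window_ratio
    wtype <- type
    if (type == "auto")
      wtype <- if (t1w < t_switch) "vertical" else "two_part"
    if (type == "auto" && wtype == "vertical")
      lim <- min(lim, t_switch)       # windows never straddle the switch
    i1 <- max(which(ts <= lim))
    t2w <- ts[i1]
    idx <- i0:i1
    if (wtype == "vertical") {
      # Bromwich-Fourier window: the transport dispersion has branch
      # structure off the negative real axis, so early broadband windows
      # use a plain vertical line (analyticity guaranteed for Re s > 0)
      # with adaptive frequency truncation on the spectrum's own decay.
      Tper <- 1.6 * t2w
      # the shift must suppress aliasing even where the signal still rises
      # within the window (large radii), so it is chosen conservatively
      gam <- 13 / Tper
      dw <- 2 * pi / Tper
      Fs <- list()
      Fmax <- rep(0, length(r))     # per-radius spectral scale
      j <- 0
      repeat {
        j <- j + 1
        Fj <- sweep_at(gam + 1i * (j - 0.5) * dw)
        Fs[[j]] <- Fj
        Fmax <- pmax(Fmax, Mod(Fj))
        if (j >= 16 && j %% 8 == 0) {
          recent <- apply(matrix(vapply(Fs[(j - 7):j], Mod,
                                        numeric(length(r))),
                                 nrow = length(r)), 1, max)
          if (all(recent < 1e-6 * Fmax)) break
        }
        if (j >= vert_cap) break
      }
      Fmat <- do.call(rbind, Fs)
      wsj <- ((seq_len(j)) - 0.5) * dw
      # cosine-taper the last quarter of the band: suppresses truncation
      # ringing near the sharp ballistic onset
      tap <- rep(1, j)
      hi <- wsj > 0.75 * wsj[j]
      tap[hi] <- cos(pi / 2 * (wsj[hi] - 0.75 * wsj[j]) /
                       (0.25 * wsj[j]))^2
      for (ir in seq_along(r))
        out_t[idx, ir] <- vapply(ts[idx], function(t)
          exp(gam * t) / pi * dw *
            sum(tap * Re(Fmat[, ir] * exp(1i * wsj * t))), 0)
    } else {
      ct <- laplace_contour(t1w, t2w, M, wtype)
      Fr <- matrix(0i, length(ct$s), length(r))
      for (j in seq_along(ct$s)) Fr[j, ] <- sweep_at(ct$s[j])
      for (ir in seq_along(r))
        out_t[idx, ir] <- vapply(ts[idx], function(t)
          sum(Im(exp(ct$s * t) * Fr[, ir] * ct$w)), 0)
    }
    i0 <- i1 + 1
  }
  peak <- max(out_t)
  if (min(out_t) < -neg_tol * peak)
    stop(sprintf("time inversion undershoot %.3g of peak exceeds tolerance %.1g; refine the contour (M, window_ratio)",
                 -min(out_t) / peak, neg_tol))
  out <- data.frame(r = rep(r, each = length(ts)),
                    t = rep(t_grid[o], length(r)),
                    R = as.vector(out_t))
  out <- out[order(out$r, out$t), ]
  class(out) <- c("lux_time_result", "data.frame")
  attr(out, "N") <- config$N
  attr(out, "contour") <- type
  attr(out, "solver") <- "pn"
  out
}

#' Internal fluence depth profile at a transverse frequency
#'
#' Convenience evaluator of the depth-resolved fluence amplitude
#' `Phi(q, z)` of a frequency solution on a depth grid.
#'
#' @param sol a `lux_freq_solution` from [solve_frequency()].
#' @param z depths \[mm\].
#' @param include_ballistic include the unscattered beam contribution.
#' @export
fluence_profile <- function(sol, z, include_ballistic = TRUE) {
  v <- sol$fluence(z, include_ballistic)
  if (all(abs(Im(v)) <= 1e-9 * pmax(abs(v), 1e-300))) Re(v) else v
}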