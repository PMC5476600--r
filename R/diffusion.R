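# Layered diffusion-equation comparator, sharing the medium description and
# the transform stack with the PN transport solver.
#
# Per layer: D = 1/(3 (mu_a + mu_s')) (option: 1/(3 mu_s')), alpha^2 =
# (mu_a + s n/c)/D + q^2. The beam is an isotropic point source at depth
# z0 = 1/(mu_a + mu_s') in the top layer; the surface is handled by the
# extrapolated-boundary construction (fluence forced to zero at -z_b,
# z_b = 2 A D, with the Fresnel-derived coefficient A; option: Robin
# condition), and mismatched internal interfaces by n^2 fluence scaling
# with flux continuity. The DE sees the phase function only through mu_s'.

.lux_de_cache <- new.env(parent = emptyenv())

de_boundary_A <- function(n_in, n_out) {
  if (abs(n_in - n_out) < 1e-12) return(1)
  key <- sprintf("A_%.9g_%.9g", n_in, n_out)
  if (!is.null(.lux_de_cache[[key]])) return(.lux_de_cache[[key]])
  g <- pracma::gaussLegendre(256, 0, 1)
  R <- fresnel_unpolarized_reflectance(n_in, n_out, g$x)
  R_phi <- sum(g$w * 2 * g$x * R)
  R_j <- sum(g$w * 3 * g$x^2 * R)
  out <- (1 + R_j) / (1 - R_phi)
  .lux_de_cache[[key]] <- out
  out
}

#' Diffusion-solver conventions
#'
#' The defaults -- `D = 1/(3 (mu_a + mu_s'))`, extrapolated boundary, and
#' the Fresnel-weighted exit-radiance reflectance -- are the classic
#' index-mismatched diffusion conventions; they also reproduce the
#' characteristic crossover between layered DE and transport reflectance
#' at large source-detector separations.
#'
#' @param D_mode `"mut"` for `D = 1/(3 (mu_a + mu_s'))` or `"musp"` for
#'   `D = 1/(3 mu_s')`.
#' @param boundary `"ebc"` (extrapolated boundary: fluence vanishes at
#'   `-z_b = -2 A D`) or `"robin"` (partial-current condition).
#' @param R_mode `"radiance"` (hemispheric Fresnel-weighted exit radiance)
#'   or `"flux"` (net diffuse flux `D dPhi/dz`).
#' @return option list for the DE solvers.
#' @export
de_options <- function(D_mode = c("mut", "musp"),
                       boundary = c("ebc", "robin"),
                       R_mode = c("radiance", "flux")) {
  list(D_mode = match.arg(D_mode), boundary = match.arg(boundary),
       R_mode = match.arg(R_mode))
}

# hemispheric exit coefficients of the radiance-based reflectance
# R = C_phi/4 * Phi(0) + C_j/2 * D dPhi/dz(0), with C from the Fresnel
# transmission moments (Kienle-Patterson form)
de_exit_coefs <- function(n_in, n_out) {
  if (abs(n_in - n_out) < 1e-12) return(list(C_phi = 1, C_j = 1))
  key <- sprintf("C_%.9g_%.9g", n_in, n_out)
  if (!is.null(.lux_de_cache[[key]])) return(.lux_de_cache[[key]])
  g <- pracma::gaussLegendre(256, 0, 1)
  Tf <- 1 - fresnel_unpolarized_reflectance(n_in, n_out, g$x)
  out <- list(C_phi = sum(g$w * 2 * g$x * Tf), C_j = sum(g$w * 3 * g$x^2 * Tf))
  .lux_de_cache[[key]] <- out
  out
}

# ---------------------------------------------------------------------------
# generic layered two-point solver on a sublayer decomposition
#
# sub: list of sublayers, each with L (finite except possibly last), D,
#      alpha, n, and exponential sources (coef_top, coef_bot, gamma) plus
#      an optional flux jump `jump` at its bottom boundary.
# top: list(type = "dirichlet") or list(type = "robin", A = ...)
# bot: NULL (semi-infinite), or same as top.
# Returns coefficient accessor functions.
# ---------------------------------------------------------------------------
de_core_solve <- function(sub, top, bot) {
  ns <- length(sub)
  semi <- is.null(bot)
  colof <- c(0, cumsum(rep(2, ns)))
  nunk <- 2 * ns - as.integer(semi)
  M <- matrix(0i, nunk, nunk); rhs <- rep(0i, nunk)
  Ej <- vapply(sub, function(sb) exp(-sb$alpha * if (is.finite(sb$L)) sb$L else 0), 0i)
  cols <- function(j) (colof[j] + 1):(colof[j] + if (semi && j == ns) 1 else 2)
  hv <- function(j, bot_side) {
    if (semi && j == ns) c(1)
    else if (bot_side) c(Ej[j], 1) else c(1, Ej[j])
  }
  hd <- function(j, bot_side) {
    a <- sub[[j]]$alpha
    if (semi && j == ns) c(-a)
    else if (bot_side) c(-a * Ej[j], a) else c(-a, a * Ej[j])
  }
  part <- lapply(sub, function(sb) {
    if (!length(sb$gamma)) {
      list(v = function(b) 0i, d = function(b) 0i,
           at = function(zeta) 0i, dat = function(zeta) 0i)
    } else {
      den <- sb$D * (sb$gamma^2 - sb$alpha^2)
      den[abs(den) < 1e-12] <- 1e-12
      Ls <- if (is.finite(sb$L)) sb$L else 0
      eL <- exp(-sb$gamma * Ls)
      at <- function(zeta)
        sum(-(sb$coef_top * exp(-sb$gamma * zeta) +
                sb$coef_bot * exp(-sb$gamma * (Ls - zeta))) / den)
      dat <- function(zeta)
        sum(-(-sb$gamma * sb$coef_top * exp(-sb$gamma * zeta) +
                sb$gamma * sb$coef_bot * exp(-sb$gamma * (Ls - zeta))) / den)
      list(v = function(b) if (b) at(Ls) else at(0),
           d = function(b) if (b) dat(Ls) else dat(0),
           at = at, dat = dat)
    }
  })

  row <- 1
  if (top$type == "dirichlet") {
    M[row, cols(1)] <- hv(1, FALSE)
    rhs[row] <- -part[[1]]$v(FALSE)
  } else {
    M[row, cols(1)] <- hv(1, FALSE) - 2 * top$A * sub[[1]]$D * hd(1, FALSE)
    rhs[row] <- -(part[[1]]$v(FALSE) - 2 * top$A * sub[[1]]$D * part[[1]]$d(FALSE))
  }
  row <- row + 1
  if (ns > 1) for (j in seq_len(ns - 1)) {
    sc <- (sub[[j + 1]]$n / sub[[j]]$n)^2
    M[row, cols(j)] <- sc * hv(j, TRUE)
    M[row, cols(j + 1)] <- -hv(j + 1, FALSE)
    rhs[row] <- -sc * part[[j]]$v(TRUE) + part[[j + 1]]$v(FALSE)
    row <- row + 1
    M[row, cols(j)] <- -sub[[j]]$D * hd(j, TRUE)
    M[row, cols(j + 1)] <- sub[[j + 1]]$D * hd(j + 1, FALSE)
    rhs[row] <- sub[[j]]$D * part[[j]]$d(TRUE) -
      sub[[j + 1]]$D * part[[j + 1]]$d(FALSE) -
      (sub[[j]]$jump %||% 0i)
    row <- row + 1
  }
  if (!semi) {
    if (bot$type == "dirichlet") {
      M[row, cols(ns)] <- hv(ns, TRUE)
      rhs[row] <- -part[[ns]]$v(TRUE)
    } else {
      M[row, cols(ns)] <- hv(ns, TRUE) + 2 * bot$A * sub[[ns]]$D * hd(ns, TRUE)
      rhs[row] <- -(part[[ns]]$v(TRUE) + 2 * bot$A * sub[[ns]]$D * part[[ns]]$d(TRUE))
    }
  }
  x <- solve(M, rhs)
  list(
    phi = function(j, zeta) {
      cf <- x[cols(j)]
      a <- sub[[j]]$alpha
      v <- cf[1] * exp(-a * zeta) + part[[j]]$at(zeta)
      if (length(cf) > 1) v <- v + cf[2] * exp(-a * (sub[[j]]$L - zeta))
      v
    },
    dphi = function(j, zeta) {
      cf <- x[cols(j)]
      a <- sub[[j]]$alpha
      v <- -a * cf[1] * exp(-a * zeta) + part[[j]]$dat(zeta)
      if (length(cf) > 1) v <- v + a * cf[2] * exp(-a * (sub[[j]]$L - zeta))
      v
    },
    x = x, cols = cols)
}

#' Diffusion-equation solution at one (q, s) point for a layered medium
#'
#' @inheritParams solve_frequency
#' @param opts convention options from [de_options()].
#' @return a list with reflectance `R`, transmittance `Tt` (finite media),
#'   the source depth `z0`, a fluence evaluator `fluence(z)` (physical
#'   depths), and the per-sublayer exponential decomposition `terms` used
#'   by the fluorescence backend.
#' @export
de_solve_frequency <- function(medium, bm, q, s = 0, opts = de_options()) {
  K <- length(medium$layers)
  lay <- medium$layers
  musp <- vapply(lay, layer_musp, 0)
  if (any(musp <= 0)) stop("diffusion solver requires mu_s' > 0 in every layer")
  mua <- vapply(lay, function(l) l$mu_a, 0)
  D <- if (opts$D_mode == "musp") 1 / (3 * musp) else 1 / (3 * (mua + musp))
  mua_eff <- mua + s * vapply(lay, function(l) l$n, 0) / c_mm_ps
  alp <- sqrt(mua_eff / D + q^2 + 0i)
  n_of <- vapply(lay, function(l) l$n, 0)
  L <- vapply(lay, function(l) l$thickness, 0)
  semi <- medium$semi_infinite

  z0 <- 1 / (lay[[1]]$mu_a + musp[1])
  if (is.finite(L[1]) && z0 >= L[1]) {
    warning("DE source depth 1/(mu_a + mu_s') exceeds the top-layer thickness; clamped (diffusion theory is unreliable here)", call. = FALSE)
    z0 <- 0.99 * L[1]
  }
  P0 <- (1 - fresnel_unpolarized_reflectance(medium$n_external_top, n_of[1], 1)) *
    beam_spectrum(bm, q)

  ebc <- opts$boundary == "ebc"
  A_top <- de_boundary_A(n_of[1], medium$n_external_top)
  zb_top <- 2 * A_top * D[1]
  zb_bot <- 0
  if (!semi) {
    A_bot <- de_boundary_A(n_of[K], medium$n_external_bottom)
    zb_bot <- 2 * A_bot * D[K]
  }

  # sublayers (top to bottom); the first extends to the extrapolated
  # boundary when ebc; the split at z0 carries the source flux jump
  subL <- c((if (ebc) zb_top else 0) + z0, L[1] - z0, if (K > 1) L[-1])
  sub_of <- c(1, 1, if (K > 1) 2:K)
  if (!semi && ebc) subL[length(subL)] <- subL[length(subL)] + zb_bot
  sub <- lapply(seq_along(subL), function(j) {
    k <- sub_of[j]
    list(L = subL[j], D = D[k], alpha = alp[k], n = n_of[k],
         coef_top = complex(0), coef_bot = complex(0), gamma = complex(0),
         jump = if (j == 1) P0 else 0i)
  })
  top <- if (ebc) list(type = "dirichlet") else list(type = "robin", A = A_top)
  bot <- if (semi) NULL
         else if (ebc) list(type = "dirichlet") else list(type = "robin", A = A_bot)
  sol <- de_core_solve(sub, top, bot)

  off1 <- if (ebc) zb_top else 0           # surface position inside sublayer 1
  if (opts$R_mode == "flux") {
    Rq <- D[1] * sol$dphi(1, off1)
  } else {
    ec <- de_exit_coefs(n_of[1], medium$n_external_top)
    Rq <- ec$C_phi / 4 * sol$phi(1, off1) +
      ec$C_j / 2 * D[1] * sol$dphi(1, off1)
  }
  Tq <- NA_complex_
  if (!semi) {
    ns <- length(subL)
    zeta_b <- subL[ns] - (if (ebc) zb_bot else 0)
    if (opts$R_mode == "flux") {
      Tq <- -D[K] * sol$dphi(ns, zeta_b)
    } else {
      ecb <- de_exit_coefs(n_of[K], medium$n_external_bottom)
      Tq <- ecb$C_phi / 4 * sol$phi(ns, zeta_b) -
        ecb$C_j / 2 * D[K] * sol$dphi(ns, zeta_b)
    }
  }

  # physical-depth fluence evaluator and exponential decomposition
  sub_top_phys <- c(-off1, cumsum(subL) - off1)[seq_along(subL)]
  fluence <- function(z) {
    vapply(z, function(zz) {
      j <- min(max(findInterval(zz, c(sub_top_phys, Inf), rightmost.closed = FALSE), 1L),
               length(subL))
      sol$phi(j, zz - sub_top_phys[j])
    }, 0i)
  }
  terms <- lapply(seq_len(K), function(k) {
    js <- which(sub_of == k)
    lapply(js, function(j) {
      cf <- sol$x[sol$cols(j)]
      list(z_top = sub_top_phys[j], L = subL[j], alpha = alp[k],
           p = cf[1], m = if (length(cf) > 1) cf[2] else 0i)
    })
  })
  list(q = q, s = s, R = Rq, Tt = Tq, z0 = z0, fluence = fluence,
       terms = terms, D = D, alpha = alp, opts = opts,
       sub_of = sub_of)
}

#' Steady-state spatially resolved diffusion reflectance
#'
#' @inheritParams steady_state_curve
#' @param opts convention options from [de_options()].
#' @param plan optional [hankel_plan()].
#' @return data frame with columns `r` and `R` (class `lux_spatial_result`).
#' @export
de_spatial_curve <- function(medium, bm, r_grid, s = 0, plan = NULL,
                             opts = de_options()) {
  Fr <- function(q) vapply(q, function(qq)
    Re(de_solve_frequency(medium, bm, qq, s, opts)$R), 0)
  R <- inverse_hankel0(Fr, r_grid, q_max = de_qmax(medium, bm), plan = plan)
  out <- data.frame(r = r_grid, R = as.numeric(R))
  class(out) <- c("lux_spatial_result", "data.frame")
  attr(out, "solver") <- "de"
  out
}

de_qmax <- function(medium, bm) {
  if (bm$profile == "gaussian") sqrt(8 * log(1e12)) / bm$rho_w else 60
}

#' Time-resolved diffusion reflectance at one radius
#'
#' Uses the hyperbolic Laplace contour (the diffusion dispersion keeps its
#' singularities on the negative real axis).
#'
#' @inheritParams time_resolved_curve
#' @param opts convention options from [de_options()].
#' @return data frame with columns `t` and `R` (class `lux_time_result`).
#' @export
de_time_curve <- function(medium, bm, r, t_grid, M = 48, opts = de_options()) {
  Ft <- function(s_nodes) {
    vapply(s_nodes, function(s) {
      Fq <- function(q) vapply(q, function(qq)
        de_solve_frequency(medium, bm, qq, s, opts)$R, 0i)
      inverse_hankel0(Fq, r, q_max = de_qmax(medium, bm))[1]
    }, 0i)
  }
  R <- inverse_laplace(Ft, t_grid, type = "hyperbolic", M = M)
  out <- data.frame(t = t_grid, R = R)
  class(out) <- c("lux_time_result", "data.frame")
  attr(out, "solver") <- "de"
  attr(out, "r") <- r
  out
}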