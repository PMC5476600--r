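# Numerical inversion of the transform chain: order-zero inverse Hankel
# (spatial frequency -> radius) and inverse Laplace (s -> time) on complex
# contours with time-independent evaluation nodes.

#' Build a panel quadrature plan for the order-zero inverse Hankel transform
#'
#' Panels are sized to resolve both the Bessel oscillation at the largest
#' requested radius and the intrinsic transverse-frequency variation of
#' layered-media reflectance amplitudes; Gauss-Legendre nodes within panels.
#'
#' @param r_max largest radius to be synthesized \[mm\].
#' @param q_max truncation frequency \[1/mm\].
#' @param pts Gauss-Legendre points per panel.
#' @param caps step caps `c(width_small_q, width_mid_q, width_large_q)`
#'   applied on `q < 2`, `q < 8`, and beyond \[1/mm\].
#' @return list with nodes `q`, weights `w`, and metadata; reusable across
#'   solutions sharing the grids.
#' @export
hankel_plan <- function(r_max, q_max, pts = 8,
                        caps = c(0.25, 0.5, 1.0)) {
  osc <- pi / max(r_max, 1e-9)
  edges <- 0
  while (edges[length(edges)] < q_max) {
    q0 <- edges[length(edges)]
    cap <- if (q0 < 2) caps[1] else if (q0 < 8) caps[2] else caps[3]
    edges <- c(edges, min(q0 + min(osc, cap), q_max))
  }
  g <- lapply(seq_len(length(edges) - 1), function(i)
    pracma::gaussLegendre(pts, edges[i], edges[i + 1]))
  list(q = unlist(lapply(g, `[[`, "x")),
       w = unlist(lapply(g, `[[`, "w")),
       r_max = r_max, q_max = q_max, pts = pts, n_panels = length(edges) - 1)
}

#' Order-zero inverse Hankel transform
#'
#' Computes \eqn{f(r) = \frac{1}{2\pi}\int_0^\infty F(q) J_0(qr) q\,dq}
#' by panel Gauss-Legendre quadrature between Bessel oscillations, with
#' adaptive truncation where `|F(q)|` has decayed below `tol` relative to
#' `|F(0)|`.
#'
#' @param F vectorized function of `q`, decaying as `q -> Inf` (values may
#'   be complex).
#' @param r_grid radii \[mm\].
#' @param q_max optional truncation; found adaptively from `tol` if `NULL`.
#' @param tol relative truncation tolerance.
#' @param pts Gauss-Legendre points per panel.
#' @param plan optional precomputed [hankel_plan()] (overrides the rest).
#' @return values `f(r)`, real when `F` is real; attribute `"tail"` holds
#'   the estimated relative truncation remainder.
#' @export
inverse_hankel0 <- function(F, r_grid, q_max = NULL, tol = 1e-10, pts = 8,
                            plan = NULL) {
  slow_tail <- FALSE
  if (is.null(plan)) {
    if (is.null(q_max)) {
      F0 <- max(abs(F(0)), 1e-300)
      q_max <- 1
      while (q_max < 256 && max(abs(F(q_max))) > tol * F0) q_max <- q_max * 1.5
      if (max(abs(F(q_max))) > tol * F0) slow_tail <- TRUE
    }
    plan <- hankel_plan(max(r_grid), q_max, pts)
  }
  Fv <- F(plan$q)
  base <- plan$w * plan$q * Fv
  out <- vapply(r_grid, function(r)
    sum(base * besselJ(plan$q * r, 0)) / (2 * pi),
    if (is.complex(Fv)) 0i else 0)
  if (slow_tail) {
    # Longman's method: continue with half-period panels of J0(qr) and
    # accelerate the alternating panel series by iterated averaging
    out <- out + vapply(r_grid, function(r) {
      if (r <= 0) return(NA_real_)
      hankel_tail_accel(F, r, plan$q_max, tol)
    }, 0)
    if (anyNA(out))
      warning("inverse_hankel0: r = 0 requested for a slowly decaying spectrum; tail dropped")
  }
  tail_est <- max(abs(Fv[plan$q > 0.95 * plan$q_max])) /
    max(abs(Fv[1]), 1e-300)
  attr(out, "tail") <- if (slow_tail) tol else tail_est
  out
}

# accelerated oscillatory tail int_{q0}^inf F(q) J0(qr) q dq / (2 pi)
hankel_tail_accel <- function(F, r, q0, tol = 1e-12, max_panels = 400) {
  h <- pi / r
  terms <- numeric(0)
  S <- numeric(0)
  acc_prev <- 0
  for (k in seq_len(max_panels)) {
    g <- pracma::gaussLegendre(8, q0 + (k - 1) * h, q0 + k * h)
    terms[k] <- sum(g$w * g$x * F(g$x) * besselJ(g$x * r, 0))
    S[k] <- if (k == 1) terms[1] else S[k - 1] + terms[k]
    if (k >= 6) {
      a <- S
      while (length(a) > 1) a <- (a[-1] + a[-length(a)]) / 2
      if (abs(a - acc_prev) < tol * max(abs(a), 1)) return(a / (2 * pi))
      acc_prev <- a
    }
  }
  acc_prev / (2 * pi)
}

# ---------------------------------------------------------------------------
# Laplace inversion on hyperbola-family contours
#   s(u) = s0 + a (1 - cosh u) + i b sinh u ,  u_j = (j + 1/2) h , j >= 0,
# summed with trapezoid weights and conjugate symmetry:
#   f(t) = (h / pi) sum_j Im[ exp(s_j t) F(s_j) s'(u_j) ].
# "hyperbolic" uses the classic wide-opening parameters (suited to the
# diffusion equation, whose singularities hug the negative real axis);
# "two_part" uses a flattened bulge with near-vertical arms that stays close
# to the imaginary axis away from the origin, avoiding the off-axis
# branch structure of the transport dispersion curves.
# ---------------------------------------------------------------------------

#' Construct a Laplace-inversion contour for a time window
#'
#' The node set is time independent: one set of complex frequencies serves
#' every `t` in `[t_min, t_max]`.
#'
#' @param t_min,t_max time window \[ps\].
#' @param M number of nodes on the upper half contour.
#' @param type `"two_part"` (flattened, transport-safe) or `"hyperbolic"`.
#' @return a `lux_contour` with nodes `s` and quadrature factors.
#' @export
laplace_contour <- function(t_min, t_max, M = 64,
                            type = c("two_part", "hyperbolic")) {
  type <- match.arg(type)
  if (type == "hyperbolic") {
    # wide-opening hyperbola (Talbot-like); suited to functions whose
    # singularities hug the negative real axis (diffusion, elementary pairs)
    alpha <- 1.1721
    mu <- 1.4 * M / t_max
    a <- mu * sin(alpha); b <- mu * cos(alpha)
    s0 <- mu * (1 - sin(alpha))
    h <- 3.4 / M
  } else {
    # flattened contour: crossing just right of the origin, arms tilted
    # only 0.3 into the left half-plane so the off-axis branch structure
    # of the transport dispersion curves is never crossed
    b <- 1 / t_min
    a <- 0.3 * b
    s0 <- 1 / t_max
    h <- 4.75 / M
  }
  u <- (seq_len(M) - 0.5) * h
  s <- s0 + a * (1 - cosh(u)) + 1i * b * sinh(u)
  sp <- -a * sinh(u) + 1i * b * cosh(u)
  structure(list(s = s, w = h / pi * sp, u = u, type = type, M = M,
                 t_min = t_min, t_max = t_max),
            class = "lux_contour")
}

# evaluate the inversion sum given F values on the contour nodes
laplace_eval <- function(contour, Fv, t_grid) {
  vapply(t_grid, function(t)
    sum(Im(exp(contour$s * t) * Fv * contour$w)), 0)
}

#' Numerical inverse Laplace transform
#'
#' Inverts `F(s)` to the time domain on a (possibly windowed) flattened or
#' hyperbolic contour. The time grid is split into sub-windows of bounded
#' dynamic range; within a window a single node set serves every `t`.
#'
#' @param F vectorized function of complex `s` (analytic right of the
#'   contour).
#' @param t_grid times \[ps\], > 0.
#' @param type contour type, see [laplace_contour()].
#' @param M nodes per window (upper half).
#' @param window_ratio maximal `t_max/t_min` per window.
#' @param check if `TRUE`, re-evaluate with `M/2` nodes and attach the
#'   maximal discrepancy as attribute `"err"` (flagging accuracy loss).
#' @return values `f(t)`; attribute `"err"` when `check = TRUE`.
#' @export
inverse_laplace <- function(F, t_grid, type = c("two_part", "hyperbolic"),
                            M = NULL, window_ratio = NULL, check = FALSE) {
  type <- match.arg(type)
  if (is.null(M)) M <- if (type == "two_part") 64 else 48
  if (is.null(window_ratio))
    window_ratio <- if (type == "two_part") 12 else 30
  if (any(t_grid <= 0)) stop("t_grid must be positive")
  o <- order(t_grid)
  ts <- t_grid[o]
  out <- numeric(length(ts))
  err <- 0
  i0 <- 1
  while (i0 <= length(ts)) {
    t1 <- ts[i0]
    i1 <- max(which(ts <= t1 * window_ratio))
    idx <- i0:i1
    ct <- laplace_contour(ts[i0], ts[i1], M, type)
    Fv <- F(ct$s)
    out[idx] <- laplace_eval(ct, Fv, ts[idx])
    if (check) {
      ct2 <- laplace_contour(ts[i0], ts[i1], M %/% 2, type)
      v2 <- laplace_eval(ct2, F(ct2$s), ts[idx])
      err <- max(err, max(abs(v2 - out[idx])))
    }
    i0 <- i1 + 1
  }
  res <- numeric(length(ts)); res[o] <- out
  if (check) attr(res, "err") <- err
  res
}
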