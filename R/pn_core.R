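# PN spectral core: per-layer eigensystems and particular solutions.
#
# In the transverse-frequency domain the PN-truncated transport operator has
# plane-wave solutions V(s) exp(i q.rho + kappa_z z). Writing the complex
# wave vector kappa = (i q, 0, kappa_z) and nu^2 = kappa.kappa = kappa_z^2
# - q^2, the angular eigenproblem separates in the kappa-rotated frame into
# one symmetric tridiagonal pencil per azimuthal family m:
#
#   nu * (T^m u)_l + sigma_l u_l = 0,   sigma_l = mu_a + mu_s (1 - f_l),
#
# with off-diagonals a_{l,m} = sqrt((l^2-m^2)/((2l-1)(2l+1))), l = m..N.
# The eigenvalues nu_j are q-independent; the vertical decay constants
# follow analytically as lambda_j = sqrt(nu_j^2 + q^2).

a_lm <- function(l, m) sqrt((l^2 - m^2) / ((2 * l - 1) * (2 * l + 1)))

# per-degree attenuation sigma_l, l = 0..N (complex when s != 0)
pn_sigma <- function(layer, N, s = 0) {
  f <- legendre_moments(layer$phase, N)
  mu_a_eff <- layer$mu_a + s * layer$n / c_mm_ps
  mu_a_eff + layer$mu_s * (1 - f)
}

# normalized associated Legendre with (1-x^2)^(m/2) removed, l = m..N,
# at (possibly complex) arguments x; returns length(x) x (N-m+1) matrix
qtilde_eval <- function(x, N, m) {
  n <- length(x)
  out <- matrix(if (is.complex(x)) 0i else 0, n, N - m + 1)
  q0 <- sqrt((2 * m + 1) / (4 * pi) * prod((2 * seq_len(m) - 1) /
                                             (2 * seq_len(m))))
  out[, 1] <- q0
  if (N > m) {
    out[, 2] <- x * out[, 1] / a_lm(m + 1, m)
    if (N > m + 1) for (l in (m + 1):(N - 1))
      out[, l - m + 2] <- (x * out[, l - m + 1] -
                             a_lm(l, m) * out[, l - m]) / a_lm(l + 1, m)
  }
  out
}

#' q-independent spectral decomposition of a layer's PN operator
#'
#' Solves, for every azimuthal family, the symmetric tridiagonal eigenvalue
#' problem of the PN-truncated transport operator. The decomposition depends
#' on the optical properties and the Laplace variable `s` only (through the
#' absorption shift `mu_a + s n / c`), not on the transverse frequency, so
#' it is computed once per layer and reused across a whole frequency sweep.
#'
#' @param layer a `lux_layer`.
#' @param N odd approximation order.
#' @param s Laplace variable \[1/ps\] (complex allowed).
#' @return a list with the stacked mode data: `nu` (spectral eigenvalues,
#'   one per decaying/growing pair), `mfam` (azimuthal family of each mode),
#'   `U` ((N+1) x n_modes matrix of normalized spherical-harmonic
#'   coefficients), `n_modes`, `sigma`, `mut_eff`, and `moments`.
#' @export
layer_eigensystem <- function(layer, N, s = 0) {
  if (N %% 2 != 1) stop("PN order N must be odd")
  sigma <- pn_sigma(layer, N, s)
  if (any(abs(sigma) < 1e-14)) {
    # degenerate conservative case: nudge absorption to keep the
    # symmetrized pencil well defined
    sigma <- sigma + 1e-12 * max(abs(sigma), 1)
  }
  nu <- NULL; mfam <- NULL; Ucols <- list()
  for (m in 0:(N - 1)) {
    nb <- N + 1 - m
    ls <- m:N
    sig <- sigma[ls + 1]
    off <- vapply((m + 1):N, function(l) a_lm(l, m), 0)
    sq <- sqrt(sig + 0i)
    M <- matrix(0i, nb, nb)
    for (i in seq_len(nb - 1)) {
      val <- off[i] / (sq[i] * sq[i + 1])
      M[i, i + 1] <- val; M[i + 1, i] <- val
    }
    ev <- eigen(M, symmetric = !is.complex(sigma) || all(Im(sigma) == 0))
    e <- ev$values; W <- ev$vectors
    tol <- 1e-10 * max(abs(e))
    keep <- which(abs(e) > tol &
                    (Re(e) < -tol | (abs(Re(e)) <= tol & Im(e) > 0)))
    for (idx in keep) {
      cj <- -1 / e[idx]                  # nu with Re > 0 (or Im > 0)
      u <- W[, idx] / sq                 # back to normalized-SH coefficients
      u <- u / sqrt(sum(u * u))          # analytic normalization
      ucol <- rep(0i, N + 1)
      ucol[ls + 1] <- u
      nu <- c(nu, cj); mfam <- c(mfam, m); Ucols <- c(Ucols, list(ucol))
    }
  }
  U <- do.call(cbind, Ucols)
  list(nu = nu, mfam = as.integer(mfam), U = U, n_modes = length(nu),
       sigma = sigma, mut_eff = layer_mut(layer) + s * layer$n / c_mm_ps,
       mu_s = layer$mu_s, moments = legendre_moments(layer$phase, N),
       N = N, s = s)
}

# Particular PN solution for an exponential source term in one layer.
#
# source_type "beam": first-scatter source mu_s f(s.z) * exp(-gamma z)
#   driven by the attenuated collimated beam (gamma = mut_eff).
# source_type "isotropic": source amp/(4 pi) * exp(-gamma z) (fluorescence
#   re-emission; only the m = 0 family is excited).
#
# Returns pseudo-mode data usable by the same evaluation kernel:
# nu = c_p = sqrt(gamma^2 - q^2), kz = -gamma, one coefficient column per
# excited azimuthal family.
pn_particular <- function(eig, q, gamma, source_type = c("beam", "isotropic")) {
  source_type <- match.arg(source_type)
  N <- eig$N
  cp <- sqrt(gamma^2 - q^2 + 0i)
  if (abs(cp) < 1e-12) cp <- cp + 1e-9      # grazing degeneracy
  # resonance with a spectral eigenvalue: nudge (logged once per call site)
  dmin <- min(abs(cp - eig$nu), abs(cp + eig$nu))
  if (dmin < 1e-9 * abs(cp)) cp <- cp * (1 + 1e-7)
  m_max <- if (source_type == "isotropic" || q == 0) 0 else N
  muz <- -gamma / cp                        # z-hat polar cosine, rotated frame
  wz <- -1i * q / cp                        # z-hat w_+ = w_- value
  nu_out <- NULL; mfam_out <- NULL; cols <- list()
  for (m in 0:m_max) {
    ls <- m:N
    if (source_type == "isotropic") {
      r <- rep(0i, length(ls))
      r[1] <- 1 / (4 * pi) / sqrt(1 / (4 * pi))   # 1/(4pi) = r * qtilde_00
    } else {
      qt <- qtilde_eval(muz, N, m)[1, ]
      eps_m <- if (m == 0) 1 else 2
      r <- eig$mu_s * eig$moments[ls + 1] * eps_m * qt * wz^m
    }
    nb <- length(ls)
    A <- matrix(0i, nb, nb)
    diag(A) <- eig$sigma[ls + 1]
    if (nb > 1) for (i in seq_len(nb - 1)) {
      val <- cp * a_lm(ls[i] + 1, m)
      A[i, i + 1] <- A[i, i + 1] + val
      A[i + 1, i] <- A[i + 1, i] + val
    }
    w <- solve(A, r)
    col <- rep(0i, N + 1); col[ls + 1] <- w
    nu_out <- c(nu_out, cp); mfam_out <- c(mfam_out, m)
    cols <- c(cols, list(col))
  }
  list(nu = nu_out, mfam = as.integer(mfam_out),
       U = do.call(cbind, cols), n_modes = length(nu_out), gamma = gamma)
}

# Evaluate the lab-frame azimuthal components of a set of modes at signed
# direction cosines mu. Returns array [n_mu, N+1, n_modes].
pn_eval_modes <- function(q, N, mu, nu, kz, mfam, U, n_phi = 2 * (N + 1)) {
  stopifnot(length(nu) == length(kz), length(nu) == length(mfam))
  arr <- .pn_eval_modes_cpp(q, as.integer(N), as.integer(n_phi),
                            as.numeric(mu), as.complex(nu), as.complex(kz),
                            as.integer(mfam), as.matrix(U) + 0i)
  array(arr, dim = c(length(mu), N + 1, length(nu)))
}

# real normalized associated Legendre (with the sin^m factor) at real mu:
# test-function matrix for the Marshak projections, columns indexed by the
# test set
marshak_test_set <- function(N) {
  out <- do.call(rbind, lapply(1:N, function(l) {
    m <- seq(l %% 2 == 0, l, by = 2)  # l - m odd
    m <- m[(l - m) %% 2 == 1]
    if (length(m)) data.frame(l = l, m = m) else NULL
  }))
  out[order(out$m, out$l), , drop = FALSE]
}

assoc_legendre_real <- function(mu, l, m) {
  qt <- qtilde_eval(mu, l, m)
  qt[, l - m + 1] * (1 - mu^2)^(m / 2)
}

# ---------------------------------------------------------------------------
# Lab-frame particular solutions.
#
# The rotated-frame particular construction degenerates when the source
# exponent gamma approaches sqrt(q^2) (c_p = sqrt(gamma^2 - q^2) -> 0, a
# removable parameterization singularity near q = mu_t). The particular
# problem is therefore solved in the lab-frame cos-parity real-harmonic
# basis, where the operator  i q B_x - gamma A_z + diag(sigma_l)  stays
# bounded for every (q, gamma).
# ---------------------------------------------------------------------------

.lux_lab_cache <- new.env(parent = emptyenv())

# cos-parity lab basis tables for order N: index set, mu- and x-coupling
# matrices (built by exact quadrature), and evaluation helpers
lab_basis <- function(N) {
  key <- as.character(N)
  if (!is.null(.lux_lab_cache[[key]])) return(.lux_lab_cache[[key]])
  idx <- do.call(rbind, lapply(0:N, function(l)
    data.frame(l = l, m = 0:l)))
  nb <- nrow(idx)
  gl <- pracma::gaussLegendre(2 * N + 6, -1, 1)
  nphi <- 4 * N + 8
  phis <- 2 * pi * (seq_len(nphi) - 1) / nphi
  MU <- rep(gl$x, nphi); PH <- rep(phis, each = length(gl$x))
  WT <- rep(gl$w, nphi) * (2 * pi / nphi)
  Bv <- matrix(0, length(MU), nb)
  for (i in seq_len(nb))
    Bv[, i] <- assoc_legendre_real(MU, idx$l[i], idx$m[i]) * cos(idx$m[i] * PH)
  nrm <- colSums(WT * Bv^2)
  SX <- sqrt(pmax(0, 1 - MU^2)) * cos(PH)
  AZ <- crossprod(Bv, (WT * MU) * Bv) / nrm   # note: row scaling below
  BX <- crossprod(Bv, (WT * SX) * Bv) / nrm
  # crossprod gives <b_i, mu b_j> in column j, row i; divide rows by <b_i,b_i>
  AZ <- sweep(crossprod(Bv * WT, MU * Bv), 1, nrm, "/")
  BX <- sweep(crossprod(Bv * WT, SX * Bv), 1, nrm, "/")
  AZ[abs(AZ) < 1e-12] <- 0
  BX[abs(BX) < 1e-12] <- 0
  out <- list(idx = idx, nb = nb, AZ = AZ, BX = BX)
  .lux_lab_cache[[key]] <- out
  out
}

# Particular PN solution for an exponential source exp(-gamma z), solved in
# the lab basis. source_type "beam": first-scatter source of the collimated
# beam; "isotropic": unit-amplitude isotropic source 1/(4 pi).
# Returns lab coefficients w (vector over basis), the fluence coefficient
# (int W dS), and an evaluator of azimuthal components at signed cosines.
pn_particular_lab <- function(eig, q, gamma, source_type = c("beam", "isotropic"),
                              res_tol = 1e-5) {
  source_type <- match.arg(source_type)
  N <- eig$N
  lb <- lab_basis(N)
  sig <- eig$sigma[lb$idx$l + 1]
  # resonance guard: the operator is singular when c = sqrt(gamma^2 - q^2)
  # equals a spectral eigenvalue nu_j of this layer; detune gamma so the
  # limiting solution is evaluated at a controlled offset
  ce <- sqrt(gamma^2 - q^2 + 0i)
  scl <- max(abs(eig$nu), abs(ce))
  dmin <- min(abs(ce - eig$nu), abs(ce + eig$nu))
  gamma_use <- gamma
  if (dmin < res_tol * scl) {
    ce2 <- ce + 2 * res_tol * scl * (if (Re(ce) >= 0) 1 else -1)
    gamma_use <- sqrt(ce2^2 + q^2 + 0i)
    if (abs(Im(gamma)) == 0 && abs(Im(gamma_use)) < 1e-12)
      gamma_use <- Re(gamma_use)
    if (Re(gamma) < 0) gamma_use <- -gamma_use
  }
  M <- 1i * q * lb$BX - gamma_use * lb$AZ + diag(sig)
  rhs <- rep(0i, lb$nb)
  i0 <- which(lb$idx$m == 0)
  if (source_type == "beam") {
    rhs[i0] <- eig$mu_s * eig$moments[lb$idx$l[i0] + 1] *
      sqrt((2 * lb$idx$l[i0] + 1) / (4 * pi))
  } else {
    rhs[i0[1]] <- 1 / (4 * pi) / sqrt(1 / (4 * pi))
  }
  w <- tryCatch(solve(M, rhs), error = function(e) {
    # large-q degeneracy: the streaming part dwarfs the spectral gaps and
    # the system loses rank in double precision. The affected source terms
    # are exponentially damped there, so the minimal-norm solution is used.
    sv <- La.svd(M)
    keep <- sv$d > 1e-12 * sv$d[1]
    di <- ifelse(keep, 1 / sv$d, 0)
    as.vector(Conj(t(sv$vt)) %*% (di * (Conj(t(sv$u)) %*% rhs)))
  })
  w00 <- w[i0[1]] * sqrt(4 * pi)      # int W dS
  list(w = w, w00 = w00, gamma = gamma_use, N = N)
}

# azimuthal cosine components of a lab particular solution at signed
# cosines mu: matrix [length(mu), N+1]
pn_particular_components <- function(part, mu) {
  N <- part$N
  lb <- lab_basis(N)
  out <- matrix(0i, length(mu), N + 1)
  s2 <- 1 - mu^2
  for (m in 0:N) {
    w_m <- part$w[lb$idx$m == m]
    qt <- qtilde_eval(mu, N, m) * s2^(m / 2)
    out[, m + 1] <- qt %*% w_m
  }
  out
}
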