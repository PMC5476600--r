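# Scattering phase functions as Legendre-moment vectors (for the PN solver)
# and samplable angular distributions (for the Monte Carlo).
#
# Convention: f(s.s') = sum_l (2l+1)/(4pi) f_l P_l(cos theta), i.e.
# f_l = 2*pi * int_{-1}^{1} f(mu) P_l(mu) dmu, so f_0 = 1 and f_1 = g.

#' Henyey-Greenstein phase function
#' @param g anisotropy factor, |g| < 1.
#' @return a `lux_phase` specification.
#' @export
phase_hg <- function(g) {
  if (!is.numeric(g) || length(g) != 1L || abs(g) >= 1)
    stop("HG anisotropy must satisfy |g| < 1")
  structure(list(family = "hg", g = g), class = "lux_phase")
}

#' Reynolds-McCormick (Gegenbauer-kernel) phase function
#' @param g shape parameter, |g| < 1.
#' @param alpha shape exponent, > -1/2 and != 0.
#' @return a `lux_phase` specification.
#' @details Kernel `f(mu) = K (1 + g^2 - 2 g mu)^-(alpha+1)` normalized to
#'   integrate to one over the sphere. `alpha = 1/2` recovers
#'   Henyey-Greenstein. Note `g` here is the kernel parameter; the mean
#'   cosine (first Legendre moment) differs from `g` unless `alpha = 1/2`.
#' @export
phase_rmcc <- function(g, alpha) {
  if (abs(g) >= 1) stop("RMcC g must satisfy |g| < 1")
  if (alpha <= -0.5) stop("RMcC alpha must be > -1/2")
  if (alpha == 0) stop("RMcC alpha = 0 is degenerate; use a nearby value")
  structure(list(family = "rmcc", g = g, alpha = alpha), class = "lux_phase")
}

#' Rayleigh (molecular) phase function, f(mu) = 3/(16 pi) (1 + mu^2)
#' @return a `lux_phase` specification.
#' @export
phase_rayleigh <- function() {
  structure(list(family = "rayleigh"), class = "lux_phase")
}

#' Tabulated phase function
#'
#' @param mu_grid ascending grid of scattering-angle cosines covering
#'   \[-1, 1\].
#' @param values non-negative kernel values on `mu_grid` (per steradian).
#'   Renormalized so that the full-sphere integral is 1; an error is raised
#'   if the supplied table deviates from unit normalization by more than 5%.
#' @return a `lux_phase` specification.
#' @export
phase_table <- function(mu_grid, values) {
  if (any(diff(mu_grid) <= 0)) stop("mu_grid must be strictly increasing")
  if (abs(mu_grid[1] + 1) > 1e-9 || abs(mu_grid[length(mu_grid)] - 1) > 1e-9)
    stop("mu_grid must cover [-1, 1]")
  if (any(values < 0)) stop("phase-function values must be >= 0")
  norm <- 2 * pi * table_quad(mu_grid, values)
  if (abs(norm - 1) > 0.05)
    stop(sprintf("table normalization %.4g deviates from 1 by more than 5%%; supply values per steradian", norm))
  if (abs(norm - 1) > 1e-12)
    message(sprintf("phase table renormalized by factor %.8g", 1 / norm))
  structure(list(family = "table", mu_grid = mu_grid,
                 values = values / norm), class = "lux_phase")
}

#' Read a tabulated phase function from a two-column text file
#'
#' Whitespace- or comma-separated columns (cos theta, unnormalized value);
#' lines starting with `#` are comments.
#' @param path file path.
#' @return a `lux_phase` specification (renormalized, see [phase_table()]).
#' @export
read_phase_table <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  txt <- gsub(",", " ", txt)
  parts <- do.call(rbind, lapply(strsplit(trimws(txt), "\\s+"),
                                 function(x) as.numeric(x[1:2])))
  o <- order(parts[, 1])
  phase_table(parts[o, 1], parts[o, 2])
}

trapz_grid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# composite Simpson on uniform odd-length grids, trapezoid otherwise
table_quad <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  if (n >= 3 && n %% 2 == 1 && diff(range(h)) < 1e-9 * mean(h)) {
    w <- rep(c(2, 4), length.out = n)
    w[1] <- w[n] <- 1
    sum(w * y) * mean(h) / 3
  } else trapz_grid(x, y)
}

#' Evaluate a phase function kernel f(mu) per steradian
#' @param spec a `lux_phase`.
#' @param mu cosine(s) of the scattering angle.
#' @export
phase_eval <- function(spec, mu) {
  switch(spec$family,
    hg = {
      g <- spec$g
      (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * mu)^1.5)
    },
    rmcc = {
      g <- spec$g; a <- spec$alpha
      K <- a * g / (pi * ((1 + g)^(2 * a) - (1 - g)^(2 * a))) *
        (1 - g^2)^(2 * a)
      K * (1 + g^2 - 2 * g * mu)^(-(a + 1))
    },
    rayleigh = 3 / (16 * pi) * (1 + mu^2),
    table = approx(spec$mu_grid, spec$values, xout = mu, rule = 2)$y
  )
}

#' Legendre polynomial values P_0..P_N at given abscissae
#' @param x abscissae in \[-1, 1\] (complex values allowed).
#' @param N maximum degree.
#' @return matrix `length(x) x (N+1)`; column `l+1` holds `P_l(x)`.
#' @export
legendre_p_matrix <- function(x, N) {
  P <- matrix(if (is.complex(x)) 0i else 0, length(x), N + 1)
  P[, 1] <- 1
  if (N >= 1) P[, 2] <- x
  if (N >= 2) for (l in 1:(N - 1))
    P[, l + 2] <- ((2 * l + 1) * x * P[, l + 1] - l * P[, l]) / (l + 1)
  P
}

#' Legendre moments f_0..f_N of a phase function
#'
#' @param spec a `lux_phase`.
#' @param N maximum order.
#' @return numeric vector `c(f_0, ..., f_N)` in the convention
#'   `f_l = 2 pi int f(mu) P_l(mu) dmu` (so `f_0 = 1`, `f_1 = g`).
#' @examples
#' legendre_moments(phase_hg(0.8), 4)  # g^l
#' @export
legendre_moments <- function(spec, N) {
  stopifnot(N >= 0)
  switch(spec$family,
    hg = spec$g^(0:N),
    rayleigh = { f <- numeric(N + 1); f[1] <- 1; if (N >= 2) f[3] <- 0.1; f },
    rmcc = moments_by_quadrature(spec, N),
    table = {
      P <- legendre_p_matrix(spec$mu_grid, N)
      vapply(0:N, function(l)
        2 * pi * table_quad(spec$mu_grid, spec$values * P[, l + 1]), 0)
    })
}

moments_by_quadrature <- function(spec, N, n_nodes = max(4 * N + 64, 256)) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  fv <- phase_eval(spec, gl$x)
  P <- legendre_p_matrix(gl$x, N)
  f <- as.numeric(2 * pi * crossprod(P, gl$w * fv))
  # convergence check against a finer rule
  gl2 <- pracma::gaussLegendre(2 * n_nodes, -1, 1)
  f2 <- as.numeric(2 * pi * crossprod(legendre_p_matrix(gl2$x, N),
                                      gl2$w * phase_eval(spec, gl2$x)))
  if (max(abs(f - f2)) > 1e-9)
    warning(sprintf("phase-function quadrature converged only to %.3g",
                    max(abs(f - f2))))
  f2
}

#' First Legendre moment (anisotropy factor) of a phase function
#' @param spec a `lux_phase`.
#' @export
phase_g <- function(spec) {
  switch(spec$family,
         hg = spec$g,
         rayleigh = 0,
         legendre_moments(spec, 1)[2])
}

#' Sample scattering deflection cosines from a phase function
#'
#' Henyey-Greenstein and Reynolds-McCormick use their closed-form inverse
#' CDFs; Rayleigh and tabulated kernels use inverse-CDF interpolation on a
#' precomputed monotone-cubic cumulative table (2^14 points).
#'
#' @param spec a `lux_phase`.
#' @param n number of draws.
#' @param u optional uniforms in (0,1) (for reproducibility); defaults to
#'   `runif(n)`.
#' @return `n` deflection cosines distributed with density `2 pi f(mu)`.
#' @export
sample_deflection <- function(spec, n, u = NULL) {
  if (is.null(u)) u <- runif(n)
  switch(spec$family,
    hg = {
      g <- spec$g
      if (abs(g) < 1e-12) 2 * u - 1
      else {
        t <- (1 - g^2) / (1 - g + 2 * g * u)
        (1 + g^2 - t^2) / (2 * g)
      }
    },
    rmcc = {
      g <- spec$g; a <- spec$alpha
      lo <- (1 + g)^(-2 * a); hi <- (1 - g)^(-2 * a)
      x <- lo + u * (hi - lo)
      (1 + g^2 - x^(-1 / a)) / (2 * g)
    },
    {
      icdf <- phase_inverse_cdf(spec)
      icdf(u)
    })
}

# Monotone-cubic inverse CDF, cached on the spec's environment-free list via
# a closure. Resolution 2^14 keeps interpolation bias below MC noise.
phase_inverse_cdf <- function(spec, n_pts = 2^14) {
  mu <- seq(-1, 1, length.out = n_pts)
  f <- phase_eval(spec, mu)
  cdf <- c(0, cumsum(diff(mu) * (f[-1] + f[-n_pts]) / 2)) * 2 * pi
  cdf <- cdf / cdf[n_pts]
  keep <- c(TRUE, diff(cdf) > 0)
  sf <- splinefun(cdf[keep], mu[keep], method = "hyman")
  function(u) pmin(1, pmax(-1, sf(u)))
}

#' Inverse-CDF lookup table for the compiled Monte Carlo kernel
#' @param spec a `lux_phase`.
#' @param n_pts table size.
#' @return numeric vector `mu(u)` on a uniform `u` grid of length `n_pts`.
#' @keywords internal
phase_icdf_table <- function(spec, n_pts = 2^14) {
  icdf <- phase_inverse_cdf(spec)
  icdf(seq(0, 1, length.out = n_pts))
}
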