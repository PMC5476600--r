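test_that("Legendre moments match closed forms for HG and Rayleigh", {
  expect_equal(legendre_moments(phase_hg(0.8), 5), 0.8^(0:5))
  expect_equal(legendre_moments(phase_hg(0), 3), c(1, 0, 0, 0))
  expect_equal(legendre_moments(phase_hg(0.99), 1)[2], 0.99)
  # f(mu) = 3/(16 pi)(1 + mu^2): f_0 = 1, f_2 = 1/10 (checked against
  # direct Gauss-Legendre quadrature), all other moments vanish
  f <- legendre_moments(phase_rayleigh(), 6)
  gl <- pracma::gaussLegendre(64, -1, 1)
  f2_quad <- 2 * pi * sum(gl$w * phase_eval(phase_rayleigh(), gl$x) *
                            (3 * gl$x^2 - 1) / 2)
  expect_equal(f, c(1, 0, f2_quad, 0, 0, 0, 0), tolerance = 1e-12)
  expect_equal(f[3], 0.1, tolerance = 1e-12)
})

test_that("Reynolds-McCormick kernel reduces to HG at alpha = 1/2 and its
           quadrature moments are rule independent", {
  expect_equal(legendre_moments(phase_rmcc(0.8, 0.5), 6), 0.8^(0:6),
               tolerance = 1e-9)
  expect_equal(legendre_moments(phase_rmcc(0.8, 2.5), 0)[1], 1,
               tolerance = 1e-10)
  # two independent quadrature rules agree (the builtin doubles its rule;
  # here a third, finer rule is the oracle)
  spec <- phase_rmcc(0.8, 2.5)
  gl <- pracma::gaussLegendre(4096, -1, 1)
  P <- legendre_p_matrix(gl$x, 4)
  oracle <- as.numeric(2 * pi * crossprod(P, gl$w * phase_eval(spec, gl$x)))
  expect_equal(legendre_moments(spec, 4), oracle, tolerance = 1e-9)
})

test_that("tabulated phase functions renormalize, project, and reject bad input", {
  mu <- seq(-1, 1, length.out = 10001)
  suppressMessages({
    tab <- phase_table(mu, phase_eval(phase_hg(0.8), mu) * 1.01)
  })
  expect_equal(legendre_moments(tab, 4), 0.8^(0:4), tolerance = 1e-6)
  suppressMessages({
    iso <- phase_table(seq(-1, 1, length.out = 201), rep(1 / (4 * pi), 201))
  })
  expect_equal(legendre_moments(iso, 3), c(1, 0, 0, 0), tolerance = 1e-12)
  expect_error(phase_table(mu, -phase_eval(phase_hg(0.5), mu)), ">= 0")
  expect_error(phase_table(mu, phase_eval(phase_hg(0.5), mu) * 2), "5%")
})

test_that("deflection sampling reproduces the Legendre moments of every family", {
  set.seed(7)
  n <- 2e5
  for (spec in list(phase_hg(0.8), phase_hg(0), phase_rmcc(0.8, 2.5),
                    phase_rayleigh())) {
    x <- sample_deflection(spec, n)
    f <- legendre_moments(spec, 4)
    for (l in 1:4) {
      pl <- legendre_p_matrix(x, l)[, l + 1]
      se <- stats::sd(pl) / sqrt(n)
      expect_lt(abs(mean(pl) - f[l + 1]), 4 * se + 1e-4)
    }
  }
  # isotropic sampling is uniform on [-1, 1]
  x0 <- sample_deflection(phase_hg(0), 1e5)
  ks <- suppressWarnings(stats::ks.test(x0, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("reduced scattering is preserved when building equal-musp layers", {
  # constructing layers from (mu_s', g): g = 0.8, mu_s' = 2 -> mu_s = 10
  m <- model_skin_two_layer()
  expect_equal(m$layers[[1]]$mu_s, 10)
  expect_equal(layer_musp(m$layers[[1]]), 2)
  # the phase-variant fixture keeps mu_s' fixed across families
  for (ph in list(phase_hg(0), phase_hg(0.99), phase_rayleigh(),
                  phase_rmcc(0.8, 2.5))) {
    m3 <- model_skin_three_layer(phases = ph)
    expect_equal(vapply(m3$layers, layer_musp, 0), c(2, 1, 0.5),
                 tolerance = 1e-9)
  }
})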