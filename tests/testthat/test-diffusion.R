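test_that("layered diffusion solver matches closed-form semi-infinite
           Green functions for both boundary treatments", {
  q <- 0.8
  D <- 1 / (3 * 2); al <- sqrt(0.02 / D + q^2); z0 <- 1 / 2.02
  A <- layerlux:::de_boundary_A(1.4, 1.0)
  P0 <- (1 - fresnel_unpolarized_reflectance(1, 1.4, 1)) *
    beam_spectrum(gauss_beam, q)
  e0 <- exp(-al * z0)
  # Robin: infinite-space kernel plus one image with reflection
  # coefficient rho = (2 A D a - 1)/(2 A D a + 1)
  de_r <- de_solve_frequency(semi_inf_medium, gauss_beam, q, 0,
                             de_options("musp", "robin", "flux"))
  rho <- (2 * A * D * al - 1) / (2 * A * D * al + 1)
  expect_equal(Re(de_r$R), P0 / 2 * (1 - rho) * e0, tolerance = 1e-8)
  # extrapolated boundary: negative image at -(z0 + 2 z_b)
  de_e <- de_solve_frequency(semi_inf_medium, gauss_beam, q, 0,
                             de_options("musp", "ebc", "flux"))
  zb <- 2 * A * D
  expect_equal(Re(de_e$R), P0 / 2 * (e0 + exp(-al * (z0 + 2 * zb))),
               tolerance = 1e-8)
  # radiance functional equals the flux functional under the Robin
  # condition (identity of the hemispheric exit coefficients)
  de_rr <- de_solve_frequency(semi_inf_medium, gauss_beam, q, 0,
                              de_options("musp", "robin", "radiance"))
  expect_equal(Re(de_rr$R), Re(de_r$R), tolerance = 1e-10)
})

test_that("diffusion layer-merging identity holds to 1e-10", {
  m_split <- layered_medium(list(layer_optics(0.02, 10, hg08, 1.4, 3),
                                 layer_optics(0.02, 10, hg08, 1.4, Inf)))
  for (q in c(0, 0.5, 2)) {
    a <- de_solve_frequency(semi_inf_medium, gauss_beam, q, 0)
    b <- de_solve_frequency(m_split, gauss_beam, q, 0)
    expect_equal(Re(b$R), Re(a$R), tolerance = 1e-10)
  }
})

test_that("the diffusion solution is blind to the phase function at fixed
           mu_s'", {
  # changing g (and the family) while preserving mu_s' changes nothing
  m_a <- model_skin_three_layer(phases = 0.8)
  m_b <- model_skin_three_layer(phases = 0.0)
  m_c <- model_skin_three_layer(phases = phase_rayleigh())
  for (q in c(0, 1.3)) {
    ra <- de_solve_frequency(m_a, gauss_beam, q, 0)$R
    expect_identical(de_solve_frequency(m_b, gauss_beam, q, 0)$R, ra)
    expect_identical(de_solve_frequency(m_c, gauss_beam, q, 0)$R, ra)
  }
})

test_that("swapped-scattering model triggers the clamped-source warning and
           departs strongly from transport", {
  m_swap <- model_skin_three_layer(swap_scattering = TRUE)
  expect_warning(de_solve_frequency(m_swap, gauss_beam, 0.5, 0),
                 "clamped|unreliable")
  # the DE result differs from PN by far more than in the regular model
  q <- 0.5
  pn_reg <- Re(solve_frequency(three_layer, gauss_beam, pn_config(N = 9), q)$R)
  de_reg <- Re(de_solve_frequency(three_layer, gauss_beam, q, 0)$R)
  pn_swp <- Re(solve_frequency(m_swap, gauss_beam, pn_config(N = 9), q)$R)
  de_swp <- Re(suppressWarnings(de_solve_frequency(m_swap, gauss_beam, q, 0))$R)
  expect_gt(abs(de_swp / pn_swp - 1), 2 * abs(de_reg / pn_reg - 1))
})

test_that("diffusion time curve is acausally nonzero at early times", {
  # r = 2 mm, t = 3 ps: light cannot have arrived (needs ~9.3 ps in
  # n = 1.4), yet the parabolic DE predicts a measurable signal
  v <- de_time_curve(two_layer, gauss_beam, 2, c(3, 30), M = 32)
  expect_gt(v$R[1], 1e-12)
  expect_gt(v$R[2], v$R[1])
})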