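test_that("emission vanishes without yield or excitation absorption and is
           restricted to fluorescent layers", {
  cfg <- pn_config(N = 3)
  pr0 <- model_fluorescence_two_layer(yields = c(0, 0))
  s0 <- solve_fluorescence_frequency(pr0, gauss_beam, cfg, 0.5)
  expect_equal(abs(s0$R), 0, tolerance = 1e-14)
  # source profile is nonzero only where the yield is nonzero
  pr <- model_fluorescence_two_layer(yields = c(1, 0))
  sx <- solve_frequency(pr$medium_x, gauss_beam, cfg, 0.5)
  src <- emission_source_profile(sx, pr)
  expect_gt(length(src[[1]]$coef), 0)
  expect_equal(nrow(src[[2]]), 0)
})

test_that("emission is exactly linear in the quantum yield", {
  cfg <- pn_config(N = 3)
  pr1 <- model_fluorescence_two_layer(yields = c(1, 0))
  pr5 <- model_fluorescence_two_layer(yields = c(0.5, 0))
  for (q in c(0, 0.8)) {
    a <- solve_fluorescence_frequency(pr1, gauss_beam, cfg, q)$R
    b <- solve_fluorescence_frequency(pr5, gauss_beam, cfg, q)$R
    expect_equal(Re(a), 2 * Re(b), tolerance = 1e-12)
  }
})

test_that("fluorescence layer-merging identity holds", {
  ph <- phase_hg(0.8)
  mk <- function(mua, mus, th) layer_optics(mua, mus, ph, 1.4, th)
  pr <- fluorescence_problem(list(
    fluorescent_layer(mk(0.02, 10, 2), mk(0.016, 8, 2), 1.0),
    fluorescent_layer(mk(0.03, 2.5, Inf), mk(0.024, 2, Inf), 0)))
  pr_split <- fluorescence_problem(list(
    fluorescent_layer(mk(0.02, 10, 1), mk(0.016, 8, 1), 1.0),
    fluorescent_layer(mk(0.02, 10, 1), mk(0.016, 8, 1), 1.0),
    fluorescent_layer(mk(0.03, 2.5, Inf), mk(0.024, 2, Inf), 0)))
  cfg <- pn_config(N = 3)
  for (q in c(0, 0.7, 2.2)) {
    a <- solve_fluorescence_frequency(pr, gauss_beam, cfg, q)$R
    b <- solve_fluorescence_frequency(pr_split, gauss_beam, cfg, q)$R
    expect_equal(Re(b), Re(a), tolerance = 1e-6)
  }
})

test_that("escaping fluorescence never exceeds the absorbed excitation
           energy in fluorescent layers", {
  pr <- model_fluorescence_two_layer(yields = c(1, 0))
  cfg <- pn_config(N = 3)
  sol <- solve_fluorescence_frequency(pr, gauss_beam, cfg, 0)
  # absorbed excitation in layer 1 by depth integration of the fluence
  z <- seq(1e-4, 2, length.out = 2000)
  phi_x <- Re(sol$excitation$fluence(z))
  absorbed <- 0.02 * sum(phi_x) * diff(z)[1]
  expect_lt(Re(sol$R), absorbed)
  expect_gt(Re(sol$R), 0)
})

test_that("low-order emission solutions sit closer to high-order transport
           than the diffusion backend does", {
  pr <- model_fluorescence_two_layer()
  r <- c(1, 2, 4, 7)
  f9 <- cached("fluo_p9_small", fluorescence_spatial_curve(
    pr, gauss_beam, pn_config(N = 9, q_max = 16), r, pts = 4))
  f1 <- fluorescence_spatial_curve(pr, gauss_beam,
                                   pn_config(N = 1, q_max = 16), r, pts = 4)
  fde <- de_fluorescence_spatial_curve(pr, gauss_beam, r)
  err_p1 <- max(abs(f1$R / f9$R - 1))
  err_de <- max(abs(fde$R / f9$R - 1))
  expect_lt(err_p1, err_de)
})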