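test_that("photon accounting is an exact integer identity and runs are
           seed-reproducible", {
  mc <- run_elastic(two_layer, gauss_beam, mc_config(2e5, seed = 3))
  expect_true(mc$accounting_ok)
  expect_equal(mc$counts$specular + mc$counts$reflected +
                 mc$counts$transmitted + sum(mc$counts$absorbed) +
                 mc$counts$guard, 2e5)
  mc2 <- run_elastic(two_layer, gauss_beam, mc_config(2e5, seed = 3))
  expect_identical(mc$Rr$counts, mc2$Rr$counts)
  expect_identical(mc$counts, mc2$counts)
  # independent seeds agree within 4 standard errors on every bin
  mc3 <- run_elastic(two_layer, gauss_beam, mc_config(2e5, seed = 99))
  se <- sqrt(mc$Rr$se^2 + mc3$Rr$se^2)
  ok <- mc$Rr$counts + mc3$Rr$counts > 25
  expect_true(all((abs(mc$Rr$estimate - mc3$Rr$estimate) / se)[ok] < 4))
})

test_that("specular fraction is binomial around the normal-incidence
           Fresnel value", {
  n <- 4e5
  mc <- run_elastic(semi_inf_medium, gauss_beam, mc_config(n, seed = 11))
  p <- 1 / 36
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mc$specular_fraction - p), 4 * se)
})

test_that("non-scattering media absorb everything and deposit
           Beer-Lambert depth profiles", {
  m0 <- layered_medium(list(layer_optics(0.5, 0, phase_hg(0), 1.0, Inf)))
  ze <- seq(0, 8, by = 0.5)
  mc <- run_elastic(m0, beam("pencil"),
                    mc_config(2e5, seed = 5, abs_z_edges = ze))
  expect_equal(mc$total_diffuse_reflectance, 0)
  expect_equal(sum(mc$absorbed_fraction), 1)
  expected <- diff(-exp(-0.5 * ze)) * 2e5
  counts <- mc$abs_z$counts
  se <- sqrt(pmax(expected, 1))
  expect_true(all(abs(counts - expected) < 4 * se + 2))
})

test_that("doubling the photon count shrinks standard errors by sqrt(2)", {
  a <- run_elastic(two_layer, gauss_beam, mc_config(1e5, seed = 8))
  b <- run_elastic(two_layer, gauss_beam, mc_config(2e5, seed = 8))
  sel <- a$Rr$counts > 200
  ratio <- a$Rr$se[sel] / b$Rr$se[sel]
  expect_true(all(abs(ratio - sqrt(2)) < 0.2 * sqrt(2)))
})

test_that("track-length fluence closes the energy balance and matches the
           ballistic profile without scattering", {
  m0 <- layered_medium(list(layer_optics(0.5, 0, phase_hg(0), 1.0, 20)))
  mc <- fluence_tally(m0, beam("pencil"), mc_config(1e5, seed = 2),
                      z_edges = seq(0, 20, by = 0.25),
                      r_edges = c(0, 0.5))
  phi <- rowSums(mc$fluence$estimate * pi * diff(mc$fluence$r_edges^2))
  zl <- mc$fluence$z_edges[-length(mc$fluence$z_edges)]
  zr <- mc$fluence$z_edges[-1]
  expected <- (exp(-0.5 * zl) - exp(-0.5 * zr)) / 0.5 / diff(mc$fluence$z_edges)
  # statistical allowance: roughly one track contribution per surviving
  # photon entering the bin
  n_exp <- 1e5 * exp(-0.5 * zl)
  tol <- 0.02 + 4 / sqrt(pmax(n_exp, 1))
  sel <- n_exp > 50
  expect_true(all((abs(phi - expected) / expected)[sel] < tol[sel]))
  # energy closure: absorbed energy from the fluence tally matches counts
  absorbed_from_phi <- sum(0.5 * phi * diff(mc$fluence$z_edges))
  # desk-scale run: the closure is statistics-limited at 1e5 photons
  expect_lt(abs(absorbed_from_phi + mc$total_transmittance - 1), 5e-3)
})

test_that("fluorescence transport obeys yields and site statistics", {
  pr0 <- model_fluorescence_two_layer(yields = c(0, 0))
  mc0 <- run_fluorescence(pr0, gauss_beam, mc_config(5e4, seed = 4))
  expect_equal(mc0$emission$launched, 0)
  expect_equal(sum(mc0$emission$Rr$counts), 0)
  # absorbing-only fluorescent layer: emission sources follow exp(-mu_ax z)
  ph0 <- phase_hg(0)
  prb <- fluorescence_problem(list(
    fluorescent_layer(layer_optics(1, 0, ph0, 1.0, 5),
                      layer_optics(0.8, 0, ph0, 1.0, 5), 1.0),
    fluorescent_layer(layer_optics(1e-9, 0, ph0, 1.0, Inf),
                      layer_optics(1e-9, 0, ph0, 1.0, Inf), 0)))
  ze <- seq(0, 5, by = 0.25)
  mcb <- run_fluorescence(prb, beam("pencil"),
                          mc_config(2e5, seed = 6, abs_z_edges = ze))
  expected <- diff(-exp(-ze)) * 2e5
  expect_true(all(abs(mcb$abs_z$counts - expected) < 4 * sqrt(expected) + 2))
  expect_true(mcb$emission$accounting_ok)
})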