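test_that("Fresnel reflectance matches closed forms and stays in [0,1]", {
  # normal incidence between n = 1.4 and air: ((n1-n2)/(n1+n2))^2 = 1/36
  expect_equal(fresnel_unpolarized_reflectance(1.4, 1.0, 1.0), 1 / 36)
  # matched indices reflect nothing at any angle
  for (mu in c(0.1, 0.5, 1)) {
    expect_equal(fresnel_unpolarized_reflectance(1.4, 1.4, mu), 0)
  }
  # total internal reflection below the critical cosine
  expect_equal(fresnel_unpolarized_reflectance(1.4, 1.0, 0.5), 1)
  mu <- seq(0.01, 1, by = 0.01)
  r <- fresnel_unpolarized_reflectance(1.0, 1.4, mu)
  expect_true(all(r >= 0 & r <= 1))
  expect_error(fresnel_unpolarized_reflectance(1.4, 1.0, 0), "mu")
})

test_that("critical and refracted cosines follow Snell geometry", {
  expect_equal(critical_cosine(1.4, 1.0), sqrt(1 - (1 / 1.4)^2))
  expect_equal(critical_cosine(1.0, 1.4), 0)
  expect_equal(critical_cosine(1.0, 1.0), 0)
  expect_equal(refracted_cosine(1.0, 1.4, 1.0), 1.0)
  expect_equal(refracted_cosine(1.3, 1.3, 0.3), 0.3)
  expect_equal(refracted_cosine(1.4, 1.0, 0.8), sqrt(0.2944), tolerance = 1e-12)
  expect_error(refracted_cosine(1.4, 1.0, 0.5), "critical")
})

test_that("refraction round trip and Fresnel reciprocity hold", {
  n1 <- 1.4; n2 <- 1.0
  mu <- seq(critical_cosine(n1, n2) + 1e-3, 1, length.out = 40)
  mu_t <- refracted_cosine(n1, n2, mu)
  expect_equal(refracted_cosine(n2, n1, mu_t), mu, tolerance = 1e-12)
  # reflection probability is reciprocal along the refracted path
  expect_equal(fresnel_unpolarized_reflectance(n1, n2, mu),
               fresnel_unpolarized_reflectance(n2, n1, mu_t),
               tolerance = 1e-12)
})

test_that("ballistic attenuation combines Beer-Lambert and interface losses", {
  m <- layered_medium(list(layer_optics(5, 5, phase_hg(0), 1.0, Inf)))
  expect_equal(ballistic_attenuation(m, 0), 1)
  expect_equal(ballistic_attenuation(m, 0.1), exp(-1), tolerance = 1e-12)
  # mismatched top surface: transmission 1 - 1/36 at z = 0+
  expect_equal(ballistic_attenuation(three_layer, 0), 1 - 1 / 36,
               tolerance = 1e-12)
  # monotone non-increasing, with interface drops equal to Fresnel factors
  mix <- layered_medium(list(layer_optics(1, 0, phase_hg(0), 1.4, 1),
                             layer_optics(1, 0, phase_hg(0), 1.6, Inf)),
                        n_external_top = 1.4)
  below <- ballistic_attenuation(mix, 1 + 1e-12)
  above <- ballistic_attenuation(mix, 1 - 1e-12)
  expect_equal(below / above,
               1 - fresnel_unpolarized_reflectance(1.4, 1.6, 1),
               tolerance = 1e-9)
  z <- seq(0, 3, by = 0.05)
  expect_true(all(diff(ballistic_attenuation(mix, z)) <= 0))
})

test_that("medium validation catches structural errors and thin-layer regime", {
  expect_error(layer_optics(-0.1, 1, phase_hg(0.8)), "mu_a")
  expect_error(layered_medium(list(
    layer_optics(0.1, 1, phase_hg(0.8), 1.4, Inf),
    layer_optics(0.1, 1, phase_hg(0.8), 1.4, Inf))), "semi-infinite")
  # swapped-scattering model: top-layer transport length 1/0.52 ~ 1.9 mm
  # exceeds its 1 mm thickness -> diffusion-reliability warning
  expect_warning(validate_medium(model_skin_three_layer(swap_scattering = TRUE)),
                 "transport length")
  expect_silent(validate_medium(three_layer))
})

test_that("Laplace absorption shift follows mu_a + s n / c", {
  l <- layer_optics(0.02, 5, phase_hg(0.8), 1.4, 2)
  expect_identical(time_domain_shift(l, 0), l)
  l2 <- time_domain_shift(l, 0.01)
  expect_equal(l2$mu_a, 0.02 + 0.01 * 1.4 / 0.299792458, tolerance = 1e-12)
  l3 <- time_domain_shift(l, 0.01i)
  expect_true(is.complex(l3$mu_a))
})

test_that("beam profiles are unit power and have matching spectra", {
  for (bm in list(beam("gaussian", 0.4), beam("flat_disc", radius = 0.7))) {
    p <- integrate(function(r) 2 * pi * r * beam_profile(bm, r), 0, Inf)$value
    expect_equal(p, 1, tolerance = 1e-6)
    expect_equal(beam_spectrum(bm, 0), 1)
  }
  q <- seq(0, 10, by = 0.5)
  expect_equal(beam_spectrum(beam("gaussian", 0.5), q), exp(-q^2 * 0.25 / 8))
})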