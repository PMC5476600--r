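parse_config_roundtrip <- function(cfg)
  serialize_config(layerlux:::parse_run_config(serialize_config(cfg)))

test_that("configuration files load, validate, and round-trip", {
  p <- system.file("extdata", "three_layer.json", package = "layerlux")
  cfg <- load_config(p)
  expect_s3_class(cfg, "lux_run_config")
  expect_length(cfg$medium$layers, 3)
  expect_equal(cfg$medium$interface_depths, c(1, 3, Inf))
  expect_equal(layer_musp(cfg$medium$layers[[2]]), 1.0)
  expect_identical(parse_config_roundtrip(cfg), serialize_config(cfg))
})

test_that("invalid configurations are rejected with context", {
  tmp <- tempfile(fileext = ".json")
  # semi-infinite middle layer
  bad <- list(layer = list(
    list(mu_a = 0.1, musp = 1, g = 0.8, n = 1.4, thickness = "inf"),
    list(mu_a = 0.1, musp = 1, g = 0.8, n = 1.4, thickness = 1)))
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE)
  expect_error(suppressMessages(load_config(tmp)), "semi-infinite")
  # unknown keys
  bad2 <- list(layer = list(list(mu_a = 0.1, musp = 1, g = 0.8, n = 1.4,
                                 thickness = 1, bogus = 1)))
  jsonlite::write_json(bad2, tmp, auto_unbox = TRUE)
  expect_error(suppressMessages(load_config(tmp)), "bogus")
})

test_that("a missing beam table defaults to the 0.5 mm Gaussian with a
           notice", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(layer = list(
    list(mu_a = 0.1, musp = 1, g = 0.8, n = 1.4, thickness = "inf"))),
    tmp, auto_unbox = TRUE)
  expect_message(cfg <- load_config(tmp), "rho_w = 0.5")
  expect_equal(cfg$beam$profile, "gaussian")
  expect_equal(cfg$beam$rho_w, 0.5)
})

test_that("fluorescence configs build coupled problems", {
  p <- system.file("extdata", "fluorescence_two_layer.yaml",
                   package = "layerlux")
  cfg <- load_config(p)
  expect_false(is.null(cfg$problem))
  expect_equal(cfg$problem$yields, c(1, 0))
  expect_equal(cfg$problem$medium_m$layers[[1]]$mu_a, 0.016)
})

test_that("run() dispatches and writes regenerable results", {
  p <- system.file("extdata", "two_layer.json", package = "layerlux")
  cfg <- load_config(p)
  cfg$solver <- "pn"; cfg$domain <- "sfd"; cfg$q <- seq(0, 2, by = 0.5)
  cfg$N <- 3
  out <- tempfile()
  res <- run(cfg, out = out)
  expect_true(file.exists(paste0(out, ".csv")))
  expect_true(file.exists(paste0(out, ".json")))
  tab <- utils::read.csv(paste0(out, ".csv"), comment.char = "#")
  expect_equal(tab$q, cfg$q)
  expect_true(all(diff(tab$R) < 0))
  # mc dispatch with exact accounting echoed in the header
  cfg$solver <- "mc"; cfg$domain <- "spatial"; cfg$photons <- 2e4
  mcres <- run(cfg)
  expect_true(mcres$accounting_ok)
})

test_that("comparison reports zero for identical curves and chi-square
           against MC errors", {
  x <- data.frame(R = c(1, 2, 3))
  r0 <- compare_results(x, x)
  expect_equal(r0$max_abs_rel, 0)
  r1 <- compare_results(c(1.1, 2.1), c(1, 2), se = c(0.05, 0.05), tol = 0.2)
  expect_true(r1$pass)
  expect_equal(r1$dof, 2)
  expect_error(compare_results(1:3, 1:4), "mismatch")
})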