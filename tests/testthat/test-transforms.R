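# Closed-form transform pairs are the independent oracles for the
# inversion machinery. Relative errors are floored against a small
# fraction of the curve maximum where the target itself underflows the
# dynamic range of double-precision quadrature.
rel_err <- function(got, want, floor_frac = 1e-4) {
  abs(got - want) / pmax(abs(want), floor_frac * max(abs(want)))
}

test_that("inverse Hankel reproduces the Gaussian pair to 1e-8", {
  sig <- 1
  r <- seq(0, 6, by = 0.2)
  f <- inverse_hankel0(function(q) exp(-q^2 * sig^2 / 2), r)
  ex <- 1 / (2 * pi * sig^2) * exp(-r^2 / (2 * sig^2))
  expect_lt(max(rel_err(f, ex)), 1e-8)
  # pointwise relative accuracy over the representable range
  in_range <- ex > 1e-4 * max(ex)
  expect_lt(max(abs(f - ex)[in_range] / ex[in_range]), 1e-8)
})

test_that("inverse Hankel reproduces the modified-Bessel pair to 1e-8", {
  kap <- 0.7
  r <- seq(0.2, 8, by = 0.2)
  f <- inverse_hankel0(function(q) 1 / (q^2 + kap^2), r)
  ex <- besselK(kap * r, 0) / (2 * pi)
  expect_lt(max(abs(f - ex) / ex), 1e-8)
})

test_that("inverse Hankel of the Gaussian beam spectrum recovers the
           beam profile", {
  rw <- 0.5
  r <- seq(0, 1.5, by = 0.05)
  f <- inverse_hankel0(function(q) exp(-q^2 * rw^2 / 8), r)
  ex <- 2 / (pi * rw^2) * exp(-2 * r^2 / rw^2)
  expect_lt(max(rel_err(f, ex)), 1e-8)
})

test_that("inverse Laplace reproduces the exponential pair to 1e-8 on
           both contour families", {
  t <- exp(seq(log(10), log(3000), length.out = 60))
  a <- 0.05
  for (ty in c("hyperbolic", "two_part")) {
    v <- inverse_laplace(function(s) 1 / (s + a), t, type = ty)
    expect_lt(max(abs(v - exp(-a * t))), 1e-8)
  }
})

test_that("inverse Laplace handles the branch-cut pair to 1e-6", {
  t <- exp(seq(log(10), log(3000), length.out = 60))
  a <- 3
  ex <- a / (2 * sqrt(pi * t^3)) * exp(-a^2 / (4 * t))
  for (ty in c("hyperbolic", "two_part")) {
    v <- inverse_laplace(function(s) exp(-a * sqrt(s)), t, type = ty)
    expect_lt(max(abs(v - ex)), 1e-6)
  }
})

test_that("both transform operators are linear to round-off", {
  r <- seq(0.5, 4, by = 0.5)
  F1 <- function(q) exp(-q^2 / 2); F2 <- function(q) 1 / (q^2 + 1)
  lhs <- inverse_hankel0(function(q) 2 * F1(q) - 3 * F2(q), r, q_max = 400)
  rhs <- 2 * inverse_hankel0(F1, r, q_max = 400) -
    3 * inverse_hankel0(F2, r, q_max = 400)
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-12)
  t <- c(20, 100, 800)
  G1 <- function(s) 1 / (s + 0.05); G2 <- function(s) 1 / (s + 0.01)^2
  lv <- inverse_laplace(function(s) G1(s) + 0.5 * G2(s), t)
  rv <- inverse_laplace(G1, t) + 0.5 * inverse_laplace(G2, t)
  expect_equal(lv, rv, tolerance = 1e-10)
})

test_that("quadrature refinement leaves the inversions unchanged", {
  t <- exp(seq(log(20), log(2000), length.out = 30))
  v <- inverse_laplace(function(s) 1 / (s + 0.03), t, type = "hyperbolic",
                       M = 64, check = TRUE)
  expect_lt(attr(v, "err"), 1e-6)
  r <- seq(0.5, 5, by = 0.5)
  f8 <- inverse_hankel0(function(q) exp(-q^2 / 3), r, pts = 8)
  f16 <- inverse_hankel0(function(q) exp(-q^2 / 3), r, pts = 16)
  expect_equal(as.numeric(f8), as.numeric(f16), tolerance = 1e-10)
})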