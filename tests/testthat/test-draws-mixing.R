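test_that("MLHS draws stratify, are reproducible, and centre on 0.5", {
  ds <- mlhs(3, 2, 4, seed = 42)
  expect_equal(dim(ds$values), c(3, 2, 4))
  for (p in 1:3) {
    for (d in 1:2) {
      v <- sort(ds$values[p, d, ])
      # one value per stratum [i/4, (i+1)/4)
      expect_equal(findInterval(v, c(0, 0.25, 0.5, 0.75, 1)), 1:4)
    }
  }
  ds2 <- mlhs(3, 2, 4, seed = 42)
  expect_identical(ds$values, ds2$values)
  # grid mean (R-1)/(2R) plus a shift in (0, 1/R) keeps every
  # person-dimension mean within 1/(2R) of 0.5
  R <- 16
  big <- mlhs(20, 3, R, seed = 7)
  means <- apply(big$values, c(1, 2), mean)
  expect_true(all(abs(means - 0.5) <= 1 / (2 * R) + 1e-12))
  expect_error(mlhs(1, 1, 0), ">= 1")
})

test_that("uniform-to-normal mapping is the inverse CDF and monotone", {
  ds <- mlhs(1, 1, 8, seed = 1)
  ds$values[1, 1, ] <- c(0.5, 0.975, 0.025, 0.1, 0.2, 0.3, 0.6, 0.9)
  z <- to_normal(ds)
  expect_equal(z$family, "std_normal")
  expect_equal(z$values[1, 1, 1], 0)
  expect_equal(z$values[1, 1, 2], 1.959964, tolerance = 1e-6)
  u <- sort(ds$values[1, 1, ])
  expect_true(all(diff(stats::qnorm(u)) > 0))
  expect_error(to_normal(z), "std_uniform")
})

test_that("transforms reproduce the closed-form special cases", {
  n <- 2; R <- 3
  dN <- matrix(c(-1, 0, 1, 2, -2, 0.5), n, R)
  u <- matrix(c(0.5, 0.25, 0.75, 0.1, 0.9, 0.3), n, R)
  # degenerate normal collapses to its mean
  out <- transform_coefficients(coef_spec("b", "normal"),
                                list(mu = 2, sigma = 0), list(dN = dN))
  expect_equal(out, matrix(2, n, R))
  # negative-sign lognormal with sigma 0 is the constant -exp(mu)
  out <- transform_coefficients(coef_spec("b", "lognormal", sign = -1),
                                list(mu = 0, sigma = 0), list(dN = dN))
  expect_equal(out, matrix(-1, n, R))
  out <- transform_coefficients(coef_spec("b", "lognormal", sign = -1),
                                list(mu = 0.3, sigma = 1.2), list(dN = dN))
  expect_true(all(out < 0))
  # uniform: a + b u
  out <- transform_coefficients(coef_spec("b", "uniform"),
                                list(a = -1, b = 2), list(u = u))
  expect_equal(out[1, 1], 0)
  # polynomial: mu + sigma1 u with sigma2 = 0 is linear in u
  out <- transform_coefficients(coef_spec("b", "fm2"),
                                list(mu = 0, sigma1 = 1, sigma2 = 0),
                                list(u = matrix(0.3, 1, 1)))
  expect_equal(out[1, 1], 0.3)
  # asymmetric triangular: upper piece at d_U2 = 1 lands on the mode
  out <- transform_coefficients(
    coef_spec("b", "asym_triangular"), list(a = 0, b = 2, c = 0),
    list(u1 = matrix(0.5, 1, 1), u2 = matrix(1, 1, 1),
         us = matrix(0.99, 1, 1)))
  expect_equal(out[1, 1], 1.0)
  expect_error(
    transform_coefficients(coef_spec("b", "triangular"),
                           list(a = 0, b = 1), list(u = u)),
    "requires draw")
})

test_that("analytic means match closed forms and a simulation oracle", {
  expect_equal(analytic_mean("normal", list(mu = -5.9, sigma = 3)), -5.9)
  expect_equal(analytic_mean("lognormal",
                             list(mu = 0, sigma = 0, sign = -1)), -1)
  expect_equal(analytic_mean("uniform", list(a = 0, b = 2)), 1)
  expect_equal(analytic_mean("loguniform", list(a = 0, b = 0, sign = 1)), 1)
  # Monte-Carlo oracle: sample mean within 3 standard errors, per family
  set.seed(99)
  cases <- list(
    list("normal", list(mu = 0.7, sigma = 1.3)),
    list("uniform", list(a = 0, b = 2)),
    list("triangular", list(a = -1, b = 0.8)),
    list("lognormal", list(mu = 0.2, sigma = 0.6, sign = -1)),
    list("loguniform", list(a = -1, b = 1.5, sign = -1)),
    list("asym_triangular", list(a = -2, b = 1, c = 0.6)),
    list("fm2", list(mu = 0.5, sigma1 = 1, sigma2 = -2)),
    list("fm3", list(mu = 0, sigma1 = 2, sigma2 = -3, sigma3 = 1.5)),
    list("normal_mixture", list(w = c(0.3, 0.7), mean = c(-2, 1),
                                sd = c(0.5, 0.5))))
  S <- 2e5
  for (cs in cases) {
    v <- mixing_sample(cs[[1]], cs[[2]], S)
    se <- stats::sd(v) / sqrt(S)
    expect_lt(abs(mean(v) - analytic_mean(cs[[1]], cs[[2]])), 3 * se + 1e-12)
  }
})

test_that("support and sign constraints hold for every family", {
  set.seed(4)
  v <- mixing_sample("lognormal", list(mu = 1, sigma = 2, sign = -1), 5000)
  expect_true(all(v < 0))
  v <- mixing_sample("loguniform", list(a = -2, b = 3, sign = 1), 5000)
  expect_true(all(v > 0 & v >= exp(-2) - 1e-12 & v <= exp(1) + 1e-12))
  v <- mixing_sample("uniform", list(a = -1, b = 2), 5000)
  expect_true(all(v >= -1 & v <= 1))
  # triangular as implemented spans [a, a + 2b]
  v <- mixing_sample("triangular", list(a = 0, b = 0.5), 5000)
  expect_true(all(v >= 0 & v <= 1))
  v <- mixing_sample("asym_triangular", list(a = -1, b = 2, c = 0.9), 5000)
  expect_true(all(v >= -1 & v <= 2))
})

test_that("asymmetric triangular with c = 0 collapses to the symmetric
           triangular on the same support", {
  set.seed(11)
  S <- 2e4
  at <- mixing_sample("asym_triangular", list(a = -1, b = 1, c = 0), S)
  # symmetric triangular on [-1, 1]: a = -1, half-range b = 1
  tri <- mixing_sample("triangular", list(a = -1, b = 1), S)
  ks <- suppressWarnings(stats::ks.test(at, tri))
  expect_gt(ks$p.value, 0.001)
})

test_that("MLHS integrates a smooth function with less variance than
           pseudo-random uniforms", {
  R <- 64
  f <- function(u) plogis(2 * qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12)))
  est_mlhs <- vapply(1:30, function(s) mean(f(mlhs(1, 1, R, s)$values)),
                     numeric(1))
  set.seed(1)
  est_prng <- vapply(1:30, function(s) mean(f(stats::runif(R))), numeric(1))
  expect_lt(stats::var(est_mlhs), stats::var(est_prng))
})
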