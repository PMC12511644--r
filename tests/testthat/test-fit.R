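test_that("MNL estimates recover the generating parameters", {
  sim <- simulate_generic_dce(two_alt_config(sigma = 0, mu = 1), 400, 8,
                              two_alt_design(), seed = 21)
  fit <- fit_msl(two_alt_spec("fixed"), sim$data, seed = 1)
  expect_true(fit$convergence$converged)
  expect_lt(abs(fit$estimates[["x.value"]] - 1), 3 * fit$se[["x.value"]])
  expect_lt(abs(fit$estimates[["price.value"]] + 0.5),
            3 * fit$se[["price.value"]])
  expect_equal(fit$AIC, 2 * 2 - 2 * fit$LL)
  expect_equal(fit$BIC, 2 * log(400) - 2 * fit$LL)
})

test_that("mixed logit on noise-free-mixing data collapses to the MNL
           likelihood", {
  sim <- simulate_generic_dce(two_alt_config(sigma = 0), 150, 6,
                              two_alt_design(), seed = 31)
  mnl <- fit_msl(two_alt_spec("fixed"), sim$data, seed = 1)
  mix <- fit_msl(two_alt_spec("normal"), sim$data, R = 100, seed = 1)
  expect_lt(mix$estimates[["x.sigma"]], 0.15)
  expect_lt(abs(mix$LL - mnl$LL), 0.5)
})

test_that("refitting with the same seed reproduces the likelihood
           bit-for-bit", {
  sim <- simulate_generic_dce(two_alt_config(), 60, 5, two_alt_design(),
                              seed = 41)
  f1 <- fit_msl(two_alt_spec("normal"), sim$data, R = 50, seed = 9)
  f2 <- fit_msl(two_alt_spec("normal"), sim$data, R = 50, seed = 9)
  expect_identical(f1$LL, f2$LL)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("person likelihoods are probabilities and sum to the reported
           log-likelihood", {
  sim <- simulate_generic_dce(two_alt_config(), 50, 5, two_alt_design(),
                              seed = 51)
  fit <- fit_msl(two_alt_spec("normal"), sim$data, R = 50, seed = 1)
  expect_true(all(fit$Pn > 0 & fit$Pn <= 1))
  expect_equal(sum(log(fit$Pn)), fit$LL)
})

test_that("matching asymmetric specification fits asymmetric data at least
           as well as the all-normal one", {
  cfg <- taste_config(
    x = list(family = "lognormal",
             params = list(mu = 0.3, sigma = 0.7, sign = -1)),
    price = list(family = "fixed", params = list(value = 0.5)))
  sim <- simulate_generic_dce(cfg, 250, 8, two_alt_design(), seed = 61)
  fLN <- fit_msl(two_alt_spec("lognormal"), sim$data, R = 100, seed = 1)
  fS <- fit_msl(two_alt_spec("normal"), sim$data, R = 100, seed = 1)
  expect_gte(fLN$LL, fS$LL)
})

test_that("information criteria follow their definitions", {
  fake <- structure(list(AIC = 2 * 10 - 2 * (-100),
                         BIC = 10 * log(50) - 2 * (-100)),
                    class = "mixl_fit")
  expect_equal(information_criteria(fake)[["AIC"]], 220)
  expect_equal(information_criteria(fake)[["BIC"]],
               10 * log(50) + 200)
})

test_that("WTP-space fit recovers generating willingness to pay", {
  # truth: V = 0.8 x - 0.5 price; in the bracket parameterization
  # V = beta_p (price + w x) this is beta_p = -0.5, w = 0.8 / -0.5 = -1.6
  cfg <- taste_config(
    x = list(family = "normal", params = list(mu = 0.8, sigma = 0)),
    price = list(family = "fixed", params = list(value = -0.5)))
  sim <- simulate_generic_dce(cfg, 400, 8, two_alt_design(), seed = 71)
  wspec <- model_spec(list(coef_spec("x", "normal"),
                           coef_spec("price", "fixed")),
                      space = "wtp", price_coefficient = "price")
  fit <- fit_msl(wspec, sim$data, R = 50, seed = 1)
  wtp <- wtp_means(fit)
  expect_equal(wtp$coefficient, "x")
  expect_lt(abs(wtp$mean - (-1.6)), 3 * wtp$se)
  expect_true(wtp$lower < wtp$mean && wtp$mean < wtp$upper)
  # the utility surface coincides with the preference-space fit
  pfit <- fit_msl(model_spec(list(coef_spec("x", "normal"),
                                  coef_spec("price", "fixed"))),
                  sim$data, R = 50, seed = 1)
  expect_equal(fit$LL, pfit$LL, tolerance = 1e-4)
})

test_that("RP fit recovers intercepts and the error-component scale", {
  ic <- c(cig = rp_intercept_for_share(0.82, 1),
          ecig = rp_intercept_for_share(0.38, 1))
  dat <- simulate_rp_binary(1500, intercepts = ic, sigma_rho = 1, seed = 5)
  fit <- fit_rp(rp_spec(), dat, R = 100, seed = 2)
  expect_true(fit$convergence$converged)
  expect_lt(abs(fit$estimates[["asc_cig"]] - ic[["cig"]]),
            3 * fit$se[["asc_cig"]])
  expect_lt(abs(fit$estimates[["sigma_rho"]] - 1),
            3 * fit$se[["sigma_rho"]])
  expect_equal(sum(log(fit$Pn)), fit$LL)
})

test_that("RP fit with covariates recovers their effects", {
  set.seed(8)
  z <- data.frame(young = rbinom(1200, 1, 0.5))
  dat <- simulate_rp_binary(1200, intercepts = c(cig = 0.5, ecig = -1),
                            gamma = list(cig = c(young = -0.6),
                                         ecig = c(young = 0.8)),
                            sigma_rho = 0.8, covariates = z, seed = 6)
  fit <- fit_rp(rp_spec(cig_covariates = "young",
                        ecig_covariates = "young"), dat, R = 100, seed = 3)
  expect_lt(abs(fit$estimates[["cig.young"]] + 0.6),
            3 * fit$se[["cig.young"]])
  expect_lt(abs(fit$estimates[["ecig.young"]] - 0.8),
            3 * fit$se[["ecig.young"]])
})
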