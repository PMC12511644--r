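test_that("MNL probabilities are the softmax over available alternatives", {
  expect_equal(mnl_probabilities(c(0, 0)), c(0.5, 0.5))
  expect_equal(mnl_probabilities(c(log(2), 0)), c(2 / 3, 1 / 3))
  p <- mnl_probabilities(c(5, 1, 3), available = c(TRUE, FALSE, TRUE))
  expect_equal(p[2], 0)
  expect_equal(p[c(1, 3)], exp(c(5, 3)) / sum(exp(c(5, 3))))
  expect_equal(sum(p), 1)
  # invariance to a common utility shift and overflow safety
  expect_equal(mnl_probabilities(c(1000, 1001)), mnl_probabilities(c(0, 1)))
  expect_error(mnl_probabilities(c(1, 2), available = c(FALSE, FALSE)),
               "no available")
})

test_that("panel probability is the product over tasks", {
  expect_equal(panel_probability(c(0.5, 0.5)), 0.25)
  expect_equal(panel_probability(0.37), 0.37)
  p <- c(0.2, 0.9, 0.55)
  expect_equal(log(panel_probability(p)), sum(log(p)))
  expect_error(panel_probability(numeric(0)), "empty")
  expect_error(panel_probability(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("utilities are linear in attributes, and WTP space multiplies the
           bracket by the price coefficient", {
  cd <- toy_choice_data()
  spec <- model_spec(list(coef_spec("bx", "fixed", attributes = "x")))
  expect_equal(build_utilities(spec, list(bx = 2), cd), 2 * cd$x)
  wspec <- model_spec(list(coef_spec("w", "fixed", attributes = "x"),
                           coef_spec("p", "fixed", attributes = "price")),
                      space = "wtp", price_coefficient = "p")
  # V = beta_p (price + w x): row with price 4, x = 1, w = 7, beta_p = -0.5
  df <- toy_task_df()
  df$price <- c(4, 1, 1)
  df$x <- c(1, 0, 0)
  cdw <- choice_data(df, choice = "chosen")
  V <- build_utilities(wspec, list(w = 7, p = -0.5), cdw)
  expect_equal(V[1], -0.5 * (4 + 7))
  expect_error(build_utilities(spec, list(), cd), "missing coefficient")
})

test_that("fixed-coefficient simulated probability equals the plain MNL
           panel probability", {
  cfg <- two_alt_config(sigma = 0)
  sim <- simulate_generic_dce(cfg, 30, 4, two_alt_design(), seed = 5)
  spec <- model_spec(list(coef_spec("x", "fixed"),
                          coef_spec("price", "fixed")))
  params <- list(x = list(value = 0.8), price = list(value = -0.4))
  Pn <- simulated_person_probability(spec, params, sim$data, R = 50)
  # reference: per-person product of hand-computed softmax probabilities
  d <- as.data.frame(sim$data)
  V <- 0.8 * d$x - 0.4 * d$price
  ref <- vapply(unique(d$person_id), function(p) {
    rows <- d$person_id == p
    dd <- d[rows, ]
    vv <- V[rows]
    out <- 1
    for (t in unique(dd$task_id)) {
      idx <- dd$task_id == t
      probs <- mnl_probabilities(vv[idx])
      out <- out * probs[dd$chosen[idx]]
    }
    out
  }, numeric(1))
  expect_equal(unname(Pn), unname(ref), tolerance = 1e-12)
})

test_that("degenerate mixing (sigma = 0) matches the fixed-coefficient
           likelihood to machine precision", {
  sim <- simulate_generic_dce(two_alt_config(), 25, 4, two_alt_design(),
                              seed = 9)
  spec_n <- two_alt_spec("normal")
  spec_f <- two_alt_spec("fixed")
  Pn_mix <- simulated_person_probability(
    spec_n, list(x = list(mu = 0.7, sigma = 0), price = list(value = -0.3)),
    sim$data, R = 25)
  Pn_fix <- simulated_person_probability(
    spec_f, list(x = list(value = 0.7), price = list(value = -0.3)),
    sim$data, R = 25)
  expect_equal(Pn_mix, Pn_fix, tolerance = 1e-12)
})

test_that("simulated probability agrees with Gauss-Hermite quadrature for
           one normal coefficient", {
  skip_if_not_installed("pracma")
  # one person, one task, two alternatives, beta ~ N(mu, sigma^2)
  df <- data.frame(person_id = 1, task_id = 1, alt_id = c("A", "B"),
                   chosen = c(TRUE, FALSE), x = c(1, 0))
  cd <- choice_data(df, choice = "chosen")
  spec <- model_spec(list(coef_spec("x", "normal")))
  for (pars in list(c(0, 1), c(0.5, 1.5), c(-1, 0.3))) {
    mu <- pars[1]; sigma <- pars[2]
    Pn <- simulated_person_probability(
      spec, list(x = list(mu = mu, sigma = sigma)), cd, R = 1e5, seed = 2)
    gh <- pracma::gaussHermite(80)
    oracle <- sum(gh$w / sqrt(pi) *
                    stats::plogis(mu + sigma * sqrt(2) * gh$x))
    expect_lt(abs(Pn[[1]] - oracle), 1e-3)
    # independent second oracle: adaptive quadrature
    aq <- stats::integrate(function(b) {
      stats::plogis(b) * stats::dnorm(b, mu, sigma)
    }, -Inf, Inf)$value
    expect_lt(abs(oracle - aq), 1e-6)
  }
})

test_that("RP probabilities follow the shared-error logistic form", {
  p <- rp_probabilities(0, 0, 0)
  expect_equal(p$cig, 0.5)
  expect_equal(p$ecig, 0.5)
  p <- rp_probabilities(1, 0, 0)
  expect_equal(p$cig, exp(1) / (1 + exp(1)))
  # large positive rho with sign +1 pushes both outcomes towards 1
  p <- rp_probabilities(0, 0, 40, sign = 1)
  expect_gt(p$cig, 0.999)
  expect_gt(p$ecig, 0.999)
  # sign -1 pushes them apart
  p <- rp_probabilities(0, 0, 40, sign = -1)
  expect_gt(p$cig, 0.999)
  expect_lt(p$ecig, 0.001)
})

test_that("RP person likelihood matches hand values and a quadrature
           oracle", {
  expect_equal(rp_person_likelihood(1, 0, 0, 0, 0), 0.25)
  # sigma_rho = 0 reduces to two independent logits
  expect_equal(rp_person_likelihood(1, 1, 0.5, -0.2, rep(0, 10)),
               plogis(0.5) * plogis(-0.2))
  # comovement: with large sigma, P(both) approaches 1/2
  set.seed(3)
  sig <- 50
  draws <- rnorm(2e4, 0, sig)
  p_both <- rp_person_likelihood(1, 1, 0, 0, draws)
  oracle <- stats::integrate(function(r) {
    stats::plogis(r)^2 * stats::dnorm(r, 0, sig)
  }, -Inf, Inf)$value
  expect_lt(abs(p_both - oracle), 0.01)
  expect_gt(p_both, 0.4)
})
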