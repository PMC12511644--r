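test_that("flat-taste simulation spreads choices uniformly", {
  cfg <- taste_config(
    branded = list(family = "fixed", params = list(value = 0)),
    country_CH = list(family = "fixed", params = list(value = 0)),
    country_IND = list(family = "fixed", params = list(value = 0)),
    char_fast = list(family = "fixed", params = list(value = 0)),
    char_double = list(family = "fixed", params = list(value = 0)),
    risk = list(family = "fixed", params = list(value = 0)),
    price = list(family = "fixed", params = list(value = 0)))
  sim <- simulate_drug_dce(150, 10, config = cfg, seed = 2)
  counts <- tapply(sim$data$chosen, sim$data$alt_id, sum)
  n_tasks <- 150 * 10
  se <- sqrt(0.25 * 0.75 * n_tasks)
  expect_true(all(abs(counts - n_tasks / 4) < 3 * se))
})

test_that("a dominant brand taste drives the branded share towards one", {
  cfg <- drug_taste_config()
  cfg$branded <- list(family = "fixed", params = list(value = 10))
  for (nm in setdiff(names(cfg), "branded")) {
    cfg[[nm]] <- list(family = "fixed", params = list(value = 0))
  }
  sim <- simulate_drug_dce(100, 5, config = cfg, seed = 3)
  shr <- sum(sim$data$chosen & sim$data$branded == 1) / (100 * 5)
  expect_gt(shr, 0.99)
})

test_that("the drug generator is reproducible and structurally correct", {
  a <- simulate_drug_dce(30, 4, seed = 11)
  b <- simulate_drug_dce(30, 4, seed = 11)
  expect_identical(as.data.frame(a$data), as.data.frame(b$data))
  expect_identical(a$truth$tastes, b$truth$tastes)
  expect_equal(nrow(a$data), 30 * 4 * 4)
  expect_equal(attr(a$data, "alt_groups"),
               list(branded = c("B1", "B2"), unbranded = c("G1", "G2")))
  # the bimodal truth density really is bimodal
  grid <- seq(-5, 4, length.out = 400)
  dens <- true_density(a$truth$config, "branded", grid)
  peaks <- which(diff(sign(diff(dens))) < 0) + 1
  expect_equal(length(peaks), 2)
})

test_that("observed branded share matches the share implied by
           integrating MNL probabilities over the truth", {
  n <- 600; TT <- 10
  sim <- simulate_drug_dce(n, TT, seed = 17)
  d <- as.data.frame(sim$data)
  tastes <- sim$truth$tastes
  # integration oracle: the generator's own tastes are the quadrature
  # points; average the branded-alternative MNL probability per task
  V <- rowSums(as.matrix(d[colnames(tastes)]) *
                 tastes[as.integer(d$person_id), , drop = FALSE])
  key <- paste(d$person_id, d$task_id)
  pb <- vapply(split(seq_len(nrow(d)), key), function(idx) {
    p <- mnl_probabilities(V[idx])
    sum(p[d$branded[idx] == 1])
  }, numeric(1))
  expected <- mean(pb)
  observed <- sum(d$chosen & d$branded == 1) / (n * TT)
  se <- sqrt(expected * (1 - expected) / (n * TT))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("generic DCE choice shares match a quadrature oracle under a
           normal taste", {
  cfg <- taste_config(x = list(family = "normal",
                               params = list(mu = 1, sigma = 1)))
  n <- 800; TT <- 4
  sim <- simulate_generic_dce(cfg, n, TT, one_coef_design(), seed = 23)
  d <- as.data.frame(sim$data)
  # share of tasks where the x = 1 alternative beats x = 0, averaged over
  # the mixing distribution by adaptive quadrature, conditional on the
  # realized share of (1, 0) vs other task compositions
  key <- paste(d$person_id, d$task_id)
  comp <- tapply(d$x, key, function(x) paste(sort(x), collapse = ","))
  target <- names(comp)[comp == "0,1"]
  dd <- d[key %in% target, ]
  p_hi <- stats::integrate(function(b) {
    stats::plogis(b) * stats::dnorm(b, 1, 1)
  }, -Inf, Inf)$value
  chose_hi <- dd$chosen[dd$x == 1]
  se <- sqrt(p_hi * (1 - p_hi) / length(chose_hi))
  expect_lt(abs(mean(chose_hi) - p_hi), 3 * se)
})

test_that("generic DCE respects panel dimensions, determinism and opt-out
           conventions", {
  cfg <- taste_config(x = list(family = "normal",
                               params = list(mu = 0.5, sigma = 0.5)))
  des <- list(n_alts = 3, attributes = list(x = c(0, 1, 2)), opt_out = 3)
  s1 <- simulate_generic_dce(cfg, 10, 1, des, seed = 4)
  expect_equal(length(unique(paste(s1$data$person_id, s1$data$task_id))), 10)
  s2 <- simulate_generic_dce(cfg, 10, 1, des, seed = 4)
  expect_identical(as.data.frame(s1$data), as.data.frame(s2$data))
  expect_true(all(s1$data$x[s1$data$alt_id == "alt3"] == 0))
  expect_error(simulate_generic_dce(cfg, 5, 2,
                                    list(n_alts = 2,
                                         attributes = list(z = 0:1)),
                                    seed = 1),
               "without a design column")
})

test_that("correlated binary outcomes show the association the error
           component implies", {
  # independence at sigma_rho = 0
  d0 <- simulate_rp_binary(4000, intercepts = c(cig = 0, ecig = 0),
                           sigma_rho = 0, seed = 31)
  tab <- table(d0$cig, d0$ecig)
  or0 <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(log(or0)), 3 * sqrt(sum(1 / tab)))
  # strong association at large sigma_rho, against a quadrature oracle
  sig <- 3
  d1 <- simulate_rp_binary(4000, intercepts = c(cig = 0, ecig = 0),
                           sigma_rho = sig, seed = 32)
  tab1 <- table(d1$cig, d1$ecig)
  or1 <- (tab1[1, 1] * tab1[2, 2]) / (tab1[1, 2] * tab1[2, 1])
  expect_gt(or1, 5)
  p11 <- stats::integrate(function(r) {
    stats::plogis(r)^2 * stats::dnorm(r, 0, sig)
  }, -Inf, Inf)$value
  expect_lt(abs(mean(d1$cig & d1$ecig) - p11),
            3 * sqrt(p11 * (1 - p11) / 4000))
})

test_that("intercepts solved for target shares reproduce the RP sample
           composition", {
  shares <- c(cig = (1038 + 619) / 2031, ecig = (148 + 619) / 2031)
  ic <- c(cig = rp_intercept_for_share(shares[["cig"]], 0.8),
          ecig = rp_intercept_for_share(shares[["ecig"]], 0.8))
  dat <- simulate_rp_binary(6000, intercepts = ic, sigma_rho = 0.8,
                            seed = 33)
  expect_lt(abs(mean(dat$cig) - shares[["cig"]]),
            3 * sqrt(0.25 / 6000) * 2)
  expect_lt(abs(mean(dat$ecig) - shares[["ecig"]]),
            3 * sqrt(0.25 / 6000) * 2)
})

test_that("true densities are proper densities", {
  cfg <- drug_taste_config()
  for (nm in c("branded", "country_CH", "char_fast", "char_double")) {
    total <- stats::integrate(function(x) true_density(cfg, nm, x),
                              -10, 10, subdivisions = 2000L,
                              stop.on.error = FALSE)$value
    expect_lt(abs(total - 1), 1e-4)
  }
  expect_equal(true_density(taste_config(
    z = list(family = "normal", params = list(mu = 0, sigma = 1))),
    "z", 0), stats::dnorm(0))
  mix <- taste_config(z = list(family = "normal_mixture",
                               params = list(w = c(0.5, 0.5),
                                             mean = c(-2, 2),
                                             sd = c(0.5, 0.5))))
  expect_equal(true_density(mix, "z", 0),
               0.5 * stats::dnorm(0, -2, 0.5) + 0.5 * stats::dnorm(0, 2, 0.5))
  expect_error(true_density(mix, "missing", 0), "no config entry")
})
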