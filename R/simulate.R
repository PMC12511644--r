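# Synthetic choice data: drug-choice DCE, generic DCE, correlated binary
# outcomes. Every generator routes all randomness through one master seed
# with fixed substreams (tastes, attribute levels, choices).

#' Define true taste distributions for simulation
#'
#' A named list, one entry per coefficient, each with a mixing
#' \code{family} (any of [mixing_families()] plus
#' \code{"normal_mixture"}) and its \code{params}. Log-family entries may
#' carry a \code{sign} inside \code{params} (default -1).
#'
#' @param ... named entries \code{name = list(family = , params = )}.
#' @return A \code{taste_config} object.
#' @export
taste_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.null(names(cfg)) && is.list(cfg[[1]]) &&
      !is.null(names(cfg[[1]])) && !"family" %in% names(cfg[[1]])) {
    cfg <- cfg[[1]]
  }
  for (nm in names(cfg)) {
    entry <- cfg[[nm]]
    if (is.null(entry$family) || is.null(entry$params)) {
      stop("taste entry '", nm, "' needs 'family' and 'params'",
           call. = FALSE)
    }
    if (entry$family == "normal_mixture") {
      w <- entry$params$w
      if (abs(sum(w) - 1) > 1e-8) {
        stop("mixture weights must sum to 1 for '", nm, "'", call. = FALSE)
      }
    }
  }
  structure(cfg, class = "taste_config")
}

#' Default true tastes for the simulated drug-choice study
#'
#' The frozen generating distributions for [simulate_drug_dce()]: a
#' bimodal (two-component normal mixture) taste for branded products,
#' normal tastes for country of production, triangular and uniform tastes
#' for the drug characteristic levels, and strictly negative log-normal
#' tastes for side-effect risk and price. Values are fixed, documented
#' choices; they are recorded in every truth file the simulator writes.
#'
#' @return A \code{taste_config}.
#' @export
drug_taste_config <- function() {
  taste_config(
    branded = list(family = "normal_mixture",
                   params = list(w = c(0.5, 0.5), mean = c(-2.5, 1.5),
                                 sd = c(0.5, 0.5))),
    country_CH = list(family = "normal", params = list(mu = 1, sigma = 0.5)),
    country_IND = list(family = "normal",
                       params = list(mu = -0.8, sigma = 0.5)),
    char_fast = list(family = "triangular",
                     params = list(a = -0.25, b = 0.5)),
    char_double = list(family = "uniform", params = list(a = 0, b = 1)),
    risk = list(family = "lognormal",
                params = list(mu = log(0.1), sigma = 0.5, sign = -1)),
    price = list(family = "lognormal",
                 params = list(mu = log(0.4), sigma = 0.5, sign = -1))
  )
}

# sample one taste vector per person per coefficient
.sample_tastes <- function(config, n) {
  tastes <- sapply(names(config), function(nm) {
    entry <- config[[nm]]
    mixing_sample(entry$family, entry$params, n)
  })
  matrix(tastes, nrow = n,
         dimnames = list(NULL, names(config)))
}

# choices by comparing a single U[0,1] draw per task to the cumulative MNL
# probabilities
.draw_choices <- function(V, task_of_row) {
  n_tasks <- max(task_of_row)
  u <- stats::runif(n_tasks)
  chosen <- logical(length(V))
  for (t in seq_len(n_tasks)) {
    idx <- which(task_of_row == t)
    p <- mnl_probabilities(V[idx])
    pick <- idx[which(cumsum(p) >= u[t])[1]]
    chosen[pick] <- TRUE
  }
  chosen
}

#' Simulate a generic discrete choice experiment
#'
#' Tastes are drawn once per person from the true distributions; attribute
#' levels are assigned to alternatives by independent uniform sampling
#' over the level grids; choices are generated by comparing a U[0,1] draw
#' per task to the cumulative MNL probabilities implied by the true
#' utilities.
#'
#' @param config a [taste_config()]; entry names must match attribute
#'   names.
#' @param n_persons,n_tasks panel dimensions.
#' @param design list with \code{n_alts}; optional \code{alt_labels},
#'   \code{attributes} (named list of level grids, sampled per row),
#'   \code{alt_attributes} (named list of length-\code{n_alts} vectors,
#'   constant per alternative, e.g. brand indicators), \code{opt_out}
#'   (index of an alternative whose attributes are all zero) and
#'   \code{alt_groups}.
#' @param seed master seed.
#' @return List with \code{data} (a \code{choice_data}) and \code{truth}
#'   (the config, the per-person taste matrix and the seed).
#' @export
simulate_generic_dce <- function(config, n_persons, n_tasks, design,
                                 seed = 1L) {
  stopifnot(inherits(config, "taste_config"))
  J <- design$n_alts
  alt_labels <- design$alt_labels
  if (is.null(alt_labels)) alt_labels <- paste0("alt", seq_len(J))
  attr_names <- c(names(design$attributes), names(design$alt_attributes))
  miss <- setdiff(names(config), attr_names)
  if (length(miss)) {
    stop("config coefficient(s) without a design column: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  set.seed(as.integer(seed))          # substream: tastes
  tastes <- .sample_tastes(config, n_persons)

  n_rows <- n_persons * n_tasks * J
  df <- data.frame(
    person_id = rep(seq_len(n_persons), each = n_tasks * J),
    task_id = rep(rep(seq_len(n_tasks), each = J), times = n_persons),
    alt_id = rep(alt_labels, times = n_persons * n_tasks),
    stringsAsFactors = FALSE
  )
  set.seed(as.integer(seed) + 1L)     # substream: attribute levels
  for (a in names(design$attributes)) {
    df[[a]] <- sample(design$attributes[[a]], n_rows, replace = TRUE)
  }
  for (a in names(design$alt_attributes)) {
    df[[a]] <- rep(design$alt_attributes[[a]], times = n_persons * n_tasks)
  }
  if (!is.null(design$opt_out)) {
    oo <- df$alt_id == alt_labels[design$opt_out]
    for (a in attr_names) df[[a]][oo] <- 0
  }

  X <- as.matrix(df[names(config)])
  person_of_row <- df$person_id
  V <- rowSums(X * tastes[person_of_row, , drop = FALSE])
  task_of_row <- (df$person_id - 1L) * n_tasks + df$task_id
  set.seed(as.integer(seed) + 2L)     # substream: choices
  df$chosen <- .draw_choices(V, task_of_row)

  data <- choice_data(df, choice = "chosen",
                      attributes = attr_names,
                      alt_groups = design$alt_groups)
  list(data = data,
       truth = list(config = config, tastes = tastes,
                    seed = as.integer(seed)))
}

#' Simulate the drug-choice experiment
#'
#' A stated-preference-style panel: each person faces \code{n_tasks}
#' tasks of 4 alternatives (2 branded, 2 unbranded) described by country
#' of production (USA reference, Switzerland, India; dummy coded), drug
#' characteristic (standard reference, fast acting, double strength;
#' dummy coded), side-effect risk (percent, continuous) and price
#' (currency units, continuous). Tastes come from [drug_taste_config()]
#' by default, with a bimodal branded taste; choices are generated by the
#' same U[0,1]-versus-cumulative-MNL rule as [simulate_generic_dce()].
#'
#' @param n_persons,n_tasks panel dimensions (defaults 1000 and 10).
#' @param config a [taste_config()] covering \code{branded},
#'   \code{country_CH}, \code{country_IND}, \code{char_fast},
#'   \code{char_double}, \code{risk}, \code{price}.
#' @param seed master seed.
#' @param risk_levels,price_levels attribute level grids.
#' @return List with \code{data} and \code{truth} as in
#'   [simulate_generic_dce()].
#' @export
simulate_drug_dce <- function(n_persons = 1000, n_tasks = 10,
                              config = drug_taste_config(), seed = 1L,
                              risk_levels = c(1, 5, 10, 15),
                              price_levels = c(1, 2, 3, 4, 5)) {
  needed <- c("branded", "country_CH", "country_IND", "char_fast",
              "char_double", "risk", "price")
  miss <- setdiff(needed, names(config))
  if (length(miss)) {
    stop("config is missing coefficient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  J <- 4L
  alt_labels <- c("B1", "B2", "G1", "G2")
  set.seed(as.integer(seed))          # substream: tastes
  tastes <- .sample_tastes(config, n_persons)

  n_rows <- n_persons * n_tasks * J
  df <- data.frame(
    person_id = rep(seq_len(n_persons), each = n_tasks * J),
    task_id = rep(rep(seq_len(n_tasks), each = J), times = n_persons),
    alt_id = rep(alt_labels, times = n_persons * n_tasks),
    branded = rep(c(1, 1, 0, 0), times = n_persons * n_tasks),
    stringsAsFactors = FALSE
  )
  set.seed(as.integer(seed) + 1L)     # substream: attribute levels
  country <- sample(c("USA", "CH", "IND"), n_rows, replace = TRUE)
  charac <- sample(c("standard", "fast", "double"), n_rows, replace = TRUE)
  df$country_CH <- as.numeric(country == "CH")
  df$country_IND <- as.numeric(country == "IND")
  df$char_fast <- as.numeric(charac == "fast")
  df$char_double <- as.numeric(charac == "double")
  df$risk <- sample(risk_levels, n_rows, replace = TRUE)
  df$price <- sample(price_levels, n_rows, replace = TRUE)

  X <- as.matrix(df[needed])
  V <- rowSums(X * tastes[df$person_id, needed, drop = FALSE])
  task_of_row <- (df$person_id - 1L) * n_tasks + df$task_id
  set.seed(as.integer(seed) + 2L)     # substream: choices
  df$chosen <- .draw_choices(V, task_of_row)

  data <- choice_data(df, choice = "chosen", attributes = needed,
                      alt_groups = list(branded = c("B1", "B2"),
                                        unbranded = c("G1", "G2")))
  list(data = data,
       truth = list(config = config, tastes = tastes,
                    seed = as.integer(seed)))
}

#' Simulate correlated binary product-use outcomes
#'
#' Per person, an error component \eqn{\rho \sim N(0, \sigma_\rho^2)} is
#' drawn once and the two outcomes are Bernoulli with probabilities
#' \eqn{\Lambda(V_{cig} + \rho)} and \eqn{\Lambda(V_{ecig} + s\rho)}, so
#' \eqn{\sigma_\rho > 0} with \eqn{s = +1} induces positive association
#' between the outcomes.
#'
#' @param n persons.
#' @param intercepts named vector \code{c(cig = , ecig = )}.
#' @param gamma optional list \code{list(cig = , ecig = )} of named
#'   covariate effect vectors.
#' @param sigma_rho error-component standard deviation (>= 0).
#' @param sign +1 or -1 on \eqn{\rho} in the e-cigarette equation.
#' @param covariates optional data.frame of person covariates.
#' @param seed master seed.
#' @return A \code{binary_panel}; the truth (parameters and seed) is
#'   attached as attribute \code{"truth"}.
#' @export
simulate_rp_binary <- function(n, intercepts = c(cig = 0, ecig = 0),
                               gamma = NULL, sigma_rho = 0, sign = 1,
                               covariates = NULL, seed = 1L) {
  if (sigma_rho < 0) stop("sigma_rho must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  rho <- stats::rnorm(n, 0, sigma_rho)
  Vc <- rep(intercepts[["cig"]], n)
  Ve <- rep(intercepts[["ecig"]], n)
  if (!is.null(gamma)) {
    Z <- as.matrix(covariates)
    if (length(gamma$cig)) {
      Vc <- Vc + drop(Z[, names(gamma$cig), drop = FALSE] %*% gamma$cig)
    }
    if (length(gamma$ecig)) {
      Ve <- Ve + drop(Z[, names(gamma$ecig), drop = FALSE] %*% gamma$ecig)
    }
  }
  p <- rp_probabilities(Vc, Ve, rho, sign)
  df <- data.frame(person_id = seq_len(n),
                   cig = stats::rbinom(n, 1, p$cig),
                   ecig = stats::rbinom(n, 1, p$ecig))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  out <- binary_panel(df)
  attr(out, "truth") <- list(intercepts = intercepts, gamma = gamma,
                             sigma_rho = sigma_rho, sign = sign,
                             seed = as.integer(seed))
  out
}

#' Exact-composition product-use panel
#'
#' Deterministic binary panel with the given cell counts for (cigarette
#' only, e-cigarette only, both, neither) — the composition reported for
#' the motivating revealed-preference sample is 1,038 / 148 / 619 / 226
#' of N = 2,031.
#'
#' @param n_cig_only,n_ecig_only,n_dual,n_neither cell counts.
#' @return A \code{binary_panel}.
#' @export
rp_composition_data <- function(n_cig_only = 1038, n_ecig_only = 148,
                                n_dual = 619, n_neither = 226) {
  df <- data.frame(
    person_id = seq_len(n_cig_only + n_ecig_only + n_dual + n_neither),
    cig = rep(c(1, 0, 1, 0), c(n_cig_only, n_ecig_only, n_dual, n_neither)),
    ecig = rep(c(0, 1, 1, 0), c(n_cig_only, n_ecig_only, n_dual, n_neither))
  )
  binary_panel(df)
}

#' Intercept reproducing a target outcome share
#'
#' Solves \eqn{E_\rho[\Lambda(a + \rho)] = share} for the intercept
#' \eqn{a} given the error-component standard deviation, by adaptive
#' quadrature over \eqn{\rho}.
#'
#' @param share target marginal probability in (0, 1).
#' @param sigma_rho error-component standard deviation.
#' @return Scalar intercept.
#' @export
rp_intercept_for_share <- function(share, sigma_rho = 0) {
  stopifnot(share > 0, share < 1)
  if (sigma_rho < 1e-12) return(stats::qlogis(share))
  f <- function(a) {
    stats::integrate(function(r) {
      stats::plogis(a + r) * stats::dnorm(r, 0, sigma_rho)
    }, -Inf, Inf)$value - share
  }
  stats::uniroot(f, c(-50, 50))$root
}

#' True density of a generating taste distribution
#'
#' Exact density of one coefficient's generating distribution on a grid,
#' for overlay and recovery analyses. Families without a closed form
#' (the polynomial expansions) raise an error.
#'
#' @param config a [taste_config()].
#' @param coefficient entry name.
#' @param grid numeric grid.
#' @return Numeric vector of density values.
#' @export
true_density <- function(config, coefficient, grid) {
  entry <- config[[coefficient]]
  if (is.null(entry)) {
    stop("no config entry for coefficient: ", coefficient, call. = FALSE)
  }
  mixing_density(entry$family, entry$params, grid)
}
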