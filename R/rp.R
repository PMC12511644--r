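# Bivariate revealed-preference logit with a shared individual error
# component.

#' Outcome probabilities of the correlated bivariate logit
#'
#' \eqn{P_{cig} = \Lambda(V_{cig} + \rho)} and
#' \eqn{P_{ecig} = \Lambda(V_{ecig} + s\rho)} where \eqn{\Lambda} is the
#' logistic function and \eqn{s = \pm 1} selects the direction of the
#' correlation the error component induces.
#'
#' @param V_cig,V_ecig deterministic utilities (scalars, vectors or
#'   matrices).
#' @param rho error-component value(s), conformable with the utilities.
#' @param sign +1 or -1.
#' @return List with elements \code{cig} and \code{ecig}.
#' @export
rp_probabilities <- function(V_cig, V_ecig, rho, sign = 1) {
  list(cig = stats::plogis(V_cig + rho),
       ecig = stats::plogis(V_ecig + sign * rho))
}

#' Simulated person likelihood for the bivariate logit
#'
#' Average over error-component draws of
#' \eqn{P_{cig}^{c}(1-P_{cig})^{1-c} P_{ecig}^{e}(1-P_{ecig})^{1-e}}.
#' (The complement enters the final factor so that the expression is a
#' probability for non-users of e-cigarettes.)
#'
#' @param c_n,e_n 0/1 outcomes.
#' @param V_cig,V_ecig deterministic utilities (scalars).
#' @param rho_draws vector of error-component draws.
#' @param sign +1 or -1 on \eqn{\rho} in the e-cigarette equation.
#' @return Scalar simulated probability, floored at 1e-300.
#' @export
rp_person_likelihood <- function(c_n, e_n, V_cig, V_ecig, rho_draws,
                                 sign = 1) {
  stopifnot(c_n %in% 0:1, e_n %in% 0:1)
  p <- rp_probabilities(V_cig, V_ecig, rho_draws, sign)
  f <- p$cig^c_n * (1 - p$cig)^(1 - c_n) *
    p$ecig^e_n * (1 - p$ecig)^(1 - e_n)
  max(mean(f), 1e-300)
}

# rho draws: one MLHS standard-normal dimension per person (R = 1 row of
# zeros when no error component is present)
.rp_draws <- function(n, R, seed, error_component) {
  if (!error_component) return(matrix(0, n, 1))
  u <- mlhs(n, 1, R, seed)$values
  eps <- .Machine$double.eps
  matrix(stats::qnorm(pmin(pmax(u[, 1, ], eps), 1 - eps)), n, R)
}

.rp_param_names <- function(spec) {
  nm <- c("asc_cig",
          if (length(spec$cig_covariates))
            paste0("cig.", spec$cig_covariates),
          "asc_ecig",
          if (length(spec$ecig_covariates))
            paste0("ecig.", spec$ecig_covariates))
  if (spec$error_component) nm <- c(nm, "log_sigma_rho")
  nm
}

.rp_utilities <- function(spec, data, theta) {
  n_c <- length(spec$cig_covariates)
  n_e <- length(spec$ecig_covariates)
  Vc <- rep(theta[1], nrow(data))
  if (n_c) {
    Zc <- as.matrix(as.data.frame(data)[spec$cig_covariates])
    Vc <- Vc + drop(Zc %*% theta[1 + seq_len(n_c)])
  }
  Ve <- rep(theta[n_c + 2], nrow(data))
  if (n_e) {
    Ze <- as.matrix(as.data.frame(data)[spec$ecig_covariates])
    Ve <- Ve + drop(Ze %*% theta[n_c + 2 + seq_len(n_e)])
  }
  list(Vc = Vc, Ve = Ve)
}

.rp_negll <- function(theta, spec, data, rho_base) {
  V <- .rp_utilities(spec, data, theta)
  rho <- if (spec$error_component) exp(theta[length(theta)]) * rho_base
         else rho_base
  Pc <- stats::plogis(V$Vc + rho)
  Pe <- stats::plogis(V$Ve + spec$sign * rho)
  f <- Pc^data$cig * (1 - Pc)^(1 - data$cig) *
    Pe^data$ecig * (1 - Pe)^(1 - data$ecig)
  Pn <- pmax(rowMeans(f), 1e-300)
  -sum(log(Pn))
}

#' Fit the bivariate revealed-preference logit
#'
#' Maximum simulated likelihood over intercepts, covariate effects and
#' (optionally) the error-component standard deviation
#' \eqn{\sigma_\rho \ge 0} (normal error component, log-parameterized).
#' The default R = 100 draws reflects the instability such models show at
#' higher draw counts on sparse binary outcomes.
#'
#' @param spec an [rp_spec()].
#' @param data a \code{binary_panel}.
#' @param R error-component draws per person.
#' @param seed draw seed.
#' @param start optional start vector.
#' @param control passed to [stats::optim()].
#' @param hessian compute the covariance?
#' @return An \code{rp_fit} with estimates (natural scale), covariance,
#'   LL, AIC/BIC, person likelihoods \code{Pn} and the draw-averaged
#'   outcome probabilities per person.
#' @export
fit_rp <- function(spec, data, R = 100, seed = 1L, start = NULL,
                   control = list(), hessian = TRUE) {
  stopifnot(inherits(spec, "rp_spec"), inherits(data, "binary_panel"))
  miss <- setdiff(c(spec$cig_covariates, spec$ecig_covariates), names(data))
  if (length(miss)) {
    stop("covariate(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  rho_base <- .rp_draws(n, R, seed, spec$error_component)
  pn <- .rp_param_names(spec)
  if (is.null(start)) {
    start <- numeric(length(pn))
    if (spec$error_component) start[length(start)] <- log(0.5)
  }
  lower <- rep(-Inf, length(pn))
  if (spec$error_component) lower[length(lower)] <- .SCALE_FLOOR
  control <- utils::modifyList(list(maxit = 500L), control)
  negll <- function(th) .rp_negll(th, spec, data, rho_base)
  opt <- stats::optim(start, negll, method = "L-BFGS-B", lower = lower,
                      control = control)
  theta <- stats::setNames(opt$par, pn)

  # natural scale: sigma_rho = exp(log_sigma_rho)
  est <- theta
  if (spec$error_component) {
    est[length(est)] <- exp(est[length(est)])
    names(est)[length(est)] <- "sigma_rho"
  }
  cov_nat <- NULL
  se <- rep(NA_real_, length(est))
  if (hessian) {
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    cov_free <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_free) && all(is.finite(cov_free))) {
      J <- diag(length(est))
      if (spec$error_component) {
        J[length(est), length(est)] <- est[length(est)]  # d sigma / d log sigma
      }
      cov_nat <- J %*% cov_free %*% t(J)
      dimnames(cov_nat) <- list(names(est), names(est))
      se <- sqrt(pmax(diag(cov_nat), 0))
    }
  }
  names(se) <- names(est)

  V <- .rp_utilities(spec, data, opt$par)
  rho <- if (spec$error_component) est[["sigma_rho"]] * rho_base else rho_base
  Pc <- stats::plogis(V$Vc + rho)
  Pe <- stats::plogis(V$Ve + spec$sign * rho)
  f <- Pc^data$cig * (1 - Pc)^(1 - data$cig) *
    Pe^data$ecig * (1 - Pe)^(1 - data$ecig)
  Pn <- pmax(rowMeans(f), 1e-300)
  LL <- sum(log(Pn))
  k <- length(pn)

  structure(list(
    spec = spec, estimates = est, se = se, covariance = cov_nat,
    LL = LL, n_params = k, AIC = 2 * k - 2 * LL, BIC = k * log(n) - 2 * LL,
    R = ncol(rho_base), seed = as.integer(seed),
    Pn = stats::setNames(Pn, data$person_id),
    prob_cig = rowMeans(Pc), prob_ecig = rowMeans(Pe),
    n_persons = n,
    convergence = list(converged = opt$convergence == 0,
                       code = opt$convergence, message = opt$message)
  ), class = "rp_fit")
}

#' @export
logLik.rp_fit <- function(object, ...) {
  structure(object$LL, df = object$n_params, class = "logLik")
}

#' @export
coef.rp_fit <- function(object, ...) object$estimates

#' @export
print.rp_fit <- function(x, ...) {
  cat("Bivariate RP logit",
      if (x$spec$error_component) "with correlated error component", "\n")
  cat(sprintf("  N = %d, R = %d, LL = %.3f, AIC = %.2f\n",
              x$n_persons, x$R, x$LL, x$AIC))
  print(round(data.frame(estimate = x$estimates, se = x$se), 4))
  invisible(x)
}
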