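# Maximum simulated likelihood fitting for the panel mixed logit.

# replace every random family by a fixed coefficient (MNL warm-start spec)
.as_fixed_spec <- function(spec) {
  coefs <- lapply(unname(spec$coefficients), function(cf) {
    coef_spec(cf$name, "fixed", attributes = cf$attributes, sign = cf$sign)
  })
  model_spec(coefs, space = spec$space,
             price_coefficient = spec$price_coefficient)
}

# starting free parameters: MNL means, small positive scales
.start_values <- function(spec, layout, mnl_means) {
  theta <- numeric(layout$n_free)
  for (nm in names(layout$per_coef)) {
    pc <- layout$per_coef[[nm]]
    cf <- pc$spec
    m <- mnl_means[[nm]]
    th <- switch(cf$dist,
      fixed = m,
      normal = c(m, log(0.5)),
      lognormal = {
        mu0 <- if (cf$sign * m > 1e-6) log(cf$sign * m) else log(0.1)
        c(mu0, log(0.5))
      },
      uniform = c(m - 0.5, log(1)),
      loguniform = {
        a0 <- if (cf$sign * m > 1e-6) log(cf$sign * m) - 0.25 else log(0.1)
        c(a0, log(0.5))
      },
      triangular = c(m - 0.5, log(0.5)),
      asym_triangular = {
        base <- c(m - 1, log(2))
        if (cf$fix_c) base else c(base, 0)
      },
      fm2 = c(m - 0.1 / 2 - 0.1 / 3, 0.1, 0.1),
      fm3 = c(m - 0.1 / 2 - 0.1 / 3 - 0.1 / 4, 0.1, 0.1, 0.1))
    theta[pc$idx] <- th
  }
  theta
}

# central-difference jacobian of the natural-parameter vector
.natural_jacobian <- function(layout, theta, h = 1e-5) {
  f0 <- .natural_vector(layout, theta)
  J <- matrix(0, length(f0), length(theta),
              dimnames = list(names(f0), layout$free_names))
  for (j in seq_along(theta)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    J[, j] <- (.natural_vector(layout, tp) - .natural_vector(layout, tm)) /
      (2 * h)
  }
  J
}

#' Fit a panel mixed logit by maximum simulated likelihood
#'
#' Maximizes the simulated log-likelihood
#' \eqn{LL = \sum_n \ln P_n}, \eqn{P_n = \frac{1}{R}\sum_r \prod_t
#' P_{ntj^*}(\beta_r)}, over the free parameters of the mixing
#' distributions. Scale parameters are optimized on the log scale (lower
#' bound \code{log(1e-8)}, so a boundary solution represents an
#' effectively-degenerate mixing distribution). The default start is the
#' MNL estimate for each location parameter with small positive scales;
#' estimation is deterministic given \code{(seed, start, control)}.
#'
#' @param spec a [model_spec()].
#' @param data a \code{choice_data}.
#' @param R number of MLHS draws per person (500 is the conventional
#'   default; smaller values trade accuracy for speed).
#' @param seed integer seed for the MLHS draws.
#' @param start optional numeric vector of free-scale starting values.
#' @param n_starts number of starts; starts beyond the first jitter the
#'   warm start deterministically.
#' @param control passed to [stats::optim()] (\code{maxit} defaults to
#'   500).
#' @param hessian compute the Hessian-based covariance?
#' @return A \code{mixl_fit} object with natural-scale \code{estimates},
#'   delta-method \code{covariance} and \code{se}, \code{LL},
#'   \code{n_params}, \code{AIC}, \code{BIC}, person likelihoods
#'   \code{Pn}, draw-averaged per-row choice probabilities
#'   \code{row_probs}, and a \code{convergence} record (code, gradient
#'   norm, boundary flag). Non-convergence is flagged, not hidden.
#' @export
fit_msl <- function(spec, data, R = 500, seed = 1L, start = NULL,
                    n_starts = 1L, control = list(), hessian = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  prep <- .prepare_model(spec, data)
  layout <- .param_layout(spec)
  all_fixed <- all(vapply(spec$coefficients, function(cf) cf$dist == "fixed",
                          logical(1)))
  R_use <- if (all_fixed) 1L else as.integer(R)
  draws <- .spec_draws(spec, prep$n_persons, R_use, seed)
  # factr 1e8 stops once the simulated LL is flat to ~1e-7 relative — well
  # below simulation noise at practical R — and keeps flexible (FM) fits,
  # whose likelihood is nearly flat in reflection-equivalent directions,
  # from spinning on negligible improvements
  control <- utils::modifyList(list(maxit = 1000L, factr = 1e8), control)

  if (is.null(start)) {
    if (all_fixed) {
      start <- numeric(layout$n_free)
      if (spec$space == "wtp") {
        p_idx <- layout$per_coef[[spec$price_coefficient]]$idx
        start[p_idx] <- -0.1
      }
    } else {
      mnl <- fit_msl(.as_fixed_spec(spec), data, R = 1, seed = seed,
                     control = control, hessian = FALSE)
      mnl_means <- as.list(stats::setNames(
        mnl$estimates_free, names(spec$coefficients)))
      start <- .start_values(spec, layout, mnl_means)
    }
  }

  ones <- matrix(1, prep$n_persons, R_use)
  cache <- new.env(parent = emptyenv())
  evalf <- function(th) {
    if (is.null(cache$th) || !identical(cache$th, th)) {
      cache$res <- .msl_eval(th, layout, spec, prep, draws, R_use,
                             want_grad = TRUE, ones = ones)
      cache$th <- th
    }
    cache$res
  }
  negll <- function(th) evalf(th)$negll
  gradf <- function(th) evalf(th)$grad
  lower <- .lower_bounds(layout)

  best <- NULL
  set.seed(as.integer(seed) + 1L)
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1L) start else start + stats::rnorm(length(start), 0, 0.5)
    th0 <- pmax(th0, lower + 1e-6)
    opt <- tryCatch(
      stats::optim(th0, negll, gradf, method = "L-BFGS-B", lower = lower,
                   control = control),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)
  opt <- best
  theta <- opt$par

  gr <- gradf(theta)
  at_boundary <- any(layout$is_scale & theta <= .SCALE_FLOOR + 1e-4)

  cov_nat <- NULL
  se <- rep(NA_real_, layout$n_free)
  if (hessian) {
    # Hessian as the central-difference jacobian of the analytic gradient
    p <- length(theta)
    H <- matrix(NA_real_, p, p)
    for (j in seq_len(p)) {
      h <- 1e-5 * max(1, abs(theta[j]))
      tp <- tm <- theta
      tp[j] <- tp[j] + h
      tm[j] <- tm[j] - h
      H[, j] <- (gradf(tp) - gradf(tm)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    cov_free <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_free) && all(is.finite(cov_free))) {
      J <- .natural_jacobian(layout, theta)
      cov_nat <- J %*% cov_free %*% t(J)
      se <- sqrt(pmax(diag(cov_nat), 0))
    }
  }

  natural <- .free_to_natural(layout, theta)
  est_nat <- .natural_vector(layout, theta)
  if (!is.null(cov_nat)) dimnames(cov_nat) <- list(names(est_nat), names(est_nat))
  names(se) <- names(est_nat)

  res <- msl_core(.assemble_B(.effective_mats(
                    spec, .coef_mats(spec, natural, draws,
                                     prep$n_persons, R_use)),
                    prep$n_persons, R_use),
                  prep$n_persons, R_use, ncol(prep$X), prep$Xt,
                  prep$task_start, prep$task_len, prep$task_person,
                  prep$chosen_row, prep$avail, TRUE, FALSE)
  LL <- sum(log(res$Pn))
  k <- layout$n_free
  N <- prep$n_persons

  structure(list(
    spec = spec, layout = layout,
    estimates = est_nat, estimates_free = stats::setNames(theta, layout$free_names),
    natural = natural, covariance = cov_nat, se = se,
    LL = LL, n_params = k,
    AIC = 2 * k - 2 * LL, BIC = k * log(N) - 2 * LL,
    R = R_use, seed = as.integer(seed),
    Pn = stats::setNames(res$Pn, prep$persons),
    row_probs = res$row_probs,
    prep = prep, n_persons = N,
    alt_groups = attr(data, "alt_groups"),
    convergence = list(converged = opt$convergence == 0,
                       code = opt$convergence,
                       message = opt$message,
                       grad_norm = sqrt(sum(gr^2)),
                       boundary = at_boundary)
  ), class = "mixl_fit")
}

#' Information criteria of a fitted model
#'
#' \eqn{AIC = 2k - 2LL} and \eqn{BIC = k\ln N - 2LL} with \eqn{N} the
#' number of persons.
#'
#' @param fitted a \code{mixl_fit}, \code{rp_fit} or \code{model_average}.
#' @return Named vector \code{c(AIC, BIC)} (\code{model_average} objects
#'   report the conservative AIC only).
#' @export
information_criteria <- function(fitted) {
  if (inherits(fitted, "model_average")) {
    return(c(AIC = fitted$AIC, BIC = NA_real_))
  }
  c(AIC = fitted$AIC, BIC = fitted$BIC)
}

#' @export
logLik.mixl_fit <- function(object, ...) {
  structure(object$LL, df = object$n_params, class = "logLik")
}

#' @export
coef.mixl_fit <- function(object, ...) object$estimates

#' @export
vcov.mixl_fit <- function(object, ...) object$covariance

#' @export
print.mixl_fit <- function(x, ...) {
  cat("Panel mixed logit (maximum simulated likelihood)\n")
  fams <- vapply(x$spec$coefficients, `[[`, character(1), "dist")
  cat("  space:", x$spec$space, "  families:",
      paste(unique(fams), collapse = "/"), "\n")
  cat(sprintf("  N = %d persons, R = %d draws, seed = %d\n",
              x$n_persons, x$R, x$seed))
  cat(sprintf("  LL = %.3f  k = %d  AIC = %.2f  BIC = %.2f\n",
              x$LL, x$n_params, x$AIC, x$BIC))
  if (!x$convergence$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$convergence$boundary) cat("  note: scale parameter at boundary\n")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.mixl_fit <- function(object, ...) {
  z <- object$estimates / object$se
  data.frame(estimate = object$estimates, se = object$se, z = z,
             p = 2 * stats::pnorm(-abs(z)))
}
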