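# Sequential latent-class model averaging over fitted models.

#' Fit a sequential latent-class model average
#'
#' Treats K already-fitted models as latent classes whose person-level
#' likelihood contributions \eqn{P_{nk}} are frozen, and estimates only
#' the class-membership (weight) parameters \eqn{\theta_k} of the
#' logistic weights \eqn{\pi_k = e^{\theta_k} / \sum_j e^{\theta_j}},
#' maximizing \eqn{LL_{MA} = \sum_n \ln \sum_k \pi_k P_{nk}}.
#' \eqn{\theta_1} is fixed at 0 for identification; the remaining
#' \eqn{\theta_k} are capped at \eqn{\pm 30} so degenerate (single-model)
#' averages are representable without overflow.
#'
#' @param models list of K >= 2 fitted models (\code{mixl_fit} /
#'   \code{rp_fit}), or a numeric persons-by-K matrix of person
#'   likelihoods in (0, 1].
#' @param n_params_constituents integer vector of constituent parameter
#'   counts; taken from the fit objects when \code{models} is a list.
#' @param cap bound on \eqn{|\theta_k|}.
#' @return A \code{model_average} with \code{theta}, \code{pi},
#'   \code{LL}, the conservative parameter count (all constituent
#'   parameters plus the K-1 weight parameters) and its \code{AIC}.
#' @export
fit_model_average <- function(models, n_params_constituents = NULL,
                              cap = 30) {
  if (is.matrix(models)) {
    P <- models
    fits <- NULL
    if (is.null(n_params_constituents)) {
      n_params_constituents <- rep(0L, ncol(P))
    }
  } else {
    fits <- models
    P <- do.call(cbind, lapply(fits, function(f) f$Pn))
    if (is.null(n_params_constituents)) {
      n_params_constituents <- vapply(fits, function(f) f$n_params,
                                      numeric(1))
    }
    if (!is.null(names(fits))) colnames(P) <- names(fits)
  }
  K <- ncol(P)
  if (K < 2) stop("model averaging needs K >= 2 constituents", call. = FALSE)
  if (!all(is.finite(P)) || any(P <= 0) || any(P > 1)) {
    stop("person likelihoods must be finite and in (0, 1]", call. = FALSE)
  }
  negll <- function(th_free) {
    th <- c(0, th_free)
    pi_k <- exp(th - max(th))
    pi_k <- pi_k / sum(pi_k)
    -sum(log(pmax(drop(P %*% pi_k), 1e-300)))
  }
  # tight tolerances: the problem is tiny and downstream checks compare
  # LL_MA against the best constituent at 1e-6 resolution
  opt <- stats::optim(rep(0, K - 1), negll, method = "L-BFGS-B",
                      lower = rep(-cap, K - 1), upper = rep(cap, K - 1),
                      control = list(maxit = 2000L, factr = 10,
                                     pgtol = 1e-12))
  theta <- c(0, opt$par)
  pi_k <- exp(theta - max(theta))
  pi_k <- pi_k / sum(pi_k)
  names(theta) <- names(pi_k) <- colnames(P)
  LL <- -opt$value
  npc <- sum(n_params_constituents) + (K - 1)
  structure(list(
    theta = theta, pi = pi_k, LL = LL, K = K,
    n_params_constituents = n_params_constituents,
    n_params_conservative = npc,
    AIC = 2 * npc - 2 * LL,
    P = P, Pn = drop(P %*% pi_k),
    constituents = fits,
    at_cap = any(abs(opt$par) >= cap - 1e-6),
    convergence = list(converged = opt$convergence == 0,
                       code = opt$convergence)
  ), class = "model_average")
}

#' Averaged person probability
#'
#' \eqn{\sum_k \pi_k P_{nk}}, the model-average likelihood contribution of
#' one person (or of every person when \code{i} is \code{NULL}).
#'
#' @param ma a \code{model_average}.
#' @param i person index or \code{NULL}.
#' @return Scalar or vector in (0, 1].
#' @export
ma_person_probability <- function(ma, i = NULL) {
  stopifnot(inherits(ma, "model_average"))
  if (is.null(i)) ma$Pn else ma$Pn[i]
}

#' Conservative AIC of a model average
#'
#' Counts all parameters from all constituent models plus the K-1 weight
#' parameters: \eqn{AIC = 2(\sum_k k_k + K - 1) - 2 LL_{MA}}.
#'
#' @param ma a \code{model_average}.
#' @return Scalar AIC.
#' @export
ma_information_criterion <- function(ma) {
  stopifnot(inherits(ma, "model_average"))
  ma$AIC
}

#' Constituent-model grouping presets
#'
#' The three conventional groupings over the eight distribution tags:
#' base (S, U, T), base + extended (adding LN, LU) and the full set
#' (adding AT, FM2, FM3).
#'
#' @return Named list of character vectors of model tags.
#' @export
ma_groups <- function() {
  list(base = c("S", "U", "T"),
       extended = c("S", "U", "T", "LN", "LU"),
       all = c("S", "U", "T", "LN", "LU", "AT", "FM2", "FM3"))
}

#' @export
print.model_average <- function(x, ...) {
  cat(sprintf("Sequential latent-class model average (K = %d)\n", x$K))
  cat(sprintf("  LL = %.3f  conservative k = %d  AIC = %.2f\n",
              x$LL, x$n_params_conservative, x$AIC))
  if (x$at_cap) cat("  note: weight parameter at cap (degenerate average)\n")
  print(round(rbind(theta = x$theta, pi = x$pi), 4))
  invisible(x)
}

#' @export
logLik.model_average <- function(object, ...) {
  structure(object$LL, df = object$K - 1, class = "logLik")
}
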