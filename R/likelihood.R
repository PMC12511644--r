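#' Multinomial logit choice probabilities for one task
#'
#' Softmax of the deterministic utilities over the available alternatives
#' (type-I extreme-value errors), with max-subtraction for overflow
#' safety. Unavailable alternatives receive probability zero.
#'
#' @param V numeric vector of deterministic utilities.
#' @param available logical vector (default: all available).
#' @return Probability vector summing to one over available alternatives.
#' @export
mnl_probabilities <- function(V, available = rep(TRUE, length(V))) {
  if (!any(available)) stop("no available alternative in task", call. = FALSE)
  if (!all(is.finite(V[available]))) {
    stop("utilities must be finite", call. = FALSE)
  }
  p <- numeric(length(V))
  e <- exp(V[available] - max(V[available]))
  p[available] <- e / sum(e)
  p
}

#' Panel probability of an observed choice sequence
#'
#' Product over tasks of the chosen alternatives' probabilities,
#' \eqn{P_n = \prod_t P_{ntj^*}}.
#'
#' @param task_probs vector of chosen-alternative probabilities, one per
#'   task, each in (0, 1].
#' @return Scalar product.
#' @export
panel_probability <- function(task_probs) {
  if (!length(task_probs)) stop("empty panel", call. = FALSE)
  if (any(task_probs <= 0 | task_probs > 1)) {
    stop("task probabilities must lie in (0, 1]", call. = FALSE)
  }
  prod(task_probs)
}

# ---- internal model preparation ------------------------------------------
# Rows are assumed grouped by (person, task) — choice_data guarantees it.
# Produces the design matrix (one column per coefficient: the row sum of
# its attribute terms, stored transposed for the C++ core) and the 0-based
# grouping indices msl_core expects.
.prepare_model <- function(spec, data) {
  validate_spec(spec, data)
  coefs <- spec$coefficients
  n_rows <- nrow(data)
  X <- matrix(0, n_rows, length(coefs),
              dimnames = list(NULL, names(coefs)))
  for (k in seq_along(coefs)) {
    terms <- coefs[[k]]$attributes
    if (length(terms)) {
      X[, k] <- rowSums(as.matrix(as.data.frame(data)[terms]))
    }
  }
  persons <- unique(data$person_id)
  person0 <- match(data$person_id, persons) - 1L
  key <- paste(data$person_id, data$task_id, sep = "\r")
  task_of_row <- match(key, unique(key))
  task_start <- match(seq_len(max(task_of_row)), task_of_row) - 1L
  task_len <- as.integer(tabulate(task_of_row))
  task_person <- person0[task_start + 1L]
  chosen_row <- which(data$chosen & data$available) - 1L
  if (length(chosen_row) != length(task_start)) {
    stop("each task must have exactly one chosen available row", call. = FALSE)
  }
  list(X = X, Xt = t(X), n_persons = length(persons), persons = persons,
       person0 = person0, task_start = task_start, task_len = task_len,
       task_person = task_person, chosen_row = chosen_row,
       avail = data$available, alt_id = data$alt_id,
       n_tasks = length(task_start),
       fingerprint = c(length(persons), length(task_start), n_rows,
                       sum(X) + sum(data$chosen)))
}

# Natural coefficient matrices (n x R), one per coefficient.
.coef_mats <- function(spec, natural, draws, n_persons, R) {
  lapply(spec$coefficients, function(cf) {
    m <- transform_coefficients(cf, natural[[cf$name]],
                                draws$draws[[cf$name]],
                                n_persons = n_persons, R = R)
    if (nrow(m) == 1L && n_persons > 1L) {
      m <- matrix(m[1, ], n_persons, R, byrow = TRUE)
    }
    m
  })
}

# Effective coefficient matrices entering V: identity in preference space;
# in WTP space all non-price coefficients are multiplied by the price
# coefficient so the core stays linear in X.
.effective_mats <- function(spec, mats) {
  if (spec$space != "wtp") return(mats)
  p_nm <- spec$price_coefficient
  bp <- mats[[p_nm]]
  for (nm in names(mats)) {
    if (nm != p_nm) mats[[nm]] <- mats[[nm]] * bp
  }
  mats
}

# flatten effective matrices to the (K x n x R) layout msl_core expects
.assemble_B <- function(mats, n_persons, R) {
  K <- length(mats)
  B <- array(0, dim = c(K, n_persons, R))
  for (k in seq_len(K)) B[k, , ] <- mats[[k]]
  as.numeric(B)
}

# derivatives of one coefficient's natural beta (n x R) wrt each of its
# free parameters, in layout order; `ones` is a shared (n x R) matrix of 1s
.coef_derivs <- function(cf, nat, dr, beta_mat, theta_sub, ones) {
  switch(cf$dist,
    fixed = list(value = ones),
    normal = list(mu = ones, log_sigma = nat$sigma * dr$dN),
    lognormal = list(mu = beta_mat,
                     log_sigma = beta_mat * nat$sigma * dr$dN),
    uniform = list(a = ones, log_b = nat$b * dr$u),
    loguniform = list(a = beta_mat, log_b = beta_mat * nat$b * dr$u),
    triangular = list(a = ones, log_b = nat$b * (dr$u1 + dr$u2)),
    asym_triangular = {
      rng <- exp(theta_sub[2])
      Tn <- if (cf$fix_c) 0 else tanh(theta_sub[3])
      mode_gap_l <- (rng / 2) * (1 + Tn)   # mode - a
      mode_gap_u <- (rng / 2) * (1 - Tn)   # b - mode
      low <- dr$us < (1 + Tn) / 2
      s1 <- sqrt(dr$u1)
      s2 <- sqrt(dr$u2)
      d_range <- ifelse(low, mode_gap_l * s1, rng - mode_gap_u * s2)
      out <- list(a = ones, log_range = d_range)
      if (!cf$fix_c) {
        d_c <- (rng / 2) * (1 - Tn^2) * ifelse(low, s1, s2)
        out$c_raw <- d_c
      }
      out
    },
    fm2 = list(mu = ones, sigma1 = dr$u, sigma2 = dr$u^2),
    fm3 = list(mu = ones, sigma1 = dr$u, sigma2 = dr$u^2,
               sigma3 = dr$u^3))
}

# Joint simulated log-likelihood, analytic gradient (chain rule through
# the mixing transforms, and through the WTP product when applicable) and
# person likelihoods, evaluated in one pass.
.msl_eval <- function(theta, layout, spec, prep, draws, R,
                      want_grad = TRUE, row_probs = FALSE, ones = NULL) {
  natural <- .free_to_natural(layout, theta)
  n <- prep$n_persons
  coefs <- spec$coefficients
  K <- length(coefs)
  mats <- .coef_mats(spec, natural, draws, n, R)
  eff <- .effective_mats(spec, mats)
  res <- msl_core(.assemble_B(eff, n, R), n, R, K, prep$Xt,
                  prep$task_start, prep$task_len, prep$task_person,
                  prep$chosen_row, prep$avail, row_probs, want_grad)
  out <- list(negll = -sum(log(res$Pn)), Pn = res$Pn,
              row_probs = res$row_probs)
  if (!want_grad) return(out)
  if (is.null(ones)) ones <- matrix(1, n, R)
  w <- 1 / (R * res$Pn)
  grad <- numeric(layout$n_free)
  p_nm <- spec$price_coefficient
  wtp <- spec$space == "wtp"
  nms <- names(coefs)
  for (k in seq_len(K)) {
    cn <- nms[k]
    cf <- coefs[[cn]]
    pc <- layout$per_coef[[cn]]
    D <- .coef_derivs(cf, natural[[cn]], draws$draws[[cn]], mats[[cn]],
                      theta[pc$idx], ones)
    for (j in seq_along(pc$idx)) {
      Dj <- D[[j]]
      g <- if (!wtp) {
        msl_grad_contract(res$score, n, R, K, k - 1L, Dj, w)
      } else if (cn == p_nm) {
        # price coefficient multiplies every term in the bracket
        tot <- msl_grad_contract(res$score, n, R, K, k - 1L, Dj, w)
        for (k2 in seq_len(K)) {
          if (k2 == k) next
          tot <- tot + msl_grad_contract(res$score, n, R, K, k2 - 1L,
                                         Dj * mats[[nms[k2]]], w)
        }
        tot
      } else {
        msl_grad_contract(res$score, n, R, K, k - 1L,
                          Dj * mats[[p_nm]], w)
      }
      grad[pc$idx[j]] <- -g
    }
  }
  out$grad <- grad
  out
}

#' Simulated person-level panel probability
#'
#' Averages the panel product of chosen-alternative probabilities over the
#' draws of the random coefficients:
#' \eqn{P_n = \frac{1}{R}\sum_r \prod_t P_{ntj^*}(\beta_r)}. Probabilities
#' that underflow are floored at 1e-300. With all coefficients fixed this
#' reduces exactly to the plain MNL panel probability.
#'
#' @param spec a [model_spec()].
#' @param params named list (per coefficient) of natural-parameter lists,
#'   e.g. \code{list(price = list(value = -0.5), brand = list(mu = 1,
#'   sigma = 0.5))}.
#' @param data a \code{choice_data}.
#' @param R draws per person; ignored when all coefficients are fixed.
#' @param seed draw seed.
#' @return Named vector of person probabilities \eqn{P_n}.
#' @export
simulated_person_probability <- function(spec, params, data, R = 500,
                                         seed = 1L) {
  prep <- .prepare_model(spec, data)
  all_fixed <- all(vapply(spec$coefficients, function(cf) cf$dist == "fixed",
                          logical(1)))
  if (all_fixed) R <- 1L
  draws <- .spec_draws(spec, prep$n_persons, R, seed)
  mats <- .effective_mats(spec, .coef_mats(spec, params, draws,
                                           prep$n_persons, R))
  res <- msl_core(.assemble_B(mats, prep$n_persons, R), prep$n_persons, R,
                  ncol(prep$X), prep$Xt,
                  prep$task_start, prep$task_len, prep$task_person,
                  prep$chosen_row, prep$avail, FALSE, FALSE)
  stats::setNames(res$Pn, prep$persons)
}

#' Deterministic utilities for each data row
#'
#' Reference implementation of the linear utility. In preference space
#' \eqn{V = \sum_k \beta_k x_k}; in WTP space \eqn{V = \beta_p(price +
#' \sum_k w_k x_k)} with every non-price coefficient inside the bracket.
#'
#' @param spec a [model_spec()].
#' @param coefficients named list of scalar coefficient values (one per
#'   coefficient in the spec).
#' @param data a \code{choice_data} or data.frame with the attribute
#'   columns.
#' @return Numeric vector of utilities, one per row.
#' @export
build_utilities <- function(spec, coefficients, data) {
  coefs <- spec$coefficients
  miss <- setdiff(names(coefs), names(coefficients))
  if (length(miss)) {
    stop("missing coefficient value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  xs <- lapply(coefs, function(cf) {
    if (length(cf$attributes)) {
      rowSums(as.matrix(as.data.frame(data)[cf$attributes]))
    } else {
      rep(0, nrow(data))
    }
  })
  if (spec$space == "wtp") {
    bp <- coefficients[[spec$price_coefficient]]
    inner <- xs[[spec$price_coefficient]]
    for (nm in names(coefs)) {
      if (nm != spec$price_coefficient) {
        inner <- inner + coefficients[[nm]] * xs[[nm]]
      }
    }
    bp * inner
  } else {
    V <- rep(0, nrow(data))
    for (nm in names(coefs)) V <- V + coefficients[[nm]] * xs[[nm]]
    V
  }
}

# negative simulated log-likelihood on the free parameter scale
.msl_negll <- function(theta, layout, spec, prep, draws, R) {
  .msl_eval(theta, layout, spec, prep, draws, R, want_grad = FALSE)$negll
}
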