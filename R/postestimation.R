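# Post-estimation: sample enumeration, unconditional distributions, WTP
# means, model comparison.

#' Sample enumeration of predicted choice shares
#'
#' Averages the draw-averaged predicted choice probabilities over persons
#' and tasks, aggregated by alternative group. For a model average the
#' result is the weight-mixed enumeration of the constituents. For the
#' bivariate RP logit the enumerated quantities are the smoker /
#' non-smoker and vaper / non-vaper shares.
#'
#' @param fitted a \code{mixl_fit}, \code{model_average} or \code{rp_fit}.
#' @param grouping named list mapping group labels to alternative labels;
#'   must partition the alternatives. Defaults to the dataset's
#'   alternative-group metadata, else one group per alternative.
#' @return Named numeric vector of shares summing to one.
#' @export
sample_enumeration <- function(fitted, grouping = NULL) {
  if (inherits(fitted, "rp_fit")) {
    smoker <- mean(fitted$prob_cig)
    vaper <- mean(fitted$prob_ecig)
    return(c(smoker = smoker, nonsmoker = 1 - smoker,
             vaper = vaper, nonvaper = 1 - vaper))
  }
  if (inherits(fitted, "model_average")) {
    if (is.null(fitted$constituents)) {
      stop("model average built from a bare matrix has no enumeration",
           call. = FALSE)
    }
    shares <- lapply(fitted$constituents, sample_enumeration,
                     grouping = grouping)
    out <- Reduce(`+`, Map(`*`, shares, as.list(fitted$pi)))
    return(out)
  }
  stopifnot(inherits(fitted, "mixl_fit"))
  prep <- fitted$prep
  if (is.null(grouping)) grouping <- fitted$alt_groups
  alts <- unique(prep$alt_id)
  if (is.null(grouping)) {
    grouping <- stats::setNames(as.list(alts), alts)
  }
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, alts)) {
    stop("grouping must partition the alternatives: ",
         paste(alts, collapse = ", "), call. = FALSE)
  }
  p <- fitted$row_probs
  shares <- vapply(grouping, function(g) {
    sum(p[prep$alt_id %in% g]) / prep$n_tasks
  }, numeric(1))
  shares
}

#' Unconditional draws from fitted mixing distributions
#'
#' Samples S values from each coefficient's estimated (population-level)
#' mixing distribution. For a model average, a constituent is first drawn
#' with probabilities \eqn{\pi_k} and the value is then drawn from that
#' constituent's distribution (mixture sampling). In a WTP-space model the
#' non-price coefficients are WTP amounts, so their unconditionals are WTP
#' distributions.
#'
#' @param fitted a \code{mixl_fit} or a \code{model_average} of
#'   \code{mixl_fit}s.
#' @param S sample size (>= 1).
#' @param seed integer seed.
#' @param coefficients optional subset of coefficient names.
#' @return Named list of \code{preference_sample} objects (fields
#'   \code{name}, \code{values}, \code{source}, \code{seed}).
#' @export
sample_unconditionals <- function(fitted, S = 10000, seed = 1L,
                                  coefficients = NULL) {
  if (S < 1) stop("S must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  if (inherits(fitted, "model_average")) {
    fits <- fitted$constituents
    if (is.null(fits)) {
      stop("model average built from a bare matrix cannot be sampled",
           call. = FALSE)
    }
    nm <- coefficients
    if (is.null(nm)) nm <- names(fits[[1]]$spec$coefficients)
    comp <- sample.int(fitted$K, S, replace = TRUE, prob = fitted$pi)
    out <- lapply(nm, function(cn) {
      vals <- numeric(S)
      for (k in seq_len(fitted$K)) {
        idx <- comp == k
        if (!any(idx)) next
        cf <- fits[[k]]$spec$coefficients[[cn]]
        if (is.null(cf)) {
          stop("coefficient '", cn, "' absent from constituent ", k,
               call. = FALSE)
        }
        pars <- fits[[k]]$natural[[cn]]
        pars$sign <- cf$sign
        vals[idx] <- mixing_sample(cf$dist, pars, sum(idx))
      }
      structure(list(name = cn, values = vals, source = "model_average",
                     seed = seed), class = "preference_sample")
    })
    names(out) <- nm
    return(out)
  }
  stopifnot(inherits(fitted, "mixl_fit"))
  nm <- coefficients
  if (is.null(nm)) nm <- names(fitted$spec$coefficients)
  out <- lapply(nm, function(cn) {
    cf <- fitted$spec$coefficients[[cn]]
    pars <- fitted$natural[[cn]]
    pars$sign <- cf$sign
    structure(list(name = cn, values = mixing_sample(cf$dist, pars, S),
                   source = "single_model", seed = seed),
              class = "preference_sample")
  })
  names(out) <- nm
  out
}

#' Mean willingness to pay with confidence intervals
#'
#' For a WTP-space model, returns the analytic mean of each non-price
#' coefficient's mixing distribution with a delta-method 95\% normal-theory
#' confidence interval from the model covariance. The means are directly
#' estimated WTP amounts; no post-estimation ratio is involved.
#'
#' @param fitted a \code{mixl_fit} with \code{space = "wtp"}.
#' @param level confidence level.
#' @return data.frame with columns \code{coefficient}, \code{mean},
#'   \code{se}, \code{lower}, \code{upper} (\code{se}/CI are \code{NA}
#'   when the covariance is unavailable).
#' @export
wtp_means <- function(fitted, level = 0.95) {
  stopifnot(inherits(fitted, "mixl_fit"))
  if (fitted$spec$space != "wtp") {
    stop("wtp_means requires a WTP-space model", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  layout <- fitted$layout
  theta <- fitted$estimates_free
  Vfree <- .free_covariance(fitted)
  mean_of <- function(cn, th) {
    nat <- .free_to_natural(layout, th)[[cn]]
    cf <- fitted$spec$coefficients[[cn]]
    nat$sign <- cf$sign
    analytic_mean(cf$dist, nat)
  }
  nm <- setdiff(names(fitted$spec$coefficients), fitted$spec$price_coefficient)
  rows <- lapply(nm, function(cn) {
    m <- mean_of(cn, theta)
    se <- NA_real_
    if (!is.null(Vfree)) {
      # numeric gradient of the mean wrt the free parameters
      g <- vapply(seq_along(theta), function(j) {
        h <- 1e-5 * max(1, abs(theta[j]))
        tp <- tm <- theta
        tp[j] <- tp[j] + h
        tm[j] <- tm[j] - h
        (mean_of(cn, tp) - mean_of(cn, tm)) / (2 * h)
      }, numeric(1))
      se <- sqrt(max(drop(t(g) %*% Vfree %*% g), 0))
    }
    data.frame(coefficient = cn, mean = m, se = se,
               lower = m - z * se, upper = m + z * se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# free-scale covariance recovered from the stored natural covariance via
# the (invertible, block-diagonal) natural-parameter jacobian
.free_covariance <- function(fitted) {
  if (is.null(fitted$covariance)) return(NULL)
  J <- .natural_jacobian(fitted$layout, fitted$estimates_free)
  Ji <- tryCatch(solve(J), error = function(e) NULL)
  if (is.null(Ji)) return(NULL)
  Ji %*% fitted$covariance %*% t(Ji)
}

#' Summarize an unconditional preference sample
#'
#' Kernel density (Gaussian kernel, Silverman bandwidth) on a grid padded
#' 5\% beyond the sample range, quantiles, the probability mass above
#' zero, and the locations of local density modes. A degenerate sample
#' (zero spread) is returned as a point mass without a kernel.
#'
#' @param sample a \code{preference_sample} or numeric vector.
#' @param grid optional evaluation grid; defaults to 512 points over the
#'   padded range.
#' @param mode_prominence minimum height of a reported mode, as a fraction
#'   of the maximum density.
#' @return List with \code{type} ("density" or "point"), \code{grid},
#'   \code{density}, \code{quantiles}, \code{share_positive},
#'   \code{modes}.
#' @export
density_summary <- function(sample, grid = NULL, mode_prominence = 0.1) {
  v <- if (inherits(sample, "preference_sample")) sample$values else sample
  share_pos <- mean(v > 0)
  qs <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975))
  if (stats::sd(v) < 1e-12) {
    return(list(type = "point", value = v[1], grid = v[1], density = Inf,
                quantiles = qs, share_positive = share_pos, modes = v[1]))
  }
  pad <- 0.05 * diff(range(v))
  from <- min(v) - pad
  to <- max(v) + pad
  if (is.null(grid)) {
    d <- stats::density(v, bw = "nrd0", from = from, to = to, n = 512)
  } else {
    d0 <- stats::density(v, bw = "nrd0", from = min(grid), to = max(grid),
                         n = max(length(grid), 512))
    d <- list(x = grid, y = stats::approx(d0$x, d0$y, xout = grid,
                                          rule = 2)$y)
  }
  y <- d$y
  is_peak <- c(FALSE, diff(sign(diff(y))) < 0, FALSE) &
    y > mode_prominence * max(y)
  list(type = "density", grid = d$x, density = y, quantiles = qs,
       share_positive = share_pos, modes = d$x[is_peak])
}

#' Model-comparison table
#'
#' One row per fitted model or model average: log-likelihood, parameter
#' count, AIC and BIC, sorted by AIC ascending. All constituent fits must
#' come from the same dataset.
#'
#' @param fits named list of \code{mixl_fit} / \code{rp_fit} /
#'   \code{model_average} objects.
#' @return data.frame sorted by AIC.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "mixl_fit") || inherits(fits, "model_average") ||
      inherits(fits, "rp_fit")) {
    fits <- list(fits)
  }
  fps <- lapply(fits, function(f) {
    if (inherits(f, "mixl_fit")) f$prep$fingerprint else NULL
  })
  fps <- fps[!vapply(fps, is.null, logical(1))]
  if (length(fps) > 1) {
    same <- vapply(fps[-1], function(fp) isTRUE(all.equal(fp, fps[[1]])),
                   logical(1))
    if (!all(same)) {
      stop("models were fitted on different datasets", call. = FALSE)
    }
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  rows <- Map(function(f, n) {
    k <- if (inherits(f, "model_average")) f$n_params_conservative
         else f$n_params
    data.frame(model = n,
               LL = if (inherits(f, "model_average")) f$LL else f$LL,
               n_params = k,
               AIC = f$AIC,
               BIC = if (inherits(f, "model_average")) NA_real_ else f$BIC)
  }, fits, nm)
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC), , drop = FALSE]
  rownames(out) <- NULL
  out
}
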