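#' Transform primitive draws into person-level coefficients
#'
#' Applies the mixing-family transform to primitive draws, yielding one
#' coefficient value per person and draw:
#' \describe{
#'   \item{normal}{\eqn{\mu + \sigma d_N}}
#'   \item{uniform}{\eqn{a + b\,d_U} (support \eqn{[a, a+b]})}
#'   \item{triangular}{\eqn{a + b(d_{U1} + d_{U2})} (support
#'     \eqn{[a, a+2b]}, mode \eqn{a+b})}
#'   \item{lognormal}{\eqn{s\,e^{\mu + \sigma d_N}}}
#'   \item{loguniform}{\eqn{s\,e^{a + b\,d_U}}}
#'   \item{asym_triangular}{triangular on \eqn{[a, b]} with mode
#'     \eqn{(a+b)/2 + c}; the lower piece \eqn{a + (mode-a)\sqrt{d_{U1}}}
#'     or upper piece \eqn{b - (b-mode)\sqrt{d_{U2}}} is selected with
#'     probability proportional to each piece's triangle area}
#'   \item{fm2 / fm3}{\eqn{\mu + \sum_{p=1}^{P} \sigma_p u^p} with a single
#'     uniform \eqn{u} per person-draw}
#'   \item{fixed}{the constant \code{value}}
#' }
#'
#' @param coef a [coef_spec()].
#' @param params named list of natural parameters for the family
#'   (\code{mu}, \code{sigma}, \code{a}, \code{b}, \code{c},
#'   \code{sigma1}..., \code{value}).
#' @param draws named list of primitive matrices (persons x R) as produced
#'   internally for the family: \code{dN}, \code{u}, \code{u1}, \code{u2},
#'   \code{us}.
#' @param n_persons,R dimensions, needed only when the family consumes no
#'   draws (\code{fixed}).
#' @return Matrix (persons x R) of coefficient values.
#' @export
transform_coefficients <- function(coef, params, draws = NULL,
                                   n_persons = NULL, R = NULL) {
  fam <- coef$dist
  need <- switch(fam,
                 fixed = character(0),
                 normal = , lognormal = "dN",
                 uniform = , loguniform = , fm2 = , fm3 = "u",
                 triangular = c("u1", "u2"),
                 asym_triangular = c("u1", "u2", "us"))
  if (length(need) && !all(need %in% names(draws))) {
    stop("family '", fam, "' requires draw component(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  switch(fam,
    fixed = {
      if (is.null(n_persons)) n_persons <- 1L
      if (is.null(R)) R <- 1L
      matrix(params$value, n_persons, R)
    },
    normal = params$mu + params$sigma * draws$dN,
    lognormal = coef$sign * exp(params$mu + params$sigma * draws$dN),
    uniform = params$a + params$b * draws$u,
    loguniform = coef$sign * exp(params$a + params$b * draws$u),
    triangular = params$a + params$b * (draws$u1 + draws$u2),
    asym_triangular = {
      a <- params$a; b <- params$b
      mode <- (a + b) / 2 + params$c
      if (mode <= a || mode >= b) {
        stop("asym_triangular mode must lie strictly inside (a, b)",
             call. = FALSE)
      }
      w_lower <- (mode - a) / (b - a)
      lower <- a + (mode - a) * sqrt(draws$u1)
      upper <- b - (b - mode) * sqrt(draws$u2)
      ifelse(draws$us < w_lower, lower, upper)
    },
    fm2 = params$mu + params$sigma1 * draws$u + params$sigma2 * draws$u^2,
    fm3 = params$mu + params$sigma1 * draws$u + params$sigma2 * draws$u^2 +
      params$sigma3 * draws$u^3)
}

#' Analytic mean of a mixing distribution
#'
#' Closed-form expectation of the coefficient under each family; used for
#' WTP means and density overlays.
#'
#' @param family family tag (see [mixing_families()]) or
#'   \code{"normal_mixture"}.
#' @param params named list of natural parameters; log families also read
#'   \code{sign} (default -1).
#' @return Scalar mean.
#' @export
analytic_mean <- function(family, params) {
  sgn <- if (is.null(params$sign)) -1 else params$sign
  switch(family,
    fixed = params$value,
    normal = params$mu,
    uniform = params$a + params$b / 2,
    triangular = params$a + params$b,
    lognormal = sgn * exp(params$mu + params$sigma^2 / 2),
    loguniform = {
      if (params$b < 1e-12) sgn * exp(params$a)
      else sgn * (exp(params$a + params$b) - exp(params$a)) / params$b
    },
    asym_triangular = {
      mode <- (params$a + params$b) / 2 + params$c
      (params$a + params$b + mode) / 3
    },
    fm2 = params$mu + params$sigma1 / 2 + params$sigma2 / 3,
    fm3 = params$mu + params$sigma1 / 2 + params$sigma2 / 3 +
      params$sigma3 / 4,
    normal_mixture = sum(params$w * params$mean),
    stop("unknown family: ", family, call. = FALSE))
}

#' Density of a mixing distribution on a grid
#'
#' Exact density where a closed form exists. The polynomial families
#' \code{fm2}/\code{fm3} have no closed form and raise an error; sample
#' them with [mixing_sample()] instead.
#'
#' @inheritParams analytic_mean
#' @param x numeric grid.
#' @return Numeric vector of density values.
#' @export
mixing_density <- function(family, params, x) {
  sgn <- if (is.null(params$sign)) -1 else params$sign
  switch(family,
    normal = stats::dnorm(x, params$mu, params$sigma),
    uniform = stats::dunif(x, params$a, params$a + params$b),
    triangular = {
      a <- params$a; b <- params$b
      d <- numeric(length(x))
      i1 <- x >= a & x <= a + b
      i2 <- x > a + b & x <= a + 2 * b
      d[i1] <- (x[i1] - a) / b^2
      d[i2] <- (a + 2 * b - x[i2]) / b^2
      d
    },
    lognormal = {
      y <- sgn * x
      d <- numeric(length(x))
      ok <- y > 0
      d[ok] <- stats::dlnorm(y[ok], params$mu, params$sigma)
      d
    },
    loguniform = {
      y <- sgn * x
      d <- numeric(length(x))
      ok <- y > 0 & log(y) >= params$a & log(y) <= params$a + params$b
      d[ok] <- 1 / (params$b * y[ok])
      d
    },
    asym_triangular = {
      a <- params$a; b <- params$b
      m <- (a + b) / 2 + params$c
      d <- numeric(length(x))
      i1 <- x >= a & x <= m
      i2 <- x > m & x <= b
      d[i1] <- 2 * (x[i1] - a) / ((b - a) * (m - a))
      d[i2] <- 2 * (b - x[i2]) / ((b - a) * (b - m))
      d
    },
    normal_mixture = {
      d <- numeric(length(x))
      for (j in seq_along(params$w)) {
        d <- d + params$w[j] * stats::dnorm(x, params$mean[j], params$sd[j])
      }
      d
    },
    fixed = stop("fixed coefficient has a point-mass, not a density",
                 call. = FALSE),
    stop("no closed-form density for family: ", family, call. = FALSE))
}

#' Pseudo-random sample from a mixing distribution
#'
#' Unconditional draws from the fitted (or true) mixing distribution, used
#' for preference/WTP distribution summaries. Uses ordinary pseudo-random
#' numbers, not MLHS.
#'
#' @inheritParams analytic_mean
#' @param S sample size.
#' @return Numeric vector of length \code{S}.
#' @export
mixing_sample <- function(family, params, S) {
  if (S < 1) stop("S must be >= 1", call. = FALSE)
  sgn <- if (is.null(params$sign)) -1 else params$sign
  switch(family,
    fixed = rep(params$value, S),
    normal = stats::rnorm(S, params$mu, params$sigma),
    uniform = stats::runif(S, params$a, params$a + params$b),
    triangular = params$a + params$b * (stats::runif(S) + stats::runif(S)),
    lognormal = sgn * exp(stats::rnorm(S, params$mu, params$sigma)),
    loguniform = sgn * exp(stats::runif(S, params$a, params$a + params$b)),
    asym_triangular = {
      a <- params$a; b <- params$b
      m <- (a + b) / 2 + params$c
      wl <- (m - a) / (b - a)
      pick <- stats::runif(S) < wl
      out <- numeric(S)
      out[pick] <- a + (m - a) * sqrt(stats::runif(sum(pick)))
      out[!pick] <- b - (b - m) * sqrt(stats::runif(sum(!pick)))
      out
    },
    fm2 = {
      u <- stats::runif(S)
      params$mu + params$sigma1 * u + params$sigma2 * u^2
    },
    fm3 = {
      u <- stats::runif(S)
      params$mu + params$sigma1 * u + params$sigma2 * u^2 +
        params$sigma3 * u^3
    },
    normal_mixture = {
      j <- sample.int(length(params$w), S, replace = TRUE, prob = params$w)
      stats::rnorm(S, params$mean[j], params$sd[j])
    },
    stop("unknown family: ", family, call. = FALSE))
}

# reflection u -> 1-u leaves the fm_P coefficient distribution unchanged;
# used to compare estimates at the distribution level
.fm_mirror <- function(family, params) {
  if (family == "fm2") {
    list(mu = params$mu + params$sigma1 + params$sigma2,
         sigma1 = -(params$sigma1 + 2 * params$sigma2),
         sigma2 = params$sigma2)
  } else if (family == "fm3") {
    list(mu = params$mu + params$sigma1 + params$sigma2 + params$sigma3,
         sigma1 = -(params$sigma1 + 2 * params$sigma2 + 3 * params$sigma3),
         sigma2 = params$sigma2 + 3 * params$sigma3,
         sigma3 = -params$sigma3)
  } else {
    params
  }
}
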