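#' Mixing-distribution families
#'
#' Tags for the per-coefficient mixing families: \code{fixed} (no
#' heterogeneity), \code{normal}, \code{uniform}, \code{triangular},
#' \code{lognormal}, \code{loguniform}, \code{asym_triangular}, and the
#' polynomial expansions \code{fm2} and \code{fm3}.
#'
#' @return Character vector of family tags.
#' @export
mixing_families <- function() {
  c("fixed", "normal", "uniform", "triangular", "lognormal", "loguniform",
    "asym_triangular", "fm2", "fm3")
}

#' Specify one utility coefficient
#'
#' A coefficient multiplies the sum of the listed attribute columns (for a
#' dummy-coded level or a continuous attribute this is a single column; an
#' alternative-specific constant uses an alternative-indicator column). Its
#' taste varies across individuals according to the chosen mixing family.
#' The \code{sign} applies to the log-family transforms \code{lognormal}
#' and \code{loguniform}, whose coefficients are \code{sign * exp(...)};
#' the default \code{-1} imposes strictly negative tastes, the convention
#' for cost-like attributes.
#'
#' @param name coefficient label.
#' @param dist mixing family tag, see [mixing_families()].
#' @param attributes character vector of attribute column names the
#'   coefficient multiplies; may be empty only for constants supplied via
#'   indicator columns.
#' @param sign +1 or -1, used by the log families.
#' @param fix_c for \code{asym_triangular} only: fix the mode offset c at 0
#'   (reducing the family to 2 parameters).
#' @return A \code{coef_spec} object.
#' @export
coef_spec <- function(name, dist = "normal", attributes = name, sign = -1,
                      fix_c = FALSE) {
  dist <- match.arg(dist, mixing_families())
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  structure(list(name = name, dist = dist,
                 attributes = as.character(attributes),
                 sign = sign, fix_c = isTRUE(fix_c)),
            class = "coef_spec")
}

#' Specify a choice model
#'
#' Collects coefficient specifications and the utility space. In
#' preference space utility is linear in attributes,
#' \eqn{V = \sum_k \beta_k x_k}. In willingness-to-pay (WTP) space
#' \eqn{V = \beta_p (price + \sum_k w_k x_k)} where \eqn{\beta_p} is the
#' designated price coefficient and every non-price coefficient is
#' interpreted directly as a WTP amount (alternative-specific constants
#' included inside the bracket).
#'
#' @param coefficients list of [coef_spec()] objects.
#' @param space \code{"preference"} or \code{"wtp"}.
#' @param price_coefficient label of the price coefficient; required when
#'   \code{space = "wtp"}.
#' @return A \code{model_spec} object.
#' @export
model_spec <- function(coefficients, space = c("preference", "wtp"),
                       price_coefficient = NULL) {
  space <- match.arg(space)
  if (inherits(coefficients, "coef_spec")) coefficients <- list(coefficients)
  stopifnot(all(vapply(coefficients, inherits, logical(1), "coef_spec")))
  nm <- vapply(coefficients, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate coefficient names", call. = FALSE)
  names(coefficients) <- nm
  if (space == "wtp") {
    if (is.null(price_coefficient) || !price_coefficient %in% nm ||
        sum(nm == price_coefficient) != 1) {
      stop("wtp space requires exactly one designated price coefficient",
           call. = FALSE)
    }
  }
  structure(list(coefficients = coefficients, space = space,
                 price_coefficient = price_coefficient),
            class = "model_spec")
}

#' Specify the bivariate revealed-preference logit
#'
#' Two binary outcomes (cigarette and e-cigarette use) modelled as logits
#' sharing an individual-specific normal error component \eqn{\rho_n} that
#' induces correlation across the outcomes: probabilities are
#' \eqn{\Lambda(V_{cig} + \rho_n)} and \eqn{\Lambda(V_{ecig} + s\rho_n)}.
#' Setting \code{sign = -1} tests for negative correlation by entering
#' \eqn{-\rho_n} in the second equation.
#'
#' @param cig_covariates,ecig_covariates covariate column names entering
#'   each equation (intercepts are always included).
#' @param error_component estimate the shared error component standard
#'   deviation \eqn{\sigma_\rho}? If \code{FALSE} the outcomes are
#'   independent logits.
#' @param sign +1 or -1: sign of \eqn{\rho_n} in the e-cigarette equation.
#' @return An \code{rp_spec} object.
#' @export
rp_spec <- function(cig_covariates = character(),
                    ecig_covariates = character(),
                    error_component = TRUE, sign = 1) {
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  structure(list(cig_covariates = as.character(cig_covariates),
                 ecig_covariates = as.character(ecig_covariates),
                 error_component = isTRUE(error_component), sign = sign),
            class = "rp_spec")
}

# parameters estimated per family (asym_triangular: 3, or 2 with c fixed)
.family_n_params <- function(dist, fix_c = FALSE) {
  switch(dist,
         fixed = 1L,
         normal = 2L, lognormal = 2L,
         uniform = 2L, loguniform = 2L, triangular = 2L,
         asym_triangular = if (fix_c) 2L else 3L,
         fm2 = 3L, fm3 = 4L,
         stop("unknown family: ", dist, call. = FALSE))
}

# natural parameter names per family
.family_param_names <- function(dist, fix_c = FALSE) {
  switch(dist,
         fixed = "value",
         normal = c("mu", "sigma"), lognormal = c("mu", "sigma"),
         uniform = c("a", "b"), loguniform = c("a", "b"),
         triangular = c("a", "b"),
         asym_triangular = if (fix_c) c("a", "b") else c("a", "b", "c"),
         fm2 = c("mu", "sigma1", "sigma2"),
         fm3 = c("mu", "sigma1", "sigma2", "sigma3"))
}

# number of primitive draw dimensions a family consumes
.family_n_dims <- function(dist) {
  switch(dist,
         fixed = 0L,
         normal = 1L, lognormal = 1L,
         uniform = 1L, loguniform = 1L, fm2 = 1L, fm3 = 1L,
         triangular = 2L,
         asym_triangular = 3L)
}

#' Validate a model specification against a dataset
#'
#' Checks that every attribute term resolves to a data column and reports
#' the free-parameter count implied by the mixing families (normal and
#' log-normal: 2; uniform, log-uniform and triangular: 2; asymmetric
#' triangular: 3, or 2 with the mode offset fixed at 0; fm2: 3; fm3: 4;
#' fixed: 1).
#'
#' @param spec a [model_spec()].
#' @param data a \code{choice_data} (or any data.frame with the attribute
#'   columns).
#' @return List with \code{ok}, \code{n_params}, per-coefficient counts and
#'   any \code{missing} columns. Unresolved attributes raise an error.
#' @export
validate_spec <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- unique(unlist(lapply(spec$coefficients, `[[`, "attributes")))
  missing_cols <- setdiff(terms, names(data))
  if (length(missing_cols)) {
    stop("attribute term(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  counts <- vapply(spec$coefficients,
                   function(cf) .family_n_params(cf$dist, cf$fix_c),
                   integer(1))
  list(ok = TRUE, n_params = sum(counts), per_coefficient = counts,
       missing = character(0))
}

#' Read or write a model specification file
#'
#' Model specs are stored as YAML or JSON with keys \code{space},
#' \code{price_coefficient} and \code{coefficients} (each with
#' \code{name}, \code{dist}, \code{attributes}, \code{sign}, \code{fix_c}).
#'
#' @param path file path; extension \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return For the reader, a \code{model_spec}; the writer returns the path
#'   invisibly.
#' @export
read_model_spec <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  coefs <- lapply(seq_along(raw$coefficients), function(i) {
    cf <- raw$coefficients[[i]]
    coef_spec(cf$name, cf$dist,
              attributes = unlist(cf$attributes),
              sign = if (is.null(cf$sign)) -1 else cf$sign,
              fix_c = isTRUE(cf$fix_c))
  })
  model_spec(coefs, space = if (is.null(raw$space)) "preference" else raw$space,
             price_coefficient = raw$price_coefficient)
}

#' @rdname read_model_spec
#' @param spec a \code{model_spec}.
#' @export
write_model_spec <- function(spec, path) {
  lst <- list(space = spec$space,
              price_coefficient = spec$price_coefficient,
              coefficients = lapply(unname(spec$coefficients), function(cf) {
                list(name = cf$name, dist = cf$dist,
                     attributes = as.list(cf$attributes), sign = cf$sign,
                     fix_c = cf$fix_c)
              }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, null = "null")
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

# ---- internal parameter layout -------------------------------------------
# Free (estimation-scale) parameters per family. Scale parameters (sigma, b,
# the asymmetric-triangular range) are optimized on the log scale so they
# stay positive; a lower bound of log(1e-8) lets the optimizer represent an
# effectively-zero boundary. The asymmetric-triangular mode offset c is
# mapped through (range/2)*tanh(c_raw) so the mode stays inside (a, b).

.SCALE_FLOOR <- log(1e-8)

.param_layout <- function(spec) {
  coefs <- spec$coefficients
  free_names <- character(0)
  is_scale <- logical(0)
  per_coef <- list()
  for (cf in coefs) {
    fam <- cf$dist
    fn <- switch(fam,
                 fixed = "value",
                 normal = c("mu", "log_sigma"),
                 lognormal = c("mu", "log_sigma"),
                 uniform = c("a", "log_b"),
                 loguniform = c("a", "log_b"),
                 triangular = c("a", "log_b"),
                 asym_triangular = if (cf$fix_c) c("a", "log_range")
                                   else c("a", "log_range", "c_raw"),
                 fm2 = c("mu", "sigma1", "sigma2"),
                 fm3 = c("mu", "sigma1", "sigma2", "sigma3"))
    sc <- grepl("^log_", fn)
    idx <- length(free_names) + seq_along(fn)
    free_names <- c(free_names, paste(cf$name, fn, sep = "."))
    is_scale <- c(is_scale, sc)
    per_coef[[cf$name]] <- list(spec = cf, idx = idx, free = fn)
  }
  list(free_names = free_names, is_scale = is_scale, per_coef = per_coef,
       n_free = length(free_names))
}

# free vector -> named list of natural parameter lists per coefficient
.free_to_natural <- function(layout, theta) {
  out <- list()
  for (nm in names(layout$per_coef)) {
    pc <- layout$per_coef[[nm]]
    th <- theta[pc$idx]
    fam <- pc$spec$dist
    out[[nm]] <- switch(fam,
      fixed = list(value = th[1]),
      normal = ,
      lognormal = list(mu = th[1], sigma = exp(th[2])),
      uniform = ,
      loguniform = ,
      triangular = list(a = th[1], b = exp(th[2])),
      asym_triangular = {
        rng <- exp(th[2])
        cc <- if (pc$spec$fix_c) 0 else (rng / 2) * tanh(th[3])
        list(a = th[1], b = th[1] + rng, c = cc)
      },
      fm2 = list(mu = th[1], sigma1 = th[2], sigma2 = th[3]),
      fm3 = list(mu = th[1], sigma1 = th[2], sigma2 = th[3], sigma3 = th[4]))
  }
  out
}

# flat named natural-parameter vector (reporting scale)
.natural_vector <- function(layout, theta) {
  nat <- .free_to_natural(layout, theta)
  unlist(lapply(names(nat), function(nm) {
    v <- unlist(nat[[nm]])
    names(v) <- paste(nm, names(v), sep = ".")
    v
  }))
}

.lower_bounds <- function(layout) {
  lo <- rep(-Inf, layout$n_free)
  lo[layout$is_scale] <- .SCALE_FLOOR
  lo
}
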