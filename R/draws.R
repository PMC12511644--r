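#' Modified Latin hypercube sampling draws
#'
#' Quasi-random uniform primitives for simulating the mixing integral. For
#' each (person, dimension) pair the R draws are a shifted equidistant grid
#' \eqn{(perm(0, ..., R-1) + u)/R} with one uniform shift \eqn{u} and one
#' random permutation per pair, so after sorting the R values occupy the R
#' strata \eqn{[i/R, (i+1)/R)} exactly once. Identical \code{(seed,
#' n_persons, n_dims, R)} produce identical arrays; draws for a given
#' person do not depend on how many persons follow.
#'
#' @param n_persons,n_dims,R positive integers: persons, coefficient
#'   dimensions, draws per person-dimension.
#' @param seed integer master seed.
#' @return A \code{draw_set}: list with \code{values} (array
#'   \code{n_persons x n_dims x R}), \code{family} (\code{"std_uniform"}),
#'   \code{R} and \code{seed}.
#' @export
mlhs <- function(n_persons, n_dims, R, seed = 1L) {
  if (n_persons < 1 || n_dims < 1 || R < 1) {
    stop("n_persons, n_dims and R must all be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  vals <- array(NA_real_, dim = c(n_persons, n_dims, R))
  grid <- seq_len(R) - 1
  for (p in seq_len(n_persons)) {
    for (d in seq_len(n_dims)) {
      shift <- stats::runif(1)
      vals[p, d, ] <- (sample(grid, R) + shift) / R
    }
  }
  structure(list(values = vals, family = "std_uniform",
                 R = as.integer(R), seed = as.integer(seed)),
            class = "draw_set")
}

#' Map uniform primitives to standard-normal primitives
#'
#' Elementwise inverse standard-normal CDF; values at 0 or 1 (impossible
#' for MLHS but possible for user-supplied primitives) are clipped to a
#' machine-safe open interval.
#'
#' @param draws a \code{draw_set} with \code{family = "std_uniform"}.
#' @return A \code{draw_set} with \code{family = "std_normal"}.
#' @export
to_normal <- function(draws) {
  stopifnot(inherits(draws, "draw_set"))
  if (draws$family != "std_uniform") {
    stop("to_normal expects std_uniform primitives", call. = FALSE)
  }
  eps <- .Machine$double.eps
  v <- pmin(pmax(draws$values, eps), 1 - eps)
  draws$values <- array(stats::qnorm(v), dim = dim(draws$values))
  draws$family <- "std_normal"
  draws
}

# Build the per-coefficient primitive draws a spec needs: one MLHS array
# over the total dimension count, sliced per coefficient and transformed
# to standard normal where the family requires it. Dimension roles:
#   normal/lognormal: dN; uniform/loguniform/fm*: u;
#   triangular: u1, u2; asym_triangular: u1, u2, us (piece selector).
.spec_draws <- function(spec, n_persons, R, seed) {
  coefs <- spec$coefficients
  dims <- vapply(coefs, function(cf) .family_n_dims(cf$dist), integer(1))
  total <- sum(dims)
  out <- list(R = as.integer(R), seed = as.integer(seed), draws = list())
  if (total == 0L) return(out)
  u <- mlhs(n_persons, total, R, seed)$values
  pos <- 0L
  for (cf in coefs) {
    nd <- .family_n_dims(cf$dist)
    if (nd == 0L) next
    sl <- lapply(seq_len(nd), function(j) {
      m <- u[, pos + j, , drop = FALSE]
      dim(m) <- c(n_persons, R)
      m
    })
    pos <- pos + nd
    names(sl) <- switch(cf$dist,
                        normal = , lognormal = "dN",
                        uniform = , loguniform = , fm2 = , fm3 = "u",
                        triangular = c("u1", "u2"),
                        asym_triangular = c("u1", "u2", "us"))
    if (cf$dist %in% c("normal", "lognormal")) {
      eps <- .Machine$double.eps
      sl$dN <- stats::qnorm(pmin(pmax(sl$dN, eps), 1 - eps))
    }
    out$draws[[cf$name]] <- sl
  }
  out
}
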