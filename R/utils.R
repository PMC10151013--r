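# Internal numeric and plumbing helpers shared across modules.

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int f(x) e^{-x^2} dx \approx \sum_k w_k f(x_k)},
#' computed by the Golub-Welsch eigen-decomposition of the Jacobi matrix of the
#' (physicists') Hermite polynomials.
#'
#' @param n number of nodes (>= 1)
#' @return list with `nodes` (ascending) and `weights`
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Bernoulli log-likelihood on the logit scale, numerically safe:
# y*eta - log(1 + exp(eta))
log_bernoulli_logit <- function(y, eta) {
  y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)
}

# Run expr under a temporary seed (if non-NULL), restoring RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Validation helper: stop with the offending field's name.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

#' Phase angle from resistance and reactance
#'
#' \eqn{\Theta = \mathrm{atan2}(X, R)} in degrees, so capacitive tissue
#' (negative reactance) gives a negative phase.
#'
#' @param resistance resistance in ohm
#' @param reactance reactance in ohm
#' @return phase angle in degrees
#' @export
#' @examples
#' phase_deg(100, -10)
phase_deg <- function(resistance, reactance) {
  atan2(reactance, resistance) * 180 / pi
}

# ISO-8601 formatting used by the device-log CSV dialect (timezone-naive).
format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
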