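#' Random birth-death-migration fixture
#'
#' Draws per-node rates uniformly on the given ranges: defaults
#' \eqn{\beta \in [0.05, 0.16]}, \eqn{\delta \in [0.05, 0.19]},
#' \eqn{\lambda \in [0.0003, 0.00046]} (all-to-all migration, zero
#' diagonal).  A criticality mode overrides the death rates to
#' \eqn{\delta = \beta + 0.03} (subcritical) or \eqn{\delta = \beta -
#' 0.03} (supercritical); with the default beta range the supercritical
#' offset keeps all \eqn{\delta > 0}.  Deterministic under the seed.
#'
#' @param n_types number of nodes.
#' @param beta_range,delta_range,lambda_range length-2 (lo, hi) ranges.
#' @param criticality \code{"free"}, \code{"subcritical"} or
#'   \code{"supercritical"}.
#' @param seed integer RNG seed; NULL leaves the RNG state alone.
#' @return a \code{\link{bdm_process}}.
#' @export
random_bdm <- function(n_types,
                       beta_range = c(0.05, 0.16),
                       delta_range = c(0.05, 0.19),
                       lambda_range = c(3e-4, 4.6e-4),
                       criticality = c("free", "subcritical", "supercritical"),
                       seed = NULL) {
  criticality <- match.arg(criticality)
  stopifnot(n_types >= 1, all(beta_range > 0), all(delta_range > 0),
            all(lambda_range >= 0))
  if (!is.null(seed)) set.seed(seed)
  beta <- stats::runif(n_types, beta_range[1], beta_range[2])
  delta <- switch(criticality,
                  free = stats::runif(n_types, delta_range[1], delta_range[2]),
                  subcritical = beta + 0.03,
                  supercritical = beta - 0.03)
  if (any(delta <= 0))
    stop("supercritical offset drives a death rate nonpositive; raise beta_range")
  lambda <- matrix(stats::runif(n_types^2, lambda_range[1], lambda_range[2]),
                   n_types, n_types)
  diag(lambda) <- 0
  bdm_process(beta, delta, lambda)
}

#' Analytic test-function registry
#'
#' Small closed-form targets used to exercise and validate the derivative
#' engines; each entry bundles the function, a point, its analytic
#' Jacobian, and (for scalars) its analytic Hessian.
#'
#' \describe{
#'   \item{square}{\eqn{f(p) = p^2}, scalar.}
#'   \item{exp_sin}{\eqn{g(p) = e^{p_1}\sin(p_2)}, scalar.}
#'   \item{polyprod}{\eqn{g(p) = p_1 p_2 + p_1^4}, scalar.}
#'   \item{decay}{\eqn{f(\delta) = I_0 e^{-\delta t}} with
#'     \eqn{I_0 = 100, t = 10}, scalar in \eqn{\delta}.}
#'   \item{trig_vec}{\eqn{f(p) = (\sin p_1\, e^{p_2},\; p_1 p_2)}, vector.}
#' }
#'
#' @param name registry key; see Details.
#' @return a list: \code{f} (a \code{\link{target_fn}}), \code{p0},
#'   \code{jacobian(p)}, and \code{hessian(p)} when scalar.
#' @export
get_test_function <- function(name) {
  reg <- list(
    square = list(
      f = target_fn(function(p) p^2, 1, name = "square"),
      p0 = 3,
      jacobian = function(p) matrix(2 * p, 1, 1),
      hessian = function(p) matrix(2, 1, 1)),
    exp_sin = list(
      f = target_fn(function(p) exp(p[1]) * sin(p[2]), 2, name = "exp_sin"),
      p0 = c(0.5, 0.8),
      jacobian = function(p)
        matrix(c(exp(p[1]) * sin(p[2]), exp(p[1]) * cos(p[2])), 1, 2),
      hessian = function(p)
        matrix(c(exp(p[1]) * sin(p[2]), exp(p[1]) * cos(p[2]),
                 exp(p[1]) * cos(p[2]), -exp(p[1]) * sin(p[2])), 2, 2)),
    polyprod = list(
      f = target_fn(function(p) p[1] * p[2] + p[1]^4, 2, name = "polyprod"),
      p0 = c(1.2, -0.7),
      jacobian = function(p) matrix(c(p[2] + 4 * p[1]^3, p[1]), 1, 2),
      hessian = function(p) matrix(c(12 * p[1]^2, 1, 1, 0), 2, 2)),
    decay = list(
      f = target_fn(function(p) 100 * exp(-p[1] * 10), 1, name = "decay"),
      p0 = 0.5,
      jacobian = function(p) matrix(-10 * 100 * exp(-p[1] * 10), 1, 1),
      hessian = function(p) matrix(100 * 100 * exp(-p[1] * 10), 1, 1)),
    trig_vec = list(
      f = target_fn(function(p) c(sin(p[1]) * exp(p[2]), p[1] * p[2]), 2,
                    name = "trig_vec"),
      p0 = c(0.3, 0.6),
      jacobian = function(p)
        matrix(c(cos(p[1]) * exp(p[2]), p[2],
                 sin(p[1]) * exp(p[2]), p[1]), 2, 2))
  )
  if (!name %in% names(reg))
    stop(sprintf("unknown test function '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")))
  reg[[name]]
}

#' @rdname get_test_function
#' @export
list_test_functions <- function() {
  c("square", "exp_sin", "polyprod", "decay", "trig_vec")
}
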