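#' First-order Taylor prediction of a perturbed trajectory
#'
#' Given a \code{sensitivity_solution} around parameters \eqn{\beta} and a
#' displacement \eqn{v}, predicts the trajectory at \eqn{\beta + v} by the
#' linear expansion \eqn{x(t,\beta) + (\partial x/\partial\beta)\, v} at
#' each saved time.
#'
#' @param sol a \code{sensitivity_solution} with first-order sensitivities.
#' @param v parameter displacement vector, length n_params.
#' @return predicted trajectory matrix (n_states x n_times).
#' @export
predict_first_order <- function(sol, v) {
  d <- dim(sol$first_order)
  if (length(v) != d[2])
    stop(sprintf("v has length %d; expected %d parameters", length(v), d[2]))
  pred <- sol$trajectory$states
  for (ti in seq_len(d[3]))
    pred[, ti] <- pred[, ti] + sol$first_order[, , ti] %*% v
  pred
}

#' Second-order Taylor prediction of a perturbed trajectory
#'
#' Adds the quadratic correction
#' \eqn{\tfrac12 v^\top (\partial^2 x/\partial\beta^2) v} per state and
#' time to the first-order prediction.
#'
#' @inheritParams predict_first_order
#' @return predicted trajectory matrix (n_states x n_times).
#' @export
predict_second_order <- function(sol, v) {
  if (is.null(sol$second_order))
    stop("sensitivity solution has no second-order terms; recompute with second_order_ode_sensitivities()")
  pred <- predict_first_order(sol, v)
  d <- dim(sol$second_order)   # n_states, np, np, n_times
  for (ti in seq_len(d[4])) {
    for (s in seq_len(d[1])) {
      H <- matrix(sol$second_order[s, , , ti], d[2], d[3])
      pred[s, ti] <- pred[s, ti] + 0.5 * as.numeric(t(v) %*% H %*% v)
    }
  }
  pred
}

#' Normalized prediction error between trajectories
#'
#' The raw norm is the Euclidean norm of the difference (Frobenius for
#' matrices).  To capture proportional errors across output sizes, vector
#' outputs are divided by their entry count and matrix outputs by the
#' square of their entry count (\code{normalization = "count"}); the
#' alternative \code{"sqrt_count"} divides by the square root of the entry
#' count (root-mean-square convention) in both cases.
#'
#' @param actual,predicted equal-shape numeric vectors or matrices.
#' @param kind \code{"matrix"} or \code{"vector"}; controls the divisor.
#' @param normalization \code{"count"} (default) or \code{"sqrt_count"}.
#' @param order optional expansion order recorded in the report.
#' @param v optional displacement recorded in the report.
#' @return an object of class \code{"prediction_report"} with fields
#'   \code{err}, \code{raw_norm}, \code{normalization}, \code{order},
#'   \code{perturbation}.
#' @export
prediction_error <- function(actual, predicted,
                             kind = c("matrix", "vector"),
                             normalization = c("count", "sqrt_count"),
                             order = NA_integer_, v = NULL) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  if (!identical(dim(actual), dim(predicted)) ||
      length(actual) != length(predicted))
    stop("actual and predicted must have identical shape")
  raw <- sqrt(sum((actual - predicted)^2))
  cnt <- length(actual)
  divisor <- switch(normalization,
                    count = if (kind == "matrix") cnt^2 else cnt,
                    sqrt_count = sqrt(cnt))
  structure(list(order = order, perturbation = v, err = raw / divisor,
                 raw_norm = raw, normalization = divisor),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report>%s err = %.6g (raw %.6g / %g)\n",
              if (is.na(x$order)) "" else sprintf(" order %d:", x$order),
              x$err, x$raw_norm, x$normalization))
  invisible(x)
}

#' Random multiplicative parameter perturbation
#'
#' Replaces each \eqn{p_i} by \eqn{p_i(1 + U_i)} with
#' \eqn{U_i \sim \mathrm{Uniform}(-m, m)} drawn independently, the design
#' of the around-25-percent perturbation experiment.  Deterministic under
#' the seed.
#'
#' @param p parameter vector.
#' @param magnitude m in (0, 1); default 0.25.
#' @param seed integer RNG seed; NULL leaves the RNG state alone.
#' @return list with \code{perturbed} (the new vector), \code{v} (the
#'   displacement \code{p * U}) and \code{u} (the draws).
#' @export
perturb_params <- function(p, magnitude = 0.25, seed = NULL) {
  stopifnot(magnitude > 0, magnitude < 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  u <- stats::runif(length(p), -magnitude, magnitude)
  list(perturbed = p * (1 + u), v = p * u, u = u)
}

#' Taylor prediction experiment for a bundled model
#'
#' Runs the full random-perturbation experiment: computes first- and
#' second-order sensitivities at the base parameters, draws a seeded
#' multiplicative perturbation, re-solves the model at the perturbed
#' parameters, and reports the normalized prediction errors of both Taylor
#' expansions against the re-solved truth, per state compartment.
#'
#' @inheritParams solve_trajectory
#' @param magnitude perturbation half-width (fraction of each parameter).
#' @param seed RNG seed for the draw.
#' @param sol optional precomputed second-order
#'   \code{sensitivity_solution} at \code{(p, x0, tspan)} to reuse.
#' @return list with the displacement \code{v}, matrices \code{actual},
#'   \code{pred1}, \code{pred2}, per-compartment error vectors
#'   \code{err1}, \code{err2}, and whole-matrix reports
#'   \code{report1}, \code{report2}.
#' @export
taylor_experiment <- function(model, p = model$default_params,
                              x0 = model$default_x0,
                              tspan = model$default_tspan, saveat = 1,
                              magnitude = 0.25, seed = 1,
                              rtol = NULL, atol = NULL, sol = NULL) {
  if (is.null(sol))
    sol <- second_order_ode_sensitivities(model, p, x0, tspan, saveat,
                                          rtol = rtol, atol = atol)
  pert <- perturb_params(p, magnitude, seed)
  actual <- solve_trajectory(model, pert$perturbed, x0, tspan, saveat,
                             rtol = rtol, atol = atol)$states
  pred1 <- predict_first_order(sol, pert$v)
  pred2 <- predict_second_order(sol, pert$v)
  per_comp <- function(pred)
    vapply(seq_len(nrow(actual)), function(s)
      prediction_error(actual[s, ], pred[s, ], kind = "vector")$err,
      numeric(1))
  list(v = pert$v, u = pert$u, actual = actual, pred1 = pred1, pred2 = pred2,
       err1 = stats::setNames(per_comp(pred1), rownames(actual)),
       err2 = stats::setNames(per_comp(pred2), rownames(actual)),
       report1 = prediction_error(actual, pred1, kind = "matrix", order = 1L,
                                  v = pert$v),
       report2 = prediction_error(actual, pred2, kind = "matrix", order = 2L,
                                  v = pert$v))
}
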