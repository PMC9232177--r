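#' Solve a model trajectory
#'
#' Integrates an \code{\link{ode_model}} and samples the solution on a
#' regular grid.  Non-stiff models use \code{deSolve::lsoda} (which switches
#' automatically if stiffness is detected); the same solver handles the
#' stiff bundled models at their tighter default tolerance.
#'
#' Defaults: \code{saveat = 1} time unit; \code{rtol = 1e-5}
#' (\code{1e-7} for stiff models); \code{atol = rtol * 1e-3}.
#'
#' @param model an \code{\link{ode_model}}.
#' @param p,x0 parameters and initial state (model defaults when missing).
#' @param tspan length-2 increasing time interval.
#' @param saveat grid spacing (scalar) or an explicit increasing time grid.
#' @param rtol,atol solver tolerances.
#' @return an object of class \code{"trajectory"}: \code{times},
#'   \code{states} (n_states x n_times matrix), tolerances used.
#' @export
solve_trajectory <- function(model, p = model$default_params,
                             x0 = model$default_x0,
                             tspan = model$default_tspan, saveat = 1,
                             rtol = NULL, atol = NULL) {
  tol <- default_tols(model, rtol, atol)
  times <- saveat_grid(tspan, saveat)
  states <- solve_real(model, p, x0, times, tol$rtol, tol$atol)
  new_trajectory(times, states, model, tol)
}

new_trajectory <- function(times, states, model, tol) {
  rownames(states) <- model$state_names
  structure(list(times = times, states = states,
                 solver_rtol = tol$rtol, solver_atol = tol$atol,
                 model_name = model$name),
            class = "trajectory")
}

default_tols <- function(model, rtol, atol) {
  if (is.null(rtol)) rtol <- if (isTRUE(model$stiff)) 1e-7 else 1e-5
  if (is.null(atol)) atol <- rtol * 1e-3
  stopifnot(rtol > 0, atol > 0)
  list(rtol = rtol, atol = atol)
}

saveat_grid <- function(tspan, saveat) {
  if (length(saveat) > 1) {
    stopifnot(all(diff(saveat) > 0))
    return(saveat)
  }
  stopifnot(length(tspan) == 2, diff(tspan) > 0, saveat > 0)
  times <- seq(tspan[1], tspan[2], by = saveat)
  if (times[length(times)] < tspan[2]) times <- c(times, tspan[2])
  times
}

solve_real <- function(model, p, x0, times, rtol, atol) {
  func <- function(t, y, parms) list(model$rhs(y, p, t))
  out <- suppressWarnings(
    deSolve::ode(y = as.numeric(x0), times = times, func = func,
                 parms = NULL, rtol = rtol, atol = atol, method = "lsoda"))
  if (nrow(out) < length(times))
    stop(sprintf("solver failed for model '%s' after t = %g",
                 model$name, out[nrow(out), 1]))
  t(out[, -1, drop = FALSE])
}

# complex-valued solve: zvode integrates the complexified system directly;
# the "split" fallback stacks real and imaginary parts into a real system
# of twice the size and integrates with lsoda.
solve_complex <- function(model, p, x0, times, rtol, atol,
                          integrator = c("zvode", "split")) {
  integrator <- match.arg(integrator)
  n <- length(x0)
  if (integrator == "zvode") {
    func <- function(t, y, parms) list(as.complex(model$rhs(y, p, t)))
    # BDF with an internally generated Jacobian (mf = 22) handles both the
    # stiff bundled models and sharp transients (e.g. the CARRGO crash
    # phase) that stall the non-stiff Adams option
    out <- suppressWarnings(
      deSolve::zvode(y = as.complex(x0), times = times, func = func,
                     parms = NULL, rtol = rtol, atol = atol,
                     mf = 22L, maxsteps = 100000L))
    if (nrow(out) < length(times))
      stop(sprintf("complex solver failed for model '%s' after t = %g",
                   model$name, Re(out[nrow(out), 1])))
    t(matrix(out[, -1], ncol = n,
             dimnames = list(NULL, model$state_names)))
  } else {
    func <- function(t, y, parms) {
      dz <- model$rhs(complex(real = y[1:n], imaginary = y[(n + 1):(2 * n)]),
                      p, t)
      list(c(Re(dz), Im(dz)))
    }
    out <- suppressWarnings(
      deSolve::ode(y = c(Re(x0), Im(x0)), times = times, func = func,
                   parms = NULL, rtol = rtol, atol = atol, method = "lsoda"))
    if (nrow(out) < length(times))
      stop(sprintf("split complex solver failed for model '%s' after t = %g",
                   model$name, out[nrow(out), 1]))
    re <- t(out[, 2:(n + 1), drop = FALSE])
    im <- t(out[, (n + 2):(2 * n + 1), drop = FALSE])
    rownames(re) <- model$state_names
    re + 1i * im
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d states x %d times, t in [%g, %g]\n",
              x$model_name, nrow(x$states), length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  graphics::matplot(x$times, t(x$states), type = "l", lty = 1,
                    xlab = "time", ylab = "state", ...)
  graphics::legend("topright", legend = rownames(x$states),
                   col = seq_len(nrow(x$states)), lty = 1, bty = "n")
  invisible(x)
}

new_sensitivity_solution <- function(trajectory, first_order, engine,
                                     param_names, second_order = NULL) {
  structure(list(trajectory = trajectory, first_order = first_order,
                 second_order = second_order, engine = engine,
                 param_names = param_names),
            class = "sensitivity_solution")
}

#' @export
print.sensitivity_solution <- function(x, ...) {
  d <- dim(x$first_order)
  cat(sprintf("<sensitivity_solution '%s'> engine=%s: %d states x %d params x %d times%s\n",
              x$trajectory$model_name, x$engine, d[1], d[2], d[3],
              if (!is.null(x$second_order)) " (+ second order)" else ""))
  invisible(x)
}

#' @export
summary.sensitivity_solution <- function(object, ...) {
  d <- dim(object$first_order)
  final <- object$first_order[, , d[3], drop = FALSE]
  dim(final) <- d[1:2]
  dimnames(final) <- list(rownames(object$trajectory$states),
                          object$param_names)
  cat(sprintf("First-order sensitivities at t = %g (engine %s):\n",
              object$trajectory$times[d[3]], object$engine))
  print(final)
  invisible(final)
}

#' @export
plot.sensitivity_solution <- function(x, state = 1, ...) {
  tr <- x$trajectory
  sens <- t(x$first_order[state, , , drop = TRUE])
  if (is.null(dim(sens))) sens <- matrix(sens, ncol = 1)
  graphics::matplot(tr$times, sens, type = "l", lty = 1, xlab = "time",
                    ylab = sprintf("d %s / d param", rownames(tr$states)[state]),
                    ...)
  graphics::legend("topright", legend = x$param_names,
                   col = seq_along(x$param_names), lty = 1, bty = "n")
  invisible(x)
}

#' Forward sensitivity equations
#'
#' Integrates the augmented system obtained by differentiating the ODE with
#' respect to its parameters: alongside the states \eqn{x}, the sensitivity
#' matrix \eqn{S = \partial x/\partial\beta} evolves as
#' \deqn{\dot S = (\partial f/\partial x) S + \partial f/\partial\beta,
#'       \qquad S(t_0) = 0,}
#' (the initial condition does not depend on the parameters).  The two
#' right-hand-side Jacobians are evaluated at each step by the chosen
#' derivative engine (complex step by default) or by a user-supplied
#' analytic \code{jacobian(x, p, t)} returning \code{list(Jx, Jp)}.
#'
#' The Jacobian-free directional variant is selected by passing a
#' \code{directions} matrix with fewer columns than parameters: only
#' \eqn{S v} for those direction columns is propagated.
#'
#' @inheritParams solve_trajectory
#' @param jacobian_engine \code{"complex_step"} or \code{"dual"}; engine
#'   used for the rhs Jacobians when \code{jacobian} is NULL.
#' @param jacobian optional analytic Jacobian function.
#' @param directions optional n_params-row matrix of parameter directions;
#'   default identity (full Jacobian of the trajectory).
#' @return a \code{sensitivity_solution} with \code{engine = "forward_ode"}.
#' @export
forward_ode_sensitivities <- function(model, p = model$default_params,
                                      x0 = model$default_x0,
                                      tspan = model$default_tspan,
                                      saveat = 1, rtol = NULL, atol = NULL,
                                      jacobian_engine = c("complex_step", "dual"),
                                      jacobian = NULL, directions = NULL) {
  jacobian_engine <- match.arg(jacobian_engine)
  tol <- default_tols(model, rtol, atol)
  times <- saveat_grid(tspan, saveat)
  n <- length(x0); np <- length(p)
  if (is.null(directions)) directions <- diag(np)
  directions <- as.matrix(directions)
  stopifnot(nrow(directions) == np)
  k <- ncol(directions)

  jac <- if (!is.null(jacobian)) jacobian else function(x, p, t) {
    fx <- function(xx) model$rhs(xx, p, t)
    fp <- function(pp) model$rhs(x, pp, t)
    if (jacobian_engine == "complex_step")
      list(Jx = cs_jacobian(fx, x)$jacobian, Jp = cs_jacobian(fp, p)$jacobian)
    else
      list(Jx = dual_jacobian(fx, x)$jacobian, Jp = dual_jacobian(fp, p)$jacobian)
  }

  func <- function(t, y, parms) {
    x <- y[1:n]
    S <- matrix(y[-(1:n)], n, k)
    J <- jac(x, p, t)
    dS <- J$Jx %*% S + J$Jp %*% directions
    list(c(model$rhs(x, p, t), as.vector(dS)))
  }
  out <- suppressWarnings(
    deSolve::ode(y = c(as.numeric(x0), rep(0, n * k)), times = times,
                 func = func, parms = NULL, rtol = tol$rtol, atol = tol$atol,
                 method = "lsoda"))
  if (nrow(out) < length(times))
    stop(sprintf("forward sensitivity solver failed for '%s' after t = %g",
                 model$name, out[nrow(out), 1]))
  states <- t(out[, 2:(n + 1), drop = FALSE])
  first <- array(t(out[, -(1:(n + 1)), drop = FALSE]),
                 dim = c(n, k, length(times)))
  traj <- new_trajectory(times, states, model, tol)
  new_sensitivity_solution(traj, first, "forward_ode",
                           if (k == np && identical(directions, diag(np)))
                             model$param_names
                           else paste0("dir", seq_len(k)))
}

#' Complex-step trajectory sensitivities
#'
#' For each parameter j the ODE is re-solved with \eqn{\beta_j + \Delta i}
#' over the complex field; the imaginary part of the saved states divided by
#' \eqn{\Delta} is \eqn{\partial x(t)/\partial\beta_j} to
#' \eqn{O(\Delta^2)} with no cancellation.  The unperturbed (real) solve
#' supplies the trajectory; each parameter's perturbation is reset before
#' the next solve, so solves are independent.
#'
#' @inheritParams solve_trajectory
#' @param delta complex-step size, default \code{1e-12}.
#' @param integrator \code{"zvode"} integrates the complex system directly;
#'   \code{"split"} integrates the equivalent stacked real/imaginary system.
#' @return a \code{sensitivity_solution} with \code{engine = "complex_step"}.
#' @export
cs_ode_sensitivities <- function(model, p = model$default_params,
                                 x0 = model$default_x0,
                                 tspan = model$default_tspan, saveat = 1,
                                 delta = 1e-12, rtol = NULL, atol = NULL,
                                 integrator = c("zvode", "split")) {
  stopifnot(delta > 0)
  integrator <- match.arg(integrator)
  tol <- default_tols(model, rtol, atol)
  times <- saveat_grid(tspan, saveat)
  n <- length(x0); np <- length(p)
  states <- solve_real(model, p, x0, times, tol$rtol, tol$atol)
  first <- array(0, dim = c(n, np, length(times)))
  for (j in seq_len(np)) {
    pc <- as.complex(p)
    pc[j] <- pc[j] + delta * 1i
    sol <- tryCatch(
      solve_complex(model, pc, as.complex(x0), times, tol$rtol, tol$atol,
                    integrator),
      error = function(e) stop(sprintf(
        "complex-step solve failed for parameter '%s': %s",
        model$param_names[j], conditionMessage(e)), call. = FALSE))
    first[, j, ] <- Im(sol) / delta
  }
  traj <- new_trajectory(times, states, model, tol)
  new_sensitivity_solution(traj, first, "complex_step", model$param_names)
}

#' Second-order trajectory sensitivities
#'
#' Treats the solve map \eqn{\beta \mapsto x(t,\beta)} as the target of the
#' rotated complex-step second-derivative formulas: pure second partials
#' from perturbations \eqn{\pm e^{i\pi/4}\Delta e_j}, mixed partials from
#' joint pair perturbations \eqn{\pm e^{i\pi/4}\Delta(e_j + e_k)} with the
#' two diagonal terms subtracted and the remainder halved.  Each evaluation
#' is one full complex ODE solve, so the solve count is
#' \eqn{1 + 2p + p(p-1)} plus the first-order solves.
#'
#' @inheritParams cs_ode_sensitivities
#' @param delta second-order step, default \code{1e-4} (the band where
#'   \eqn{\Delta^4} truncation and \eqn{\epsilon/\Delta^2} roundoff
#'   balance).
#' @param delta1 first-order complex-step size, default \code{1e-12}.
#' @return a \code{sensitivity_solution} with both \code{first_order}
#'   (n_states x n_params x n_times) and \code{second_order}
#'   (n_states x n_params x n_params x n_times, symmetric in the parameter
#'   axes).
#' @export
second_order_ode_sensitivities <- function(model, p = model$default_params,
                                           x0 = model$default_x0,
                                           tspan = model$default_tspan,
                                           saveat = 1, delta = 1e-4,
                                           delta1 = 1e-12,
                                           rtol = NULL, atol = NULL) {
  stopifnot(delta > 0)
  tol <- default_tols(model, rtol, atol)
  times <- saveat_grid(tspan, saveat)
  n <- length(x0); np <- length(p); nt <- length(times)
  base <- cs_ode_sensitivities(model, p, x0, tspan, saveat, delta = delta1,
                               rtol = tol$rtol, atol = tol$atol)
  dp <- delta * exp(1i * pi / 4)
  pair_eval <- function(idx) {
    pc <- as.complex(p); pc[idx] <- pc[idx] + dp
    plus <- solve_complex(model, pc, as.complex(x0), times, tol$rtol, tol$atol)
    pc <- as.complex(p); pc[idx] <- pc[idx] - dp
    minus <- solve_complex(model, pc, as.complex(x0), times, tol$rtol, tol$atol)
    Im(plus + minus) / delta^2              # n x nt
  }
  second <- array(0, dim = c(n, np, np, nt))
  for (j in seq_len(np)) second[, j, j, ] <- pair_eval(j)
  if (np > 1) {
    for (j in 2:np) for (k in 1:(j - 1)) {
      raw <- pair_eval(c(j, k))
      mixed <- (raw - second[, j, j, ] - second[, k, k, ]) / 2
      second[, j, k, ] <- mixed
      second[, k, j, ] <- mixed
    }
  }
  new_sensitivity_solution(base$trajectory, base$first_order,
                           "complex_step", model$param_names,
                           second_order = second)
}

#' Scalar functional of a trajectory endpoint
#'
#' @param g analytic function \code{(x_final, p)} returning a scalar;
#'   must accept complex arguments.
#' @param description short text label.
#' @return an object of class \code{"scalar_functional"}.
#' @export
scalar_functional <- function(g, description = "g(x(T), p)") {
  stopifnot(is.function(g))
  structure(list(g = g, description = description),
            class = "scalar_functional")
}

#' Adjoint gradient of a scalar functional
#'
#' Computes \eqn{\nabla_\beta\, g[x(T,\beta), \beta]} by the continuous
#' adjoint method: a forward solve with dense interpolation, then
#' reverse-time integration of the costate
#' \eqn{\dot\lambda = -(\partial f/\partial x)^\top \lambda} from
#' \eqn{\lambda(T) = \partial g/\partial x(T)}, accumulating the parameter
#' quadrature \eqn{\int_0^T \lambda^\top \partial f/\partial\beta\, dt}
#' jointly, plus the explicit \eqn{\partial g/\partial\beta} term.  Cost is
#' one forward and one reverse solve regardless of the number of
#' parameters, O(n+p) rather than the O(np) of the forward method.
#'
#' @inheritParams solve_trajectory
#' @param g a \code{\link{scalar_functional}} or plain analytic function
#'   \code{(x_final, p)}.
#' @param dense_n number of forward save points used to build the state
#'   interpolants for the reverse pass.
#' @return named numeric gradient over the parameters.
#' @export
adjoint_gradient <- function(model, g, p = model$default_params,
                             x0 = model$default_x0,
                             tspan = model$default_tspan,
                             rtol = 1e-8, atol = NULL, dense_n = 2001) {
  if (inherits(g, "scalar_functional")) g <- g$g
  stopifnot(is.function(g))
  tol <- default_tols(model, rtol, atol)
  n <- length(x0); np <- length(p)
  tgrid <- seq(tspan[1], tspan[2], length.out = dense_n)
  states <- solve_real(model, p, x0, tgrid, tol$rtol, tol$atol)
  interp <- lapply(seq_len(n), function(s)
    stats::splinefun(tgrid, states[s, ], method = "fmm"))
  x_at <- function(t) vapply(interp, function(f) f(t), numeric(1))
  xT <- states[, dense_n]

  gx <- function(x) g(x, as.complex(p))
  gp <- function(pp) g(as.complex(xT), pp)
  test <- g(xT, p)
  if (length(test) != 1) stop("g must be scalar-valued")
  lamT <- as.vector(cs_jacobian(gx, xT)$jacobian)
  g_beta <- as.vector(cs_jacobian(gp, p)$jacobian)

  T1 <- tspan[2]
  func <- function(s, y, parms) {   # s = T - t
    t <- T1 - s
    x <- x_at(t)
    lam <- y[1:n]
    Jx <- cs_jacobian(function(xx) model$rhs(xx, p, t), x)$jacobian
    Jp <- cs_jacobian(function(pp) model$rhs(x, pp, t), p)$jacobian
    list(c(t(Jx) %*% lam, as.vector(t(Jp) %*% lam)))
  }
  out <- suppressWarnings(
    deSolve::ode(y = c(lamT, rep(0, np)), times = c(0, T1 - tspan[1]),
                 func = func, parms = NULL, rtol = tol$rtol, atol = tol$atol,
                 method = "lsoda"))
  if (nrow(out) < 2)
    stop("adjoint (reverse) solve failed")
  quad <- out[2, (n + 2):(n + np + 1)]
  stats::setNames(g_beta + quad, model$param_names)
}
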