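#' Construct an ODE model
#'
#' Bundles a right-hand side with names, default parameters, initial values
#' and a default time span.  The rhs must be written with analytic
#' elementary operations so that it accepts complexified (and dual) states
#' and parameters, which is what the complex-step trajectory engines rely
#' on.
#'
#' @param name model identifier.
#' @param rhs function \code{(x, p, t)} returning the state derivative
#'   vector; must tolerate complex \code{x} and \code{p}.
#' @param state_names,param_names character vectors naming states and
#'   parameters.
#' @param default_params,default_x0 numeric defaults, matching the names.
#' @param default_tspan length-2 increasing numeric vector.
#' @param stiff logical; selects a stiff-capable integrator by default.
#' @return an object of class \code{"ode_model"}.
#' @export
ode_model <- function(name, rhs, state_names, param_names,
                      default_params, default_x0, default_tspan,
                      stiff = FALSE) {
  stopifnot(length(default_params) == length(param_names),
            length(default_x0) == length(state_names),
            length(default_tspan) == 2, diff(default_tspan) > 0)
  test <- rhs(default_x0, default_params, default_tspan[1])
  if (!all(is.finite(test)))
    stop("rhs at the model defaults is not finite")
  structure(list(name = name, rhs = rhs,
                 state_names = state_names, param_names = param_names,
                 default_params = stats::setNames(default_params, param_names),
                 default_x0 = stats::setNames(default_x0, state_names),
                 default_tspan = default_tspan, stiff = stiff),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model '%s'>%s\n", x$name, if (x$stiff) " (stiff)" else ""))
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat("  params:",
      paste(sprintf("%s=%g", x$param_names, x$default_params), collapse = ", "),
      "\n")
  cat(sprintf("  tspan: (%g, %g)\n", x$default_tspan[1], x$default_tspan[2]))
  invisible(x)
}

#' CARRGO tumour--immune model
#'
#' Predator--prey dynamics of CAR T-cell therapy: cancer cells \eqn{x} are
#' prey and CAR T-cells \eqn{y} predators,
#' \deqn{dx/dt = \rho x(1 - y/\gamma) - \kappa_1 x y, \qquad
#'       dy/dt = \kappa_2 x y - \theta y,}
#' with defaults \eqn{\kappa_1 = 6\times10^{-9}},
#' \eqn{\kappa_2 = 3\times10^{-11}}, \eqn{\theta = 10^{-6}},
#' \eqn{\rho = 0.06} (per day, per cell where applicable),
#' \eqn{\gamma = 10^9} cells, \eqn{x_0 = 1.25\times10^4},
#' \eqn{y_0 = 6.25\times10^2} cells, over 1000 days.
#'
#' The logistic brake divides the predator count \eqn{y} by the carrying
#' capacity in the default form.  The conventional logistic form, with the
#' brake on the prey population itself (\eqn{1 - x/\gamma}), is available
#' via \code{logistic_in_x = TRUE}.
#'
#' @param logistic_in_x logical; use \eqn{\rho x (1 - x/\gamma)} growth.
#' @return an \code{\link{ode_model}} with parameters
#'   \code{(kappa1, kappa2, theta, rho, gamma)}.
#' @export
carrgo_model <- function(logistic_in_x = FALSE) {
  rhs <- if (logistic_in_x) {
    function(x, p, t)
      c(p[4] * x[1] * (1 - x[1] / p[5]) - p[1] * x[1] * x[2],
        p[2] * x[1] * x[2] - p[3] * x[2])
  } else {
    function(x, p, t)
      c(p[4] * x[1] * (1 - x[2] / p[5]) - p[1] * x[1] * x[2],
        p[2] * x[1] * x[2] - p[3] * x[2])
  }
  ode_model("carrgo", rhs,
            state_names = c("x", "y"),
            param_names = c("kappa1", "kappa2", "theta", "rho", "gamma"),
            default_params = c(6e-9, 3e-11, 1e-6, 6e-2, 1e9),
            default_x0 = c(1.25e4, 6.25e2),
            default_tspan = c(0, 1000))
}

#' Deterministic SIR epidemic model
#'
#' \deqn{dS/dt = -\eta I S/N, \quad dI/dt = \eta I S/N - \delta I, \quad
#'       dR/dt = \delta I,}
#' where \eqn{\eta} is the daily infection rate per encounter and
#' \eqn{\delta} the daily recovery (progression to immunity) rate.  The
#' population size \eqn{N = 3.4\times10^8} (the initial US-scale
#' population) is a fixed constant, not a sensitivity parameter, unless
#' \code{include_N = TRUE} appends it as a third parameter.  Defaults:
#' \eqn{\eta = 0.7194}, \eqn{\delta = 0.5025},
#' \eqn{(S_0, I_0, R_0) = (3.4\times10^8, 100, 0)} over 365 days.
#'
#' Small-population studies (e.g. the Taylor-prediction demonstration at
#' \eqn{S_0 = 1000, I_0 = 10}) should set \code{N} to the actual
#' population so the force of infection \eqn{\eta I S/N} is on scale and
#' the epidemic can take off.
#'
#' @param N population-size constant in the force of infection.
#' @param x0 initial state \code{(S, I, R)}.
#' @param include_N expose N as a third sensitivity parameter instead.
#' @return an \code{\link{ode_model}} with parameters \code{(eta, delta)}
#'   (plus \code{N} when requested).
#' @export
sir_model <- function(N = 3.4e8, x0 = c(3.4e8, 100, 0), include_N = FALSE) {
  if (include_N) {
    rhs <- function(x, p, t) {
      inf <- p[1] * x[2] * x[1] / p[3]
      c(-inf, inf - p[2] * x[2], p[2] * x[2])
    }
    pn <- c("eta", "delta", "N")
    pd <- c(0.7194, 0.5025, N)
  } else {
    force(N)
    rhs <- function(x, p, t) {
      inf <- p[1] * x[2] * x[1] / N
      c(-inf, inf - p[2] * x[2], p[2] * x[2])
    }
    pn <- c("eta", "delta")
    pd <- c(0.7194, 0.5025)
  }
  ode_model("sir", rhs,
            state_names = c("S", "I", "R"), param_names = pn,
            default_params = pd,
            default_x0 = x0,
            default_tspan = c(0, 365))
}

#' Robertson (ROBER) stiff chemical kinetics model
#'
#' The classic three-species autocatalytic reaction network, a standard
#' stiff benchmark typical of enzymatic behaviour:
#' \deqn{dx_1/dt = -p_1 x_1 + p_3 x_2 x_3, \quad
#'       dx_2/dt = p_1 x_1 - p_3 x_2 x_3 - p_2 x_2^2, \quad
#'       dx_3/dt = p_2 x_2^2,}
#' with rates \eqn{p = (4\times10^{-2}, 3\times10^7, 10^4)} and
#' \eqn{x_0 = (1, 0, 0)}.  Mass is conserved: the components sum to 1.
#'
#' @return a stiff \code{\link{ode_model}} with parameters
#'   \code{(p1, p2, p3)}.
#' @export
rober_model <- function() {
  rhs <- function(x, p, t)
    c(-p[1] * x[1] + p[3] * x[2] * x[3],
      p[1] * x[1] - p[3] * x[2] * x[3] - p[2] * x[2]^2,
      p[2] * x[2]^2)
  ode_model("rober", rhs,
            state_names = c("x1", "x2", "x3"),
            param_names = c("p1", "p2", "p3"),
            default_params = c(4e-2, 3e7, 1e4),
            default_x0 = c(1, 0, 0),
            default_tspan = c(0, 1000), stiff = TRUE)
}

#' Bundled model registry
#'
#' @param name one of \code{"carrgo"}, \code{"sir"}, \code{"rober"}.
#' @param ... passed to the model constructor.
#' @return the requested \code{\link{ode_model}}.
#' @export
get_model <- function(name, ...) {
  switch(name,
         carrgo = carrgo_model(...),
         sir = sir_model(...),
         rober = rober_model(...),
         stop(sprintf("unknown model '%s'; available: carrgo, sir, rober",
                      name)))
}
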