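#' Wrap a vector function as a differentiation target
#'
#' A target function is a map from a real parameter vector of length
#' \code{n_params} to an output vector of length \code{n_outputs}.  The
#' complex-step engines additionally require that the implementation be
#' analytic: built only from elementary operations (arithmetic, \code{exp},
#' \code{log}, \code{sin}, \code{cos}, \code{sqrt}, powers) with no branches
#' on parameter values, absolute values, \code{max}/\code{min} or rounding,
#' so that it extends to arguments with infinitesimal imaginary parts.
#'
#' @param fun function of a single numeric (possibly complex) vector
#'   argument returning a numeric (possibly complex) vector.
#' @param n_params number of parameters \code{fun} expects.
#' @param n_outputs length of the output vector; inferred by evaluation at
#'   \code{p0} when missing.
#' @param analytic logical; asserts \code{fun} uses only analytic
#'   elementary operations.  Complex-step engines warn when \code{FALSE}.
#' @param name optional identifier used in printing.
#' @param p0 point used to infer \code{n_outputs} when it is missing.
#' @return an object of class \code{"target_fn"}, itself callable.
#' @examples
#' f <- target_fn(function(p) p^2, n_params = 1)
#' cs_jacobian(f, 3)$jacobian   # 6 to machine precision
#' @export
target_fn <- function(fun, n_params, n_outputs = NULL, analytic = TRUE,
                      name = NULL, p0 = NULL) {
  stopifnot(is.function(fun), n_params >= 1)
  if (is.null(n_outputs)) {
    probe <- if (is.null(p0)) rep(1, n_params) else p0
    n_outputs <- length(fun(probe))
  }
  structure(
    function(p) fun(p),
    class = "target_fn",
    n_params = as.integer(n_params),
    n_outputs = as.integer(n_outputs),
    analytic = isTRUE(analytic),
    name = if (is.null(name)) "target" else name
  )
}

#' @export
print.target_fn <- function(x, ...) {
  cat(sprintf("<target_fn '%s'> R^%d -> R^%d (%s)\n", attr(x, "name"),
              attr(x, "n_params"), attr(x, "n_outputs"),
              if (attr(x, "analytic")) "analytic" else "not flagged analytic"))
  invisible(x)
}

as_target_fn <- function(f, p) {
  if (inherits(f, "target_fn")) return(f)
  target_fn(f, n_params = length(p), p0 = p)
}

new_derivative_result <- function(value, jacobian, engine, step) {
  structure(list(value = value, jacobian = jacobian,
                 engine = engine, step = step),
            class = "derivative_result")
}

#' @export
print.derivative_result <- function(x, ...) {
  cat(sprintf("<derivative_result> engine=%s step=%g, %d x %d jacobian\n",
              x$engine, x$step, nrow(x$jacobian), ncol(x$jacobian)))
  print(x$jacobian)
  invisible(x)
}

check_finite_cols <- function(J, engine) {
  bad <- which(!apply(J, 2, function(col) all(is.finite(col))))
  if (length(bad))
    stop(sprintf("%s: non-finite derivative for parameter index %s",
                 engine, paste(bad, collapse = ", ")), call. = FALSE)
}

warn_if_not_analytic <- function(f) {
  if (!isTRUE(attr(f, "analytic")))
    warning("target function not flagged analytic; complex-step result may be invalid",
            call. = FALSE)
}

#' Complex-step Jacobian
#'
#' First derivatives by complex perturbation: column j of the Jacobian is
#' \code{Im(f(p + delta*1i*e_j))/delta}.  Because no subtraction of nearby
#' values occurs, the approximation is free of cancellation error and is
#' accurate to machine precision for analytic \code{f} at very small steps.
#'
#' With \code{relative = TRUE} coordinate j is perturbed by
#' \code{p_j*delta*1i} and the imaginary part divided by \code{p_j*delta},
#' a scaling heuristic for parameters of widely different magnitude;
#' coordinates with \code{p_j == 0} fall back to the absolute step.
#'
#' @param f a \code{\link{target_fn}} or plain function.
#' @param p numeric parameter vector (finite).
#' @param delta positive real perturbation, default \code{1e-12}.
#' @param relative use the per-coordinate relative step heuristic.
#' @return a \code{derivative_result}: \code{value} (real f(p)),
#'   \code{jacobian} (n_outputs x n_params), \code{engine}, \code{step}.
#' @export
cs_jacobian <- function(f, p, delta = 1e-12, relative = FALSE) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a positive real scalar")
  if (!all(is.finite(p))) stop("p must be finite")
  f <- as_target_fn(f, p)
  warn_if_not_analytic(f)
  value <- Re(f(as.complex(p)))
  m <- length(value)
  cols <- lapply(seq_along(p), function(j) {
    dj <- if (relative && p[j] != 0) p[j] * delta else delta
    pc <- as.complex(p)
    pc[j] <- pc[j] + dj * 1i
    Im(f(pc)) / dj
  })
  J <- matrix(unlist(cols), nrow = m, ncol = length(p))
  check_finite_cols(J, "cs_jacobian")
  new_derivative_result(value, J, "complex_step", delta)
}

new_hessian_result <- function(hessian, step) {
  structure(list(hessian = hessian, step = step), class = "hessian_result")
}

#' @export
print.hessian_result <- function(x, ...) {
  cat(sprintf("<hessian_result> step=%g\n", x$step))
  print(x$hessian)
  invisible(x)
}

#' Complex-step Hessian of a scalar function
#'
#' Second derivatives by rotated complex perturbation.  Pure second partials
#' use the step \code{exp(1i*pi/4)*delta}:
#' \deqn{g''(\beta) \approx \mathrm{Im}[g(\beta + e^{i\pi/4}\Delta) +
#'   g(\beta - e^{i\pi/4}\Delta)]/\Delta^2 + O(\Delta^4).}
#' Mixed partials perturb coordinate pairs \code{(j,k)} jointly by
#' \code{exp(1i*pi/4)*delta*(e_j + e_k)}; the raw imaginary sum equals
#' \code{H[j,j] + H[k,k] + 2 H[j,k] + O(delta^4)}, so the two diagonal
#' entries (computed first) are subtracted and the remainder halved.  Both
#' \code{[j,k]} and \code{[k,j]} are assigned, so the result is exactly
#' symmetric by construction.
#'
#' Truncation error is \code{O(delta^4)}; roundoff grows as
#' \code{eps/delta^2}, so steps in the band 1e-3 to 1e-6 balance the two.
#'
#' @inheritParams cs_jacobian
#' @param g scalar-valued analytic target function.
#' @param delta positive real step, default \code{1e-4}.
#' @return a \code{hessian_result} with the symmetric \code{hessian} matrix.
#' @export
cs_hessian <- function(g, p, delta = 1e-4) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a positive real scalar")
  g <- as_target_fn(g, p)
  if (attr(g, "n_outputs") != 1L)
    stop("cs_hessian requires a scalar-valued target (n_outputs == 1)")
  warn_if_not_analytic(g)
  n <- length(p)
  dp <- delta * exp(1i * pi / 4)
  H <- matrix(0, n, n)
  eval_pair <- function(idx) {
    pc <- as.complex(p)
    pc[idx] <- pc[idx] + dp
    fplus <- g(pc)
    pc <- as.complex(p)
    pc[idx] <- pc[idx] - dp
    fminus <- g(pc)
    Im(fplus + fminus) / delta^2
  }
  # diagonal entries first: the mixed formula consumes them
  for (j in seq_len(n)) H[j, j] <- eval_pair(j)
  if (n > 1) {
    for (j in 2:n) for (k in 1:(j - 1)) {
      raw <- eval_pair(c(j, k))
      H[j, k] <- (raw - H[j, j] - H[k, k]) / 2
      H[k, j] <- H[j, k]
    }
  }
  if (!all(is.finite(H))) {
    bad <- which(!is.finite(H), arr.ind = TRUE)[1, ]
    stop(sprintf("cs_hessian: non-finite entry at (%d, %d)", bad[1], bad[2]))
  }
  new_hessian_result(H, delta)
}

#' Forward-difference Jacobian
#'
#' Column j is \code{(f(p + delta*e_j) - f(p))/delta}, evaluated in real
#' arithmetic.  Simple but subject to subtractive cancellation; accuracy is
#' best near \code{delta ~ sqrt(eps)}.
#'
#' @inheritParams cs_jacobian
#' @export
fd_jacobian <- function(f, p, delta = 1e-6) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a positive real scalar")
  f <- as_target_fn(f, p)
  value <- f(p)
  J <- vapply(seq_along(p), function(j) {
    pj <- p
    pj[j] <- pj[j] + delta
    (f(pj) - value) / delta
  }, numeric(length(value)))
  J <- matrix(J, nrow = length(value))
  check_finite_cols(J, "fd_jacobian")
  new_derivative_result(value, J, "forward_diff", delta)
}

#' Central-difference Jacobian
#'
#' Column j is \code{(f(p + delta/2*e_j) - f(p - delta/2*e_j))/delta}.
#' Second-order accurate (exact for quadratics up to roundoff) but still
#' cancellation-limited: the error curve over \code{delta} is U-shaped with
#' an interior optimum near \code{eps^(1/3)}.
#'
#' @inheritParams cs_jacobian
#' @export
cd_jacobian <- function(f, p, delta = 1e-6) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a positive real scalar")
  f <- as_target_fn(f, p)
  value <- f(p)
  J <- vapply(seq_along(p), function(j) {
    pp <- p; pm <- p
    pp[j] <- pp[j] + delta / 2
    pm[j] <- pm[j] - delta / 2
    (f(pp) - f(pm)) / delta
  }, numeric(length(value)))
  J <- matrix(J, nrow = length(value))
  check_finite_cols(J, "cd_jacobian")
  new_derivative_result(value, J, "central_diff", delta)
}

#' Directional derivative by a chosen engine
#'
#' Computes \code{jacobian(f)(p) \%*\% v} without forming the full Jacobian:
#' the complex-step engine evaluates \code{Im(f(p + delta*1i*v))/delta},
#' the difference engines perturb along \code{v}, and the dual engine seeds
#' a single dual direction.
#'
#' @inheritParams cs_jacobian
#' @param v direction vector, same length as \code{p}, not all zero.
#' @param engine one of \code{"complex_step"}, \code{"forward_diff"},
#'   \code{"central_diff"}, \code{"dual"}.
#' @return numeric output vector of length \code{n_outputs}.
#' @export
directional_derivative <- function(f, p, v,
                                   engine = c("complex_step", "forward_diff",
                                              "central_diff", "dual"),
                                   delta = NULL) {
  engine <- match.arg(engine)
  if (length(v) != length(p)) stop("v must have the same length as p")
  if (all(v == 0)) stop("direction v must be nonzero")
  f <- as_target_fn(f, p)
  switch(engine,
    complex_step = {
      if (is.null(delta)) delta <- 1e-12
      Im(f(as.complex(p) + delta * 1i * v)) / delta
    },
    forward_diff = {
      if (is.null(delta)) delta <- 1e-6
      (f(p + delta * v) - f(p)) / delta
    },
    central_diff = {
      if (is.null(delta)) delta <- 1e-6
      (f(p + delta / 2 * v) - f(p - delta / 2 * v)) / delta
    },
    dual = {
      out <- f(dual(p, matrix(v, ncol = 1)))
      as.vector(dual_deriv(out))
    })
}
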