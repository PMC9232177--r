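#' Mean extinction time and mean total infected for the stochastic SIR chain
#'
#' First-step analysis of the continuous-time Markov chain on (infectives
#' \eqn{i}, survivors \eqn{n = i + s}) with recovery rate \eqn{i\delta} and
#' infection rate \eqn{i(n-i)\eta/N} gives triangular recurrences for the
#' mean days to elimination \eqn{t_{in}} and the mean number ever infected
#' \eqn{m_{in}}:
#' \deqn{t_{in} = \frac{1 + a\,t_{i-1,n-1} + b\,t_{i+1,n}}{a + b}, \qquad
#'       m_{in} = \frac{a\,(m_{i-1,n-1} + 1) + b\,m_{i+1,n}}{a + b},}
#' with \eqn{a = i\delta}, \eqn{b = i(n-i)\eta/N}, boundary rows
#' \eqn{t_{0n} = m_{0n} = 0}, \eqn{m_{ii} = i} and
#' \eqn{t_{ii} = \sum_{j=1}^{i} 1/(j\delta)}.  The sweep runs
#' \eqn{n = 1, \dots, N} with \eqn{i} descending, in a compiled inner loop;
#' only two columns are retained in streaming mode, so population sizes in
#' the tens of thousands complete in seconds.
#'
#' @param N target population size (initial infectives + susceptibles).
#' @param delta recovery rate per person per day (> 0).
#' @param eta infection rate per encounter per day (>= 0).
#' @param full keep the full (N+1) x (N+1) grids (indexed \code{[i+1, n+1]}
#'   for 0 <= i <= n <= N).  Defaults to TRUE for N <= 2000; requesting
#'   full grids beyond \code{max_full_N} is an error (memory grows as
#'   2(N+1)^2 doubles) and the column-only streaming mode should be used.
#' @param max_full_N guard for full-grid storage.
#' @return an object of class \code{"sir_chain_grid"} with
#'   \code{T_at_N}, \code{M_at_N} (the n = N columns over i = 0..N) and,
#'   when \code{full}, matrices \code{T} and \code{M}.
#' @examples
#' g <- sir_mean_grids(100, delta = 0.5025, eta = 0.7194)
#' g$T_at_N[2]   # mean days to extinction starting from (i=1, n=100)
#' @export
sir_mean_grids <- function(N, delta, eta, full = (N <= 2000),
                           max_full_N = 8000) {
  check_sir_spec(N, delta, eta)
  if (full && N > max_full_N)
    stop(sprintf(paste0("full grids for N = %d need ~%.1f GB; ",
                        "use full = FALSE (streaming column mode)"),
                 N, 2 * 8 * (N + 1)^2 / 1e9))
  res <- .sir_grids_real(as.integer(N), delta, eta, full)
  structure(list(N = N, delta = delta, eta = eta,
                 T_at_N = res$Tcol, M_at_N = res$Mcol,
                 T = res$T, M = res$M, full = full),
            class = "sir_chain_grid")
}

check_sir_spec <- function(N, delta, eta) {
  if (!(is.numeric(N) && length(N) == 1 && N >= 1 && N == floor(N)))
    stop("N must be a positive integer")
  if (!(Re(delta) > 0)) stop("delta must be positive")
  if (!(Re(eta) >= 0)) stop("eta must be nonnegative")
  invisible(TRUE)
}

#' @export
print.sir_chain_grid <- function(x, ...) {
  cat(sprintf("<sir_chain_grid> N=%d, delta=%g, eta=%g (%s)\n", x$N,
              x$delta, x$eta, if (x$full) "full grids" else "streaming"))
  cat(sprintf("  from (i=1, n=N): mean extinction time %.6g days, mean total infected %.6g\n",
              x$T_at_N[2], x$M_at_N[2]))
  invisible(x)
}

#' @export
plot.sir_chain_grid <- function(x, what = c("T", "M"), ...) {
  what <- match.arg(what)
  if (!x$full) stop("plotting needs full grids (full = TRUE)")
  z <- x[[what]]
  graphics::image(0:x$N, 0:x$N, z, xlab = "infectives i", ylab = "n = i + s",
                  main = if (what == "T") "mean days to extinction"
                         else "mean total infected", ...)
  invisible(x)
}

#' Parameter sensitivities of the SIR-chain means
#'
#' Derivatives of the \eqn{t_{in}} and \eqn{m_{in}} grids with respect to
#' \eqn{\delta} and \eqn{\eta}, by either engine:
#' \describe{
#'   \item{complex_step}{re-runs the recurrence with
#'     \eqn{\delta + \Delta i} (then \eqn{\eta + \Delta i}) over the
#'     complex field and divides imaginary parts by \eqn{\Delta}.}
#'   \item{manual}{propagates the analytically differentiated recurrence
#'     (quotient rule on \eqn{a}, \eqn{b}, \eqn{1/(a+b)}) in tandem with
#'     the primal sweep, including the differentiated boundary rows
#'     \eqn{\partial t_{ii}/\partial\delta = -\sum_{j\le i} 1/(j\delta^2)}
#'     and \eqn{\partial m_{ii}/\partial\theta = 0}.}
#' }
#' The two engines agree entrywise to about 1e-6 relative.
#'
#' @inheritParams sir_mean_grids
#' @param engine \code{"complex_step"} or \code{"manual"}.
#' @param delta_step complex perturbation size, default 1e-10.
#' @return a list of class \code{"sir_chain_sens"}: columns at n = N
#'   (\code{dT_ddelta}, \code{dT_deta}, \code{dM_ddelta}, \code{dM_deta},
#'   plus primal \code{T_at_N}, \code{M_at_N}) and, when \code{full},
#'   the corresponding full grids in \code{grids}.
#' @export
sir_mean_sensitivities <- function(N, delta, eta,
                                   engine = c("complex_step", "manual"),
                                   delta_step = 1e-10,
                                   full = (N <= 2000), max_full_N = 8000) {
  engine <- match.arg(engine)
  check_sir_spec(N, delta, eta)
  if (full && N > max_full_N)
    stop("full grids too large; use full = FALSE")
  if (engine == "complex_step") {
    stopifnot(delta_step > 0)
    rd <- .sir_grids_complex(as.integer(N),
                             as.complex(delta + delta_step * 1i),
                             as.complex(eta), full)
    re <- .sir_grids_complex(as.integer(N), as.complex(delta),
                             as.complex(eta + delta_step * 1i), full)
    out <- list(T_at_N = Re(rd$Tcol), M_at_N = Re(rd$Mcol),
                dT_ddelta = Im(rd$Tcol) / delta_step,
                dM_ddelta = Im(rd$Mcol) / delta_step,
                dT_deta = Im(re$Tcol) / delta_step,
                dM_deta = Im(re$Mcol) / delta_step)
    if (full)
      out$grids <- list(T = Re(rd$T), M = Re(rd$M),
                        dT_ddelta = Im(rd$T) / delta_step,
                        dM_ddelta = Im(rd$M) / delta_step,
                        dT_deta = Im(re$T) / delta_step,
                        dM_deta = Im(re$M) / delta_step)
  } else {
    rm_ <- .sir_grids_manual(as.integer(N), delta, eta, full)
    out <- list(T_at_N = rm_$Tcol, M_at_N = rm_$Mcol,
                dT_ddelta = rm_$dTddelta_col, dM_ddelta = rm_$dMddelta_col,
                dT_deta = rm_$dTdeta_col, dM_deta = rm_$dMdeta_col)
    if (full)
      out$grids <- list(T = rm_$T, M = rm_$M,
                        dT_ddelta = rm_$dTddelta, dM_ddelta = rm_$dMddelta,
                        dT_deta = rm_$dTdeta, dM_deta = rm_$dMdeta)
  }
  out$N <- N; out$delta <- delta; out$eta <- eta; out$engine <- engine
  out$step <- if (engine == "complex_step") delta_step else 0
  class(out) <- "sir_chain_sens"
  out
}

#' @export
print.sir_chain_sens <- function(x, ...) {
  cat(sprintf("<sir_chain_sens> N=%d engine=%s\n", x$N, x$engine))
  cat(sprintf("  at (i=1, n=N): dT/ddelta=%.6g dT/deta=%.6g dM/ddelta=%.6g dM/deta=%.6g\n",
              x$dT_ddelta[2], x$dT_deta[2], x$dM_ddelta[2], x$dM_deta[2]))
  invisible(x)
}

#' Exact stochastic simulation (Gillespie) of the SIR chain
#'
#' Direct-method simulation of the same Markov chain the recurrences
#' solve: infection (rate \eqn{i(n-i)\eta/N}, \eqn{i \to i+1}) and
#' recovery (rate \eqn{i\delta}, \eqn{i \to i-1}, \eqn{n \to n-1}) where
#' \eqn{N = s_0 + i_0}, run until the infectives die out.  Records the
#' extinction time and total ever infected per run; reproducible under the
#' seed.
#'
#' @param s0,i0 initial susceptibles and infectives.
#' @param delta,eta recovery and infection rates (per day).
#' @param runs number of independent runs (>= 2).
#' @param seed integer RNG seed.
#' @return an object of class \code{"ssa_summary"}: \code{runs},
#'   \code{mean_time}, \code{se_time} (days), \code{mean_infected},
#'   \code{se_infected} (people), \code{seed}, and the per-run
#'   \code{samples} matrix.
#' @export
sir_ssa_simulate <- function(s0, i0, delta, eta, runs = 100, seed = 1) {
  stopifnot(runs >= 2, s0 >= 0, i0 >= 1)
  if (delta <= 0 || eta < 0) stop("rates must be positive (delta) / nonnegative (eta)")
  set.seed(seed)
  samples <- .sir_ssa_runs(as.integer(s0), as.integer(i0), delta, eta,
                           as.integer(runs))
  colnames(samples) <- c("time", "infected")
  structure(list(runs = runs,
                 mean_time = mean(samples[, 1]),
                 se_time = stats::sd(samples[, 1]) / sqrt(runs),
                 mean_infected = mean(samples[, 2]),
                 se_infected = stats::sd(samples[, 2]) / sqrt(runs),
                 seed = seed, samples = samples),
            class = "ssa_summary")
}

#' @export
print.ssa_summary <- function(x, ...) {
  cat(sprintf("<ssa_summary> %d runs (seed %d)\n", x$runs, x$seed))
  cat(sprintf("  time to extinction: %.4g +/- %.3g days\n",
              x$mean_time, x$se_time))
  cat(sprintf("  total infected:     %.4g +/- %.3g people\n",
              x$mean_infected, x$se_infected))
  invisible(x)
}
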