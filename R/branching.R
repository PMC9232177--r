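#' Birth-death-migration branching process
#'
#' A multitype continuous-time branching process on n nodes: a particle at
#' node i splits in two at rate \eqn{\beta_i > 0}, dies at rate
#' \eqn{\delta_i > 0}, and migrates to node j at rate
#' \eqn{\lambda_{ij} \ge 0} (zero diagonal).  \eqn{\lambda_i =
#' \sum_{j\ne i}\lambda_{ij}} denotes the total migration rate out of i.
#'
#' Parameter vectors follow the packing \code{(delta, beta, vec(lambda))}
#' (column-major) throughout; see \code{\link{bdm_pack_params}}.
#'
#' @param beta,delta per-node birth and death rates, length n, positive.
#' @param lambda n x n migration-rate matrix, nonnegative, zero diagonal.
#' @return an object of class \code{"bdm_process"}.
#' @export
bdm_process <- function(beta, delta, lambda) {
  n <- length(beta)
  lambda <- as.matrix(lambda)
  stopifnot(length(delta) == n, all(dim(lambda) == n))
  if (!all(is.finite(beta)) || !all(is.finite(delta)) ||
      !all(is.finite(lambda)))
    stop("all rates must be finite")
  if (any(beta <= 0)) stop("birth rates beta must be positive")
  if (any(delta <= 0)) stop("death rates delta must be positive")
  if (any(lambda < 0)) stop("migration rates must be nonnegative")
  if (any(diag(lambda) != 0)) stop("lambda must have a zero diagonal")
  structure(list(beta = as.numeric(beta), delta = as.numeric(delta),
                 lambda = lambda, lam_row_sums = rowSums(lambda),
                 n = n),
            class = "bdm_process")
}

#' @export
print.bdm_process <- function(x, ...) {
  cat(sprintf("<bdm_process> %d node(s)\n", x$n))
  cat("  beta: ", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  delta:", paste(signif(x$delta, 4), collapse = ", "), "\n")
  cat("  total migration out:", paste(signif(x$lam_row_sums, 4),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Pack / unpack the parameter vector of a process
#'
#' The canonical packing is \code{(delta_1..delta_n, beta_1..beta_n,
#' vec(lambda))} with \code{vec} column-major, giving \code{2n + n^2}
#' parameters.  Diagonal lambda slots are carried (always zero) so that
#' index arithmetic stays uniform.
#'
#' @param proc a \code{\link{bdm_process}}.
#' @return numeric parameter vector.
#' @export
bdm_pack_params <- function(proc) {
  c(proc$delta, proc$beta, as.vector(proc$lambda))
}

#' @rdname bdm_pack_params
#' @param theta packed parameter vector (possibly complex, for
#'   complex-step differentiation).
#' @param n number of nodes.
#' @return for \code{bdm_unpack_params}, a list \code{(delta, beta,
#'   lambda)} without validation (complex entries allowed).
#' @export
bdm_unpack_params <- function(theta, n) {
  stopifnot(length(theta) == 2 * n + n^2)
  list(delta = theta[seq_len(n)],
       beta = theta[n + seq_len(n)],
       lambda = matrix(theta[2 * n + seq_len(n^2)], n, n))
}

#' Mean infinitesimal generator
#'
#' \eqn{\Omega_{ii} = \beta_i - \delta_i - \lambda_i},
#' \eqn{\Omega_{ij} = \lambda_{ij}} for \eqn{j \ne i}.  Its exponential
#' \eqn{e^{t\Omega}} propagates expected counts by node.
#'
#' @param proc a \code{\link{bdm_process}}.
#' @return n x n numeric matrix.
#' @export
generator_matrix <- function(proc) {
  omega <- proc$lambda
  diag(omega) <- proc$beta - proc$delta - proc$lam_row_sums
  omega
}

#' Mean matrix \eqn{e^{t\Omega}}
#'
#' Entry (i, j) is the expected number of particles at node j at time t
#' descending from one particle at node i at time 0.
#'
#' @inheritParams generator_matrix
#' @param t nonnegative time.
#' @return n x n numeric matrix.
#' @export
mean_matrix <- function(proc, t) {
  stopifnot(t >= 0)
  as.matrix(Matrix::expm(t * Matrix::Matrix(generator_matrix(proc))))
}

# strong connectivity of the migration graph by forward+backward reachability
migration_irreducible <- function(lambda) {
  n <- nrow(lambda)
  if (n == 1) return(TRUE)
  reach <- function(adj) {
    seen <- c(TRUE, rep(FALSE, n - 1))
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  reach(lambda) && reach(t(lambda))
}

#' Dominant eigenvalue and eigenvectors of the generator
#'
#' For an irreducible process \eqn{\Omega} is an irreducible Metzler
#' matrix, so its eigenvalue of maximal real part \eqn{\rho} is real and
#' simple with entrywise-positive right eigenvector (Perron-Frobenius
#' applied to \eqn{\Omega + cI}).  The sign of \eqn{\rho} classifies the
#' process: subcritical (\eqn{\rho < 0}), critical (0), supercritical
#' (\eqn{\rho > 0}).  \code{w} is normalized positive and the left
#' eigenvector \code{v} rescaled so \eqn{v w = 1}.
#'
#' @inheritParams generator_matrix
#' @return an object of class \code{"eigen_triple"}: \code{rho}, \code{v}
#'   (row, left), \code{w} (column, right).
#' @export
dominant_eigen <- function(proc) {
  if (!migration_irreducible(proc$lambda))
    stop("migration graph is not strongly connected; analyse each communicating component separately")
  omega <- generator_matrix(proc)
  er <- eigen(omega)
  k <- which.max(Re(er$values))
  rho <- Re(er$values[k])
  if (abs(Im(er$values[k])) > 1e-10 * max(1, abs(rho)))
    stop("dominant eigenvalue has a non-negligible imaginary part")
  w <- Re(er$vectors[, k])
  if (sum(w) < 0) w <- -w
  if (any(w <= 0)) stop("dominant right eigenvector is not positive")
  el <- eigen(t(omega))
  kl <- which.min(abs(el$values - er$values[k]))
  v <- Re(el$vectors[, kl])
  v <- v / sum(v * w)
  res <- max(abs(omega %*% w - rho * w), abs(t(v) %*% omega - rho * t(v)))
  if (res > 1e-8 * max(1, abs(rho)))
    stop("eigen solution residual too large")
  structure(list(rho = rho, v = v, w = w), class = "eigen_triple")
}

#' @export
print.eigen_triple <- function(x, ...) {
  cat(sprintf("<eigen_triple> rho = %.8g (%s)\n", x$rho,
              if (x$rho > 0) "supercritical" else if (x$rho < 0)
                "subcritical" else "critical"))
  invisible(x)
}

# elementary structure matrix dOmega/dtheta for one rate parameter
omega_structure <- function(n, param, i, j = NULL) {
  D <- matrix(0, n, n)
  switch(param,
    beta = D[i, i] <- 1,
    delta = D[i, i] <- -1,
    lambda = {
      if (is.null(j) || j == i) stop("lambda sensitivity needs j != i")
      D[i, i] <- -1
      D[i, j] <- 1
    },
    stop(sprintf("unknown parameter '%s' (use beta, delta or lambda)", param)))
  D
}

#' Sensitivity of the growth rate
#'
#' Differentiating \eqn{\Omega w = \rho w} and multiplying by the left
#' eigenvector gives \eqn{\partial\rho/\partial\theta =
#' v\,(\partial\Omega/\partial\theta)\,w} for normalized \eqn{v w = 1}.
#' The structure matrices are elementary: \eqn{\partial\Omega/\partial
#' \beta_i} has a single 1 at (i, i), \eqn{\partial\Omega/\partial\delta_i}
#' a single -1, and \eqn{\partial\Omega/\partial\lambda_{ij}} a -1 at
#' (i, i) and +1 at (i, j).  In particular
#' \eqn{\partial\rho/\partial\delta_i = -\partial\rho/\partial\beta_i}
#' exactly.
#'
#' @inheritParams generator_matrix
#' @param param \code{"beta"}, \code{"delta"} or \code{"lambda"}.
#' @param i node index (row index for lambda).
#' @param j column index for lambda.
#' @param eig optional precomputed \code{\link{dominant_eigen}} triple.
#' @return the scalar derivative \eqn{\partial\rho/\partial\theta}.
#' @export
growth_rate_sensitivity <- function(proc, param, i, j = NULL, eig = NULL) {
  if (is.null(eig)) eig <- dominant_eigen(proc)
  D <- omega_structure(proc$n, param, i, j)
  as.numeric(t(eig$v) %*% D %*% eig$w)
}

# per-node normalizers beta_i + delta_i + lambda_i (complex-safe)
bdm_totals <- function(delta, beta, lambda) {
  beta + delta + rowSums(lambda) - diag(lambda)
}

#' Offspring generating function
#'
#' At the first event a node-i particle dies (probability
#' \eqn{\delta_i/s_i}), splits into two node-i particles
#' (\eqn{\beta_i/s_i}), or migrates to node j
#' (\eqn{\lambda_{ij}/s_i}), with \eqn{s_i = \beta_i+\delta_i+\lambda_i}:
#' \deqn{P_i(x) = \frac{\delta_i + \beta_i x_i^2 +
#'   \sum_{j\ne i}\lambda_{ij} x_j}{\beta_i + \delta_i + \lambda_i}.}
#' \eqn{P} maps \eqn{[0,1]^n} into itself and \eqn{P(1) = 1}.
#'
#' @inheritParams generator_matrix
#' @param x vector in [0,1]^n (complex entries accepted for perturbation).
#' @return vector \eqn{P(x)}.
#' @export
progeny_gf <- function(proc, x) {
  stopifnot(length(x) == proc$n)
  s <- proc$beta + proc$delta + proc$lam_row_sums
  (proc$delta + proc$beta * x^2 + as.vector(proc$lambda %*% x)) / s
}

# parameter-vector form of the extinction fixed point, used as the
# complex-step oracle: iterates e <- P(e) over possibly-complex rates
bdm_extinction_fp <- function(theta, n, tol = 1e-16, maxiter = 500) {
  u <- bdm_unpack_params(theta, n)
  s <- bdm_totals(u$delta, u$beta, u$lambda)
  lam0 <- u$lambda
  diag(lam0) <- 0
  x <- rep(if (is.complex(theta)) 0 + 0i else 0, n)
  for (k in seq_len(maxiter)) {
    y <- (u$delta + u$beta * x^2 + as.vector(lam0 %*% x)) / s
    if (sqrt(sum(Mod(y - x)^2)) < tol) return(y)
    x <- y
  }
  x
}

#' Extinction probabilities by monotone fixed-point iteration
#'
#' Starting from \eqn{e_0 = 0}, the sequence \eqn{e_k = P(e_{k-1})} is
#' entrywise nondecreasing, bounded above by the true extinction vector,
#' and converges to the minimal solution of \eqn{e = P(e)}: the vector of
#' probabilities that the line of descent of one node-i particle dies out.
#' For subcritical or critical processes \eqn{e = 1}; for supercritical
#' ones all \eqn{e_i \in (0,1)}.
#'
#' @inheritParams generator_matrix
#' @param tol stop when the successive-iterate norm falls below this
#'   (default 1e-16).
#' @param maxiter iteration cap (default 500); reaching it sets
#'   \code{converged = FALSE} rather than erroring (near-critical
#'   processes converge slowly).
#' @return an object of class \code{"extinction_result"}: \code{e},
#'   \code{iterations}, \code{converged}, \code{residual}.
#' @export
extinction_probabilities <- function(proc, tol = 1e-16, maxiter = 500) {
  stopifnot(tol > 0, maxiter >= 1)
  x <- rep(0, proc$n)
  converged <- FALSE
  iter <- maxiter
  for (k in seq_len(maxiter)) {
    y <- progeny_gf(proc, x)
    if (sqrt(sum((y - x)^2)) < tol) {
      converged <- TRUE
      iter <- k
      x <- y
      break
    }
    x <- y
  }
  structure(list(e = pmin(x, 1), iterations = iter, converged = converged,
                 residual = sqrt(sum((progeny_gf(proc, x) - x)^2))),
            class = "extinction_result")
}

#' @export
print.extinction_result <- function(x, ...) {
  cat(sprintf("<extinction_result> %d iteration(s), %s, residual %.3g\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              x$residual))
  print(x$e)
  invisible(x)
}

#' Implicit-differentiation sensitivities of the extinction vector
#'
#' Differentiating the fixed point \eqn{e(\theta) = P[e(\theta), \theta]}
#' gives \eqn{d_\theta e = [I - d_e P(e)]^{-1} d_\theta P(e)}.  For a
#' strictly supercritical process the inverse exists at the minimal fixed
#' point.  The Jacobians are analytic: \eqn{\partial P_i/\partial x_i =
#' 2\beta_i e_i / s_i}, \eqn{\partial P_i/\partial x_j = \lambda_{ij}/s_i},
#' and the parameter derivatives include each parameter's appearance in the
#' normalizer \eqn{s_i}.
#'
#' @inheritParams generator_matrix
#' @param e optional precomputed extinction vector.
#' @return n x (2n + n^2) matrix of derivatives, columns in the
#'   \code{(delta, beta, vec(lambda))} packing.
#' @export
extinction_sensitivities <- function(proc, e = NULL) {
  eig <- dominant_eigen(proc)
  if (eig$rho <= 0)
    stop(sprintf(paste0("process is not supercritical (rho = %.4g); ",
                        "e = 1 identically and the implicit system is singular. ",
                        "Use complex-step differentiation of the fixed point ",
                        "for near-critical studies."), eig$rho))
  n <- proc$n
  if (is.null(e)) e <- extinction_probabilities(proc)$e
  s <- proc$beta + proc$delta + proc$lam_row_sums
  P_e <- progeny_gf(proc, e)
  # d_e P
  deP <- proc$lambda / s
  diag(deP) <- 2 * proc$beta * e / s
  # d_theta P, one column per packed parameter
  p <- 2 * n + n^2
  dthP <- matrix(0, n, p)
  for (k in seq_len(n)) {
    dthP[k, k] <- (1 - P_e[k]) / s[k]                 # delta_k
    dthP[k, n + k] <- (e[k]^2 - P_e[k]) / s[k]        # beta_k
  }
  for (l in seq_len(n)) for (k in seq_len(n)) {
    if (k != l) dthP[k, 2 * n + (l - 1) * n + k] <- (e[l] - P_e[k]) / s[k]
  }
  A <- diag(n) - deP
  out <- tryCatch(solve(A, dthP),
                  error = function(err) stop("implicit system I - d_eP is singular",
                                             call. = FALSE))
  out <- matrix(out, n, p)
  colnames(out) <- bdm_param_names(n)
  out
}

bdm_param_names <- function(n) {
  c(paste0("delta", seq_len(n)), paste0("beta", seq_len(n)),
    as.vector(outer(seq_len(n), seq_len(n),
                    function(i, j) paste0("lambda", i, ".", j))))
}

#' Expected offspring matrix
#'
#' \eqn{F_{ii} = 2\beta_i/s_i} (a split replaces one particle by two of
#' the same node) and \eqn{F_{ij} = \lambda_{ij}/s_i}, with
#' \eqn{s_i = \beta_i + \delta_i + \lambda_i}; the embedded-jump-chain
#' mean offspring counts.
#'
#' @inheritParams generator_matrix
#' @return n x n numeric matrix F.
#' @export
offspring_matrix <- function(proc) {
  s <- proc$beta + proc$delta + proc$lam_row_sums
  F_ <- proc$lambda / s
  diag(F_) <- 2 * proc$beta / s
  F_
}

#' Total progeny matrix
#'
#' \eqn{A = (I - F)^{-1}}: entry (i, j) is the expected number of node-j
#' particles ever generated by one initial node-i particle.  Requires the
#' process subcritical (spectral radius of F below 1) for the series
#' \eqn{\sum_k F^k} to converge.
#'
#' @inheritParams generator_matrix
#' @return n x n numeric matrix A.
#' @export
total_progeny <- function(proc) {
  F_ <- offspring_matrix(proc)
  sr <- max(Mod(eigen(F_, only.values = TRUE)$values))
  if (sr >= 1)
    stop(sprintf("spectral radius of F is %.4g >= 1: total progeny diverges (process not subcritical)", sr))
  solve(diag(proc$n) - F_)
}

# analytic dF/dtheta for one rate parameter (quotient rule on s_k)
offspring_matrix_sensitivity <- function(proc, param, i, j = NULL) {
  n <- proc$n
  s <- proc$beta + proc$delta + proc$lam_row_sums
  dF <- matrix(0, n, n)
  k <- i
  row_lambda <- proc$lambda[k, ]
  switch(param,
    beta = {
      dF[k, ] <- -row_lambda / s[k]^2
      dF[k, k] <- 2 * (proc$delta[k] + proc$lam_row_sums[k]) / s[k]^2
    },
    delta = {
      dF[k, ] <- -row_lambda / s[k]^2
      dF[k, k] <- -2 * proc$beta[k] / s[k]^2
    },
    lambda = {
      if (is.null(j) || j == i) stop("lambda sensitivity needs j != i")
      dF[k, ] <- -row_lambda / s[k]^2
      dF[k, k] <- -2 * proc$beta[k] / s[k]^2
      dF[k, j] <- dF[k, j] + 1 / s[k]
    },
    stop(sprintf("unknown parameter '%s'", param)))
  dF
}

#' Sensitivity of the total progeny matrix
#'
#' Differentiating \eqn{A = (I - F)^{-1}} gives
#' \eqn{d_\theta A = (I - F)^{-1}\, d_\theta F\, (I - F)^{-1}}, with
#' \eqn{d_\theta F} obtained analytically by the quotient rule on the
#' normalizer \eqn{s_i}.
#'
#' @inheritParams growth_rate_sensitivity
#' @param A optional precomputed \code{\link{total_progeny}} matrix.
#' @return n x n matrix \eqn{\partial A/\partial\theta}.
#' @export
total_progeny_sensitivity <- function(proc, param, i, j = NULL, A = NULL) {
  if (is.null(A)) A <- total_progeny(proc)
  dF <- offspring_matrix_sensitivity(proc, param, i, j)
  A %*% dF %*% A
}
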