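# Shared oracles and small utilities, independent of the package internals.

rel_dist <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

max_rel_err <- function(got, want, floor = 1e-300) {
  max(abs(got - want) / pmax(abs(want), floor))
}

# Dense first-step-analysis oracle for the stochastic SIR chain: sets up
# the exact linear system over all states (i, n), 1 <= i <= n <= N, and
# solves it directly.  Feasible for tiny N only; used to validate the
# recurrence sweep.
#   (a+b) T(i,n) - a T(i-1,n-1) - b T(i+1,n) = 1
#   (a+b) M(i,n) - a M(i-1,n-1) - b M(i+1,n) = a
# with T(0,.) = M(0,.) = 0 and b = i (n-i) eta / N.
sir_dense_oracle <- function(N, delta, eta) {
  states <- do.call(rbind, lapply(1:N, function(n) cbind(i = 1:n, n = n)))
  idx <- function(i, n) which(states[, 1] == i & states[, 2] == n)
  m <- nrow(states)
  A <- matrix(0, m, m)
  bt <- numeric(m)
  bm <- numeric(m)
  for (r in seq_len(m)) {
    i <- states[r, 1]; n <- states[r, 2]
    a <- i * delta
    b <- i * (n - i) * eta / N
    A[r, r] <- a + b
    if (i - 1 >= 1) A[r, idx(i - 1, n - 1)] <- -a
    if (i + 1 <= n) A[r, idx(i + 1, n)] <- -b
    bt[r] <- 1
    bm[r] <- a
  }
  Tsol <- solve(A, bt)
  Msol <- solve(A, bm)
  Tm <- matrix(0, N + 1, N + 1)
  Mm <- matrix(0, N + 1, N + 1)
  for (r in seq_len(m)) {
    Tm[states[r, 1] + 1, states[r, 2] + 1] <- Tsol[r]
    Mm[states[r, 1] + 1, states[r, 2] + 1] <- Msol[r]
  }
  list(T = Tm, M = Mm)
}

# 2-node birth-death-migration example process used in several tests
bdm_example2 <- function() {
  bdm_process(beta = c(1.5, 1.5), delta = c(1.0, 1.75),
              lambda = matrix(c(0, 1.0, 0.5, 0), 2, 2))
}

# dominant eigenvalue of the generator as a (complex-capable) function of
# the packed parameter vector; used as the complex-step oracle for the
# analytic growth-rate sensitivity
bdm_rho_of_theta <- function(theta, n) {
  u <- bdm_unpack_params(theta, n)
  lam <- u$lambda
  diag(lam) <- 0
  omega <- lam
  diag(omega) <- u$beta - u$delta - rowSums(lam)
  ev <- eigen(omega, only.values = TRUE)$values
  ev[which.max(Re(ev))]
}

# total progeny matrix as a function of packed parameters (complex-capable)
bdm_progeny_of_theta <- function(theta, n) {
  u <- bdm_unpack_params(theta, n)
  lam <- u$lambda
  diag(lam) <- 0
  s <- u$beta + u$delta + rowSums(lam)
  F_ <- lam / s
  diag(F_) <- 2 * u$beta / s
  as.vector(solve(diag(n) - F_))
}

# extinction fixed point as a complex-capable function of packed parameters,
# written independently of the package internals
bdm_extinction_fp_oracle <- function(theta, n, tol = 1e-16, maxiter = 2000) {
  u <- bdm_unpack_params(theta, n)
  lam <- u$lambda
  diag(lam) <- 0
  s <- u$beta + u$delta + rowSums(lam)
  x <- rep(if (is.complex(theta)) 0 + 0i else 0, n)
  for (k in seq_len(maxiter)) {
    y <- (u$delta + u$beta * x^2 + as.vector(lam %*% x)) / s
    if (sqrt(sum(Mod(y - x)^2)) < tol) break
    x <- y
  }
  y
}

# differentiate the extinction iteration itself in tandem:
# dx_{k+1} = d_x P(x_k) dx_k + d_theta P(x_k), with both local jacobians
# obtained by complex step on the progeny map, independently of the
# implicit-differentiation linear solve being checked
tandem_extinction_sens <- function(proc, maxiter = 5000, tol = 1e-14) {
  n <- proc$n
  theta <- bdm_pack_params(proc)
  np <- length(theta)
  Pmap <- function(x, th) {
    u <- bdm_unpack_params(th, n)
    lam <- u$lambda
    diag(lam) <- 0
    s <- u$beta + u$delta + rowSums(lam)
    (u$delta + u$beta * x^2 + as.vector(lam %*% x)) / s
  }
  x <- rep(0, n)
  dx <- matrix(0, n, np)
  for (k in seq_len(maxiter)) {
    dP_x <- cs_jacobian(function(xx) Pmap(xx, as.complex(theta)), x)$jacobian
    dP_th <- cs_jacobian(function(th) Pmap(as.complex(x), th), theta)$jacobian
    dx_new <- dP_x %*% dx + dP_th
    x_new <- Pmap(x, theta)
    if (max(abs(x_new - x)) < tol && max(abs(dx_new - dx)) < tol) {
      dx <- dx_new
      break
    }
    x <- x_new
    dx <- dx_new
  }
  dx
}
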