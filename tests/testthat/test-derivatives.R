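test_that("complex-step jacobian matches closed forms to machine precision", {
  r <- cs_jacobian(function(p) p^2, 3, delta = 1e-12)
  expect_equal(r$jacobian, matrix(6), tolerance = 1e-13)
  expect_equal(r$value, 9)
  expect_identical(r$engine, "complex_step")

  r <- cs_jacobian(function(p) sin(p[1]) * exp(p[2]), c(0, 0), delta = 1e-12)
  expect_equal(r$jacobian, matrix(c(1, 0), 1, 2), tolerance = 1e-13)

  # exponential decay I0 * exp(-delta * t): d/ddelta = -t I0 exp(-delta t)
  decay <- get_test_function("decay")
  r <- cs_jacobian(decay$f, decay$p0)
  expect_equal(r$jacobian, decay$jacobian(decay$p0), tolerance = 1e-12)
  expect_equal(r$jacobian[1, 1], -10 * 100 * exp(-5), tolerance = 1e-12)
})

test_that("relative stepping scales the perturbation and guards zeros", {
  f <- function(p) p[1] * 1e-8 + p[2]^2
  p <- c(3e8, 2)
  r_abs <- cs_jacobian(f, p, relative = FALSE)
  r_rel <- cs_jacobian(f, p, relative = TRUE)
  expect_equal(r_rel$jacobian, r_abs$jacobian, tolerance = 1e-10)
  # a zero coordinate must fall back to the absolute step, not divide by 0
  r0 <- cs_jacobian(function(p) p[1] + p[2]^2, c(0, 2), relative = TRUE)
  expect_equal(r0$jacobian, matrix(c(1, 4), 1, 2), tolerance = 1e-10)
})

test_that("derivative engines validate arguments and flag bad evaluations", {
  expect_error(cs_jacobian(function(p) p, 1, delta = 0), "positive")
  expect_error(fd_jacobian(function(p) p, 1, delta = -1), "positive")
  expect_error(cd_jacobian(function(p) p, 1, delta = 0), "positive")
  f_na <- target_fn(function(p) c(0 * p[1] / 0, p[2]), 2)
  expect_error(cs_jacobian(f_na, c(1, 1)), "parameter index")
  f_flag <- target_fn(function(p) p^2, 1, analytic = FALSE)
  expect_warning(cs_jacobian(f_flag, 2), "analytic")
})

test_that("complex-step hessian reproduces analytic hessians and is symmetric", {
  h <- cs_hessian(function(p) p[1] * p[2], c(2, 3), delta = 1e-4)
  expect_equal(h$hessian, matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-8)

  h <- cs_hessian(function(p) p^4, 1, delta = 1e-4)
  expect_equal(h$hessian[1, 1], 12, tolerance = 1e-8)

  # exact symmetry by construction on a generic cubic, random points
  set.seed(11)
  g <- function(p) p[1]^3 + 2 * p[1] * p[2]^2 + p[2] * p[3] + p[3]^3
  for (k in 1:5) {
    p <- runif(3, 0.5, 2)
    H <- cs_hessian(g, p)$hessian
    expect_identical(H, t(H))
  }
  expect_error(cs_hessian(target_fn(function(p) c(p, p), 1), 1), "scalar")
})

test_that("finite differences behave as their truncation orders predict", {
  r <- fd_jacobian(function(p) p^2, 3, delta = 1e-6)
  expect_equal(r$jacobian[1, 1], 2 * 3 + 1e-6, tolerance = 1e-9)
  expect_equal(fd_jacobian(function(p) p[1] * 0 + 5, c(1, 2))$jacobian,
               matrix(0, 1, 2))
  expect_equal(fd_jacobian(function(p) p, 2, delta = 0.3)$jacobian[1, 1], 1)

  # central differences: exact on quadratics, error delta^2/4 on p^3 at 1
  expect_equal(cd_jacobian(function(p) p^2, 3, delta = 1e-4)$jacobian[1, 1],
               6, tolerance = 1e-10)
  expect_equal(cd_jacobian(function(p) p^3, 1, delta = 0.1)$jacobian[1, 1],
               3 + 0.1^2 / 4, tolerance = 1e-12)
  expect_equal(cd_jacobian(function(p) sin(p), 0, delta = 2e-1)$jacobian[1, 1],
               sin(0.1) * 2 / 0.2, tolerance = 1e-14)
})

test_that("all first-order engines agree pairwise on smooth functions", {
  for (nm in c("exp_sin", "polyprod", "trig_vec")) {
    tf <- get_test_function(nm)
    J <- list(cs = cs_jacobian(tf$f, tf$p0)$jacobian,
              fd = fd_jacobian(tf$f, tf$p0, delta = 1e-7)$jacobian,
              cd = cd_jacobian(tf$f, tf$p0, delta = 1e-5)$jacobian,
              dual = dual_jacobian(tf$f, tf$p0)$jacobian)
    ref <- tf$jacobian(tf$p0)
    for (j in J) expect_lt(max_rel_err(j, ref, floor = 1), 1e-5)
  }
})

test_that("complex step is immune to the cancellation that limits central differences", {
  tf <- get_test_function("exp_sin")
  ref <- tf$jacobian(tf$p0)
  deltas <- 10^-(2:12)
  cs_err <- vapply(deltas, function(d)
    max_rel_err(cs_jacobian(tf$f, tf$p0, delta = d)$jacobian, ref), numeric(1))
  cd_err <- vapply(deltas, function(d)
    max_rel_err(cd_jacobian(tf$f, tf$p0, delta = d)$jacobian, ref), numeric(1))
  # complex step: error decreases to the floor and stays there
  expect_lt(cs_err[length(deltas)], 1e-12)
  expect_true(all(diff(pmax(cs_err, 1e-15)) < 1e-12))
  # central differences blow up at tiny steps: U-shaped error
  expect_gt(cd_err[length(deltas)], 1e3 * min(cd_err))
  expect_gt(cd_err[length(deltas)], 1e3 * cs_err[length(deltas)])
  expect_lt(min(cd_err), cd_err[1])   # interior optimum beats the largest step
})

test_that("directional derivatives equal jacobian-vector products", {
  tf <- get_test_function("trig_vec")
  J <- tf$jacobian(tf$p0)
  # unit direction extracts a column
  expect_equal(directional_derivative(tf$f, tf$p0, c(1, 0)), J[, 1],
               tolerance = 1e-10)
  # linear map (written elementwise so every carrier supports it):
  # exact for any engine
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  flin <- function(p) c(2 * p[1] + 0.5 * p[2], -1 * p[1] + 3 * p[2])
  v <- c(0.3, -1.2)
  for (eng in c("complex_step", "forward_diff", "central_diff", "dual"))
    expect_equal(directional_derivative(flin, c(1, 1), v, engine = eng),
                 as.vector(A %*% v), tolerance = 1e-8)
  # random quadratic against the complex-step jacobian product
  set.seed(4)
  Q <- crossprod(matrix(runif(9), 3, 3))
  fq <- function(p) c(sum(p * (Q %*% p)), p[1] * p[3])
  p <- runif(3); v <- runif(3)
  expect_equal(directional_derivative(fq, p, v),
               as.vector(cs_jacobian(fq, p)$jacobian %*% v),
               tolerance = 1e-10)
  expect_error(directional_derivative(fq, p, c(0, 0, 0)), "nonzero")
})

test_that("column evaluation order does not change the complex-step jacobian", {
  # evaluations across parameters are independent; permuting them must
  # reproduce the same matrix entry for entry
  tf <- get_test_function("trig_vec")
  J <- cs_jacobian(tf$f, tf$p0)$jacobian
  perm <- 2:1
  Jperm <- vapply(perm, function(j) {
    pc <- as.complex(tf$p0)
    pc[j] <- pc[j] + 1e-12i
    Im(tf$f(pc)) / 1e-12
  }, numeric(2))
  expect_identical(J, Jperm[, order(perm)])
})
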