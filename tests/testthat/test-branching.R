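test_that("generator and mean matrices match hand arithmetic", {
  p1 <- bdm_process(beta = 1.5, delta = 1.0, lambda = matrix(0, 1, 1))
  expect_equal(generator_matrix(p1), matrix(0.5))
  expect_equal(mean_matrix(p1, 2), matrix(exp(1)), tolerance = 1e-10)
  expect_equal(mean_matrix(p1, 0), matrix(1))

  p2 <- bdm_example2()
  expect_equal(generator_matrix(p2),
               matrix(c(0, 1, 0.5, -1.25), 2, 2))
  # beta = delta leaves the conservative migration semigroup
  pm <- bdm_process(beta = c(1, 1), delta = c(1, 1),
                    lambda = matrix(c(0, 0.4, 0.7, 0), 2, 2))
  expect_equal(rowSums(generator_matrix(pm)), c(0, 0))
  expect_equal(rowSums(mean_matrix(pm, 3.7)), c(1, 1), tolerance = 1e-9)

  expect_error(bdm_process(beta = c(1, -1), delta = c(1, 1),
                           lambda = matrix(0, 2, 2)), "positive")
  expect_error(bdm_process(beta = 1, delta = 1, lambda = matrix(2, 1, 1)),
               "diagonal")
})

test_that("dominant eigenvalue classifies criticality with a valid eigensystem", {
  p1 <- bdm_process(beta = 1.5, delta = 1.0, lambda = matrix(0, 1, 1))
  e1 <- dominant_eigen(p1)
  expect_equal(e1$rho, 0.5)
  expect_equal(e1$v * e1$w, 1)

  p2 <- bdm_example2()
  e2 <- dominant_eigen(p2)
  om <- generator_matrix(p2)
  expect_lt(max(abs(om %*% e2$w - e2$rho * e2$w)), 1e-10)
  expect_lt(max(abs(t(e2$v) %*% om - e2$rho * t(e2$v))), 1e-10)
  expect_equal(sum(e2$v * e2$w), 1, tolerance = 1e-12)
  expect_true(all(e2$w > 0))

  sub <- random_bdm(3, criticality = "subcritical", seed = 21)
  expect_lt(dominant_eigen(sub)$rho, 0)

  # reducible migration graph is refused
  pr <- bdm_process(beta = c(1, 1), delta = c(2, 2),
                    lambda = matrix(c(0, 0, 1, 0), 2, 2))
  expect_error(dominant_eigen(pr), "strongly connected")
})

test_that("growth-rate sensitivity equals the eigenvector sandwich and its oracle", {
  p1 <- bdm_process(beta = 1.5, delta = 1.0, lambda = matrix(0, 1, 1))
  expect_equal(growth_rate_sensitivity(p1, "beta", 1), 1)
  expect_equal(growth_rate_sensitivity(p1, "delta", 1), -1)

  p2 <- bdm_example2()
  eig <- dominant_eigen(p2)
  theta <- bdm_pack_params(p2)
  # complex-step differentiation of the dominant eigenvalue itself
  oracle <- function(k) {
    th <- as.complex(theta)
    th[k] <- th[k] + 1e-9i
    Im(bdm_rho_of_theta(th, 2)) / 1e-9
  }
  expect_equal(growth_rate_sensitivity(p2, "delta", 1, eig = eig), oracle(1),
               tolerance = 1e-6)
  expect_equal(growth_rate_sensitivity(p2, "beta", 2, eig = eig), oracle(4),
               tolerance = 1e-6)
  expect_equal(growth_rate_sensitivity(p2, "lambda", 1, 2, eig = eig),
               oracle(2 * 2 + 2 * 1 + 1), tolerance = 1e-6)
  # a death-rate increase mirrors a birth-rate decrease exactly
  for (i in 1:2)
    expect_identical(growth_rate_sensitivity(p2, "delta", i, eig = eig),
                     -growth_rate_sensitivity(p2, "beta", i, eig = eig))
  expect_error(growth_rate_sensitivity(p2, "gamma", 1), "unknown")
})

test_that("progeny generating function is a proper stochastic map", {
  p2 <- bdm_example2()
  expect_equal(progeny_gf(p2, c(1, 1)), c(1, 1))
  s <- p2$beta + p2$delta + p2$lam_row_sums
  expect_equal(progeny_gf(p2, c(0, 0)), p2$delta / s)
  # hand-evaluated fractions at x = (0.5, 0.5)
  expect_equal(progeny_gf(p2, c(0.5, 0.5)),
               c((1.0 + 1.5 * 0.25 + 0.5 * 0.5) / 3.0,
                 (1.75 + 1.5 * 0.25 + 1.0 * 0.5) / 4.25))
  # random processes: P maps the unit cube into itself
  for (seed in 1:10) {
    pr <- random_bdm(3, criticality = "free", seed = seed)
    x <- runif(3)
    px <- progeny_gf(pr, x)
    expect_true(all(px >= 0 & px <= 1))
    expect_equal(progeny_gf(pr, rep(1, 3)), rep(1, 3))
  }
})

test_that("extinction iteration is monotone and lands on the minimal fixed point", {
  # scalar supercritical: e = delta / beta
  p1 <- bdm_process(beta = 1.5, delta = 1.0, lambda = matrix(0, 1, 1))
  r <- extinction_probabilities(p1)
  expect_true(r$converged)
  expect_equal(r$e, 2 / 3, tolerance = 1e-12)
  # subcritical processes are certain to die out
  sub <- random_bdm(3, criticality = "subcritical", seed = 33)
  expect_equal(extinction_probabilities(sub, tol = 1e-13)$e, rep(1, 3),
               tolerance = 1e-6)
  # iterates are entrywise nondecreasing
  p2 <- bdm_example2()
  x <- rep(0, 2)
  for (k in 1:60) {
    y <- progeny_gf(p2, x)
    expect_true(all(y >= x - 1e-15))
    x <- y
  }
  sup <- extinction_probabilities(p2)$e
  expect_true(all(sup > 0 & sup < 1))
})

test_that("implicit differentiation of the extinction vector matches oracles", {
  # scalar closed forms: e = delta/beta, de/ddelta = 1/beta, de/dbeta = -delta/beta^2
  p1 <- bdm_process(beta = 1.5, delta = 1.0, lambda = matrix(0, 1, 1))
  d1 <- extinction_sensitivities(p1)
  expect_equal(d1[1, "delta1"], 1 / 1.5, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(d1[1, "beta1"], -1.0 / 1.5^2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # 2-node example against complex-step differentiation of the fixed point
  p2 <- bdm_example2()
  d2 <- extinction_sensitivities(p2)
  theta <- bdm_pack_params(p2)
  cs <- cs_jacobian(function(th) bdm_extinction_fp_oracle(th, 2), theta,
                    delta = 1e-9)
  expect_lt(max(abs(d2 - cs$jacobian)) / max(abs(cs$jacobian)), 1e-6)

  # tandem differentiation of the iteration itself converges to the same limit
  tandem <- tandem_extinction_sens(p2)
  expect_lt(max(abs(d2 - tandem)), 1e-8)

  sub <- random_bdm(2, criticality = "subcritical", seed = 5)
  expect_error(extinction_sensitivities(sub), "supercritical")
})

test_that("total progeny and its sensitivity match scalar chain rules and series", {
  p1 <- bdm_process(beta = 1, delta = 2, lambda = matrix(0, 1, 1))
  expect_equal(offspring_matrix(p1), matrix(2 / 3))
  A1 <- total_progeny(p1)
  expect_equal(A1, matrix(3), tolerance = 1e-12)
  # (beta + delta)/(delta - beta) closed form
  expect_equal(A1[1, 1], (1 + 2) / (2 - 1))
  expect_equal(total_progeny_sensitivity(p1, "delta", 1)[1, 1], -2,
               tolerance = 1e-12)

  p2 <- bdm_process(beta = c(0.05, 0.08), delta = c(0.08, 0.11),
                    lambda = matrix(c(0, 4e-4, 3e-4, 0), 2, 2))
  F2 <- offspring_matrix(p2)
  A2 <- total_progeny(p2)
  # Neumann series oracle
  S <- diag(2); Fk <- diag(2)
  for (k in 1:2000) { Fk <- Fk %*% F2; S <- S + Fk }
  expect_lt(max(abs(A2 - S)), 1e-10)
  # analytic sensitivity vs complex step on the packed parameters
  theta <- bdm_pack_params(p2)
  for (spec in list(list("delta", 1, NULL, 1), list("beta", 2, NULL, 4),
                    list("lambda", 1, 2, 2 * 2 + 2 * 1 + 1))) {
    got <- total_progeny_sensitivity(p2, spec[[1]], spec[[2]], spec[[3]])
    th <- as.complex(theta)
    th[spec[[4]]] <- th[spec[[4]]] + 1e-9i
    want <- matrix(Im(bdm_progeny_of_theta(th, 2)) / 1e-9, 2, 2)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
    # central difference of A as a second, real-arithmetic oracle
    thp <- theta; thm <- theta
    thp[spec[[4]]] <- thp[spec[[4]]] + 1e-5
    thm[spec[[4]]] <- thm[spec[[4]]] - 1e-5
    cdiff <- matrix((bdm_progeny_of_theta(thp, 2) -
                     bdm_progeny_of_theta(thm, 2)) / 2e-5, 2, 2)
    expect_lt(max(abs(got - cdiff)) / max(abs(got)), 1e-4)
  }
  # supercritical process has no finite total progeny
  psup <- bdm_process(beta = 2, delta = 1, lambda = matrix(0, 1, 1))
  expect_error(total_progeny(psup), "spectral radius")
})

test_that("criticality of the generator governs extinction", {
  for (seed in 1:8) {
    pr <- random_bdm(3, criticality = "free", seed = seed)
    rho <- dominant_eigen(pr)$rho
    e <- extinction_probabilities(pr, tol = 1e-13)$e
    if (rho <= 0) expect_equal(e, rep(1, 3), tolerance = 1e-5)
    else expect_true(all(e < 1))
  }
})
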