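# one-state exponential decay, the workhorse closed-form model:
# x(t) = x0 exp(-beta t); dx/dbeta = -t x; d2x/dbeta2 = t^2 x
decay_model <- function(x0 = 100, tspan = c(0, 10))
  ode_model("decay", function(x, p, t) -p[1] * x[1], "I", "delta",
            0.5, x0, tspan)

test_that("trajectories honour closed forms and conservation", {
  # SIR with eta = 0: susceptibles frozen (checked in model tests); ROBER mass
  rob <- solve_trajectory(rober_model(), saveat = 10)
  expect_equal(colSums(rob$states), rep(1, length(rob$times)),
               tolerance = 1e-6)
  # CARRGO from the extinction point stays there
  car <- solve_trajectory(carrgo_model(), x0 = c(0, 0), saveat = 100)
  expect_equal(max(abs(car$states)), 0)
  # explicit saveat grid honoured
  tr <- solve_trajectory(decay_model(), saveat = c(0, 0.5, 2, 10))
  expect_equal(tr$times, c(0, 0.5, 2, 10))
  expect_error(solve_trajectory(decay_model(), rtol = -1))
})

test_that("forward sensitivity equations recover analytic sensitivities", {
  fs <- forward_ode_sensitivities(decay_model(), rtol = 1e-8)
  tt <- fs$trajectory$times
  expect_equal(fs$first_order[1, 1, ], -tt * 100 * exp(-0.5 * tt),
               tolerance = 1e-6)
  expect_equal(fs$first_order[1, 1, 11], -10 * 100 * exp(-5),
               tolerance = 1e-6)

  # SIR at eta = 0: dS/deta(t) = -S0 I0 (1 - exp(-delta t)) / (N delta)
  sir <- sir_model()
  fs <- forward_ode_sensitivities(sir, p = c(0, 0.5025), tspan = c(0, 50),
                                  rtol = 1e-9)
  tt <- fs$trajectory$times
  expect_equal(fs$first_order[1, 1, ],
               -3.4e8 * 100 * (1 - exp(-0.5025 * tt)) / (3.4e8 * 0.5025),
               tolerance = 1e-6)
})

test_that("directional forward variant propagates J.v without full jacobians", {
  sir <- sir_model()
  v <- c(0.3, -0.8)
  full <- forward_ode_sensitivities(sir, tspan = c(0, 60), rtol = 1e-8)
  dir1 <- forward_ode_sensitivities(sir, tspan = c(0, 60), rtol = 1e-8,
                                    directions = matrix(v, 2, 1))
  nt <- length(full$trajectory$times)
  want <- sapply(seq_len(nt), function(ti) full$first_order[, , ti] %*% v)
  expect_equal(dir1$first_order[, 1, ], want, tolerance = 1e-6)
})

test_that("complex-step trajectory sensitivities match forward and closed forms", {
  cs <- cs_ode_sensitivities(decay_model(), delta = 1e-10, rtol = 1e-8)
  tt <- cs$trajectory$times
  expect_lt(max_rel_err(cs$first_order[1, 1, -1],
                        (-tt * 100 * exp(-0.5 * tt))[-1]), 1e-6)
  # a parameter absent from the rhs yields an identically zero sheet
  m2 <- ode_model("decay2", function(x, p, t) -p[1] * x[1], "I",
                  c("delta", "unused"), c(0.5, 3), 100, c(0, 10))
  cs2 <- cs_ode_sensitivities(m2, rtol = 1e-8)
  expect_equal(max(abs(cs2$first_order[1, 2, ])), 0)
})

test_that("direct complex integration and the split real system agree", {
  sir <- sir_model()
  a <- cs_ode_sensitivities(sir, tspan = c(0, 100), delta = 1e-10, rtol = 1e-8)
  b <- cs_ode_sensitivities(sir, tspan = c(0, 100), delta = 1e-10, rtol = 1e-8,
                            integrator = "split")
  expect_lt(rel_dist(a$first_order, b$first_order), 1e-6)
})

test_that("complex-step solve real part reproduces the unperturbed trajectory", {
  sir <- sir_model()
  tr <- solve_trajectory(sir, tspan = c(0, 100), rtol = 1e-8)
  pc <- as.complex(sir$default_params)
  pc[1] <- pc[1] + 1e-10i
  sol <- diffsens:::solve_complex(sir, pc, as.complex(sir$default_x0),
                                  tr$times, 1e-8, 1e-11)
  expect_lt(rel_dist(Re(sol), tr$states), 1e-7)
})

test_that("CARRGO sensitivities show the published time structure", {
  # d x / d gamma changes sign over the course of therapy, and the
  # sensitivity to the birth rate rho peaks in the early phase near day 200
  cs <- cs_ode_sensitivities(carrgo_model(), delta = 1e-13, saveat = 1)
  dgam <- cs$first_order[1, 5, ]
  expect_true(min(dgam) < 0 && max(dgam) > 0)
  drho <- abs(cs$first_order[1, 4, ])
  t_peak <- cs$trajectory$times[which.max(drho)]
  expect_gt(t_peak, 100)
  expect_lt(t_peak, 300)
})

test_that("second-order trajectory sensitivities are symmetric and exact on closed forms", {
  so <- second_order_ode_sensitivities(decay_model(), saveat = 1, rtol = 1e-9)
  tt <- so$trajectory$times
  expect_lt(max_rel_err(so$second_order[1, 1, 1, -1],
                        (tt^2 * 100 * exp(-0.5 * tt))[-1]), 1e-3)
  # rhs linear in beta with state-independent coefficient: x = x0 + beta t,
  # all second derivatives vanish
  lin <- ode_model("lin", function(x, p, t) p[1] + 0 * x[1], "x", "b",
                   2, 0, c(0, 5))
  so <- second_order_ode_sensitivities(lin, saveat = 1)
  expect_lt(max(abs(so$second_order)), 1e-6)
  # symmetry in the parameter axes is exact by construction
  sir <- sir_model()
  so <- second_order_ode_sensitivities(sir, tspan = c(0, 30), saveat = 5)
  expect_identical(so$second_order[, 1, 2, ], so$second_order[, 2, 1, ])
})

test_that("conservation transfers to every sensitivity sheet", {
  for (m in list(sir_model(), rober_model())) {
    atol <- if (m$stiff) 1e-10 else 1e-8
    cs <- cs_ode_sensitivities(m, tspan = c(0, 100), delta = 1e-10,
                               rtol = 1e-7, atol = atol)
    sums <- apply(cs$first_order, c(2, 3), sum)
    scale <- max(abs(cs$first_order))
    expect_lt(max(abs(sums)), max(atol * 10, 1e-9 * scale))
  }
})

test_that("adjoint gradients match closed forms and the forward method", {
  m <- ode_model("d1", function(x, p, t) -p[1] * x[1], "x", "beta",
                 0.5, 1, c(0, 2))
  g <- scalar_functional(function(xT, p) xT[1], "final state")
  expect_equal(unname(adjoint_gradient(m, g, rtol = 1e-9)),
               -2 * exp(-1), tolerance = 1e-6)
  # functional independent of state and parameters has zero gradient
  expect_equal(unname(adjoint_gradient(m, function(xT, p) xT[1] * 0 + 3)),
               0, tolerance = 1e-10)
  # CARRGO: adjoint vs forward chain rule on well-conditioned functionals
  # (the cancer compartment during the growth phase at day 200, and the
  # CAR T-cell count at day 1000; the cancer count at day 1000 is extinct
  # to machine precision and its derivative sits below solver noise)
  car <- carrgo_model()
  ga_x <- adjoint_gradient(car, function(xT, p) xT[1], tspan = c(0, 200),
                           rtol = 1e-8, dense_n = 4001)
  fs <- forward_ode_sensitivities(car, saveat = c(0, 200), rtol = 1e-8)
  expect_lt(rel_dist(ga_x, fs$first_order[1, , 2]), 1e-3)
  ga_y <- adjoint_gradient(car, function(xT, p) xT[2], rtol = 1e-8,
                           dense_n = 8001)
  fs2 <- forward_ode_sensitivities(car, saveat = c(0, 1000), rtol = 1e-8)
  expect_lt(rel_dist(ga_y, fs2$first_order[2, , 2]), 1e-3)
})
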