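# Reduced ODE integration, cohort simulation and cross-validation.

test_that("integrate_reduced: scalar decay, zero matrix, and a dual-route Daphnia check", {
  tg <- seq(0, 5, by = 1e-3)
  tr <- integrate_reduced(matrix(-0.7), N0 = 2, t_grid = tg)
  expect_equal(tr$values[, 1], 2 * exp(-0.7 * tg), tolerance = 1e-8)
  tr0 <- integrate_reduced(matrix(0), N0 = 1.5, t_grid = tg)
  expect_equal(tr0$values[, 1], rep(1.5, length(tg)), tolerance = 1e-14)

  # two independent right-hand-side implementations must agree: the
  # env_matrix K from the TEST integrated by fixed-step RK4 versus a
  # hand-coded explicit moment system solved by deSolve's adaptive lsoda
  fx <- daphnia_fixture(); p <- fx$p
  res <- run_test(fx$model, seed = 3)
  r2 <- reorder_reduction(res, degree_order(res$basis))
  env <- env_input(f = 1.1)
  N0 <- c(1.2, 1.05, 0.98, 0.95)
  a <- integrate_reduced(r2$K, env, N0, tg)
  rhs <- function(t, y, parms) {
    f <- 1.1
    list(c(p$alpha * f * y[3] - p$mu * y[1],
           p$x_b * p$alpha * f * y[3] + p$delta * f * y[1] - (p$mu + p$eps) * y[2],
           p$x_b^2 * p$alpha * f * y[3] + 2 * p$delta * f * y[2] - (p$mu + 2 * p$eps) * y[3],
           p$x_b^3 * p$alpha * f * y[3] + 3 * p$delta * f * y[3] - (p$mu + 3 * p$eps) * y[4]))
  }
  b <- deSolve::ode(N0, tg, rhs, NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(a$values - b[, -1]) / pmax(abs(b[, -1]), 1)), 1e-8)
})

test_that("cohort solver conserves transported quantities and exact decay", {
  # pure transport (age): mass conserved exactly, positions translate
  sp <- istate_space(1, lower = 0, upper = 100)
  m <- pspm_model(sp, list(env_atom("e")), g = "1", mu = "0",
                  births = list(), outputs = list("1"))
  init <- cohort_population(cbind(c(1, 2.5)), c(1, 0.4))
  s <- simulate_cohorts(m, env_input(e = 1), init, dt = 0.01, t_end = 2,
                        weights = list("1"))
  expect_equal(s$outputs[, 1], rep(1.4, nrow(s$outputs)), tolerance = 1e-13)
  expect_equal(sort(s$cohorts$positions[, 1]), c(3, 4.5), tolerance = 1e-10)

  # pure decay: total mass e^{-mu0 t} with second-order error in dt
  m2 <- pspm_model(sp, list(env_atom("mu0")), g = "0", mu = "mu0",
                   births = list(), outputs = list("1"))
  errs <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    s2 <- simulate_cohorts(m2, env_input(mu0 = 0.8), init, dt = dt, t_end = 2,
                           weights = list("1"))
    max(abs(s2$outputs[, 1] - 1.4 * exp(-0.8 * s2$times)))
  }, numeric(1))
  expect_lt(errs[3], 1e-12)  # constant rate: midpoint exponential is exact
})

test_that("a conserved weight (A0 psi = 0) is preserved by the cohort solver", {
  # g = x (exponential growth), mu = 0: psi = 1/x satisfies psi' g = -psi *0?
  # use the transported invariant psi with psi' g = 0 -> constant psi; instead
  # take mu = 0, births off and check <m, psi> with psi solving psi' g = 0,
  # i.e. any constant; the sharper invariant: g = 1 and psi = exp(-x) decays
  # along transport like the death-discount, so pair it with mu = 0 and
  # verify d/dt <m, psi> = <m, A0 psi> numerically
  sp <- istate_space(1, lower = 0, upper = 50)
  m <- pspm_model(sp, list(env_atom("e")), g = "1", mu = "0",
                  births = list(), outputs = list("exp(-0.5*x)"))
  init <- cohort_population(cbind(c(0.5, 1.5)), c(1, 1))
  s <- simulate_cohorts(m, env_input(e = 1), init, dt = 0.005, t_end = 1,
                        weights = list("exp(-0.5*x)"))
  # exact: output(t) = sum m_i exp(-0.5 (x_i + t))
  expected <- (exp(-0.25) + exp(-0.75)) * exp(-0.5 * s$times)
  expect_lt(max(abs(s$outputs[, 1] - expected)), 1e-9)
})

test_that("open-loop Daphnia: structured and reduced trajectories agree and converge", {
  fx <- daphnia_fixture()
  res <- run_test(fx$model, seed = 3)
  r2 <- reorder_reduction(res, degree_order(res$basis))
  env <- env_input(f = 1)
  init <- cohort_population(cbind(c(0.6, 0.9, 1.2)), c(1, 0.8, 0.5))
  w <- lapply(0:3, function(i) sf_pow_int(sf_sym("x"), i))
  N0 <- vapply(0:3, function(i) sum(init$masses * init$positions[, 1]^i), numeric(1))
  errs <- vapply(c(8e-3, 4e-3, 2e-3), function(dt) {
    s <- simulate_cohorts(fx$model, env, init, dt = dt, t_end = 5, weights = w)
    r <- integrate_reduced(r2$K, env, N0, seq(0, 5, by = dt))
    max(compare_trajectories(r, s)$sup_rel)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_gt(convergence_order(errs), 0.7)
  # identical trajectories compare to zero error; mismatched grids interpolate
  r <- integrate_reduced(r2$K, env, N0, seq(0, 5, by = 2e-3))
  expect_equal(max(compare_trajectories(r, r)$sup_rel), 0)
  rc <- integrate_reduced(r2$K, env, N0, seq(0, 5, by = 5e-3))
  cmp <- compare_trajectories(r, rc)
  expect_lt(max(cmp$sup_rel), 1e-5)
  expect_gt(cmp$max_gap, 0)
})

test_that("closed-loop community: consistent at t = 0 and under switched-off feedback", {
  p <- daphnia_params()
  p$f_E <- function(E) E / (1 + E)
  p$h_E <- function(E) 1.5 * (2 - E)
  init <- list(cohorts = cohort_population(cbind(c(0.6, 1.1)), c(0.9, 0.6)), E0 = 1.2)
  cl <- run_daphnia_community(p, init, dt = 2e-3, t_end = 2)
  # initialisation identity: reduced state at t=0 equals the cohort moments
  N0 <- vapply(0:3, function(i)
    sum(init$cohorts$masses * init$cohorts$positions[, 1]^i), numeric(1))
  expect_equal(cl$reduced$values[1, 1:4], N0, tolerance = 1e-14)
  expect_equal(cl$structured$outputs[1, ], N0, tolerance = 1e-14)
  # short-horizon agreement between the two closed loops
  cmp <- compare_trajectories(
    list(times = cl$reduced$times, values = cl$reduced$values[, 1:4]),
    list(times = cl$structured$times, values = cl$structured$outputs))
  expect_lt(max(cmp$sup_rel), 5e-3)
  # h = 0, f = 0: E stays constant (open loop limit)
  p0 <- p; p0$f_E <- function(E) 0; p0$h_E <- function(E) 0
  cl0 <- run_daphnia_community(p0, init, dt = 2e-3, t_end = 0.5)
  expect_equal(cl0$structured$E, rep(1.2, length(cl0$structured$E)), tolerance = 1e-14)
})
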