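test_that("matched histories satisfy the matching condition", {
  # constant-rate interface: closed form F(0) = p eta E0 (1-e^{-mu0 T})/mu0
  pp <- const_params_sub
  sc <- tick_scenario("constant", pp)
  hh <- make_history(E0 = 20, F0 = "matched", pp, sc, h = 0.1)
  F_closed <- pp$p * pp$eta * 20 * (1 - exp(-pp$mu0 * pp$T)) / pp$mu0
  expect_equal(hh$F[1], F_closed, tolerance = 1e-6)
  expect_lt(hh$matching_residual, 1e-10)

  # an equilibrium history is self-consistent
  eq <- solve_reactive(quadri$params)
  row <- eq[eq$branch == "plus_minus", ]
  he <- make_history(E0 = row$E, F0 = row$F, quadri$params,
                     quadri$scenario, h = 0.1)
  expect_lt(he$matching_residual, 1e-8)

  # zero engorged history forces zero feeding load
  h0 <- make_history(E0 = 0, F0 = "matched", quadri$params,
                     quadri$scenario, h = 0.5)
  expect_identical(max(h0$F), 0)

  # solving the condition for E at a prescribed load reproduces E* at F*
  hF <- make_history(E0 = "matched", F0 = row$F, quadri$params,
                     quadri$scenario, h = 0.1)
  expect_equal(hF$E[1], row$E, tolerance = 1e-8)

  expect_error(make_history("matched", "matched", quadri$params,
                            quadri$scenario), "at most one")
  expect_error(make_history(E0 = 5, F0 = 3, quadri$params, quadri$scenario,
                            h = 0.3), "divide")
})

test_that("equilibria and the tick-free state are fixed points of the flow", {
  eq <- solve_reactive(quadri$params)
  row <- eq[eq$branch == "minus_plus", ]
  he <- make_history(E0 = row$E, F0 = row$F, quadri$params, quadri$scenario,
                     h = 0.1)
  tr <- simulate_ticks(he, quadri$params, quadri$scenario, t_end = 100,
                       h = 0.1, monitor_every = NA)
  expect_lt(max(abs(tr$F - row$F)) / row$F, 1e-9)
  expect_lt(max(abs(tr$E - row$E)) / row$E, 1e-9)

  h0 <- make_history(E0 = 0, F0 = 0, quadri$params, quadri$scenario,
                     h = 0.5)
  tr0 <- simulate_ticks(h0, quadri$params, quadri$scenario, t_end = 500,
                        h = 0.5, monitor_every = NA)
  expect_identical(max(tr0$E), 0)
  expect_identical(max(tr0$F), 0)
})

test_that("trajectories from matched nonnegative histories stay nonnegative", {
  set.seed(9)
  for (i in 1:6) {
    pr <- if (i %% 2) quadri else bi
    E0 <- runif(1, 0.5, 80)
    hh <- make_history(E0 = E0, F0 = "matched", pr$params, pr$scenario,
                       h = 0.5)
    tr <- simulate_ticks(hh, pr$params, pr$scenario, t_end = 1414, h = 0.5,
                         monitor_every = NA)
    expect_gte(min(tr$E), 0)
    expect_gte(min(tr$F), 0)
    # the questing inflow is the delayed engorged series scaled by eta
    expect_gte(min(tr$Q), 0)
  }
})

test_that("density profile integrates back to the feeding load", {
  pq <- quadri
  hh <- make_history(E0 = 30, F0 = "matched", pq$params, pq$scenario,
                     h = 0.1)
  tr <- simulate_ticks(hh, pq$params, pq$scenario, t_end = 500, h = 0.1,
                       monitor_every = NA)
  for (t in c(0, 100, 500)) {
    prof <- density_profile(tr, t, pq$params, pq$scenario)
    expect_equal(attr(prof, "integral"), attr(prof, "F_t"),
                 tolerance = 1e-7)
    # boundary value: n(t, 0) = rho(F(t)) * Q(t)
    i <- which.min(abs(tr$t - t))
    expect_equal(prof$n[1], pq$scenario$rho(tr$F[i]) * tr$Q[i],
                 tolerance = 1e-10)
  }
  expect_error(density_profile(tr, 1e6, pq$params, pq$scenario), "range")

  # constant-rate interface at criticality: exponential profile in a
  pc <- const_params_crit
  scc <- tick_scenario("constant", pc)
  hc <- make_history(E0 = 15, F0 = "matched", pc, scc, h = 0.1)
  tc <- simulate_ticks(hc, pc, scc, t_end = 50, h = 0.1, monitor_every = NA)
  prof <- density_profile(tc, 50, pc, scc)
  n_closed <- pc$p * pc$eta * 15 * exp(-pc$mu0 * prof$a)
  expect_equal(prof$n, n_closed, tolerance = 1e-7)
})

test_that("subcritical constant interface decays at the characteristic rate", {
  # shrink the life cycle so the asymptotic regime is reached quickly
  pp <- tick_params(delta = 0.033, eta = 45, tau = 70, T = 7,
                    p = 0.002, mu0 = 0.4)
  expect_lt(basic_reproduction_number(pp), 1)
  sc <- tick_scenario("constant", pp)
  hh <- make_history(E0 = 10, F0 = "matched", pp, sc, h = 0.1)
  tr <- simulate_ticks(hh, pp, sc, t_end = 1500, h = 0.1,
                       monitor_every = NA)
  expect_lt(tr$E[length(tr$E)], 1e-3 * 10)
  # independent oracle: the real root of
  # lambda = -delta + p eta e^{-mu0 T} e^{-lambda (tau+T)}
  L <- pp$tau + pp$T
  gain <- pp$p * pp$eta * exp(-pp$mu0 * pp$T)
  lam <- uniroot(function(l) l + pp$delta - gain * exp(-l * L),
                 c(-1, 0), tol = 1e-14)$root
  i1 <- which.min(abs(tr$t - 700)); i2 <- which.min(abs(tr$t - 1470))
  lam_hat <- log(tr$E[i2] / tr$E[i1]) / (tr$t[i2] - tr$t[i1])
  expect_equal(lam_hat, lam, tolerance = 0.01)
})

test_that("critical constant interface obeys asymptotic constancy", {
  # shortened life cycle; perturbed positive history
  pp <- tick_params(delta = 0.033, eta = 45, tau = 70, T = 7, mu0 = 0.4,
                    p = 0.033 * exp(0.4 * 7) / 45)
  sc <- tick_scenario("constant", pp)
  L <- pp$tau + pp$T
  Ehist <- function(s) 10 * (1 + 0.5 * sin(s / 15))
  Ec <- critical_case_limit(Ehist, pp)
  hh <- make_history(E0 = Ehist, F0 = "matched", pp, sc, h = 0.1)
  tr <- simulate_ticks(hh, pp, sc, t_end = 30 * L, h = 0.1,
                       monitor_every = NA)

  # conservation law behind the limit: E(t) + delta*int_{t-L}^t E is flat
  n_L <- as.integer(round(L / tr$h))
  inv <- vapply(seq(n_L + 1, length(tr$t), by = 200), function(i) {
    tr$E[i] + pp$delta * sum((tr$E[(i - n_L):(i - 1)] +
                                tr$E[(i - n_L + 1):i]) / 2) * tr$h
  }, numeric(1))
  expect_lt(diff(range(inv)) / mean(inv), 1e-6)

  # envelope decays at the rightmost nonzero characteristic-root rate
  mu_root <- local({
    f <- function(z) z - pp$delta * L * (exp(-z) - 1)  # z = lambda * L
    best <- -Inf
    for (k in 1:10) {
      z <- complex(real = -0.5, imaginary = 2 * pi * k * 0.8)
      for (it in 1:100) z <- z - f(z) / (1 + pp$delta * L * exp(-z))
      if (abs(f(z)) < 1e-10 && Im(z) > 1e-3) best <- max(best, Re(z))
    }
    best / L
  })
  env <- vapply(c(5, 25), function(m) {
    w <- tr$t >= (m - 1) * L & tr$t <= m * L
    max(abs(tr$E[w] - Ec))
  }, numeric(1))
  expect_equal(log(env[2] / env[1]) / (20 * L), mu_root, tolerance = 0.05)
  # and the trajectory is inside the mode-predicted envelope of E_c
  expect_lt(abs(tr$E[length(tr$E)] - Ec), 1.2 * env[2])
})

test_that("terminal states are detected and reported", {
  eq <- classify_reactive(quadri$params)
  # extinction basin: tiny initial load
  h1 <- make_history(E0 = "matched", F0 = 3.3, quadri$params,
                     quadri$scenario, h = 0.5)
  t1 <- simulate_ticks(h1, quadri$params, quadri$scenario, t_end = 5000,
                       h = 0.5, equilibria = eq, monitor_every = NA)
  expect_identical(t1$terminal$status, "converged")
  expect_identical(t1$terminal$branch, "trivial")
  # horizon exhaustion without convergence
  h2 <- make_history(E0 = "matched", F0 = 300, quadri$params,
                     quadri$scenario, h = 0.5)
  t2 <- simulate_ticks(h2, quadri$params, quadri$scenario, t_end = 50,
                       h = 0.5, equilibria = eq, monitor_every = NA)
  expect_identical(t2$terminal$status, "max_time")
})

test_that("fold location satisfies the tangency identity and the scan", {
  fold <- fold_point(bi$params, "ricker_linear", "T", c(7, 20))
  pp <- bi$params
  gap <- pp$delta / (pp$eta * pp$p) * exp(pp$mu0 * fold$value) -
    exp(-1) / (1 / pp$c + pp$mu * fold$value)
  expect_lt(abs(gap), 1e-10)
  expect_equal(fold$F_star, 1 / (1 / pp$c + pp$mu * fold$value))

  scan <- bifurcation_scan(bi$params, "ricker_linear", "T",
                           seq(7, 11, by = 0.5))
  expect_equal(scan$fold$value, fold$value, tolerance = 1e-10)
  # branch counts only change at the fold
  counts <- tapply(scan$table$branch != "trivial", scan$table$value, sum)
  below <- counts[as.numeric(names(counts)) < fold$value]
  above <- counts[as.numeric(names(counts)) > fold$value]
  expect_true(all(below == 2))
  expect_true(all(above == 0))
})
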