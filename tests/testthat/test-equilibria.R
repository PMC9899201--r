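test_that("engorged coordinate follows the equilibrium identity", {
  # any F* with eta*rho(F*) = 2*delta and nu(F*) = delta/F* gives E* = 1
  pp <- tick_params(delta = 0.1, eta = 1, tau = 700, T = 7)
  sc <- structure(list(tag = "constant",
                       rho = function(F) rep(0.2, length(F)),
                       rho_prime = function(F) rep(0, length(F)),
                       nu = function(F) 0.1 / F,
                       nu_prime = function(F) -0.1 / F^2),
                  class = "tick_scenario")
  expect_equal(E_from_F(5, pp, sc), 1)
  expect_equal(E_from_F(123.4, pp, sc), 1)
  # infeasible when eta * rho(F*) <= delta
  sc$rho <- function(F) rep(0.05, length(F))
  expect_error(E_from_F(5, pp, sc), "infeasible")
})

test_that("quadri preset reproduces the reference equilibrium structure", {
  eq <- solve_reactive(quadri$params)
  roots <- attr(eq, "rho_roots")
  expect_equal(roots, c(0.1981, 1.0147), tolerance = 5e-4)
  pos <- eq[eq$branch != "trivial", ]
  expect_identical(pos$branch,
                   c("minus_minus", "plus_minus", "plus_plus", "minus_plus"))
  expect_equal(pos$F, c(9.9730, 66.1540, 217.6735, 1443.8375),
               tolerance = 5e-3)
  expect_equal(pos$E, c(5.8070, 14.5072, 47.7346, 840.7008),
               tolerance = 5e-3)
  # ordering around the Holling peak j
  j <- quadri$params$j
  expect_true(all(pos$F[1:2] < j) && all(pos$F[3:4] > j))
  expect_true(all(pos$residual < 1e-10))
  # all nontrivial equilibria lie where eta*rho(F) > delta
  rhoF <- quadri$scenario$rho(pos$F)
  expect_true(all(quadri$params$eta * rhoF > quadri$params$delta))
})

test_that("Ricker solver returns two roots bracketing the capacity", {
  eq <- solve_ricker(bi$params)
  pos <- eq[eq$branch != "trivial", ]
  expect_identical(pos$branch, c("minus", "plus"))
  xstar <- 1 / (1 / bi$params$c + bi$params$mu * bi$params$T)
  expect_lt(pos$F[1], xstar)
  expect_gt(pos$F[2], xstar)
  expect_true(all(pos$residual < 1e-10))
  # oracle: dense sign-change scan of g1 against the right-hand side
  a <- 1 / bi$params$c + bi$params$mu * bi$params$T
  rhs <- bi$params$delta / (bi$params$eta * bi$params$p) *
    exp(bi$params$mu0 * bi$params$T)
  expect_identical(scan_roots(function(x) x * exp(-a * x), rhs, 5000), 2L)
})

test_that("root counts match the dense-scan oracle over random draws", {
  set.seed(42)
  for (i in 1:300) {
    # Ricker family draw
    pp <- tick_params(delta = runif(1, 0.01, 0.5), eta = runif(1, 1, 60),
                      tau = 700, T = runif(1, 1, 10),
                      p = runif(1, 1e-4, 0.05), c = runif(1, 20, 300),
                      mu = runif(1, 0, 0.01), mu0 = runif(1, 0, 1))
    a <- 1 / pp$c + pp$mu * pp$T
    rhs <- pp$delta / (pp$eta * pp$p) * exp(pp$mu0 * pp$T)
    n_oracle <- scan_roots(function(x) x * exp(-a * x), rhs, 200 / a)
    eq <- solve_ricker(pp)
    n_solver <- sum(!eq$branch %in% c("trivial", "critical"))
    expect_identical(n_solver, n_oracle)

    # biting-reactive family draw
    pp2 <- tick_params(delta = runif(1, 0.01, 0.5), eta = runif(1, 0.5, 10),
                       tau = 700, T = runif(1, 1, 10),
                       k = runif(1, 0.05, 1), r = runif(1, 0.005, 0.05),
                       j = runif(1, 30, 300))
    kT <- pp2$k * pp2$T
    n_rho_oracle <- scan_roots(function(x) x * exp(-kT * x),
                               pp2$delta / pp2$eta, 100 / kT)
    roots <- reactive_rho_roots(pp2)
    expect_identical(length(roots), n_rho_oracle)
    # each feasible rho root contributes exactly the scanned F-roots
    for (rs in roots) {
      # tail asymptote rho ~ r j^2 / F puts the upper root near r j^2 / rho*
      n_F_oracle <- scan_roots(function(F) rho_holling3(F, pp2$r, pp2$j),
                               rs, 10 * pp2$r * pp2$j^2 / rs + 10 * pp2$j)
      Fs <- if (rs > pp2$r * pp2$j / 2) numeric(0)
            else holling3_invert(rs, pp2$r, pp2$j)
      if (length(Fs) == 2) expect_identical(n_F_oracle, 2L)
    }
  }
})

test_that("closed-form Holling inversion agrees with a brute-force scan", {
  set.seed(7)
  for (i in 1:1000) {
    r <- runif(1, 0.001, 0.1); j <- runif(1, 10, 500)
    rho_star <- runif(1, 0.05, 0.95) * r * j / 2
    Fs <- holling3_invert(rho_star, r, j)
    expect_length(Fs, 2L)
    # oracle: bisection on each monotone side of the Holling curve
    g <- function(F) rho_holling3(F, r, j) - rho_star
    lo <- uniroot(g, c(1e-9, j), tol = 1e-13)$root
    hi_up <- 10 * j
    while (g(hi_up) > 0) hi_up <- hi_up * 2
    hi <- uniroot(g, c(j, hi_up), tol = 1e-13)$root
    expect_equal(Fs, c(lo, hi), tolerance = 1e-8)
  }
  # tangency: discriminant zero collapses both roots onto j
  expect_equal(holling3_invert(0.02 * 120 / 2, 0.02, 120), 120)
})

test_that("monotone interface has one equilibrium exactly when R0 > 1", {
  # supercritical: closed form when mu = 0: F* = c (log(eta p / delta) - mu0 T)
  pp <- tick_params(delta = 0.02, eta = 45, tau = 700, T = 7,
                    p = 0.01, c = 100, mu = 0, mu0 = 0.1)
  expect_gt(basic_reproduction_number(pp), 1)
  eq <- solve_monotone(pp)
  pos <- eq[eq$branch != "trivial", ]
  F_closed <- pp$c * (log(pp$eta * pp$p / pp$delta) - pp$mu0 * pp$T)
  expect_equal(pos$F, F_closed, tolerance = 1e-9)
  expect_lt(pos$residual, 1e-10)

  # subcritical: no positive equilibrium
  pp2 <- tick_params(delta = 0.05, eta = 45, tau = 700, T = 7,
                     p = 0.002, c = 100, mu = 0.001, mu0 = 0.4)
  expect_lt(basic_reproduction_number(pp2), 1)
  expect_identical(solve_monotone(pp2)$branch, "trivial")
})

test_that("tick-free stability follows the scalar threshold", {
  # rho(0) = 0 families: always stable
  expect_identical(trivial_stability(quadri$params, quadri$scenario),
                   "stable")
  expect_identical(trivial_stability(bi$params, bi$scenario), "stable")
  # constant interface: follows R0
  sc_sub <- tick_scenario("constant", const_params_sub)
  expect_identical(trivial_stability(const_params_sub, sc_sub), "stable")
  sc_crit <- tick_scenario("constant", const_params_crit)
  expect_identical(trivial_stability(const_params_crit, sc_crit), "critical")
  pp_sup <- tick_params(delta = 0.033, eta = 45, tau = 700, T = 7,
                        p = 0.05, mu0 = 0.4)
  expect_identical(trivial_stability(pp_sup, tick_scenario("constant",
                                                           pp_sup)),
                   "unstable")
})

test_that("asymptotic-constancy limit matches analytic quadratures", {
  # constant history: E_c = E0
  expect_equal(critical_case_limit(function(s) rep(12, length(s)),
                                   const_params_crit), 12)
  # linear history E(s) = s + 1 over [-2, 0] with delta = 0.5: E_c = 1/2
  pp <- tick_params(delta = 0.5, eta = 1, tau = 1, T = 1,
                    p = 0.5 * exp(0.2) / 1, mu0 = 0.2)
  expect_equal(critical_case_limit(function(s) s + 1, pp), 0.5)
  # zero history stays extinct
  expect_equal(critical_case_limit(function(s) rep(0, length(s)),
                                   const_params_crit), 0)
  # non-critical parameters are refused
  expect_error(critical_case_limit(function(s) rep(1, length(s)),
                                   const_params_sub), "critical")
})
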