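#' Linearised characteristic system and perturbation-based stability
#'
#' Linearising the coupled delay-algebraic system about a nontrivial
#' equilibrium `(E*, F*)` and seeking exponential solutions
#' \eqn{e^{\lambda t}} yields a 2x2 system whose determinant
#' \eqn{f(\lambda) = (\lambda - a_{11})(-a_{22}) - a_{12}a_{21}} is the
#' characteristic function. Locating its rightmost zero in general is hard;
#' the classifiers below use the fact that the feeding duration `T` is short
#' relative to the life cycle `tau + T`, expanding the characteristic
#' equation in `T` and reading stability off the leading eigenvalue
#' coefficient.
#'
#' @name stability
NULL

.sign_tol <- 1e-9  # |A| or |lambda0| below this -> verdict "undetermined"

.small_T_guard <- function(params) {
  if (params$T / (params$tau + params$T) > 0.1)
    warning("feeding duration T is not small relative to the life cycle; ",
            "the perturbation verdict is first-order in T", call. = FALSE)
}

# (1 - e^{-x T}) / x with a series branch near x = 0
.phi <- function(x, T) {
  out <- ifelse(abs(x) < 1e-8,
                T - x * T^2 / 2 + x^2 * T^3 / 6,
                (1 - exp(-x * T)) / x)
  out
}

#' Entries of the characteristic matrix at a nontrivial equilibrium
#'
#' Returns the four entries \eqn{a_{ij}(\lambda)} of the linearised system
#' as functions of the (possibly complex) spectral variable, with the
#' removable singularities at \eqn{\lambda = 0} replaced by their analytic
#' limits. Entries are finite for \eqn{Re(\lambda) > -\nu(F^*)}.
#'
#' @param E_star,F_star The equilibrium coordinates (`F_star > 0`; use
#'   [trivial_stability()] for the tick-free state).
#' @param params A [tick_params()].
#' @param scenario A [tick_scenario()].
#' @return An object of class `tick_char_entries`: list of functions
#'   `a11`, `a12`, `a21`, `a22` of `lambda`.
#' @export
char_entries <- function(E_star, F_star, params, scenario) {
  if (F_star <= 0)
    stop("trivial equilibrium: use trivial_stability() for the scalar ",
         "criterion", call. = FALSE)
  eta <- params$eta; delta <- params$delta; T <- params$T; tau <- params$tau
  rho <- scenario$rho(F_star); rhop <- scenario$rho_prime(F_star)
  nu <- scenario$nu(F_star); nup <- scenario$nu_prime(F_star)
  sT <- exp(-nu * T)  # feeding-period survival at equilibrium

  a11 <- function(lambda)
    -delta + eta * sT * rho * exp(-lambda * (tau + T))
  a12 <- function(lambda) {
    frac <- ifelse(abs(lambda) < 1e-8,
                   T - lambda * T^2 / 2 + lambda^2 * T^3 / 6,
                   (1 - exp(-lambda * T)) / lambda)
    eta * sT * E_star * (rhop * exp(-lambda * T) - rho * nup * frac)
  }
  a21 <- function(lambda)
    eta * rho * exp(-lambda * tau) * .phi(nu + lambda, T)
  a22 <- function(lambda) {
    # eta E* rho' phi(nu+l) + eta E* rho nu' (phi(nu+l)-phi(nu))/l - 1
    u <- exp(-nu * T)
    phip_nu <- (T * u * nu - (1 - u)) / nu^2
    phipp_nu <- (2 * (1 - u) - T^2 * u * nu^2) / nu^3
    D <- ifelse(abs(lambda) < 1e-8,
                phip_nu + lambda * phipp_nu / 2,
                (.phi(nu + lambda, T) - .phi(nu, T)) / lambda)
    eta * E_star * rhop * .phi(nu + lambda, T) +
      eta * E_star * rho * nup * D - 1
  }
  structure(list(a11 = a11, a12 = a12, a21 = a21, a22 = a22,
                 E_star = E_star, F_star = F_star),
            class = "tick_char_entries")
}

#' Characteristic determinant
#'
#' Evaluates \eqn{f(\lambda) = (\lambda - a_{11})(-a_{22}) -
#' (-a_{12})(-a_{21})}; its zeros are the characteristic values of the
#' linearised system.
#'
#' @param lambda Spectral variable (numeric or complex, vectorised).
#' @param entries A [char_entries()] object.
#' @return Value(s) of the characteristic function.
#' @export
char_det <- function(lambda, entries) {
  (lambda - entries$a11(lambda)) * (-entries$a22(lambda)) -
    entries$a12(lambda) * entries$a21(lambda)
}

#' Real characteristic roots on an interval by sign-change scan
#'
#' Dense real-axis scan of the characteristic determinant followed by
#' bracketed refinement of each sign change. This is a diagnostic, not a
#' spectral certificate: complex roots are invisible to it (see
#' [char_contour_count()]).
#'
#' @param entries A [char_entries()] object.
#' @param interval Real interval to scan, within the domain
#'   \eqn{\lambda > -\nu(F^*)}.
#' @param n Number of grid points.
#' @return Numeric vector of located real roots (possibly empty).
#' @export
char_real_roots <- function(entries, interval = c(-0.5, 1), n = 2000L) {
  grid <- seq(interval[1], interval[2], length.out = n)
  vals <- Re(char_det(grid, entries))
  idx <- which(vals[-n] * vals[-1] < 0)
  vapply(idx, function(i)
    stats::uniroot(function(l) Re(char_det(l, entries)),
                   c(grid[i], grid[i + 1]), tol = 1e-12)$root,
    numeric(1))
}

#' Count characteristic roots inside a rectangle (argument principle)
#'
#' Walks the boundary of a rectangle in the complex plane accumulating the
#' winding of \eqn{\arg f(\lambda)}; by the argument principle the total
#' winding equals the number of enclosed zeros (f is analytic in the scanned
#' half-plane). Intended as a coarse check over a user-set window; it is not
#' a rigorous certification.
#'
#' @param entries A [char_entries()] object.
#' @param re Real-part range of the rectangle (length 2).
#' @param im Imaginary-part range (length 2).
#' @param n Points per edge.
#' @return Integer root count (with multiplicity).
#' @export
char_contour_count <- function(entries, re = c(1e-6, 1), im = c(-5, 5),
                               n = 4000L) {
  z <- c(complex(real = seq(re[1], re[2], length.out = n), imaginary = im[1]),
         complex(real = re[2], imaginary = seq(im[1], im[2], length.out = n)),
         complex(real = seq(re[2], re[1], length.out = n), imaginary = im[2]),
         complex(real = re[1], imaginary = seq(im[2], im[1], length.out = n)))
  f <- char_det(z, entries)
  dphase <- diff(Arg(f))
  dphase <- (dphase + pi) %% (2 * pi) - pi
  round(sum(dphase) / (2 * pi))
}

.perturbation_result <- function(...) {
  structure(list(...), class = "tick_perturbation")
}

#' @export
print.tick_perturbation <- function(x, ...) {
  cat(sprintf("<tick_perturbation> verdict: %s\n", x$verdict))
  nums <- Filter(function(v) is.numeric(v) && length(v) == 1L, unclass(x))
  for (nm in names(nums)) cat(sprintf("  %-12s % .6g\n", nm, nums[[nm]]))
  invisible(x)
}

#' Leading eigenvalue sign for the Ricker/linear-grooming equilibria
#'
#' Expanding equilibrium and eigenvalue in the feeding duration
#' \eqn{T = \epsilon} reduces the characteristic equation at a positive
#' equilibrium to the scalar transcendental
#' \deqn{-\frac{F_0}{c}\lambda_0 + \delta e^{-\lambda_0\tau} =
#'       \frac{F_0}{c}\delta,}
#' whose unique real root is positive exactly when \eqn{F_0 < c} (the lower
#' branch) and negative when \eqn{F_0 > c} (the upper branch). Hence the
#' lower positive equilibrium is unstable and the upper one locally
#' asymptotically stable; together with the stable tick-free state this is
#' the bi-stable configuration.
#'
#' @param F_star Feeding-tick coordinate of the positive equilibrium.
#' @param params A [tick_params()] with `p`, `c`, `mu`, `mu0`.
#' @return A `tick_perturbation` with `lambda0`, series coefficients
#'   (`F0`, `F1`, `E0`, `E1`, `rho0`, `rho1`, `nu0`, `nu1`, `rho_tilde0`)
#'   and a `verdict`.
#' @export
sign_lambda0_ricker <- function(F_star, params) {
  if (F_star <= 0) stop("nontrivial equilibrium required", call. = FALSE)
  .small_T_guard(params)
  p <- param_get(params, "p"); cc <- param_get(params, "c")
  mu <- param_get(params, "mu"); mu0 <- param_get(params, "mu0")
  delta <- params$delta; tau <- params$tau
  F0 <- F_star
  rho0 <- p * F0 * exp(-F0 / cc)
  nu0 <- mu0 + mu * F0
  rho_tilde0 <- p * (1 - F0 / cc) * exp(-F0 / cc)
  F1 <- if (abs(1 - F0 / cc) > 1e-12) nu0 * F0 / (1 - F0 / cc) else NA_real_
  E0 <- F0 / delta
  E1 <- if (is.finite(F1))
    nu0 * F0 * (cc / (cc - F0) - 0.5) / delta else NA_real_

  g <- function(l) -(F0 / cc) * l + delta * exp(-l * tau) - (F0 / cc) * delta
  lambda0 <- if (abs(F0 - cc) < .sign_tol * cc) 0 else if (F0 < cc) {
    up <- delta * (cc / F0 - 1) + 1
    stats::uniroot(g, c(0, up), tol = 1e-14)$root
  } else {
    lo <- -1e-3
    while (g(lo) < 0) lo <- lo * 2
    stats::uniroot(g, c(lo, 0), tol = 1e-14)$root
  }
  verdict <- if (abs(F0 - cc) < .sign_tol * cc) "undetermined"
             else if (F0 < cc) "unstable" else "stable"
  .perturbation_result(lambda0 = lambda0, A = NA_real_, F0 = F0, F1 = F1,
                       E0 = E0, E1 = E1, rho0 = rho0, rho1 = nu0 * rho0,
                       nu0 = nu0, nu1 = if (is.finite(F1)) mu * F1 else
                         NA_real_,
                       rho_tilde0 = rho_tilde0, verdict = verdict,
                       condition45_holds = NA)
}

#' Composite stability constant A for biting-reactive grooming equilibria
#'
#' For grooming reactive to biting with strong per-attachment grooming
#' (`k` of order `1/T`, with `k0 = k*T` held fixed), the leading term of the
#' characteristic equation at a positive equilibrium is
#' \eqn{\lambda_0 + \delta - \delta e^{-\lambda_0\tau} +
#' A e^{-\lambda_0\tau} = 0} with
#' \deqn{A = \frac{\eta^2 E_0\tilde\rho_0 e^{-k_0\rho_0}(1 - k_0\rho_0)
#'       (1 - e^{-k_0\rho_0})}{k_0(\eta E_0\tilde\rho_0 e^{-k_0\rho_0} - 1)},}
#' where \eqn{\rho_0 = \rho(F_0)}, \eqn{\tilde\rho_0 = \rho'(F_0)} and
#' \eqn{E_0 = F_0 k_0 / (\eta(1 - e^{-k_0\rho_0}))}. Provided
#' \eqn{\eta E_0\tilde\rho_0 < \min\{e^{k_0\rho_0},
#' \rho_0 k_0/(k_0\rho_0 + e^{-k_0\rho_0} - 1)\}} and \eqn{\delta > A}, the
#' equilibrium is stable iff `A > 0`; when either hypothesis fails the
#' verdict is `"undetermined"`.
#'
#' @param F_star Feeding-tick coordinate of the positive equilibrium.
#' @param params A [tick_params()] with `k`, `r`, `j`.
#' @return A `tick_perturbation` with `A`, `lambda0`, the series
#'   coefficients, the hypothesis flags and a `verdict`.
#' @export
A_value <- function(F_star, params) {
  if (F_star <= 0) stop("nontrivial equilibrium required", call. = FALSE)
  .small_T_guard(params)
  scenario <- tick_scenario("holling3_reactive", params)
  eta <- params$eta; delta <- params$delta; tau <- params$tau
  k0 <- param_get(params, "k") * params$T  # adopted reading: k0 = k*T, k1 = 0
  F0 <- F_star
  rho0 <- scenario$rho(F0)
  rho_tilde0 <- scenario$rho_prime(F0)
  E0 <- F0 * k0 / (eta * (1 - exp(-k0 * rho0)))
  ee <- exp(-k0 * rho0)
  A <- eta^2 * E0 * rho_tilde0 * ee * (1 - k0 * rho0) * (1 - ee) /
    (k0 * (eta * E0 * rho_tilde0 * ee - 1))
  cond45 <- eta * E0 * rho_tilde0 <
    min(exp(k0 * rho0), rho0 * k0 / (k0 * rho0 + ee - 1))
  delta_gt_A <- delta > A

  lambda0 <- NA_real_
  if (delta_gt_A) {
    h <- function(l) l + delta - (delta - A) * exp(-l * tau)
    lambda0 <- if (abs(A) < .sign_tol) 0 else if (A < 0) {
      up <- abs(A) + 1
      stats::uniroot(h, c(0, up), tol = 1e-14)$root
    } else {
      lo <- -1e-3
      while (h(lo) > 0) lo <- lo * 2
      stats::uniroot(h, c(lo, 0), tol = 1e-14)$root
    }
  }
  verdict <- if (!cond45 || !delta_gt_A || abs(A) < .sign_tol)
    "undetermined" else if (A > 0) "stable" else "unstable"
  .perturbation_result(lambda0 = lambda0, A = A, F0 = F0, E0 = E0,
                       rho0 = rho0, rho_tilde0 = rho_tilde0, k0 = k0,
                       verdict = verdict, condition45_holds = cond45,
                       delta_gt_A = delta_gt_A)
}

#' Classify all equilibria of the biting-reactive grooming scenario
#'
#' Solves the equilibrium structure via [solve_reactive()] and fills in
#' stability verdicts: the tick-free state from the scalar criterion, and
#' each positive equilibrium from the sign of its [A_value()]. In the
#' quadri-stable configuration (four positive equilibria) this yields three
#' locally stable states (tick-free, the high-attachment/low-load branch,
#' and the low-attachment/high-load branch) interleaved with two unstable
#' ones.
#'
#' @param params A [tick_params()] with `k`, `r`, `j`.
#' @return A `tick_equilibria` data frame with `stability`, `A` and
#'   `lambda0` columns filled; perturbation details attached as attribute
#'   `perturbation` (a list keyed by branch).
#' @export
classify_reactive <- function(params) {
  eq <- solve_reactive(params)
  eq$A <- NA_real_
  eq$lambda0 <- NA_real_
  pert <- list()
  for (i in seq_len(nrow(eq))) {
    if (eq$branch[i] == "trivial") next
    pr <- A_value(eq$F[i], params)
    eq$stability[i] <- pr$verdict
    eq$A[i] <- pr$A
    eq$lambda0[i] <- pr$lambda0
    pert[[eq$branch[i]]] <- pr
  }
  attr(eq, "perturbation") <- pert
  eq
}

#' Classify the equilibria of the Ricker/linear-grooming scenario
#'
#' Companion to [classify_reactive()] for cooperative feeding: verdicts for
#' the positive equilibria come from [sign_lambda0_ricker()].
#'
#' @param params A [tick_params()] with `p`, `c`, `mu`, `mu0`.
#' @return A `tick_equilibria` data frame with `lambda0` column filled.
#' @export
classify_ricker <- function(params) {
  eq <- solve_ricker(params)
  eq$lambda0 <- NA_real_
  pert <- list()
  for (i in seq_len(nrow(eq))) {
    if (eq$branch[i] %in% c("trivial", "critical")) next
    pr <- sign_lambda0_ricker(eq$F[i], params)
    eq$stability[i] <- pr$verdict
    eq$lambda0[i] <- pr$lambda0
    pert[[eq$branch[i]]] <- pr
  }
  attr(eq, "perturbation") <- pert
  eq
}
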