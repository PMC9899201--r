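#' Equilibrium structure of the coupled tick-host system
#'
#' A nontrivial equilibrium `(E*, F*)` of the coupled delay-algebraic system
#' satisfies
#' \deqn{\nu(F^*) = \frac{1}{T}\log\frac{\eta\rho(F^*)}{\delta}, \qquad
#'       E^* = \frac{F^*\nu(F^*)}{\eta\rho(F^*) - \delta},}
#' which requires \eqn{\eta\rho(F^*) > \delta}. The solvers below return the
#' full equilibrium set (always including the trivial tick-free state) for
#' each behaviour family, with branch labels and the equilibrium-equation
#' residual.
#'
#' @name equilibria
NULL

# Tolerances used across the solvers (see package vignette).
.tol_g <- 1e-12        # absolute tolerance on g-function residuals
.tol_F_rel <- 1e-10    # relative tolerance on F roots
.tol_tangency <- 1e-9  # relative gap for double-root (fold) detection

.equilibrium_row <- function(branch, E, F, residual, stability) {
  data.frame(branch = branch, E = E, F = F, residual = residual,
             stability = stability, stringsAsFactors = FALSE)
}

.equilibria_table <- function(rows, params, scenario) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "scenario_tag") <- scenario$tag
  class(out) <- c("tick_equilibria", "data.frame")
  out
}

# Residual of the two equilibrium equations at (E, F), scale-free.
.equilibrium_residual <- function(E, F, params, scenario) {
  if (F == 0) return(abs(E))
  nu <- scenario$nu(F)
  rr <- params$eta * scenario$rho(F)
  r1 <- abs(nu - log(rr / params$delta) / params$T) / max(nu, 1)
  r2 <- abs(E - F * nu / (rr - params$delta)) / max(E, 1)
  max(r1, r2)
}

#' Engorged-tick coordinate of an equilibrium from its feeding-tick load
#'
#' Applies \eqn{E^* = F^*\nu(F^*)/(\eta\rho(F^*) - \delta)}; feasibility
#' requires \eqn{\eta\rho(F^*) > \delta}.
#'
#' @param F_star Feeding-tick load at equilibrium (ticks).
#' @param params A [tick_params()].
#' @param scenario A [tick_scenario()].
#' @return The engorged-tick count `E*`.
#' @export
E_from_F <- function(F_star, params, scenario) {
  denom <- params$eta * scenario$rho(F_star) - params$delta
  if (denom <= 0)
    stop("infeasible equilibrium: eta * rho(F*) <= delta", call. = FALSE)
  F_star * scenario$nu(F_star) / denom
}

# Bracketed root find with Newton polish; g and gprime are functions of x.
.polished_root <- function(g, gprime, lower, upper) {
  x <- stats::uniroot(g, c(lower, upper), tol = 1e-12)$root
  for (i in 1:3) {
    step <- g(x) / gprime(x)
    if (!is.finite(step)) break
    xn <- x - step
    if (xn <= lower || xn >= upper) break
    x <- xn
    if (abs(step) < .tol_F_rel * max(x, 1)) break
  }
  x
}

# Expand 'hi' geometrically until fun(hi) < target (fun unimodal, decaying).
.expand_upper <- function(fun, start, target) {
  hi <- start
  for (i in 1:60) {
    if (fun(hi) < target) return(hi)
    hi <- hi * 2
  }
  stop("failed to bracket upper root", call. = FALSE)
}

#' Equilibria for cooperative (Ricker) attachment with linear grooming
#'
#' With \eqn{\rho(F) = pFe^{-F/c}} and \eqn{\nu(F) = \mu F + \mu_0}, the
#' feeding-tick equilibrium equation reduces to
#' \eqn{x e^{-(1/c + \mu T)x} = \delta(\eta p)^{-1}e^{\mu_0 T}.}
#' The left side is unimodal with maximum \eqn{e^{-1}(1/c + \mu T)^{-1}} at
#' \eqn{x = (1/c + \mu T)^{-1}}, giving zero, one (tangent), or two positive
#' equilibria according as the right side is above, equal to, or below that
#' maximum. At tangency a single equilibrium is returned with branch
#' `"critical"`.
#'
#' @param params A [tick_params()] with `p`, `c`, `mu`, `mu0`.
#' @return A `tick_equilibria` data frame (branch, E, F, residual,
#'   stability); stability is filled by the stability module and is
#'   `"undetermined"` here except for the trivial row.
#' @export
solve_ricker <- function(params) {
  scenario <- tick_scenario("ricker_linear", params)
  p <- param_get(params, "p"); cc <- param_get(params, "c")
  mu <- param_get(params, "mu"); mu0 <- param_get(params, "mu0")
  a <- 1 / cc + mu * params$T
  rhs <- params$delta / (params$eta * p) * exp(mu0 * params$T)
  xmax <- 1 / a
  gmax <- xmax * exp(-1)
  triv <- .equilibrium_row("trivial", 0, 0, 0,
                           trivial_stability(params, scenario))
  rows <- list(triv)
  g <- function(x) x * exp(-a * x) - rhs
  gp <- function(x) exp(-a * x) * (1 - a * x)
  if (abs(gmax - rhs) < .tol_tangency * rhs) {
    E <- E_from_F(xmax, params, scenario)
    rows <- c(rows, list(.equilibrium_row(
      "critical", E, xmax,
      .equilibrium_residual(E, xmax, params, scenario), "undetermined")))
  } else if (rhs < gmax) {
    hi <- .expand_upper(function(x) x * exp(-a * x),
                        100 * max(cc, xmax), rhs / 2)
    Fm <- .polished_root(g, gp, .tol_g, xmax)
    Fp <- .polished_root(g, gp, xmax, hi)
    for (br in list(c("minus", Fm), c("plus", Fp))) {
      Fv <- as.numeric(br[[2]])
      E <- E_from_F(Fv, params, scenario)
      rows <- c(rows, list(.equilibrium_row(
        br[[1]], E, Fv,
        .equilibrium_residual(E, Fv, params, scenario), "undetermined")))
    }
  }
  .equilibria_table(rows, params, scenario)
}

#' Positive roots of the attachment-rate equilibrium equation
#' \eqn{\rho e^{-kT\rho} = \delta/\eta}
#'
#' For grooming reactive to biting (\eqn{\nu = k\rho}), the equilibrium
#' condition is an equation in the attachment rate itself. The left side
#' peaks at \eqn{\rho = (kT)^{-1}} with value \eqn{(ekT)^{-1}}, so there are
#' zero, one, or two positive roots according as \eqn{\delta/\eta} is above,
#' at, or below \eqn{(ekT)^{-1}}.
#'
#' @param params A [tick_params()] with `k` (plus `delta`, `eta`, `T`).
#' @return Numeric vector of roots (length 0, 1, or 2, increasing).
#' @export
reactive_rho_roots <- function(params) {
  k <- param_get(params, "k")
  kT <- k * params$T
  rhs <- params$delta / params$eta
  rmax <- 1 / kT
  gmax <- rmax * exp(-1)
  if (abs(gmax - rhs) < .tol_tangency * rhs) return(rmax)
  if (rhs > gmax) return(numeric(0))
  g <- function(x) x * exp(-kT * x) - rhs
  gp <- function(x) exp(-kT * x) * (1 - kT * x)
  hi <- .expand_upper(function(x) x * exp(-kT * x), 2 * rmax, rhs / 2)
  c(.polished_root(g, gp, .tol_g, rmax), .polished_root(g, gp, rmax, hi))
}

#' Invert the Holling type III attachment rate at a given level
#'
#' Solves \eqn{rF/(1 + F^2/j^2) = \rho^*} in closed form:
#' \deqn{F_\mp = \frac{r/\rho^* \mp \sqrt{(r/\rho^*)^2 - 4j^{-2}}}{2j^{-2}}.}
#' Real solutions exist iff \eqn{\rho^* \le rj/2}; at equality the two roots
#' coincide at `F = j`.
#'
#' @param rho_star Attachment-rate level, `0 < rho_star <= r*j/2`.
#' @param r,j Holling parameters.
#' @return Numeric vector: the two roots (smaller first), or a single `j`
#'   at tangency.
#' @export
holling3_invert <- function(rho_star, r, j) {
  if (rho_star <= 0) stop("rho_star must be positive", call. = FALSE)
  rmax <- r * j / 2
  if (abs(rho_star - rmax) < .tol_tangency * rmax) return(j)
  if (rho_star > rmax)
    stop("rho_star exceeds the maximum attachment rate r*j/2", call. = FALSE)
  b <- r / rho_star
  disc <- sqrt(b^2 - 4 / j^2)
  c((b - disc) / (2 / j^2), (b + disc) / (2 / j^2))
}

#' Equilibria for Holling type III attachment with biting-reactive grooming
#'
#' First solves \eqn{\rho e^{-kT\rho} = \delta/\eta} for the attachment-rate
#' roots (see [reactive_rho_roots()]), then inverts the Holling curve at each
#' feasible root via [holling3_invert()]. With two rho roots both below
#' `r*j/2` this yields four positive equilibria ordered
#' \eqn{F_{--} < F_{+-} < j < F_{++} < F_{-+}} (first subscript: rho root;
#' second: lower/upper Holling branch), exhibiting the quadri-stable
#' configuration together with the always-stable tick-free state.
#'
#' @param params A [tick_params()] with `k`, `r`, `j`.
#' @return A `tick_equilibria` data frame with attribute `rho_roots`.
#' @export
solve_reactive <- function(params) {
  scenario <- tick_scenario("holling3_reactive", params)
  r <- param_get(params, "r"); j <- param_get(params, "j")
  roots <- reactive_rho_roots(params)
  triv <- .equilibrium_row("trivial", 0, 0, 0,
                           trivial_stability(params, scenario))
  rows <- list(triv)
  sign_lab <- c("minus", "plus")
  for (i in seq_along(roots)) {
    rs <- roots[i]
    if (rs > r * j / 2 * (1 + .tol_tangency)) next
    Fv <- holling3_invert(rs, r, j)
    lab1 <- if (length(roots) == 1L) "critical" else sign_lab[i]
    if (length(Fv) == 1L) {
      E <- E_from_F(Fv, params, scenario)
      rows <- c(rows, list(.equilibrium_row(
        paste0(lab1, "_critical"), E, Fv,
        .equilibrium_residual(E, Fv, params, scenario), "undetermined")))
    } else {
      for (q in 1:2) {
        E <- E_from_F(Fv[q], params, scenario)
        rows <- c(rows, list(.equilibrium_row(
          paste(lab1, sign_lab[q], sep = "_"), E, Fv[q],
          .equilibrium_residual(E, Fv[q], params, scenario),
          "undetermined")))
      }
    }
  }
  out <- .equilibria_table(rows, params, scenario)
  out <- out[order(out$F), ]
  rownames(out) <- NULL
  attr(out, "rho_roots") <- roots
  class(out) <- c("tick_equilibria", "data.frame")
  out
}

#' Equilibrium for monotone attachment decline and linear grooming
#'
#' With \eqn{\rho(F) = pe^{-F/c}} decreasing and \eqn{\nu(F) = \mu F + \mu_0}
#' increasing, the equilibrium equation
#' \eqn{\nu(F) = T^{-1}\log(\eta\rho(F)/\delta)} pits an increasing left side
#' against a decreasing right side: there is a unique positive equilibrium
#' when the reproduction number \eqn{R_0 = p\eta e^{-\mu_0 T}/\delta}
#' exceeds 1, and none otherwise.
#'
#' @param params A [tick_params()] with `p`, `c`, `mu`, `mu0`.
#' @return A `tick_equilibria` data frame.
#' @export
solve_monotone <- function(params) {
  scenario <- tick_scenario("monotone", params)
  triv <- .equilibrium_row("trivial", 0, 0, 0,
                           trivial_stability(params, scenario))
  rows <- list(triv)
  R0 <- basic_reproduction_number(params)
  if (R0 > 1) {
    d <- function(F) scenario$nu(F) -
      log(params$eta * scenario$rho(F) / params$delta) / params$T
    hi <- param_get(params, "c")
    for (i in 1:60) {
      if (d(hi) > 0) break
      hi <- hi * 2
    }
    Fs <- stats::uniroot(d, c(0, hi), tol = 1e-12)$root
    E <- E_from_F(Fs, params, scenario)
    rows <- c(rows, list(.equilibrium_row(
      "plus", E, Fs, .equilibrium_residual(E, Fs, params, scenario),
      "undetermined")))
  }
  .equilibria_table(rows, params, scenario)
}

#' Local stability of the tick-free equilibrium
#'
#' Linearising about the tick-free state gives the scalar delayed equation
#' \eqn{E' = -\delta E + \rho(0)\eta e^{-\nu(0)T} E(t - \tau - T)}, whose
#' positive delayed feedback makes stability equivalent to the sign of
#' \eqn{\delta - \rho(0)\eta e^{-\nu(0)T}}. Families with \eqn{\rho(0) = 0}
#' (Ricker, Holling III) therefore always have a stable tick-free state.
#'
#' @param params A [tick_params()].
#' @param scenario A [tick_scenario()].
#' @return `"stable"`, `"unstable"`, or `"critical"`.
#' @export
trivial_stability <- function(params, scenario) {
  thr <- scenario$rho(0) * params$eta * exp(-scenario$nu(0) * params$T)
  if (abs(params$delta - thr) <= 1e-9 * params$delta) return("critical")
  if (params$delta > thr) "stable" else "unstable"
}

#' Limiting engorged-tick level at the critical constant interface
#'
#' At the critical parameterisation \eqn{\eta p = \delta e^{\mu_0 T}} of the
#' constant scenario, every solution converges to a history-dependent
#' constant (asymptotic constancy):
#' \deqn{E_c = \frac{E(0) + \delta\int_{-\tau-T}^{0} E(s)\,ds}
#'             {1 + \delta(\tau + T)}.}
#'
#' @param history_E Function giving the engorged-tick history on
#'   `[-tau-T, 0]` (vectorised over its argument).
#' @param params A [tick_params()] with `p`, `mu0`, at criticality.
#' @return The limit `E_c` (ticks).
#' @export
critical_case_limit <- function(history_E, params) {
  p <- param_get(params, "p"); mu0 <- param_get(params, "mu0")
  lhs <- params$eta * p
  rhs <- params$delta * exp(mu0 * params$T)
  if (abs(lhs - rhs) > 1e-8 * rhs)
    stop("parameters are not at the critical point eta*p = delta*exp(mu0*T)",
         call. = FALSE)
  L <- params$tau + params$T
  int <- stats::integrate(history_E, -L, 0, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value
  (history_E(0) + params$delta * int) / (1 + params$delta * L)
}

#' @export
print.tick_equilibria <- function(x, digits = 6, ...) {
  cat(sprintf("<tick_equilibria> scenario: %s\n", attr(x, "scenario_tag")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  rr <- attr(x, "rho_roots")
  if (!is.null(rr) && length(rr))
    cat("rho roots:", paste(format(rr, digits = digits), collapse = ", "),
        "\n")
  invisible(x)
}
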