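#' Behaviour-function families for tick attachment and host grooming
#'
#' The model couples a density-dependent attachment rate `rho(F)` (per
#' questing tick) and a grooming-driven drop-off rate `nu(F)` (per feeding
#' tick), both functions of the current feeding-tick load `F`. Four named
#' families are supported:
#'
#' * `rho_ricker()`: cooperative-then-self-limiting attachment
#'   \eqn{\rho(F) = p F e^{-F/c}}, maximal at the capacity `F = c`.
#' * `rho_holling3()`: Holling type III attachment
#'   \eqn{\rho(F) = r F / (1 + F^2/j^2)}, maximal value `r*j/2` at `F = j`.
#' * `rho_expdecay()`: monotone declining attachment
#'   \eqn{\rho(F) = p e^{-F/c}}.
#' * `nu_linear()`: load-proportional grooming \eqn{\nu(F) = \mu F + \mu_0}.
#' * `nu_reactive()`: grooming triggered by biting, \eqn{\nu(F) = k \rho(F)}.
#'
#' All are nonnegative and continuously differentiable on `[0, Inf)`;
#' a negative `F` is a domain error.
#'
#' @param F Feeding-tick load (ticks), nonnegative (vectorised).
#' @param p Attachment scale.
#' @param c Attachment capacity (ticks).
#' @param r Holling attack rate (1/(tick day)).
#' @param j Holling shape parameter (ticks).
#' @param mu Grooming slope (1/(tick day)).
#' @param mu0 Baseline grooming rate (1/day).
#' @param k Grooming-per-attachment coefficient (days).
#' @param rho Attachment function of one argument, used by `nu_reactive`.
#' @return Rate value(s), same length as `F`.
#' @name behaviours
NULL

.check_F <- function(F) {
  if (any(!is.finite(F)) || any(F < 0))
    stop("feeding-tick load F must be finite and nonnegative", call. = FALSE)
  F
}

#' @rdname behaviours
#' @export
rho_ricker <- function(F, p, c) {
  .check_F(F)
  p * F * exp(-F / c)
}

#' @rdname behaviours
#' @export
rho_holling3 <- function(F, r, j) {
  .check_F(F)
  r * F / (1 + (F / j)^2)
}

#' @rdname behaviours
#' @export
rho_expdecay <- function(F, p, c) {
  .check_F(F)
  p * exp(-F / c)
}

#' @rdname behaviours
#' @export
nu_linear <- function(F, mu, mu0) {
  .check_F(F)
  mu * F + mu0
}

#' @rdname behaviours
#' @export
nu_reactive <- function(F, k, rho) {
  .check_F(F)
  k * rho(F)
}

.scenario_tags <- c("constant", "monotone", "ricker_linear",
                    "holling3_reactive")

#' Build a behaviour scenario: an (attachment, grooming) function pair
#'
#' A scenario fixes the \eqn{(\rho, \nu)} family combination and closes the
#' behaviour functions (and their exact derivatives) over a parameter set.
#' The derivative closures are carried explicitly so that the stability
#' module never differentiates numerically at an equilibrium.
#'
#' Tags and their families:
#' \describe{
#'   \item{`constant`}{\eqn{\rho = p}, \eqn{\nu = \mu_0} (needs `p`, `mu0`).}
#'   \item{`monotone`}{\eqn{\rho = p e^{-F/c}}, \eqn{\nu = \mu F + \mu_0}
#'     (needs `p`, `c`, `mu`, `mu0`).}
#'   \item{`ricker_linear`}{\eqn{\rho = p F e^{-F/c}},
#'     \eqn{\nu = \mu F + \mu_0} (needs `p`, `c`, `mu`, `mu0`).}
#'   \item{`holling3_reactive`}{\eqn{\rho = r F/(1 + F^2/j^2)},
#'     \eqn{\nu = k \rho(F)} (needs `r`, `j`, `k`).}
#' }
#'
#' @param tag Scenario tag, one of `constant`, `monotone`, `ricker_linear`,
#'   `holling3_reactive`.
#' @param params A [tick_params()] object carrying the family's parameters;
#'   missing required fields raise an error here (fail fast).
#' @return An object of class `tick_scenario` with elements `tag`, `rho`,
#'   `rho_prime`, `nu`, `nu_prime` (functions of `F`).
#' @examples
#' pq <- tick_params(delta = 0.2, eta = 1.5, tau = 700, T = 7,
#'                   k = 2 / 7, r = 0.02, j = 120)
#' sc <- tick_scenario("holling3_reactive", pq)
#' sc$rho(120)  # r * j / 2
#' @export
tick_scenario <- function(tag, params) {
  tag <- match.arg(tag, .scenario_tags)
  sc <- switch(tag,
    constant = {
      p <- param_get(params, "p"); mu0 <- param_get(params, "mu0")
      list(rho = function(F) { .check_F(F); rep_len(p, length(F)) },
           rho_prime = function(F) rep_len(0, length(F)),
           nu = function(F) { .check_F(F); rep_len(mu0, length(F)) },
           nu_prime = function(F) rep_len(0, length(F)))
    },
    monotone = {
      p <- param_get(params, "p"); cc <- param_get(params, "c")
      mu <- param_get(params, "mu"); mu0 <- param_get(params, "mu0")
      list(rho = function(F) rho_expdecay(F, p, cc),
           rho_prime = function(F) -p / cc * exp(-F / cc),
           nu = function(F) nu_linear(F, mu, mu0),
           nu_prime = function(F) rep_len(mu, length(F)))
    },
    ricker_linear = {
      p <- param_get(params, "p"); cc <- param_get(params, "c")
      mu <- param_get(params, "mu"); mu0 <- param_get(params, "mu0")
      list(rho = function(F) rho_ricker(F, p, cc),
           rho_prime = function(F) p * (1 - F / cc) * exp(-F / cc),
           nu = function(F) nu_linear(F, mu, mu0),
           nu_prime = function(F) rep_len(mu, length(F)))
    },
    holling3_reactive = {
      r <- param_get(params, "r"); j <- param_get(params, "j")
      k <- param_get(params, "k")
      rho <- function(F) rho_holling3(F, r, j)
      rho_prime <- function(F) r * (1 - (F / j)^2) / (1 + (F / j)^2)^2
      list(rho = rho,
           rho_prime = rho_prime,
           nu = function(F) nu_reactive(F, k, rho),
           nu_prime = function(F) k * rho_prime(F))
    })
  structure(c(list(tag = tag), sc), class = "tick_scenario")
}

#' @export
print.tick_scenario <- function(x, ...) {
  cat(sprintf("<tick_scenario> %s\n", x$tag))
  invisible(x)
}

#' Basic reproduction number of the constant tick-host interface
#'
#' For constant attachment `p` and constant grooming `mu0`, the expected
#' number of engorged nymphs produced per engorged nymph over one life cycle
#' is \eqn{R_0 = p \eta e^{-\mu_0 T} / \delta}: the life-cycle gain `eta`
#' times survival through the feeding period times the attachment scale,
#' over the engorged-stage turnover. The monotone (declining-attachment)
#' family shares the same threshold since `rho(0) = p` there too. For
#' families with `rho(0) = 0` (Ricker, Holling III) the tick-free state is
#' always locally stable and this number does not apply; use
#' [trivial_stability()] instead.
#'
#' @param params A [tick_params()] with `p`, `mu0` (plus the always-required
#'   fields).
#' @return The dimensionless reproduction number.
#' @examples
#' basic_reproduction_number(tick_params(delta = 0.033, eta = 45, tau = 700,
#'                                       T = 7, p = 0.002, mu0 = 0.4))
#' @export
basic_reproduction_number <- function(params) {
  p <- param_get(params, "p")
  mu0 <- param_get(params, "mu0")
  p * params$eta * exp(-mu0 * params$T) / params$delta
}
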