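#' Built-in parameter presets for the two multi-stability configurations
#'
#' Two preset tick-host interfaces are bundled:
#' \describe{
#'   \item{`"bi"`}{Cooperative (Ricker) attachment with load-proportional
#'     grooming: `eta1 = 0.15`, `eta2 = 0.3`, `sigma = 1000` (so
#'     `eta = 45`), `tau = 700` d, `T = 7` d, `p = 0.002`, `delta = 0.033`,
#'     `mu0 = 0.4`, `mu = 0.0014`, `c = 100`. Bi-stable: tick-free plus one
#'     attracting positive state, separated by an unstable equilibrium.}
#'   \item{`"quadri"`}{Holling type III attachment with grooming reactive
#'     to biting: `eta1 = 0.05`, `eta2 = 0.1`, `sigma = 300` (so
#'     `eta = 1.5`), `tau = 700` d, `T = 7` d, `delta = 0.2`, `k = 2/7`,
#'     `r = 0.02`, `j = 120`. Quadri-stable equilibrium structure: four
#'     positive equilibria, two of them attracting, plus the attracting
#'     tick-free state.}
#' }
#'
#' @param name `"bi"` or `"quadri"`.
#' @return A list with `name`, `params` ([tick_params()]), `scenario`
#'   ([tick_scenario()]), and `documented_sources` (parameter provenance
#'   notes).
#' @examples
#' preset <- tick_preset("quadri")
#' solve_reactive(preset$params)
#' @export
tick_preset <- function(name = c("bi", "quadri")) {
  name <- match.arg(name)
  if (name == "bi") {
    params <- tick_params(delta = 0.033, eta1 = 0.15, eta2 = 0.3,
                          sigma = 1000, tau = 700, T = 7,
                          p = 0.002, c = 100, mu = 0.0014, mu0 = 0.4)
    scenario <- tick_scenario("ricker_linear", params)
    src <- c(eta1 = "stage survival, field estimate",
             eta2 = "egg-to-nymph survival, field estimate",
             sigma = "egg production rate, laboratory estimate",
             tau = "development delay, literature",
             T = "average nymphal feeding duration, literature",
             p = "attachment slope, assumed",
             delta = "engorged-nymph exit rate, assumed",
             mu0 = "baseline grooming rate, assumed",
             mu = "grooming slope, assumed",
             c = "attachment capacity, assumed")
  } else {
    params <- tick_params(delta = 0.2, eta1 = 0.05, eta2 = 0.1, sigma = 300,
                          tau = 700, T = 7, k = 2 / 7, r = 0.02, j = 120)
    scenario <- tick_scenario("holling3_reactive", params)
    src <- c(eta1 = "stage survival, field estimate",
             eta2 = "egg-to-nymph survival, field estimate",
             sigma = "egg production rate, laboratory estimate",
             tau = "development delay, literature",
             T = "average nymphal feeding duration, literature",
             delta = "engorged-nymph exit rate, assumed",
             k = "grooming-per-attachment coefficient, assumed",
             r = "Holling attack rate, assumed",
             j = "Holling shape parameter, assumed")
  }
  list(name = name, params = params, scenario = scenario,
       documented_sources = src)
}

# Published reference equilibrium values for the two configurations, kept
# separate from computed output so deviations stay visible.
.printed_reference <- function(name) {
  if (name == "quadri")
    data.frame(branch = c("minus_minus", "plus_minus", "plus_plus",
                          "minus_plus"),
               E_printed = c(5.8070, 14.5072, 47.7346, 840.7008),
               F_printed = c(9.9730, 66.1540, 217.6735, 1443.8375),
               stringsAsFactors = FALSE)
  else
    data.frame(branch = c("minus", "plus"),
               E_printed = c(5.1798, 37.1687),
               F_printed = c(7.0223, 164.9135),
               stringsAsFactors = FALSE)
}

.join_printed <- function(eq, name) {
  ref <- .printed_reference(name)
  out <- merge(as.data.frame(eq), ref, by = "branch", all.x = TRUE,
               sort = FALSE)
  out$F_rel_dev <- ifelse(is.na(out$F_printed), NA,
                          (out$F - out$F_printed) / out$F_printed)
  out <- out[order(out$F), ]
  rownames(out) <- NULL
  out
}

#' Quadri-stability report: equilibria, verdicts, and optional basin runs
#'
#' Computes, for the `"quadri"` preset: the attachment-rate equation roots,
#' the existence condition \eqn{\delta/\eta < (ekT)^{-1}}, the four positive
#' equilibria with stability verdicts from the A-sign classifier, and
#' (optionally) forward simulations from a set of initial feeding loads to
#' confirm which attractor each basin feeds.
#'
#' @param with_sims Run the basin-confirmation simulations (slow: each run
#'   integrates up to `t_end` days at step `step`).
#' @param initial_F Initial feeding loads for the basin runs.
#' @param step Integration step (days).
#' @param t_end Horizon (days) for each basin run.
#' @return A list of class `tick_report`: `condition` (left/right sides and
#'   verdict), `rho_roots`, `equilibria` (computed next to the printed
#'   reference values with relative deviation), and `basins` (if run).
#' @export
run_quadri_report <- function(with_sims = FALSE,
                              initial_F = c(1600, 700, 300, 200, 150, 10,
                                            3.3),
                              step = 0.1, t_end = NULL) {
  preset <- tick_preset("quadri")
  params <- preset$params; scenario <- preset$scenario
  eq <- classify_reactive(params)
  lhs <- params$delta / params$eta
  rhs <- exp(-1) / (param_get(params, "k") * params$T)
  out <- list(
    preset = "quadri",
    condition = list(delta_over_eta = lhs, inv_ekT = rhs,
                     positive_equilibria_exist = lhs < rhs),
    rho_roots = attr(eq, "rho_roots"),
    equilibria = .join_printed(eq, "quadri"))
  if (with_sims) {
    if (is.null(t_end)) t_end <- 50 * (params$tau + params$T)
    out$basins <- lapply(initial_F, function(F0) {
      histry <- make_history(E0 = "matched", F0 = F0, params, scenario,
                             h = step)
      tr <- simulate_ticks(histry, params, scenario, t_end = t_end,
                           h = step, equilibria = eq)
      list(initial_F = F0, E0 = histry$E[1],
           status = tr$terminal$status, branch = tr$terminal$branch,
           final_E = tr$E[length(tr$E)], final_F = tr$F[length(tr$F)])
    })
  }
  class(out) <- "tick_report"
  out
}

#' Bi-stability report: Ricker equilibria, verdicts, and the fold in T
#'
#' Computes, for the `"bi"` preset: the two positive equilibria of the
#' Ricker/linear-grooming equilibrium equation with their leading-eigenvalue
#' verdicts, the fold in the feeding duration `T` located by bisection of
#' the tangency condition, and (optionally) simulations from paired initial
#' data. The printed reference equilibria for this configuration are not
#' simultaneous roots of the equilibrium equation under the stated
#' parameters, so computed values are reported next to them with the
#' deviation left visible.
#'
#' @param with_sims Run the confirmation simulations.
#' @param initial_data List of initial `(E, F)` pairs (interpreted in that
#'   order) for the simulation runs; each is also run with the pair swapped
#'   when `both_orderings` is `TRUE`, since either reading of a bare number
#'   pair is defensible.
#' @param both_orderings Also simulate each pair as `(F, E)`.
#' @param step Integration step (days).
#' @param t_end Horizon (days) for each run.
#' @return A list of class `tick_report`: `equilibria`, `fold`, and
#'   `runs` (if simulated).
#' @export
run_bi_report <- function(with_sims = FALSE,
                          initial_data = list(c(80, 180), c(60, 90),
                                              c(30, 20), c(5, 8)),
                          both_orderings = FALSE,
                          step = 0.1, t_end = NULL) {
  preset <- tick_preset("bi")
  params <- preset$params; scenario <- preset$scenario
  eq <- classify_ricker(params)
  fold <- fold_point(params, "ricker_linear", "T", c(params$T, 20))
  out <- list(preset = "bi",
              equilibria = .join_printed(eq, "bi"),
              fold = fold)
  if (with_sims) {
    if (is.null(t_end)) t_end <- 50 * (params$tau + params$T)
    runs <- list()
    for (pair in initial_data) {
      orderings <- if (both_orderings) list(pair, rev(pair)) else list(pair)
      for (ord in orderings) {
        histry <- make_history(E0 = ord[1], F0 = ord[2], params, scenario,
                               h = step)
        tr <- simulate_ticks(histry, params, scenario, t_end = t_end,
                             h = step, equilibria = eq)
        runs[[length(runs) + 1L]] <-
          list(E0 = ord[1], F0 = ord[2],
               matching_residual = histry$matching_residual,
               status = tr$terminal$status, branch = tr$terminal$branch,
               final_E = tr$E[length(tr$E)], final_F = tr$F[length(tr$F)])
      }
    }
    out$runs <- runs
  }
  class(out) <- "tick_report"
  out
}

#' @export
print.tick_report <- function(x, digits = 6, ...) {
  cat(sprintf("<tick_report> preset: %s\n", x$preset))
  if (!is.null(x$condition))
    cat(sprintf("  delta/eta = %.4f %s (e k T)^-1 = %.4f\n",
                x$condition$delta_over_eta,
                if (x$condition$positive_equilibria_exist) "<" else ">=",
                x$condition$inv_ekT))
  if (!is.null(x$rho_roots))
    cat("  rho roots:",
        paste(format(x$rho_roots, digits = digits), collapse = ", "), "\n")
  cat("  equilibria (computed vs printed reference):\n")
  print.data.frame(x$equilibria, digits = digits, row.names = FALSE)
  if (!is.null(x$fold))
    cat(sprintf("  fold in %s at %.6g (F* = %.6g)\n",
                x$fold$param, x$fold$value, x$fold$F_star))
  for (b in x$basins)
    cat(sprintf("  F0 = %8.4g -> %s%s (final F = %.6g)\n", b$initial_F,
                b$status,
                if (!is.na(b$branch)) paste0(" [", b$branch, "]") else "",
                b$final_F))
  for (b in x$runs)
    cat(sprintf("  (E0, F0) = (%g, %g) -> %s%s (final F = %.6g)\n",
                b$E0, b$F0, b$status,
                if (!is.na(b$branch)) paste0(" [", b$branch, "]") else "",
                b$final_F))
  invisible(x)
}
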