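#' Method-of-steps simulation of the coupled delay-algebraic system
#'
#' The state equations integrated are the differentiated form of the coupled
#' system, valid on the constraint manifold fixed by the matching condition:
#' \deqn{E'(t) = -\delta E(t) + e^{-S(t)}\rho(F(t-T))\,\eta E(t-\tau-T),}
#' \deqn{F'(t) = \rho(F(t))\,\eta E(t-\tau) -
#'   e^{-S(t)}\rho(F(t-T))\,\eta E(t-\tau-T) - \nu(F(t))F(t),}
#' where \eqn{S(t) = \int_{t-T}^{t}\nu(F(s))ds} is the running feeding-period
#' grooming exposure, carried as a third state with
#' \eqn{S'(t) = \nu(F(t)) - \nu(F(t-T))}. Integration is classical
#' fourth-order Runge-Kutta on a fixed grid whose step divides both delays;
#' delayed values at half-steps come from cubic Hermite interpolation of the
#' stored solution (values and derivatives), so the scheme retains fourth
#' order. The algebraic (integral) equation for `F` is monitored, not
#' enforced: its residual stays at discretisation level when the history is
#' matched, and is reported along the trajectory.
#'
#' @name simulator
NULL

# (1 - e^{-nu T}) / nu, the constant-rate survival-weighted feeding window
.window <- function(nu, T) if (nu < 1e-12) T else (1 - exp(-nu * T)) / nu

.check_step <- function(h, params) {
  nT <- params$T / h
  ntau <- params$tau / h
  if (abs(nT - round(nT)) > 1e-8 || abs(ntau - round(ntau)) > 1e-8)
    stop("step h must divide both the feeding duration T and the delay tau",
         call. = FALSE)
  c(nT = as.integer(round(nT)), ntau = as.integer(round(ntau)))
}

# Composite Simpson weights for n+1 points (n even), already scaled by h/3.
.simpson_w <- function(n, h) {
  w <- rep(c(2, 4), length.out = n + 1)
  w[1] <- 1; w[n + 1] <- 1
  w * h / 3
}

# Cumulative integral of a sampled function given values v and derivatives
# dv at spacing h, by Hermite-corrected trapezoid (O(h^4)). v[1] is the
# earliest point; returns the integral from v[1] to each grid point.
.cum_hermite <- function(v, dv, h) {
  n <- length(v)
  panels <- h / 2 * (v[-n] + v[-1]) + h^2 / 12 * (dv[-n] - dv[-1])
  c(0, cumsum(panels))
}

# Algebraic right-hand side F_alg(t_i) evaluated from stored arrays.
# i must be >= ntau + nT + 1 grid points into the arrays.
.alg_rhs <- function(i, Ev, Fv, dFv, nT, ntau, h, params, scenario) {
  idx <- i - (nT:0)                    # times t-T .. t (earliest first)
  vF <- Fv[idx]
  v <- scenario$nu(vF)
  dv <- scenario$nu_prime(vF) * dFv[idx]
  Wup <- .cum_hermite(v, dv, h)        # int from t-T to each point
  W <- Wup[nT + 1] - Wup               # int from each point up to t
  g <- exp(-W) * scenario$rho(vF) * params$eta * Ev[idx - ntau]
  if (nT %% 2L == 0L) sum(.simpson_w(nT, h) * g)
  else sum(h * (g[-1] + g[-(nT + 1)]) / 2)
}

#' Construct an initial history satisfying the matching condition
#'
#' Builds the initial data `(E, F)` on the interval `[-tau-T, 0]`. The
#' engorged-tick history may be a constant or a function of time; the
#' feeding-tick history is a constant, a function, or the sentinel
#' `"matched"`, in which case the constant level is the fixed point of the
#' matching condition
#' \deqn{F(0) = \rho(F)\,\eta \int_0^T e^{-\nu(F)a} E(-\tau - a)\,da,}
#' so the algebraic equation holds at `t = 0` and hence (by conservation)
#' along the whole forward solution. Alternatively set `E0 = "matched"` with
#' a numeric `F0` to solve the same condition for the constant engorged
#' level that supports a prescribed feeding load.
#'
#' @param E0 Constant engorged-tick level, a function of `s` on
#'   `[-tau-T, 0]`, or `"matched"` (requires numeric `F0`).
#' @param F0 Constant feeding-tick level, a function, or `"matched"`.
#' @param params A [tick_params()].
#' @param scenario A [tick_scenario()].
#' @param h Grid step (days); must divide `T` and `tau`. Default `T/70`.
#' @return An object of class `tick_history`: grid, `E`, `F`, derivative
#'   samples, and the matching residual
#'   `|F(0) - F_alg(0)| / max(F(0), 1)`.
#' @examples
#' pq <- tick_params(delta = 0.2, eta = 1.5, tau = 700, T = 7,
#'                   k = 2 / 7, r = 0.02, j = 120)
#' sc <- tick_scenario("holling3_reactive", pq)
#' hist <- make_history(E0 = 10, F0 = "matched", pq, sc)
#' hist$matching_residual
#' @export
make_history <- function(E0, F0 = "matched", params, scenario,
                         h = params$T / 70) {
  nn <- .check_step(h, params)
  nT <- nn[["nT"]]; ntau <- nn[["ntau"]]
  ntt <- nT + ntau
  grid <- seq(-(params$tau + params$T), 0, by = h)
  stopifnot(length(grid) == ntt + 1)

  matchedE <- identical(E0, "matched")
  matchedF <- identical(F0, "matched")
  if (matchedE && matchedF)
    stop("at most one of E0, F0 may be \"matched\"", call. = FALSE)

  Efun <- if (is.function(E0)) E0 else NULL
  if (!matchedE) {
    Ev <- if (is.function(E0)) E0(grid) else rep(E0, ntt + 1)
    if (any(Ev < 0)) stop("history E must be nonnegative", call. = FALSE)
  }

  # survival-weighted integral of E over the feeding window, at grooming nu
  Ewindow <- function(nu) {
    a <- seq(0, params$T, by = h)
    Ea <- Ev[ntt + 1 - ntau - round(a / h)]   # E(-tau - a)
    g <- exp(-nu * a) * Ea
    if (nT %% 2L == 0L) sum(.simpson_w(nT, h) * g)
    else sum(h * (g[-1] + g[-(nT + 1)]) / 2)
  }

  if (matchedF && max(Ev) == 0) {
    Fv <- rep(0, ntt + 1)
  } else if (matchedF) {
    # damped fixed-point iteration for the constant feeding level
    Fbar <- scenario$rho(1) * params$eta * mean(Ev)  # any positive seed
    if (!is.finite(Fbar) || Fbar <= 0) Fbar <- 1
    ok <- FALSE
    for (it in seq_len(1e4)) {
      Fnew <- scenario$rho(Fbar) * params$eta * Ewindow(scenario$nu(Fbar))
      step <- 0.5 * (Fnew - Fbar)
      Fbar2 <- Fbar + step
      rel <- abs(Fbar2 - Fbar) / max(Fbar, 1)
      Fbar <- Fbar2
      if (rel < 1e-12) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(paste0("matching fixed point did not converge in 1e4 ",
                          "iterations (last relative change %.3e)"), rel),
           call. = FALSE)
    Fv <- rep(Fbar, ntt + 1)
  } else if (matchedE) {
    if (!is.numeric(F0) || F0 < 0)
      stop("F0 must be a nonnegative number when E0 = \"matched\"",
           call. = FALSE)
    Fv <- rep(F0, ntt + 1)
    rhoF <- scenario$rho(F0)
    Econst <- if (F0 == 0 || rhoF == 0) 0 else
      F0 / (params$eta * rhoF * .window(scenario$nu(F0), params$T))
    Ev <- rep(Econst, ntt + 1)
  } else {
    Fv <- if (is.function(F0)) F0(grid) else rep(F0, ntt + 1)
    if (any(Fv < 0)) stop("history F must be nonnegative", call. = FALSE)
  }

  # derivative samples for Hermite interpolation (exact zero for constants)
  deriv <- function(v) {
    if (max(v) - min(v) == 0) return(rep(0, length(v)))
    n <- length(v)
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
    d[1] <- (v[2] - v[1]) / h
    d[n] <- (v[n] - v[n - 1]) / h
    d
  }
  dE <- deriv(Ev); dF <- deriv(Fv)

  Falg <- .alg_rhs(ntt + 1, Ev, Fv, dF, nT, ntau, h, params, scenario)
  res <- abs(Fv[ntt + 1] - Falg) / max(Fv[ntt + 1], 1)
  structure(list(grid = grid, E = Ev, F = Fv, dE = dE, dF = dF, h = h,
                 matching_residual = res, scenario_tag = scenario$tag),
            class = "tick_history")
}

#' @export
print.tick_history <- function(x, ...) {
  cat(sprintf(paste0("<tick_history> on [%.1f, 0], h = %g, E(0) = %.6g, ",
                     "F(0) = %.6g\n  matching residual = %.3e\n"),
              x$grid[1], x$h, x$E[length(x$E)], x$F[length(x$F)],
              x$matching_residual))
  invisible(x)
}

#' Integrate the coupled system forward from a history
#'
#' Advances the system by fixed-step fourth-order Runge-Kutta (see
#' [simulator]) until `t_end`, early-stopping when the state has stayed
#' within relative distance `1e-4` of a supplied equilibrium for one full
#' life cycle `tau + T` (convergence), or when the state exceeds `1e10`
#' (divergence). Positivity is a theorem for matched nonnegative histories,
#' so a state below `-1e-9` aborts with diagnostics.
#'
#' @param history A [make_history()] object.
#' @param params A [tick_params()].
#' @param scenario A [tick_scenario()].
#' @param t_end Integration horizon (days). Default `50 * (tau + T)`:
#'   delays of hundreds of days mean transients span dozens of generations.
#' @param h Step (days); defaults to the history grid step.
#' @param equilibria Optional `tick_equilibria` table; enables convergence
#'   detection against its rows.
#' @param monitor_every Spacing (days) of algebraic-constraint residual
#'   checks; `NA` disables monitoring.
#' @param resync_every Steps between full re-quadratures of the running
#'   survival integral (bounds floating-point drift).
#' @return An object of class `tick_trajectory` with fields `t`, `E`, `F`,
#'   `Q` (questing input \eqn{\eta E(t-\tau)}), `constraint` (data frame of
#'   monitored residuals), and `terminal` (status and, if converged, the
#'   branch reached).
#' @export
simulate_ticks <- function(history, params, scenario,
                           t_end = 50 * (params$tau + params$T),
                           h = history$h, equilibria = NULL,
                           monitor_every = 7, resync_every = 10000L) {
  nn <- .check_step(h, params)
  nT <- nn[["nT"]]; ntau <- nn[["ntau"]]; ntt <- nT + ntau
  if (abs(h - history$h) > 1e-12)
    stop("history grid step does not match h", call. = FALSE)
  n_steps <- as.integer(ceiling(t_end / h - 1e-9))
  N <- ntt + 1L + n_steps
  E <- numeric(N); F <- numeric(N); dE <- numeric(N); dF <- numeric(N)
  S <- numeric(N)
  i0 <- ntt + 1L
  E[1:i0] <- history$E; F[1:i0] <- history$F
  dE[1:i0] <- history$dE; dF[1:i0] <- history$dF

  rho <- scenario$rho; nu <- scenario$nu; nup <- scenario$nu_prime
  eta <- params$eta; delta <- params$delta

  # survival integral over [-T, 0] from the history
  idxT <- (i0 - nT):i0
  S[i0] <- {
    v <- nu(F[idxT]); dv <- nup(F[idxT]) * dF[idxT]
    sum(h / 2 * (v[-1] + v[-(nT + 1)]) + h^2 / 12 * (dv[-(nT + 1)] - dv[-1]))
  }

  # node derivative at t = 0. The solution's first derivative generally
  # jumps at the junction with the history, so keep the history's left-sided
  # derivatives for Hermite interpolation on the interval just left of it.
  dEl_j <- dE[i0]; dFl_j <- dF[i0]
  B0 <- exp(-S[i0]) * rho(F[i0 - nT]) * eta * E[i0 - ntt]
  dE[i0] <- -delta * E[i0] + B0
  dF[i0] <- rho(F[i0]) * eta * E[i0 - ntau] - B0 - nu(F[i0]) * F[i0]

  # convergence bookkeeping
  eqE <- eqF <- NULL
  if (!is.null(equilibria)) {
    eqE <- equilibria$E; eqF <- equilibria$F
    last_bad <- rep(0, length(eqE))     # last time each target was violated
  }
  check_stride <- max(1L, as.integer(round(1 / h)))
  window <- params$tau + params$T
  mon_stride <- if (is.na(monitor_every)) NA_integer_ else
    max(1L, as.integer(round(monitor_every / h)))
  mon_t <- numeric(0); mon_r <- numeric(0)

  status <- "max_time"; branch <- NA_character_
  i_last <- i0 + n_steps
  half <- h / 2

  for (step in seq_len(n_steps)) {
    i <- i0 + step - 1L
    t <- (step - 1L) * h

    # delayed values at the three stage times (t, t + h/2, t + h)
    q1 <- i - ntau; q2 <- i - ntt; q3 <- i - nT
    EL1_0 <- E[q1]; EL2_0 <- E[q2]; FL_0 <- F[q3]
    EL1_1 <- E[q1 + 1L]; EL2_1 <- E[q2 + 1L]; FL_1 <- F[q3 + 1L]
    dE1r <- if (q1 + 1L == i0) dEl_j else dE[q1 + 1L]
    dE2r <- if (q2 + 1L == i0) dEl_j else dE[q2 + 1L]
    dF3r <- if (q3 + 1L == i0) dFl_j else dF[q3 + 1L]
    EL1_h <- 0.5 * (EL1_0 + EL1_1) + h * (dE[q1] - dE1r) / 8
    EL2_h <- 0.5 * (EL2_0 + EL2_1) + h * (dE[q2] - dE2r) / 8
    FL_h  <- 0.5 * (FL_0 + FL_1) + h * (dF[q3] - dF3r) / 8
    rhoFL <- rho(c(FL_0, FL_h, FL_1))
    nuFL <- nu(c(FL_0, FL_h, FL_1))

    y1 <- E[i]; y2 <- F[i]; y3 <- S[i]

    # k1 (node derivative, already stored for E and F)
    k1E <- dE[i]; k1F <- dF[i]; k1S <- nu(y2) - nuFL[1L]

    # k2
    e2 <- y1 + half * k1E; f2 <- y2 + half * k1F; s2 <- y3 + half * k1S
    B <- exp(-s2) * rhoFL[2L] * eta * EL2_h
    nf2 <- nu(f2)
    k2E <- -delta * e2 + B
    k2F <- rho(f2) * eta * EL1_h - B - nf2 * f2
    k2S <- nf2 - nuFL[2L]

    # k3
    e3 <- y1 + half * k2E; f3 <- y2 + half * k2F; s3 <- y3 + half * k2S
    B <- exp(-s3) * rhoFL[2L] * eta * EL2_h
    nf3 <- nu(f3)
    k3E <- -delta * e3 + B
    k3F <- rho(f3) * eta * EL1_h - B - nf3 * f3
    k3S <- nf3 - nuFL[2L]

    # k4
    e4 <- y1 + h * k3E; f4 <- y2 + h * k3F; s4 <- y3 + h * k3S
    B <- exp(-s4) * rhoFL[3L] * eta * EL2_1
    nf4 <- nu(f4)
    k4E <- -delta * e4 + B
    k4F <- rho(f4) * eta * EL1_1 - B - nf4 * f4
    k4S <- nf4 - nuFL[3L]

    En <- y1 + h / 6 * (k1E + 2 * k2E + 2 * k3E + k4E)
    Fn <- y2 + h / 6 * (k1F + 2 * k2F + 2 * k3F + k4F)
    Sn <- y3 + h / 6 * (k1S + 2 * k2S + 2 * k3S + k4S)

    if (En < -1e-9 || Fn < -1e-9) {
      i_last <- i
      stop(sprintf(paste0("positivity violated at t = %.2f (E = %.3e, ",
                          "F = %.3e); check that the history is matched ",
                          "and nonnegative"), t + h, En, Fn), call. = FALSE)
    }
    if (En < 0) En <- 0
    if (Fn < 0) Fn <- 0
    ii <- i + 1L
    E[ii] <- En; F[ii] <- Fn; S[ii] <- Sn

    # node derivative at the new point (k1 of the next step)
    B <- exp(-Sn) * rhoFL[3L] * eta * EL2_1
    dE[ii] <- -delta * En + B
    dF[ii] <- rho(Fn) * eta * EL1_1 - B - nu(Fn) * Fn

    if (step %% resync_every == 0L) {
      idx <- (ii - nT):ii
      v <- nu(F[idx]); dv <- nup(F[idx]) * dF[idx]
      S[ii] <- sum(h / 2 * (v[-1] + v[-(nT + 1)]) +
                     h^2 / 12 * (dv[-(nT + 1)] - dv[-1]))
    }

    if (!is.na(mon_stride) && step %% mon_stride == 0L) {
      Falg <- .alg_rhs(ii, E, F, dF, nT, ntau, h, params, scenario)
      mon_t <- c(mon_t, t + h)
      mon_r <- c(mon_r, abs(F[ii] - Falg) / max(F[ii], 1))
    }

    if (En > 1e10 || Fn > 1e10) {
      status <- "diverged"; i_last <- ii; break
    }
    if (!is.null(eqE) && step %% check_stride == 0L) {
      tn <- t + h
      d <- pmax(abs(En - eqE) / pmax(eqE, 1), abs(Fn - eqF) / pmax(eqF, 1))
      last_bad[d >= 1e-4] <- tn
      hit <- which(tn - last_bad >= window)
      if (length(hit)) {
        status <- "converged"
        branch <- equilibria$branch[hit[1]]
        i_last <- ii
        break
      }
    }
    i_last <- ii
  }

  keep <- i0:i_last
  tgrid <- (keep - i0) * h
  Q <- eta * E[keep - ntau]
  structure(list(t = tgrid, E = E[keep], F = F[keep], Q = Q,
                 constraint = data.frame(t = mon_t, residual = mon_r),
                 terminal = list(status = status, branch = branch,
                                 t_final = tgrid[length(tgrid)]),
                 h = h, i0 = i0, nT = nT, ntau = ntau,
                 scenario_tag = scenario$tag,
                 arrays = list(E = E[1:i_last], F = F[1:i_last],
                               dE = dE[1:i_last], dF = dF[1:i_last])),
            class = "tick_trajectory")
}

#' @export
print.tick_trajectory <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf(paste0("<tick_trajectory> %s scenario, t in [0, %.1f], ",
                     "h = %g\n  final (E, F) = (%.6g, %.6g); status: %s%s\n"),
              x$scenario_tag, x$t[n], x$h, x$E[n], x$F[n],
              x$terminal$status,
              if (!is.na(x$terminal$branch))
                paste0(" -> ", x$terminal$branch) else ""))
  if (nrow(x$constraint))
    cat(sprintf("  max constraint residual: %.3e\n",
                max(x$constraint$residual)))
  invisible(x)
}

#' Reconstruct the feeding-duration density profile at a time point
#'
#' The density of feeding ticks over time-since-attachment `a` is
#' \eqn{n(t, a) = e^{-\int_{t-a}^{t}\nu(F)}\rho(F(t-a))\,\eta E(t-\tau-a)};
#' its integral over `[0, T]` recovers the total feeding load `F(t)`.
#'
#' @param trajectory A [simulate_ticks()] result.
#' @param t Time within the trajectory range (snapped to the grid).
#' @param params A [tick_params()].
#' @param scenario The [tick_scenario()] used for the run.
#' @return A data frame with columns `a` and `n`, with attributes
#'   `integral` (quadrature of `n` over the feeding window) and `F_t`
#'   (the state value it should equal).
#' @export
density_profile <- function(trajectory, t, params, scenario) {
  if (t < 0 || t > trajectory$t[length(trajectory$t)])
    stop("t outside the trajectory range", call. = FALSE)
  h <- trajectory$h
  nT <- trajectory$nT; ntau <- trajectory$ntau
  i <- trajectory$i0 + as.integer(round(t / h))
  ar <- trajectory$arrays
  idx <- i - (nT:0)
  vF <- ar$F[idx]
  v <- scenario$nu(vF)
  dv <- scenario$nu_prime(vF) * ar$dF[idx]
  Wup <- .cum_hermite(v, dv, h)
  W <- Wup[nT + 1] - Wup
  n_a <- exp(-W) * scenario$rho(vF) * params$eta * ar$E[idx - ntau]
  out <- data.frame(a = seq(params$T, 0, by = -h), n = n_a)
  out <- out[order(out$a), ]
  rownames(out) <- NULL
  integral <- if (nT %% 2L == 0L) sum(.simpson_w(nT, h) * out$n)
    else sum(h * (out$n[-1] + out$n[-(nT + 1)]) / 2)
  attr(out, "integral") <- integral
  attr(out, "F_t") <- ar$F[i]
  out
}

# Tangency gap whose zero is the fold (branch-merging) point.
.tangency_gap <- function(params, scenario_tag) {
  if (scenario_tag == "ricker_linear") {
    p <- param_get(params, "p"); cc <- param_get(params, "c")
    mu <- param_get(params, "mu"); mu0 <- param_get(params, "mu0")
    params$delta / (params$eta * p) * exp(mu0 * params$T) -
      exp(-1) / (1 / cc + mu * params$T)
  } else if (scenario_tag == "holling3_reactive") {
    params$delta / params$eta -
      exp(-1) / (param_get(params, "k") * params$T)
  } else stop("no fold condition for scenario ", scenario_tag, call. = FALSE)
}

#' Locate the fold point where two equilibrium branches merge
#'
#' Bisects the tangency condition (equality case of the equilibrium
#' trichotomy) in a single parameter: for the Ricker family,
#' \eqn{\delta(\eta p)^{-1}e^{\mu_0 T} = e^{-1}(1/c + \mu T)^{-1}}; for
#' biting-reactive grooming, \eqn{\delta/\eta = (ekT)^{-1}}.
#'
#' @param params A [tick_params()].
#' @param scenario_tag `"ricker_linear"` or `"holling3_reactive"`.
#' @param param_name Parameter to vary (e.g. `"T"`, `"p"`, `"delta"`).
#' @param interval Search interval for the parameter.
#' @return List with the fold parameter `value` and the merged-branch
#'   feeding load `F_star` there.
#' @export
fold_point <- function(params, scenario_tag, param_name,
                       interval) {
  gap <- function(v) {
    pp <- params; pp[[param_name]] <- v
    .tangency_gap(pp, scenario_tag)
  }
  v <- stats::uniroot(gap, interval, tol = 1e-13)$root
  pp <- params; pp[[param_name]] <- v
  F_star <- if (scenario_tag == "ricker_linear")
    1 / (1 / param_get(pp, "c") + param_get(pp, "mu") * pp$T)
  else {
    rho_star <- 1 / (param_get(pp, "k") * pp$T)
    Fs <- try(holling3_invert(rho_star, param_get(pp, "r"),
                              param_get(pp, "j")), silent = TRUE)
    if (inherits(Fs, "try-error")) NA_real_ else Fs
  }
  list(param = param_name, value = v, F_star = F_star)
}

#' Scan equilibrium branches and their stability along one parameter
#'
#' Recomputes the equilibrium set and perturbation verdicts at each grid
#' value of a chosen parameter, and refines the fold point (where positive
#' branches merge and vanish) whenever the positive-equilibrium count
#' changes across the grid.
#'
#' @param params Baseline [tick_params()].
#' @param scenario_tag `"ricker_linear"` or `"holling3_reactive"`.
#' @param param_name Name of the parameter to scan.
#' @param grid Numeric vector of parameter values.
#' @return A list with `table` (one row per branch per grid value: value,
#'   branch, E, F, stability) and `fold` (a [fold_point()] result or `NULL`
#'   if the branch count never changes on the grid).
#' @export
bifurcation_scan <- function(params, scenario_tag, param_name, grid) {
  classify <- switch(scenario_tag,
                     ricker_linear = classify_ricker,
                     holling3_reactive = classify_reactive,
                     stop("scan supports the ricker_linear and ",
                          "holling3_reactive scenarios", call. = FALSE))
  rows <- vector("list", length(grid))
  counts <- integer(length(grid))
  for (i in seq_along(grid)) {
    pp <- params
    pp[[param_name]] <- grid[i]
    eq <- classify(pp)
    counts[i] <- sum(eq$branch != "trivial")
    rows[[i]] <- data.frame(value = grid[i], branch = eq$branch,
                            E = eq$E, F = eq$F, stability = eq$stability,
                            stringsAsFactors = FALSE)
  }
  fold <- NULL
  chg <- which(diff(counts) != 0)
  if (length(chg)) {
    i <- chg[1]
    fold <- fold_point(params, scenario_tag, param_name,
                       sort(c(grid[i], grid[i + 1])))
  }
  list(table = do.call(rbind, rows), fold = fold)
}
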