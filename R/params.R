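#' Model parameters for the tick-host interface
#'
#' Bundles the life-cycle rates, delays, and behaviour-function parameters of
#' the coupled engorged/feeding tick system. Only the fields required by the
#' active scenario need be supplied; accessing an unset field is an error.
#'
#' @param delta Exit rate of engorged nymphs (1/day). Required, > 0.
#' @param tau Development delay from engorged nymph back to questing nymph
#'   (days), the sum of the nymph-to-adult and egg-to-nymph delays. Required,
#'   > 0.
#' @param T Average feeding duration on the host (days). Required, > 0.
#' @param eta Composite life-cycle gain: expected questing nymphs produced per
#'   engorged nymph, \code{eta = eta2 * sigma * eta1}. Either give `eta`
#'   directly or give all of `eta1`, `eta2`, `sigma`.
#' @param eta1 Survival probability from engorged nymph to egg-laying adult.
#' @param eta2 Survival probability from egg to questing nymph.
#' @param sigma Egg production rate (eggs/day).
#' @param p Attachment scale. For the constant scenario this is the attachment
#'   rate itself; for the Ricker family it is the slope at zero load; for the
#'   exponential-decay family it is the rate at zero load.
#' @param c Attachment capacity (ticks): the feeding load at which Ricker
#'   attachment peaks, or the e-folding load of the exponential-decay family.
#' @param mu Grooming slope (1/(tick day)) of the linear grooming rate.
#' @param mu0 Baseline grooming rate (1/day).
#' @param k Grooming-per-attachment coefficient (days) of the
#'   reactive grooming rate \code{nu(F) = k * rho(F)}.
#' @param r Holling type III attack rate (1/(tick day)).
#' @param j Holling type III shape parameter (ticks); attachment peaks at
#'   \code{F = j} with value \code{r*j/2}.
#'
#' @return An object of class `tick_params`.
#' @examples
#' tick_params(delta = 0.2, eta1 = 0.05, eta2 = 0.1, sigma = 300,
#'             tau = 700, T = 7, k = 2 / 7, r = 0.02, j = 120)
#' @export
tick_params <- function(delta, tau, T, eta = NULL,
                        eta1 = NULL, eta2 = NULL, sigma = NULL,
                        p = NULL, c = NULL, mu = NULL, mu0 = NULL,
                        k = NULL, r = NULL, j = NULL) {
  comp <- c(eta1 = is.null(eta1), eta2 = is.null(eta2), sigma = is.null(sigma))
  if (!all(comp)) {
    if (any(comp))
      stop("supply all of eta1, eta2, sigma or none of them", call. = FALSE)
    eta_derived <- eta2 * sigma * eta1
    if (!is.null(eta) && !isTRUE(all.equal(eta, eta_derived)))
      stop("eta does not equal eta2 * sigma * eta1", call. = FALSE)
    eta <- eta_derived
  }
  if (is.null(eta)) stop("eta (or eta1, eta2, sigma) is required", call. = FALSE)

  x <- list(delta = delta, eta = eta, eta1 = eta1, eta2 = eta2, sigma = sigma,
            tau = tau, T = T, p = p, c = c, mu = mu, mu0 = mu0,
            k = k, r = r, j = j)
  for (nm in c("delta", "eta", "tau", "T")) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  for (nm in c("eta1", "eta2", "sigma", "p", "c", "mu", "mu0", "k", "r", "j")) {
    v <- x[[nm]]
    if (!is.null(v) &&
        (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0))
      stop(sprintf("'%s' must be a single nonnegative finite number", nm),
           call. = FALSE)
  }
  structure(x, class = "tick_params")
}

#' Access a required parameter, failing if it was not supplied
#'
#' @param params A `tick_params` object.
#' @param name Parameter name.
#' @return The parameter value.
#' @keywords internal
param_get <- function(params, name) {
  v <- params[[name]]
  if (is.null(v))
    stop(sprintf("parameter '%s' is required by this scenario but was not set",
                 name), call. = FALSE)
  v
}

#' @export
print.tick_params <- function(x, ...) {
  set <- Filter(Negate(is.null), unclass(x))
  cat("<tick_params>\n")
  for (nm in names(set))
    cat(sprintf("  %-6s %g\n", nm, set[[nm]]))
  invisible(x)
}

# Keys accepted in configuration files, and which are scenario selectors.
.config_keys <- c("scenario", "delta", "eta", "eta1", "eta2", "sigma",
                  "tau", "T", "p", "c", "mu", "mu0", "k", "r", "j")

#' Read a scenario and parameter set from a key-value configuration file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. `scenario` selects the behaviour-function
#' family (one of `constant`, `monotone`, `ricker_linear`,
#' `holling3_reactive`); the remaining keys are [tick_params()] fields with
#' units in days and tick counts. Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `params` (a `tick_params`) and `scenario`
#'   (a `tick_scenario`).
#' @export
read_tick_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  unknown <- setdiff(keys, .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  if (!"scenario" %in% keys) stop("config must set 'scenario'", call. = FALSE)
  tag <- vals[keys == "scenario"]
  num <- as.list(as.numeric(vals[keys != "scenario"]))
  names(num) <- keys[keys != "scenario"]
  if (anyNA(unlist(num))) stop("non-numeric parameter value", call. = FALSE)
  params <- do.call(tick_params, num)
  list(params = params, scenario = tick_scenario(tag, params))
}
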