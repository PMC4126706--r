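# Calibration of the kinetic rate constants by multistart Nelder-Mead.
#
# The objective is a weighted squared error between simulated and observed
# series. Mixed-unit observables (mM pools, elemental totals) are made
# comparable by the default weighting w_o = 1 / max(obs_o)^2, which
# normalizes each series to unit scale. Optimization runs in log-parameter
# space, which enforces positivity without constraints and suits rate
# constants spread over several orders of magnitude.

OBS_DERIVED <- c("X_C", "X_N", "chlorophyll")

obs_names <- function(obs) setdiff(names(obs), "time")

default_weights <- function(obs) {
  nm <- obs_names(obs)
  w <- vapply(nm, function(o) {
    m <- max(abs(obs[[o]]), na.rm = TRUE)
    if (m == 0) 1 else 1 / m^2
  }, numeric(1L))
  names(w) <- nm
  w
}

#' Average duplicate-culture observations
#'
#' Observations from replicate cultures sampled at the same times are
#' averaged per time point before fitting (a preprocessing convention, not
#' part of the objective).
#'
#' @param obs data frame with a `time` column and one column per observable.
#' @return data frame with one row per unique time, observables averaged.
#' @export
average_duplicates <- function(obs) {
  agg <- stats::aggregate(obs[obs_names(obs)], by = list(time = obs$time),
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$time), , drop = FALSE]
}

simulate_observables <- function(params, model, laws, env, obs, init,
                                 compositions, chl_fraction, rtol, atol) {
  laws <- set_params(laws, params)
  t_obs <- obs$time
  times <- sort(unique(c(0, t_obs)))
  traj <- simulate_model(model, laws, env, times, init,
                         rtol = rtol, atol = atol)
  idx <- match(t_obs, traj$times)
  nm <- obs_names(obs)
  out <- matrix(NA_real_, nrow = length(t_obs), ncol = length(nm),
                dimnames = list(NULL, nm))
  derived <- intersect(nm, OBS_DERIVED)
  if (length(derived) > 0L) {
    tb <- total_biomass(traj, compositions, chl_fraction)
    for (o in derived) out[, o] <- tb[[o]][idx]
  }
  for (o in setdiff(nm, derived)) {
    if (!(o %in% colnames(traj$state))) {
      stop("observable '", o, "' maps to no model species or derived ",
           "quantity", call. = FALSE)
    }
    out[, o] <- traj$state[idx, o]
  }
  out
}

#' Squared-error objective between simulation and observations
#'
#' Simulates the model with the given rate constants and accumulates
#' `w_o (sim_o(t_k) - obs_o(t_k))^2` over every observable and sampling
#' time. A failed simulation (solver breakdown, negative blow-up) scores
#' `+Inf` so the optimizer steps away from it.
#'
#' @param params rate-constant vector in [param_vector()] order
#'   (nonnegative).
#' @param model,laws,env the reduced model, its kinetic laws, and the
#'   chemostat environment.
#' @param obs data frame with a `time` column (hours) and one column per
#'   observable; observables are model species ids or the derived
#'   quantities `X_C`, `X_N`, `chlorophyll`.
#' @param init initial state for the fitting simulations.
#' @param weights per-observable positive weights; default
#'   `1 / max(obs_o)^2`.
#' @param compositions,chl_fraction needed when derived observables are
#'   fitted.
#' @param rtol,atol solver tolerances used during fitting (defaults looser
#'   than simulation defaults, `1e-6`/`1e-9`).
#' @return scalar objective (sum of weighted squared residuals).
#' @export
fit_objective <- function(params, model, laws, env, obs, init,
                          weights = NULL, compositions = NULL,
                          chl_fraction = 0.05, rtol = 1e-6, atol = 1e-9) {
  if (any(params < 0)) return(Inf)
  if (is.null(weights)) weights <- default_weights(obs)
  sim <- tryCatch(
    simulate_observables(params, model, laws, env, obs, init,
                         compositions, chl_fraction, rtol, atol),
    error = function(e) {
      if (grepl("observable", conditionMessage(e))) stop(e)
      NULL
    })
  if (is.null(sim)) return(Inf)
  total <- 0
  for (o in obs_names(obs)) {
    r <- sim[, o] - obs[[o]]
    total <- total + weights[[o]] * sum(r^2, na.rm = TRUE)
  }
  if (!is.finite(total)) return(Inf)
  total
}

#' Fit kinetic rate constants by multistart Nelder-Mead
#'
#' Draws `n_starts` parameter vectors log-uniformly within `bounds`,
#' polishes each with Nelder-Mead in log-parameter space (positivity by
#' construction), and returns the best. The best point receives a few
#' Nelder-Mead restarts to tighten convergence. Fully reproducible given
#' `seed`. Directions along which the objective is flat at the optimum
#' (relative curvature below `flat_tol`) are reported in `flat_directions`
#' rather than hidden.
#'
#' @inheritParams fit_objective
#' @param n_starts number of random starts (>= 1).
#' @param seed integer seed for the start draws.
#' @param bounds list with `lower` and `upper` positive vectors (length 1
#'   or one per parameter).
#' @param maxit Nelder-Mead iteration cap per start (default 2000).
#' @param reltol Nelder-Mead relative convergence tolerance (default 1e-8).
#' @param polish_restarts extra restarts applied to the best start.
#' @param flat_tol relative objective change under a 1% parameter
#'   perturbation below which a parameter is reported as non-identifiable.
#' @return object of class `drum_fit`: list with `best_params` (named),
#'   `objective`, `starts` (per-start data frame), `seed`,
#'   `flat_directions`.
#' @export
fit_kinetics <- function(model, laws, env, obs, n_starts = 20, seed = 1,
                         bounds, init, weights = NULL, compositions = NULL,
                         chl_fraction = 0.05, maxit = 2000, reltol = 1e-8,
                         rtol = 1e-6, atol = 1e-9, polish_restarts = 25,
                         flat_tol = 1e-10) {
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  p0 <- param_vector(laws)
  np <- length(p0)
  if (np == 0L) stop("no free parameters to fit", call. = FALSE)
  lower <- rep_len(bounds$lower, np)
  upper <- rep_len(bounds$upper, np)
  if (any(lower <= 0) || any(upper < lower)) {
    stop("bounds must satisfy 0 < lower <= upper", call. = FALSE)
  }
  if (is.null(weights)) weights <- default_weights(obs)
  # Nelder-Mead needs finite vertex values; a failed simulation scores a
  # large finite penalty instead of +Inf so the simplex can retreat from it
  obj_log <- function(lp) {
    v <- fit_objective(exp(lp), model, laws, env, obs, init, weights,
                       compositions, chl_fraction, rtol, atol)
    if (!is.finite(v)) 1e10 else v
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  # Nelder-Mead is used uniformly, including one-parameter problems; mute
  # optim's advisory about the 1-D case
  nm <- function(par, ...) {
    withCallingHandlers(
      stats::optim(par, ...),
      warning = function(w) {
        if (grepl("one-dimensional optimization", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  starts_lp <- matrix(stats::runif(n_starts * np, log(lower), log(upper)),
                      nrow = n_starts, byrow = TRUE)
  start_rows <- vector("list", n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    lp0 <- starts_lp[s, ]
    if (maxit > 0) {
      res <- nm(lp0, obj_log, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
    } else {
      res <- list(par = lp0, value = obj_log(lp0), convergence = 1L)
    }
    start_rows[[s]] <- data.frame(
      start = s, initial_objective = obj_log(lp0), objective = res$value,
      converged = res$convergence == 0L)
    if (is.null(best) || res$value < best$value) best <- res
  }
  for (k in seq_len(polish_restarts)) {
    if (maxit <= 0) break
    res <- nm(best$par, obj_log, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (res$value >= best$value * (1 - 1e-12)) {
      best <- if (res$value < best$value) res else best
      break
    }
    best <- res
  }
  best_params <- exp(best$par)
  names(best_params) <- names(p0)
  flat <- character(0)
  if (is.finite(best$value)) {
    base <- best$value
    for (i in seq_len(np)) {
      lp <- best$par
      lp[i] <- lp[i] + log(1.01)
      dv <- abs(obj_log(lp) - base)
      if (dv <= flat_tol * max(1, base)) flat <- c(flat, names(p0)[i])
    }
  }
  structure(list(best_params = best_params, objective = best$value,
                 starts = do.call(rbind, start_rows), seed = seed,
                 flat_directions = flat),
            class = "drum_fit")
}

#' @export
print.drum_fit <- function(x, ...) {
  cat("<drum_fit> objective ", format(x$objective, digits = 6), " over ",
      nrow(x$starts), " starts (seed ", x$seed, ")\n", sep = "")
  print(signif(x$best_params, 4))
  if (length(x$flat_directions) > 0L) {
    cat("  flat (non-identifiable) directions:",
        paste(x$flat_directions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a fit report as JSON
#' @param fit a `drum_fit`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
write_fit_json <- function(fit, path = NULL) {
  obj <- list(best_params = as.list(fit$best_params),
              objective = fit$objective,
              starts = fit$starts, seed = fit$seed,
              flat_directions = fit$flat_directions)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
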