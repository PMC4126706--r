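# Chemostat simulation of the reduced model under light forcing.
#
#   dM'/dt = K' alpha(M', I(t)) B  -  D M'  +  D M_in
#
# Functional biomass B multiplies the kinetics (it catalyzes every
# macroscopic reaction); clamped species rows are held constant (dissolved
# gases and minerals treated as non-limiting). Units: concentrations mM,
# time h, D in 1/h, irradiance in uE m-2 s-1.

#' Describe the light forcing
#'
#' @param form `"truncated-sine"` (default), `"square"` or `"tabulated"`.
#' @param period photoperiod in hours (default 24).
#' @param day_length lit hours per period (default 12).
#' @param I_max peak irradiance, uE m-2 s-1 (default 100).
#' @param phase clock time of sunrise in hours (default 12, so midday falls
#'   at t = 18 h within each cycle).
#' @param table for `"tabulated"`: data frame with columns `time` (hours,
#'   within one period) and `I`.
#' @return object of class `drum_light`.
#' @export
light_signal <- function(form = c("truncated-sine", "square", "tabulated"),
                         period = 24, day_length = 12, I_max = 100,
                         phase = 12, table = NULL) {
  form <- match.arg(form)
  if (day_length < 0 || day_length > period) {
    stop("day_length must lie in [0, period]", call. = FALSE)
  }
  if (form == "tabulated" && is.null(table)) {
    stop("tabulated light needs a table", call. = FALSE)
  }
  structure(list(form = form, period = period, day_length = day_length,
                 I_max = I_max, phase = phase, table = table),
            class = "drum_light")
}

#' Irradiance at time t
#'
#' Periodic and nonnegative. The truncated sine is
#' `I_max * sin(pi (t - phase) / day_length)` inside the lit window and 0
#' outside; the square wave is `I_max` inside the window.
#'
#' @param signal a [light_signal()].
#' @param t time in hours (vectorized).
#' @return irradiance value(s).
#' @export
light_intensity <- function(signal, t) {
  tt <- (t - signal$phase) %% signal$period
  lit <- tt < signal$day_length
  out <- numeric(length(t))
  if (signal$form == "square") {
    out[lit] <- signal$I_max
  } else if (signal$form == "truncated-sine") {
    out[lit] <- signal$I_max * sin(pi * tt[lit] / signal$day_length)
  } else {
    tab <- signal$table
    out <- stats::approx(tab$time, tab$I, xout = t %% signal$period,
                         rule = 2)$y
  }
  pmax(out, 0)
}

#' Chemostat environment
#'
#' @param D dilution rate in 1/h (a chemostat run at 1/day has
#'   `D = 1/24`).
#' @param inflow named concentrations of the feed (mM); species not listed
#'   enter at 0.
#' @param light a [light_signal()].
#' @return object of class `drum_env`.
#' @export
chemostat_env <- function(D, inflow = numeric(), light = light_signal()) {
  if (D < 0) stop("dilution rate must be nonnegative", call. = FALSE)
  if (any(inflow < 0)) stop("inflow concentrations must be nonnegative",
                            call. = FALSE)
  structure(list(D = D, inflow = inflow, light = light), class = "drum_env")
}

inflow_vector <- function(model, env) {
  m_in <- stats::setNames(numeric(length(model$species)), model$species)
  common <- intersect(names(env$inflow), model$species)
  m_in[common] <- env$inflow[common]
  m_in
}

#' ODE right-hand side of the reduced model (reference implementation)
#'
#' `K' alpha B - D M' + D M_in`, with clamped rows forced to zero. The
#' compiled right-hand side used by [simulate_model()] is checked against
#' this function in the test suite.
#'
#' @param t time (hours).
#' @param state named state vector aligned to `model$species`.
#' @param model a `drum_model`.
#' @param laws list of [kinetic_law()] aligned to the model's reactions.
#' @param env a [chemostat_env()].
#' @return named derivative vector.
#' @export
ode_rhs <- function(t, state, model, laws, env) {
  if (length(state) != length(model$species)) {
    stop("state has ", length(state), " entries, model has ",
         length(model$species), " species", call. = FALSE)
  }
  names(state) <- model$species
  I <- light_intensity(env$light, t)
  alpha <- rate_vector(state, I, laws)
  B <- state[[model$biomass]]
  m_in <- inflow_vector(model, env)
  d <- drop(model$K %*% alpha) * B - env$D * state + env$D * m_in
  d[model$clamped] <- 0
  names(d) <- model$species
  d
}

# Pack model + laws + environment into the flat double vector consumed by
# the compiled right-hand side (see src/drum_rhs.c for the layout).
pack_rhs_parms <- function(model, laws, env) {
  ns <- length(model$species)
  nr <- length(model$macro_reactions)
  if (length(laws) != nr) {
    stop("need one kinetic law per macroscopic reaction", call. = FALSE)
  }
  if (!identical(law_ids(laws), colnames(model$K))) {
    stop("law order must match the model's macroscopic reactions", call. = FALSE)
  }
  form_code <- c("zero" = 0, "light-proportional" = 1, "mass-action-1" = 2,
                 "reversible-mass-action" = 3, "product-2" = 4,
                 "product-3" = 5)
  light_code <- c("square" = 0, "truncated-sine" = 1)
  if (!(env$light$form %in% names(light_code))) return(NULL)  # R fallback
  law_block <- unlist(lapply(laws, function(l) {
    e <- match(l$effectors, model$species) - 1
    if (any(is.na(e))) {
      stop("effector of law '", l$reaction, "' not in model species",
           call. = FALSE)
    }
    e <- c(e, rep(-1, 3 - length(e)))
    p <- c(l$params, rep(0, 2 - length(l$params)))
    c(form_code[[l$form]], e, p)
  }))
  c(ns, nr, env$D, match(model$biomass, model$species) - 1,
    light_code[[env$light$form]], env$light$period, env$light$day_length,
    env$light$I_max, env$light$phase,
    as.vector(model$K),
    inflow_vector(model, env),
    as.numeric(model$species %in% model$clamped),
    law_block)
}

#' Integrate the reduced kinetic model
#'
#' Integrates the chemostat ODE with a stiff solver (`deSolve::lsoda`) and
#' records the macroscopic rates alongside the state. Small negative
#' excursions (above `-1e-6` mM) from the solver are clipped to zero;
#' anything below that aborts with the time of failure. A compiled
#' right-hand side is used when available (square or truncated-sine light);
#' set `use_compiled = FALSE` to force the pure-R reference implementation.
#'
#' @param model a `drum_model`.
#' @param laws list of [kinetic_law()], one per macroscopic reaction, in
#'   model order.
#' @param env a [chemostat_env()].
#' @param times output time grid (hours, strictly increasing, `>= 0`).
#' @param init named nonnegative initial state (missing species start at 0).
#' @param rtol,atol solver tolerances (defaults `1e-8`, `1e-10`).
#' @param use_compiled use the compiled right-hand side when possible.
#' @param ... passed to [deSolve::ode()].
#' @return object of class `drum_trajectory`: list with `times`, `state`
#'   (times x species), `alpha` (times x reactions), `env`, `model`.
#' @export
simulate_model <- function(model, laws, env, times, init,
                           rtol = 1e-8, atol = 1e-10,
                           use_compiled = TRUE, ...) {
  y0 <- stats::setNames(numeric(length(model$species)), model$species)
  common <- intersect(names(init), model$species)
  y0[common] <- init[common]
  if (any(y0 < 0)) stop("initial state must be nonnegative", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  parms <- if (use_compiled) pack_rhs_parms(model, laws, env) else NULL
  if (!is.null(parms)) {
    .Call("drum_set_rhs_data", as.numeric(parms), PACKAGE = "drumr")
    sol <- deSolve::ode(y = unname(y0), times = times, func = "drum_derivs",
                        parms = NULL, dllname = "drumr",
                        initfunc = "drum_initmod", nout = 0,
                        rtol = rtol, atol = atol, ...)
  } else {
    rhs <- function(t, y, p) {
      list(unname(ode_rhs(t, y, model, laws, env)))
    }
    sol <- deSolve::ode(y = unname(y0), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol, ...)
  }
  if (attr(sol, "istate")[1L] < 0) {
    stop("ODE solver failed near t = ", max(sol[, 1L]), " h", call. = FALSE)
  }
  state <- sol[, -1L, drop = FALSE]
  colnames(state) <- model$species
  low <- min(state)
  if (low < -1e-6) {
    bad <- which(state < -1e-6, arr.ind = TRUE)[1L, ]
    stop("state went negative (", signif(low, 3), ") at t = ",
         sol[bad[1L], 1L], " h", call. = FALSE)
  }
  state[state < 0] <- 0
  alpha <- matrix(0, nrow = length(times), ncol = length(laws))
  for (i in seq_along(times)) {
    alpha[i, ] <- rate_vector(stats::setNames(state[i, ], model$species),
                              light_intensity(env$light, times[i]), laws)
  }
  colnames(alpha) <- law_ids(laws)
  structure(list(times = times, state = state, alpha = alpha,
                 env = env, model = model),
            class = "drum_trajectory")
}

#' @export
print.drum_trajectory <- function(x, ...) {
  cat("<drum_trajectory> ", length(x$times), " time points, t in [",
      min(x$times), ", ", max(x$times), "] h, ", ncol(x$state),
      " species\n", sep = "")
  invisible(x)
}

#' Reconstruct original-network fluxes from macroscopic rates
#'
#' Maps each macroscopic rate back through the elementary mode it came
#' from: `v(t) = sum_SN E_SN alpha_SN(t)`. A reaction duplicated across
#' sub-networks receives the sum of both contributions; a negative
#' (reverse) macroscopic rate routes flux along the mode's reverse
#' direction. Without EFM provenance (model built directly from a
#' macroscopic table) the macroscopic rates themselves are returned,
#' flagged `macro_only`.
#'
#' @param traj a `drum_trajectory`.
#' @param efms named list: sub-network name -> `drum_efms` used in the
#'   reduction, or `NULL` when no provenance exists.
#' @return matrix (times x reactions) with attribute `macro_only`.
#' @export
reconstruct_fluxes <- function(traj, efms = NULL) {
  model <- traj$model
  sources <- lapply(model$macro_reactions, `[[`, "source")
  if (is.null(efms) || any(vapply(sources, is.null, NA))) {
    out <- traj$alpha
    attr(out, "macro_only") <- TRUE
    return(out)
  }
  rxn_ids <- unique(unlist(lapply(efms, `[[`, "reaction_ids")))
  v <- matrix(0, nrow = length(traj$times), ncol = length(rxn_ids),
              dimnames = list(NULL, rxn_ids))
  for (j in seq_along(model$macro_reactions)) {
    src <- sources[[j]]
    if (!is.null(src$subnetwork)) src <- list(src) else src <- unname(src)
    for (s in src) {
      E <- efms[[s$subnetwork]]
      v[, E$reaction_ids] <- v[, E$reaction_ids] +
        outer(traj$alpha[, j], E$modes[, s$mode])
    }
  }
  attr(v, "macro_only") <- FALSE
  v
}

#' Elemental totals and chlorophyll along a trajectory
#'
#' Total particulate carbon and nitrogen are element balances over the
#' accumulating pools and functional biomass,
#' `X_C = sum_A C_A A(t) + C_B B(t)` (untracked energy cofactors excluded);
#' chlorophyll is reported as a fixed fraction of functional biomass.
#'
#' @param traj a `drum_trajectory`.
#' @param compositions composition matrix covering all accumulating species
#'   and the biomass species for C and N.
#' @param chl_fraction chlorophyll as a fraction of functional biomass
#'   (mol/mol; default 0.05).
#' @return data frame `time`, `X_C`, `X_N`, `chlorophyll`.
#' @export
total_biomass <- function(traj, compositions, chl_fraction = 0.05) {
  comp <- as_composition_matrix(compositions)
  model <- traj$model
  pools <- c(model$accumulating, model$biomass)
  for (sp in pools) {
    if (is.na(comp_count(comp, sp, "C")) || is.na(comp_count(comp, sp, "N"))) {
      stop("composition of '", sp, "' unknown", call. = FALSE)
    }
  }
  Cw <- comp[pools, "C"]
  Nw <- comp[pools, "N"]
  X_C <- drop(traj$state[, pools, drop = FALSE] %*% Cw)
  X_N <- drop(traj$state[, pools, drop = FALSE] %*% Nw)
  data.frame(time = traj$times, X_C = X_C, X_N = X_N,
             chlorophyll = chl_fraction * traj$state[, model$biomass])
}

#' Carbon allocation shares and photosynthetic quotient at a time point
#'
#' The share of each sink is its gross carbon inflow — atoms per mole times
#' the positive part of each producing reaction's rate — normalized so the
#' shares sum to one. The photosynthetic quotient is net O2 production over
#' net CO2 fixation read off the corresponding rows of K'.
#'
#' @param traj a `drum_trajectory`.
#' @param compositions composition matrix (carbon counts for the sinks).
#' @param t time at which to evaluate (nearest grid point is used).
#' @param sinks species receiving carbon (default: the accumulating storage
#'   pools CARB and PA plus functional biomass, when present).
#' @param o2,co2 row ids used for the photosynthetic quotient.
#' @return list with `t`, `shares` (named, sums to 1, `NA` if no sink
#'   inflow), `pq` (photosynthetic quotient, `NA` when no net CO2 is fixed).
#' @export
carbon_diagnostics <- function(traj, compositions, t, sinks = NULL,
                               o2 = "O2", co2 = "CO2") {
  comp <- as_composition_matrix(compositions)
  model <- traj$model
  if (is.null(sinks)) {
    sinks <- intersect(c("CARB", "PA", model$biomass), model$species)
  }
  i <- which.min(abs(traj$times - t))
  alpha <- traj$alpha[i, ]
  inflow <- vapply(sinks, function(sp) {
    contrib <- model$K[sp, ] * alpha
    comp_count(comp, sp, "C") * sum(pmax(contrib, 0))
  }, numeric(1L))
  total <- sum(inflow)
  shares <- if (total > 0) inflow / total else rep(NA_real_, length(inflow))
  names(shares) <- sinks
  pq <- NA_real_
  if (all(c(o2, co2) %in% model$species)) {
    o2_net <- sum(model$K[o2, ] * alpha)
    co2_net <- -sum(model$K[co2, ] * alpha)
    if (co2_net > 0) pq <- o2_net / co2_net
  }
  list(t = traj$times[i], shares = shares, pq = pq)
}

#' Export a trajectory (with derived totals) as CSV
#'
#' @param traj a `drum_trajectory`.
#' @param path output file.
#' @param compositions optional composition matrix; when given, `X_C`,
#'   `X_N` and `chlorophyll` columns are appended.
#' @param chl_fraction see [total_biomass()].
#' @export
write_trajectory <- function(traj, path, compositions = NULL,
                             chl_fraction = 0.05) {
  df <- data.frame(time = traj$times, traj$state,
                   stats::setNames(as.data.frame(traj$alpha),
                                   paste0("alpha_", colnames(traj$alpha))))
  if (!is.null(compositions)) {
    df <- cbind(df, total_biomass(traj, compositions, chl_fraction)[, -1L])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
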