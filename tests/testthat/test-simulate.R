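test_that("light signals are periodic, nonnegative and peak as specified", {
  sq <- light_signal("square", period = 24, day_length = 12, I_max = 100,
                     phase = 0)
  expect_equal(light_intensity(sq, 6), 100)
  expect_equal(light_intensity(sq, 18), 0)
  expect_equal(light_intensity(sq, 6 + 48), 100)

  ts <- light_signal("truncated-sine", period = 24, day_length = 12,
                     I_max = 250, phase = 12)
  expect_equal(light_intensity(ts, 12 + 6), 250)     # mid-window peak
  expect_equal(light_intensity(ts, 3), 0)            # dark window
  expect_true(all(light_intensity(ts, seq(0, 96, 0.5)) >= 0))

  tab <- light_signal("tabulated", period = 24,
                      table = data.frame(time = c(0, 6, 12, 18, 24),
                                         I = c(0, 50, 0, 0, 0)))
  expect_equal(light_intensity(tab, 6 + 24), 50)
  expect_error(light_signal("square", day_length = 30), "day_length")
})

test_that("rate vector evaluates each kinetic form", {
  laws <- tiso$laws
  state <- stats::setNames(numeric(15), tiso$model$species)
  a0 <- rate_vector(state, 100, laws)
  expect_equal(unname(a0["MR1"]), 11.07e-3 * 100)   # 1.107
  expect_equal(unname(a0["MR2"]), 0)
  expect_true(all(a0[c("MR3", "MR4", "MR5", "MR6", "MR7", "MR8")] == 0))

  state["CARB"] <- 1
  a1 <- rate_vector(state, 0, laws)
  expect_lt(a1[["MR6"]], 0)   # net carbohydrate remobilization

  state["GAP"] <- -1
  expect_error(rate_vector(state, 0, laws), "negative")
})

test_that("the ODE right-hand side has the chemostat structure", {
  env <- chemostat_env(D = 0.05, inflow = c(NO3 = 0.5),
                       light = tiso$env$light)
  state <- stats::setNames(runif(15, 0, 0.2), tiso$model$species)
  state["B"] <- 0
  d <- ode_rhs(6, state, tiso$model, tiso$laws, env)
  m_in <- stats::setNames(numeric(15), tiso$model$species)
  m_in["NO3"] <- 0.5
  free <- setdiff(tiso$model$species, tiso$model$clamped)
  expect_equal(d[free], (-env$D * state + env$D * m_in)[free])  # pure washout
  expect_true(all(d[tiso$model$clamped] == 0))

  env0 <- chemostat_env(D = 0, inflow = numeric(), light = tiso$env$light)
  zero_state <- stats::setNames(numeric(15), tiso$model$species)
  expect_true(all(ode_rhs(3, zero_state, tiso$model, tiso$laws, env0) == 0))

  # single active column: MR6 only
  laws6 <- knockout(knockout(knockout(tiso$laws, "MR1"), "MR5"), "MR7")
  laws6 <- knockout(knockout(knockout(laws6, "MR3"), "MR4"), "MR8")
  st <- zero_state
  st[c("G6P", "CARB", "B")] <- c(0.4, 0.1, 2)
  d6 <- ode_rhs(0, st, tiso$model, laws6, chemostat_env(0.01, light = tiso$env$light))
  a6 <- 70 * 0.4 - 6.5 * 0.1
  expect_equal(unname(d6["CARB"]), a6 * 2 - 0.01 * 0.1)
  expect_equal(unname(d6["G6P"]), -a6 * 2 - 0.01 * 0.4)

  expect_error(ode_rhs(0, numeric(3), tiso$model, tiso$laws, env0),
               "state has")
})

test_that("compiled and reference right-hand sides integrate identically", {
  times <- seq(0, 72, by = 1)
  trC <- simulate_model(tiso$model, tiso$laws, tiso$env, times, tiso$init)
  trR <- simulate_model(tiso$model, tiso$laws, tiso$env, times, tiso$init,
                        use_compiled = FALSE)
  expect_lt(max(abs(trC$state - trR$state)), 1e-6)
})

test_that("with no biomass the chemostat washes out along the closed form", {
  set.seed(31)
  for (D in stats::runif(3, 0.001, 2 / 24)) {
    env <- chemostat_env(D = D, inflow = c(NO3 = 0.5, GAP = 0.1),
                         light = tiso$env$light)
    init <- c(GAP = 0.3, G6P = 0.2, PEP = 0.1, CARB = 0.4, PA = 0.2,
              B = 0, NO3 = 0.1)
    tr <- simulate_model(tiso$model, tiso$laws, env, seq(0, 48, 2), init)
    m_in <- stats::setNames(numeric(15), tiso$model$species)
    m_in[c("NO3", "GAP")] <- c(0.5, 0.1)
    free <- setdiff(tiso$model$species, tiso$model$clamped)
    y0 <- tr$state[1, ]
    for (k in seq_along(tr$times)) {
      exact <- m_in[free] + (y0[free] - m_in[free]) * exp(-D * tr$times[k])
      expect_lt(max(abs(tr$state[k, free] - exact) / pmax(abs(exact), 1e-9)),
                1e-6)
    }
  }
})

test_that("a dark closed system with empty pools stays constant", {
  dark <- chemostat_env(D = 0, light = light_signal("square", I_max = 0))
  init <- c(B = 0.2, NO3 = 0.3)
  tr <- simulate_model(tiso$model, tiso$laws, dark, seq(0, 24, 4), init)
  expect_equal(max(abs(sweep(tr$state, 2, tr$state[1, ]))), 0)
  expect_true(all(abs(tr$alpha) < 1e-12))
})

test_that("simulation enforces nonnegativity and rejects bad inputs", {
  expect_error(simulate_model(tiso$model, tiso$laws, tiso$env,
                              c(0, 1, 0.5), tiso$init), "increasing")
  expect_error(simulate_model(tiso$model, tiso$laws, tiso$env,
                              0:3, c(B = -1)), "nonnegative")
  tr <- simulate_model(tiso$model, tiso$laws, tiso$env, seq(0, 240, 2),
                       tiso$init)
  expect_gte(min(tr$state), 0)
})

test_that("the forced system converges toward a periodic regime", {
  times <- seq(0, 480, by = 0.5)
  tr <- simulate_model(tiso$model, tiso$laws, tiso$env, times, tiso$init)
  at_sunrise <- seq(12, 468, by = 24)
  states <- tr$state[match(at_sunrise, times), c("CARB", "PA", "B")]
  deltas <- sqrt(rowSums(diff(states)^2))
  late <- deltas[(length(deltas) - 4):length(deltas)]
  early <- deltas[1:5]
  expect_lt(mean(late), mean(early) / 100)
  expect_lt(late[length(late)], 1e-5)
})

test_that("flux reconstruction routes macroscopic rates through their modes", {
  net <- parse_reaction_table("r1: Aext -> X\nr2: X -> Bext")
  sub <- extract_subnetwork(net, subnetwork_spec("sn", c("r1", "r2"), "X"))
  mrs <- reduce_subnetwork(sub)
  model <- suppressWarnings(assemble_reduced_model(
    mrs, accumulating = "Bext", biomass = "Bext", substrates = "Aext"))
  efms <- list(sn = enumerate_efms(sub, internal = "X"))
  fake <- structure(list(times = c(0, 1), model = model,
                         alpha = matrix(c(2, 0), ncol = 1,
                                        dimnames = list(NULL, "sn.1"))),
                    class = "drum_trajectory")
  v <- reconstruct_fluxes(fake, efms)
  expect_false(attr(v, "macro_only"))
  expect_equal(unname(v[1, c("r1", "r2")]), c(2, 2))   # v = 2 e
  expect_equal(unname(v[2, ]), c(0, 0))

  # without provenance the macroscopic rates are returned, flagged
  fake2 <- structure(list(times = 0, model = tiso$model,
                          alpha = matrix(0, 1, 8)), class = "drum_trajectory")
  v2 <- reconstruct_fluxes(fake2)
  expect_true(attr(v2, "macro_only"))
})

test_that("duplicated reactions accumulate flux from every sub-network", {
  net <- parse_reaction_table(paste(
    "r1: Aext -> X", "r2: X -> Bext", "r3: X -> Cext", sep = "\n"))
  subA <- extract_subnetwork(net, subnetwork_spec("snA", c("r1", "r2"), "X"))
  subB <- extract_subnetwork(net, subnetwork_spec("snB", c("r1", "r3"), "X"))
  mrs <- c(reduce_subnetwork(subA), reduce_subnetwork(subB))
  model <- suppressWarnings(assemble_reduced_model(
    mrs, accumulating = c("Bext", "Cext"), biomass = "Bext",
    substrates = "Aext"))
  efms <- list(snA = enumerate_efms(subA, internal = "X"),
               snB = enumerate_efms(subB, internal = "X"))
  fake <- structure(list(times = 0, model = model,
                         alpha = matrix(c(1, 3), 1, 2,
                                        dimnames = list(NULL, c("snA.1", "snB.1")))),
                    class = "drum_trajectory")
  v <- reconstruct_fluxes(fake, efms)
  expect_equal(unname(v[1, "r1"]), 4)   # shared uptake: 1 + 3
  expect_equal(unname(v[1, "r2"]), 1)
  expect_equal(unname(v[1, "r3"]), 3)
})

test_that("elemental totals and chlorophyll follow the composition sums", {
  fake <- structure(list(
    times = c(0, 1),
    state = matrix(c(0, 0, 0, 0, 2, 0, 0, 0, 0, 2, 0, 1),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, c("GAP", "G6P", "PEP", "CARB",
                                           "PA", "B"))),
    model = list(accumulating = c("GAP", "G6P", "PEP", "CARB", "PA"),
                 biomass = "B", species = c("GAP", "G6P", "PEP", "CARB",
                                            "PA", "B"))),
    class = "drum_trajectory")
  tb <- total_biomass(fake, tiso$compositions, chl_fraction = 0.05)
  expect_equal(tb$X_C, c(2 * 36.22, 2 * 6 + 1 * 8.5442))  # hand sums
  expect_equal(tb$X_N[2], 1 * 1.31)
  expect_equal(tb$chlorophyll, c(0, 0.05))
  comp2 <- tiso$compositions
  comp2["PA", "C"] <- NA
  expect_error(total_biomass(fake, comp2), "unknown")
})

test_that("carbon allocation shares and the photosynthetic quotient", {
  mk_traj <- function(alpha) {
    structure(list(times = 0, state = matrix(0, 1, 15,
                                             dimnames = list(NULL, tiso$model$species)),
                   alpha = matrix(alpha, 1, 8,
                                  dimnames = list(NULL, colnames(tiso$model$K))),
                   model = tiso$model), class = "drum_trajectory")
  }
  only8 <- carbon_diagnostics(mk_traj(c(0, 0, 0, 0, 0, 0, 0, 1)),
                              tiso$compositions, 0)
  expect_equal(unname(only8$shares["B"]), 1)
  expect_equal(unname(only8$shares[c("CARB", "PA")]), c(0, 0))

  only6 <- carbon_diagnostics(mk_traj(c(0, 0, 0, 0, 0, 1, 0, 0)),
                              tiso$compositions, 0)
  expect_equal(unname(only6$shares["CARB"]), 1)

  only1 <- carbon_diagnostics(mk_traj(c(1, 0, 0, 0, 0, 0, 0, 0)),
                              tiso$compositions, 0)
  expect_equal(only1$pq, 1)   # 3 O2 out per 3 CO2 in
  expect_true(all(is.na(carbon_diagnostics(mk_traj(numeric(8)),
                                           tiso$compositions, 0)$shares)))
})

test_that("a closed system conserves carbon to rounding precision", {
  m2 <- tiso_open_co2()
  env0 <- chemostat_env(D = 0, light = tiso$env$light)
  init <- c(tiso$init, CO2 = 300)
  tr <- simulate_model(m2, tiso$laws, env0, seq(0, 48, 1), init)
  tb <- total_biomass(tr, tiso$compositions, tiso$chl_fraction)
  total <- tb$X_C + tr$state[, "CO2"]
  drift <- (max(total) - min(total)) / total[1]
  expect_lt(drift, 0.005)
})

test_that("trajectory CSV export includes states, rates and derived totals", {
  tr <- simulate_model(tiso$model, tiso$laws, tiso$env, seq(0, 12, 4),
                       tiso$init)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f, compositions = tiso$compositions)
  df <- utils::read.csv(f)
  expect_true(all(c("time", "CARB", "alpha_MR1", "X_C", "chlorophyll")
                  %in% names(df)))
  expect_equal(nrow(df), 4L)
})
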