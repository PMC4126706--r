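# The packaged worked example: the day/night carbon-storage model of the
# microalga Tisochrysis lutea (eight macroscopic reactions MR1-MR8 over 15
# metabolite rows), its calibrated kinetic constants, default chemostat
# environment, a synthetic observation generator standing in for the
# day/night culture measurements, and small hand-verified toy networks for
# exercising the EFM engine.

TISO_COFACTORS <- c("ATP", "ADP", "NADH", "NAD", "NADPH", "NADP")
TISO_ACCUMULATING <- c("GAP", "G6P", "PEP", "CARB", "PA")
TISO_CLAMPED <- c("Light", "CO2", "H2O", "H", "Pi", "O2", "SO4", "Mg")

tiso_file <- function(name) {
  system.file("extdata", name, package = "drumr", mustWork = TRUE)
}

tiso_laws <- function() {
  list(
    kinetic_law("MR1", "light-proportional", params = 11.07e-3,
                units = "uE-1.m2.s.mM.h-1.mMB-1"),
    kinetic_law("MR2", "zero"),
    kinetic_law("MR3", "mass-action-1", "GAP", 223.53, "h-1.mMB-1"),
    kinetic_law("MR4", "mass-action-1", "G6P", 10.30, "h-1.mMB-1"),
    kinetic_law("MR5", "reversible-mass-action", c("GAP", "PEP"),
                c(436.95, 5.00), rep("h-1.mMB-1", 2)),
    kinetic_law("MR6", "reversible-mass-action", c("G6P", "CARB"),
                c(70.00, 6.50), rep("h-1.mMB-1", 2)),
    kinetic_law("MR7", "product-2", c("PEP", "GAP", "PA"),
                c(4.50e3, 0.60), c("mM-1.h-1.mMB-1", "h-1.mMB-1")),
    kinetic_law("MR8", "product-3", c("PEP", "G6P", "NO3"),
                2.18e4, "mM-2.h-1.mMB-1")
  )
}

#' Build the packaged Tisochrysis lutea day/night model
#'
#' Assembles the eight macroscopic reactions of the reduced carbon-storage
#' model (photosynthesis MR1, a futile ATP cycle MR2, upper-glycolysis
#' G6P formation/consumption MR3/MR4, lower glycolysis MR5, carbohydrate
#' storage MR6, lipid storage MR7, biomass synthesis MR8), their
#' proportional kinetics with the calibrated rate constants, the carbon and
#' nitrogen compositions (the lumped lipid PA and functional biomass B
#' completed by carbon/nitrogen closure of MR7 and MR8), and the default
#' chemostat environment: dilution 1/day, feed of 4.018 mg N per litre as
#' nitrate (0.287 mM at 14.007 g N/mol), and a 12 h:12 h truncated-sine
#' light cycle peaking at 500 uE m-2 s-1 with sunrise at t = 12 h.
#'
#' @return object of class `drum_tisochrysis`: list with `network` (the
#'   macroscopic reaction table as a network), `model` (`drum_model`, 15
#'   species x 8 reactions), `laws`, `params` (named vector of the 10 rate
#'   constants), `env`, `compositions` (C and N matrix including the
#'   closure-derived PA and B counts), `init` (default initial state:
#'   0.01 mM per accumulating pool, 0.1 mM functional biomass, nitrate at
#'   the feed concentration), and `chl_fraction` (0.05).
#' @examples
#' tiso <- build_tisochrysis_model()
#' count_reduced_efms(tiso$model)
#' @export
build_tisochrysis_model <- function() {
  net <- parse_reaction_table(readLines(tiso_file("tisochrysis_reactions.txt")))
  comp <- read_compositions(tiso_file("tisochrysis_compositions.csv"))
  cN <- infer_composition_by_closure(
    net, "C",
    known = stats::setNames(comp[, "C"], rownames(comp))[!is.na(comp[, "C"])],
    unknowns = c("PA", "B"), ignore = TISO_COFACTORS)
  nN <- infer_composition_by_closure(
    net, "N",
    known = stats::setNames(comp[, "N"], rownames(comp))[!is.na(comp[, "N"])],
    unknowns = c("PA", "B"), ignore = TISO_COFACTORS)
  species <- union(rownames(comp), c("PA", "B"))
  compositions <- cbind(C = cN[species], N = nN[species])
  rownames(compositions) <- species

  model <- assemble_reduced_model(
    as_macro_reactions(net),
    accumulating = TISO_ACCUMULATING,
    biomass = "B",
    drop = TISO_COFACTORS,
    clamp = TISO_CLAMPED,
    substrates = "NO3")

  laws <- tiso_laws()
  s_in <- 4.018 / 14.007   # mg N/L as nitrate -> mM (atomic N, 14.007 g/mol)
  env <- chemostat_env(D = 1 / 24, inflow = c(NO3 = s_in),
                       light = light_signal("truncated-sine", period = 24,
                                            day_length = 12, I_max = 500,
                                            phase = 12))
  init <- c(GAP = 0.01, G6P = 0.01, PEP = 0.01, CARB = 0.01, PA = 0.01,
            B = 0.1, NO3 = s_in)
  structure(list(network = net, model = model, laws = laws,
                 params = param_vector(laws), env = env,
                 compositions = compositions, init = init,
                 chl_fraction = 0.05),
            class = "drum_tisochrysis")
}

#' @export
print.drum_tisochrysis <- function(x, ...) {
  cat("<drum_tisochrysis> reduced day/night carbon-storage model\n")
  print(x$model)
  invisible(x)
}

#' Generate synthetic day/night culture observations
#'
#' Forward-simulates the model past an initial transient (to reach the
#' periodic day/night regime), samples the measured quantities of a
#' day/night chemostat experiment — particulate carbon `X_C`, particulate
#' nitrogen `X_N`, `chlorophyll`, carbohydrates `CARB`, neutral lipids
#' `PA`, functional biomass `B` and nitrate `NO3` — and adds independent
#' Gaussian noise with standard deviation `noise_sd` times each
#' observable's range. With `noise_sd = 0` the observations equal the model
#' output exactly; the dataset is reproducible bit-for-bit from the seed.
#'
#' @param tiso a [build_tisochrysis_model()] object (possibly with modified
#'   parameters).
#' @param times sampling times in hours, relative to the end of the
#'   transient (default every 4 h over 5 days).
#' @param noise_sd noise level as a fraction of each observable's range
#'   (default 0.05).
#' @param seed integer seed.
#' @param transient discarded spin-up in hours (default 240, ten cycles).
#' @return object of class `drum_synthetic`: list with `observations`
#'   (data frame `time` + observables), `truth` (noiseless values),
#'   `init_state` (state at the end of the transient), `parameters`,
#'   `noise_sd`, `seed`.
#' @export
generate_synthetic_observations <- function(tiso,
                                            times = seq(0, 120, by = 4),
                                            noise_sd = 0.05, seed = 1,
                                            transient = 240) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (any(times < 0)) {
    stop("sampling times fall outside the simulated span", call. = FALSE)
  }
  grid <- sort(unique(c(seq(0, transient, by = 6), transient + times)))
  traj <- simulate_model(tiso$model, tiso$laws, tiso$env, grid, tiso$init)
  idx <- match(transient + times, traj$times)
  tb <- total_biomass(traj, tiso$compositions, tiso$chl_fraction)
  truth <- data.frame(time = times,
                      X_C = tb$X_C[idx], X_N = tb$X_N[idx],
                      chlorophyll = tb$chlorophyll[idx],
                      CARB = traj$state[idx, "CARB"],
                      PA = traj$state[idx, "PA"],
                      B = traj$state[idx, "B"],
                      NO3 = traj$state[idx, "NO3"])
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  obs <- truth
  for (o in setdiff(names(truth), "time")) {
    sd_o <- noise_sd * diff(range(truth[[o]]))
    obs[[o]] <- truth[[o]] + stats::rnorm(nrow(truth), 0, sd_o)
  }
  init_state <- traj$state[match(transient, traj$times), ]
  structure(list(observations = obs, truth = truth,
                 init_state = init_state,
                 parameters = tiso$params, noise_sd = noise_sd, seed = seed),
            class = "drum_synthetic")
}

#' Knock out a macroscopic reaction
#'
#' Sets every rate constant of the targeted reaction's kinetic law to zero
#' (an in-silico deletion of that metabolic function); the stoichiometry is
#' left untouched.
#'
#' @param x a [build_tisochrysis_model()] object or a list of
#'   [kinetic_law()].
#' @param macro_reaction_id id of the reaction to silence.
#' @return the modified object.
#' @export
knockout <- function(x, macro_reaction_id) {
  laws <- if (inherits(x, "drum_tisochrysis")) x$laws else x
  i <- match(macro_reaction_id, law_ids(laws))
  if (is.na(i)) {
    stop("unknown macroscopic reaction '", macro_reaction_id, "'",
         call. = FALSE)
  }
  laws[[i]]$params <- rep(0, length(laws[[i]]$params))
  if (inherits(x, "drum_tisochrysis")) {
    x$laws <- laws
    x$params <- param_vector(laws)
    return(x)
  }
  laws
}

#' Toy networks with hand-verified elementary flux modes
#'
#' A registry of small networks used to exercise the EFM engine: `chain`
#' (one through-mode), `diamond` (two parallel routes), `reversible-pair`
#' (one reversible exchange, two directed modes), `futile-cycle` (a genuine
#' two-reaction cycle, kept by the enumerator), `cofactor-loop` (a
#' two-step pathway whose internal cofactors cancel), `dead-end` (an
#' internal species produced but never consumed; no modes), and `random`
#' (a seeded generator of small sparse networks; no expected set).
#'
#' @param name registry entry.
#' @param seed seed for `random`.
#' @param n_reactions,n_species size of `random` networks (defaults 6, 5).
#' @return list with `network`, `internal` (species ids at quasi-steady
#'   state), and `expected` (matrix reactions x modes for hand-verified
#'   entries, `NULL` for `random`).
#' @export
toy_network <- function(name, seed = 1, n_reactions = 6, n_species = 5) {
  mk <- function(text, internal, expected) {
    net <- parse_reaction_table(text, pseudo = character())
    if (!is.null(expected)) {
      expected <- matrix(expected, nrow = length(net$reactions),
                         dimnames = list(reaction_ids(net), NULL))
    }
    list(network = net, internal = internal, expected = expected, name = name)
  }
  switch(
    name,
    "chain" = mk("r1: -> A\nr2: A ->", "A", c(1, 1)),
    "diamond" = mk(paste("r1: -> A", "r2: A -> B", "r3: A -> C",
                         "r4: B -> D", "r5: C -> D", "r6: D ->", sep = "\n"),
                   c("A", "B", "C", "D"),
                   c(1, 1, 0, 1, 0, 1,
                     1, 0, 1, 0, 1, 1)),
    "reversible-pair" = mk("r1: A <-> B", character(),
                           matrix(c(1, -1), nrow = 1)),
    "futile-cycle" = mk("r1: A -> B\nr2: B -> A", c("A", "B"), c(1, 1)),
    "cofactor-loop" = mk(paste("r1: Aext + ATP -> X + ADP",
                               "r2: X + ADP -> Bext + ATP", sep = "\n"),
                         c("X", "ATP", "ADP"), c(1, 1)),
    "dead-end" = mk("r1: -> A\nr2: A -> X", c("A", "X"),
                    matrix(numeric(0), nrow = 2)),
    "random" = {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
      set.seed(seed)
      sp <- paste0("S", seq_len(n_species))
      lines <- character(n_reactions)
      for (j in seq_len(n_reactions)) {
        ns <- sample(0:2, 1, prob = c(0.2, 0.5, 0.3))
        np <- sample(0:2, 1, prob = c(0.2, 0.5, 0.3))
        if (ns == 0 && np == 0) np <- 1
        subs <- sample(sp, ns)
        prods <- sample(setdiff(sp, subs), min(np, n_species - ns))
        term <- function(ids) {
          if (length(ids) == 0L) return("")
          paste(sample(1:2, length(ids), replace = TRUE), ids,
                collapse = " + ")
        }
        arrow <- if (stats::runif(1) < 0.3) "<->" else "->"
        lines[j] <- paste0("r", j, ": ", term(subs), " ", arrow, " ",
                           term(prods))
      }
      net <- parse_reaction_table(lines, pseudo = character())
      internal <- species_ids(net)[stats::runif(nrow(net$species)) < 0.5]
      list(network = net, internal = internal, expected = NULL,
           name = paste0("random-", seed))
    },
    stop("unknown toy network '", name, "'", call. = FALSE)
  )
}
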