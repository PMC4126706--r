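# DRUM reduction: partition a network into sub-networks (reaction
# duplication across sub-networks is allowed and meaningful — the same
# biochemical step can serve several cell functions), reduce each
# sub-network to macroscopic reactions via its elementary flux modes, and
# assemble the macroscopic reactions into a reduced stoichiometric matrix
# K' whose rows are the retained species: substrates, the accumulating set
# A, and functional biomass B.

#' Describe one sub-network of a partition
#'
#' @param name sub-network name (token).
#' @param reactions reaction ids belonging to the sub-network; the same id
#'   may appear in several sub-networks.
#' @param internal species ids held at quasi-steady state *within* this
#'   sub-network; every other participant is treated as an incoming or
#'   outgoing (accumulation-capable) species.
#' @return object of class `drum_subnetwork_spec`.
#' @export
subnetwork_spec <- function(name, reactions, internal = character()) {
  structure(list(name = name, reactions = reactions,
                 internal = internal),
            class = "drum_subnetwork_spec")
}

#' Read a partition config (YAML or JSON)
#'
#' Expected keys: `subnetworks` (list of `{name, reactions, internal}`),
#' `accumulating`, `biomass`, `drop`, `clamp`, and optionally `substrates`
#' and per-sub-network `selection` entries
#' (`{policy: best-yield, numerator, denominator, reference}`).
#'
#' @param path config file; format chosen by extension (`.yml`/`.yaml` vs
#'   `.json`).
#' @return list with `subnetworks` (list of [subnetwork_spec()]) plus the
#'   remaining keys.
#' @export
read_partition <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  cfg$subnetworks <- lapply(cfg$subnetworks, function(s) {
    subnetwork_spec(s$name, unlist(s$reactions),
                    if (is.null(s$internal)) character() else unlist(s$internal))
  })
  cfg
}

#' Extract a sub-network view from a network
#'
#' @param net a [drum_network()].
#' @param spec a [subnetwork_spec()].
#' @return a `drum_network` restricted to the listed reactions and their
#'   participant species, with attributes `internal` and `name`.
#' @export
extract_subnetwork <- function(net, spec) {
  rids <- reaction_ids(net)
  unknown <- setdiff(spec$reactions, rids)
  if (length(unknown) > 0L) {
    stop("sub-network '", spec$name, "' lists unknown reactions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  reactions <- net$reactions[match(spec$reactions, rids)]
  touched <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  untouched <- setdiff(spec$internal, touched)
  if (length(untouched) > 0L) {
    stop("internal species not touched by sub-network '", spec$name, "': ",
         paste(untouched, collapse = ", "), call. = FALSE)
  }
  sub <- drum_network(net$species[net$species$id %in% touched, , drop = FALSE],
                      reactions)
  attr(sub, "internal") <- spec$internal
  attr(sub, "name") <- spec$name
  sub
}

new_macro_reaction <- function(id, stoich, source = NULL, reversible = FALSE) {
  stoich <- stoich[abs(stoich) > 1e-12]
  structure(list(id = id, stoich = stoich, source = source,
                 reversible = isTRUE(reversible)),
            class = "drum_macro_reaction")
}

#' Reduce a sub-network to macroscopic reactions
#'
#' Enumerates the elementary flux modes of the sub-network under
#' quasi-steady state of its internal species and converts each mode `e`
#' into the net input/output reaction `K_SN e` over the boundary species
#' (internal rows cancel to ~0 by construction and are verified to).
#'
#' @param sub a sub-network from [extract_subnetwork()].
#' @param selection `"keep-all"` (default) keeps one macroscopic reaction
#'   per mode; a list `list(policy = "best-yield", numerator =,
#'   denominator =, reference =)` keeps only the mode with the best
#'   substrate/by-product yield per unit reference flux.
#' @return list of macroscopic reactions (`drum_macro_reaction`), each with
#'   a `source` field recording the sub-network and mode column it came
#'   from. A dead sub-network (no modes) gives an empty list with a warning.
#' @export
reduce_subnetwork <- function(sub, selection = "keep-all") {
  internal <- attr(sub, "internal")
  name <- attr(sub, "name")
  if (is.null(name)) name <- "SN"
  if (length(sub$reactions) == 0L) stop("empty sub-network", call. = FALSE)
  efms <- enumerate_efms(sub, internal = internal)
  if (ncol(efms$modes) == 0L) {
    warning("sub-network '", name, "' has no elementary flux modes",
            call. = FALSE)
    return(list())
  }
  cols <- seq_len(ncol(efms$modes))
  if (is.list(selection) && identical(selection$policy, "best-yield")) {
    yt <- yield_projection(efms, sub, selection$numerator,
                           selection$denominator, selection$reference)
    cols <- select_best_yield(yt)
  }
  K <- stoichiometric_matrix(sub)
  out <- list()
  for (k in seq_along(cols)) {
    j <- cols[k]
    stoich <- drop(K %*% efms$modes[, j])
    names(stoich) <- rownames(K)
    if (length(internal) > 0L && max(abs(stoich[internal])) > 1e-9) {
      stop("internal species of sub-network '", name,
           "' do not cancel in mode ", j, call. = FALSE)
    }
    stoich <- stoich[setdiff(names(stoich), internal)]
    out[[k]] <- new_macro_reaction(paste0(name, ".", k), stoich,
                                   source = list(subnetwork = name, mode = j))
  }
  out
}

#' Merge macroscopic reactions that are exact opposites
#'
#' Two macroscopic reactions whose stoichiometries are negatives of each
#' other (within `tol` after normalization) arise from a reversible pathway
#' enumerated in both directions; they are merged into one reversible
#' macroscopic reaction. Reactions that are not exact negatives — e.g. a
#' G6P-forming and a G6P-consuming pathway that differ in their ATP terms —
#' pass through unmerged.
#'
#' @param mrs list of `drum_macro_reaction`.
#' @param tol comparison tolerance (default `1e-9`).
#' @return list of macroscopic reactions, opposite pairs merged (the
#'   first-listed direction is kept, flagged `reversible`).
#' @export
merge_reverse_pairs <- function(mrs, tol = 1e-9) {
  if (length(mrs) == 0L) return(list())
  normed <- lapply(mrs, function(m) {
    v <- m$stoich
    v / max(abs(v))
  })
  used <- rep(FALSE, length(mrs))
  out <- list()
  for (i in seq_along(mrs)) {
    if (used[i]) next
    merged <- mrs[[i]]
    for (j in seq_along(mrs)) {
      if (j <= i || used[j]) next
      a <- normed[[i]]; b <- normed[[j]]
      if (setequal(names(a), names(b)) &&
          max(abs(a[names(a)] + b[names(a)])) <= tol) {
        merged$reversible <- TRUE
        merged$source <- list(forward = mrs[[i]]$source,
                              backward = mrs[[j]]$source)
        used[j] <- TRUE
        break
      }
    }
    used[i] <- TRUE
    out[[length(out) + 1L]] <- merged
  }
  out
}

#' Turn the reactions of a network into macroscopic reactions
#'
#' Used when a model is supplied directly as a table of already-macroscopic
#' reactions (each row its own single-reaction sub-network), bypassing the
#' enumeration step.
#'
#' @param net a [drum_network()].
#' @return list of `drum_macro_reaction` preserving ids, coefficients and
#'   reversibility.
#' @export
as_macro_reactions <- function(net) {
  lapply(net$reactions, function(r) {
    new_macro_reaction(r$id, r$stoich, source = NULL,
                       reversible = r$reversible)
  })
}

#' Assemble macroscopic reactions into a reduced kinetic model
#'
#' Builds the reduced stoichiometric matrix K' over the retained species:
#' rows for dropped species (untracked energy cofactors) are removed, the
#' accumulating set A and functional biomass B must be present, and clamped
#' species remain as rows for bookkeeping but are held constant during
#' simulation. Any retained species that is neither accumulating, clamped,
#' biomass nor a declared substrate would silently accumulate in violation
#' of the quasi-steady-state bookkeeping; such species are reported in
#' `qss_violations` (checked under a strictly positive flux vector).
#'
#' @param mrs list of `drum_macro_reaction`.
#' @param accumulating species ids allowed to accumulate (the set A).
#' @param biomass functional-biomass species id.
#' @param drop species ids removed from the model (must not intersect
#'   `accumulating`).
#' @param clamp species ids held constant during simulation.
#' @param substrates species ids exchanged with the environment (exempt
#'   from the accumulation check; e.g. the limiting nutrient).
#' @return object of class `drum_model`: list with `species`,
#'   `macro_reactions`, `K` (species x reactions), `accumulating`,
#'   `biomass`, `clamped`, `dropped`, `substrates`, `qss_violations`.
#' @export
assemble_reduced_model <- function(mrs, accumulating, biomass,
                                   drop = character(), clamp = character(),
                                   substrates = character()) {
  if (length(intersect(drop, accumulating)) > 0L) {
    stop("dropped species overlap the accumulating set: ",
         paste(intersect(drop, accumulating), collapse = ", "), call. = FALSE)
  }
  if (biomass %in% drop) stop("biomass species cannot be dropped", call. = FALSE)
  touched <- unique(unlist(lapply(mrs, function(m) names(m$stoich))))
  for (sp in c(accumulating, biomass)) {
    if (!(sp %in% touched)) {
      stop("species '", sp, "' occurs in no macroscopic reaction", call. = FALSE)
    }
  }
  retained <- setdiff(touched, drop)
  accumulating <- setdiff(accumulating, biomass)
  other <- setdiff(retained, c(accumulating, biomass))
  species <- c(other, intersect(accumulating, retained), biomass)
  ids <- vapply(mrs, `[[`, "", "id")
  K <- matrix(0, nrow = length(species), ncol = length(mrs),
              dimnames = list(species, ids))
  for (j in seq_along(mrs)) {
    s <- mrs[[j]]$stoich
    keep <- intersect(names(s), species)
    K[keep, j] <- s[keep]
  }
  free <- setdiff(species, c(accumulating, biomass, clamp, substrates))
  net_prod <- drop(K %*% rep(1, length(mrs)))
  qss_violations <- free[abs(net_prod[free]) > 1e-9]
  if (length(qss_violations) > 0L) {
    warning("species with nonzero net production outside the accumulating/",
            "clamped/substrate sets: ",
            paste(qss_violations, collapse = ", "), call. = FALSE)
  }
  structure(list(species = species, macro_reactions = mrs, K = K,
                 accumulating = intersect(accumulating, retained),
                 biomass = biomass,
                 clamped = intersect(clamp, species),
                 dropped = intersect(drop, touched),
                 substrates = intersect(substrates, species),
                 qss_violations = qss_violations),
            class = "drum_model")
}

#' @export
print.drum_model <- function(x, ...) {
  cat("<drum_model> ", length(x$species), " species x ",
      length(x$macro_reactions), " macroscopic reactions\n", sep = "")
  cat("  accumulating:", paste(x$accumulating, collapse = ", "), "\n")
  cat("  biomass:", x$biomass,
      " clamped:", paste(x$clamped, collapse = ","), "\n")
  for (m in x$macro_reactions) {
    cat("  ", format_reaction(list(id = m$id, stoich = round(m$stoich, 4),
                                   reversible = m$reversible)), "\n", sep = "")
  }
  invisible(x)
}

#' Count the elementary modes represented by a reduced model
#'
#' Each irreversible macroscopic reaction stands for one elementary mode of
#' the original network; each reversible one stands for two (one per
#' direction).
#'
#' @param model a `drum_model`.
#' @return integer count.
#' @export
count_reduced_efms <- function(model) {
  rev <- vapply(model$macro_reactions, `[[`, NA, "reversible")
  sum(!rev) + 2L * sum(rev)
}

#' Serialize a reduced model to JSON (full precision, with provenance)
#' @param model a `drum_model`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- list(
    species = model$species,
    accumulating = model$accumulating,
    biomass = model$biomass,
    clamped = model$clamped,
    dropped = model$dropped,
    substrates = model$substrates,
    macro_reactions = lapply(model$macro_reactions, function(m) {
      list(id = m$id, species = names(m$stoich), coeff = unname(m$stoich),
           reversible = m$reversible, source = m$source)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Read a reduced model from JSON written by [write_model_json()]
#' @param path file path or JSON string.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  mrs <- lapply(obj$macro_reactions, function(m) {
    stoich <- unlist(m$coeff)
    names(stoich) <- unlist(m$species)
    new_macro_reaction(m$id, stoich, source = m$source,
                       reversible = isTRUE(m$reversible))
  })
  assemble_reduced_model(mrs,
                         accumulating = unlist(obj$accumulating),
                         biomass = obj$biomass,
                         drop = if (is.null(obj$dropped)) character() else unlist(obj$dropped),
                         clamp = if (is.null(obj$clamped)) character() else unlist(obj$clamped),
                         substrates = if (is.null(obj$substrates)) character() else unlist(obj$substrates))
}
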