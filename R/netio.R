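# Network representation and plain-text reaction-table I/O.
#
# A network is an ordered list of species and an ordered list of reactions;
# the stoichiometric matrix K has one row per species and one column per
# reaction, in declaration order. Species flagged `pseudo` (photons written
# as a reactant, as in "30 Light + 3 CO2 + ... -> GAP + 3 O2") carry no
# matter and are excluded from every elemental balance.

ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Mg")

new_reaction <- function(id, stoich, reversible = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- unlist(stoich)
  if (length(stoich) == 0L) {
    stop("reaction '", id, "' references no species", call. = FALSE)
  }
  if (anyDuplicated(names(stoich))) {
    stop("reaction '", id, "' lists a species twice on one side", call. = FALSE)
  }
  structure(list(id = id, stoich = stoich, reversible = isTRUE(reversible)),
            class = "drum_reaction")
}

#' Construct a metabolic network
#'
#' @param species data frame with columns `id` (unique character), and
#'   optionally `name` (free text) and `pseudo` (logical; non-material
#'   pseudo-species such as photons, excluded from elemental balances).
#' @param reactions list of reactions as returned by the parser: each a list
#'   with `id`, `stoich` (named signed numeric, negative = consumed) and
#'   `reversible`.
#' @return An object of class `drum_network`.
#' @export
drum_network <- function(species, reactions) {
  if (is.character(species)) {
    species <- data.frame(id = species, stringsAsFactors = FALSE)
  }
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$pseudo)) species$pseudo <- FALSE
  species <- species[, c("id", "name", "pseudo")]
  if (anyDuplicated(species$id)) {
    stop("duplicate species id: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "),
         call. = FALSE)
  }
  reactions <- lapply(reactions, function(r) {
    if (!inherits(r, "drum_reaction")) r <- new_reaction(r$id, r$stoich, r$reversible)
    r
  })
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction id: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  }
  for (r in reactions) {
    missing <- setdiff(names(r$stoich), species$id)
    if (length(missing) > 0L) {
      stop("reaction '", r$id, "' references unknown species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(species = species, reactions = reactions),
            class = "drum_network")
}

#' @export
print.drum_network <- function(x, ...) {
  cat("<drum_network> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  for (r in x$reactions) cat("  ", format_reaction(r), "\n", sep = "")
  invisible(x)
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, "", "id")

species_ids <- function(net) net$species$id

# ---------------------------------------------------------------------------
# Reaction-table dialect: one reaction per line,
#   id: c1 A + c2 B -> c3 C        (irreversible)
#   id: c1 A <-> c2 B              (reversible)
# Unicode arrows from typeset tables (em/en dash variants) are accepted.
# Coefficients default to 1; '#' starts a comment; blank lines are skipped.
# An empty side denotes exchange with the environment ("r1: -> A").

ARROW_RE <- "(<->|<—>|<–>|->|—>|–>|→|⇄)"

parse_side <- function(text, line, n) {
  text <- trimws(text)
  if (!nzchar(text)) return(numeric(0))
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  coeffs <- numeric(0)
  for (term in terms) {
    if (!nzchar(term)) {
      stop("line ", n, ": empty term in '", line, "'", call. = FALSE)
    }
    parts <- strsplit(term, "[ \t]+")[[1]]
    if (length(parts) == 1L) {
      coef <- 1
      sp <- parts[1L]
    } else if (length(parts) == 2L) {
      coef <- suppressWarnings(as.numeric(parts[1L]))
      sp <- parts[2L]
      if (is.na(coef)) {
        stop("line ", n, ": bad coefficient '", parts[1L], "'", call. = FALSE)
      }
    } else {
      stop("line ", n, ": cannot parse term '", term, "'", call. = FALSE)
    }
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", sp)) {
      stop("line ", n, ": bad species token '", sp, "'", call. = FALSE)
    }
    coeffs[sp] <- if (sp %in% names(coeffs)) coeffs[[sp]] + coef else coef
  }
  coeffs
}

#' Parse a plain-text reaction table into a network
#'
#' Each non-comment line has the form `id: c1 A + c2 B -> c3 C` with `<->`
#' marking a reversible reaction (typeset arrow glyphs are also accepted).
#' Coefficients default to 1 and species are registered in order of first
#' mention. An empty reaction side denotes exchange with the environment.
#'
#' @param text character scalar (or vector of lines) with the table content.
#' @param pseudo ids of non-material pseudo-species (default `"Light"`),
#'   flagged so that elemental balances skip them.
#' @return A [drum_network()].
#' @examples
#' net <- parse_reaction_table("MR6: G6P <-> CARB + Pi")
#' net$reactions[[1]]$stoich
#' @export
parse_reaction_table <- function(text, pseudo = "Light") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  species <- character(0)
  reactions <- list()
  for (n in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[n]])
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0L) stop("line ", n, ": missing 'id:' prefix in '", line, "'",
                     call. = FALSE)
    id <- trimws(substr(line, 1L, m - 1L))
    body <- substr(line, m + 1L, nchar(line))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)) {
      stop("line ", n, ": bad reaction id '", id, "'", call. = FALSE)
    }
    arrow <- regexpr(ARROW_RE, body)
    if (arrow < 0L) stop("line ", n, ": no reaction arrow in '", line, "'",
                         call. = FALSE)
    arrow_txt <- regmatches(body, arrow)
    reversible <- startsWith(arrow_txt, "<") || arrow_txt == "⇄"
    lhs <- parse_side(substr(body, 1L, arrow - 1L), line, n)
    rhs <- parse_side(substr(body, arrow + attr(arrow, "match.length"),
                             nchar(body)), line, n)
    if (length(lhs) == 0L && length(rhs) == 0L) {
      stop("line ", n, ": reaction '", id, "' has no species", call. = FALSE)
    }
    stoich <- -lhs
    for (sp in names(rhs)) {
      stoich[sp] <- if (sp %in% names(stoich)) stoich[[sp]] + rhs[[sp]] else rhs[[sp]]
    }
    if (any(vapply(reactions, `[[`, "", "id") == id)) {
      stop("line ", n, ": duplicate reaction id '", id, "'", call. = FALSE)
    }
    species <- union(species, c(names(lhs), names(rhs)))
    reactions[[length(reactions) + 1L]] <- new_reaction(id, stoich, reversible)
  }
  sp <- data.frame(id = species, name = species,
                   pseudo = species %in% pseudo, stringsAsFactors = FALSE)
  drum_network(sp, reactions)
}

format_coef <- function(x) {
  ifelse(abs(x - 1) < 1e-12, "", paste0(format(x, trim = TRUE, digits = 10), " "))
}

format_reaction <- function(r) {
  lhs <- r$stoich[r$stoich < 0]
  rhs <- r$stoich[r$stoich > 0]
  zero <- r$stoich[r$stoich == 0]   # net-zero participants kept on both sides
  fmt <- function(v, flip) {
    if (length(v) == 0L) return("")
    paste0(format_coef(if (flip) -v else v), names(v), collapse = " + ")
  }
  left <- fmt(lhs, TRUE)
  right <- fmt(rhs, FALSE)
  if (length(zero) > 0L) {
    extra <- paste0(names(zero), collapse = " + ")
    left <- if (nzchar(left)) paste(left, "+", extra) else extra
    right <- if (nzchar(right)) paste(right, "+", extra) else extra
  }
  paste0(r$id, ": ", left, if (r$reversible) " <-> " else " -> ", right)
}

#' Serialize a network back to the reaction-table dialect
#'
#' `parse_reaction_table(format_reaction_table(net))` reproduces `net`
#' (species order, coefficients, reversibility).
#'
#' @param net a [drum_network()].
#' @return character scalar, one reaction per line.
#' @export
format_reaction_table <- function(net) {
  paste(vapply(net$reactions, format_reaction, ""), collapse = "\n")
}

#' Stoichiometric matrix of a network
#'
#' Entry `(i, j)` is the signed coefficient of species `i` in reaction `j`
#' (negative = consumed). Restricting `rows` to the internal species of a
#' sub-network yields the quasi-steady-state constraint matrix.
#'
#' @param net a [drum_network()].
#' @param rows optional character vector of species ids selecting (and
#'   ordering) the rows.
#' @return numeric matrix with species ids as row names and reaction ids as
#'   column names.
#' @export
stoichiometric_matrix <- function(net, rows = NULL) {
  sp <- species_ids(net)
  if (is.null(rows)) {
    rows <- sp
  } else {
    unknown <- setdiff(rows, sp)
    if (length(unknown) > 0L) {
      stop("unknown species in row subset: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  K <- matrix(0, nrow = length(rows), ncol = length(net$reactions),
              dimnames = list(rows, reaction_ids(net)))
  for (j in seq_along(net$reactions)) {
    s <- net$reactions[[j]]$stoich
    keep <- intersect(names(s), rows)
    K[keep, j] <- s[keep]
  }
  K
}

# ---------------------------------------------------------------------------
# Elemental bookkeeping. Compositions are a numeric matrix with species ids
# as row names and element symbols as column names; NA marks an unknown
# count. The CSV interface has columns species_id, C, H, N, O, P, S, Mg with
# blanks for unknowns.

as_composition_matrix <- function(compositions) {
  if (is.matrix(compositions)) return(compositions)
  if (is.data.frame(compositions)) {
    idcol <- intersect(c("species_id", "id"), names(compositions))[1]
    if (is.na(idcol)) stop("compositions need a species_id column", call. = FALSE)
    m <- as.matrix(compositions[, setdiff(names(compositions), idcol), drop = FALSE])
    rownames(m) <- compositions[[idcol]]
    storage.mode(m) <- "double"
    return(m)
  }
  stop("compositions must be a matrix or data frame", call. = FALSE)
}

#' Read species compositions from CSV
#'
#' @param path CSV file with columns `species_id` then element symbols
#'   (`C,H,N,O,P,S,Mg`); blank cells mean unknown.
#' @return numeric matrix, species ids as row names, `NA` = unknown.
#' @export
read_compositions <- function(path) {
  as_composition_matrix(utils::read.csv(path, stringsAsFactors = FALSE))
}

comp_count <- function(comp, species, element) {
  if (!(species %in% rownames(comp)) || !(element %in% colnames(comp))) {
    return(NA_real_)
  }
  comp[species, element]
}

#' Check elemental balance of every reaction
#'
#' For each reaction and element, the residual is the signed sum of
#' `coefficient x atoms-per-mole` over all material, non-ignored
#' participants; a closed reaction has residual zero. H and O are not
#' checked by default because water/proton bookkeeping in lumped reactions
#' is unreliable.
#'
#' @param net a [drum_network()].
#' @param compositions composition matrix or data frame (see
#'   [read_compositions()]).
#' @param elements element symbols to check (default C, N, P, S, Mg).
#' @param tolerance absolute residual above which a reaction is flagged
#'   (default 0.05, slack for coefficients printed to 2 decimals).
#' @param ignore species ids to exclude (e.g. untracked energy cofactors).
#' @return data frame with one row per reaction x element: `reaction`,
#'   `element`, `residual`, `balanced`.
#' @export
check_elemental_balance <- function(net, compositions,
                                    elements = c("C", "N", "P", "S", "Mg"),
                                    tolerance = 0.05,
                                    ignore = character()) {
  comp <- as_composition_matrix(compositions)
  skip <- union(ignore, net$species$id[net$species$pseudo])
  out <- expand.grid(reaction = reaction_ids(net), element = elements,
                     stringsAsFactors = FALSE)
  out$residual <- NA_real_
  for (k in seq_len(nrow(out))) {
    r <- net$reactions[[match(out$reaction[k], reaction_ids(net))]]
    el <- out$element[k]
    res <- 0
    for (sp in names(r$stoich)) {
      if (sp %in% skip) next
      cnt <- comp_count(comp, sp, el)
      if (is.na(cnt)) {
        stop("composition of species '", sp, "' unknown for element ", el,
             " (reaction '", r$id, "')", call. = FALSE)
      }
      res <- res + r$stoich[[sp]] * cnt
    }
    out$residual[k] <- res
  }
  out$balanced <- abs(out$residual) <= tolerance
  out
}

#' Infer unknown compositions by closing reaction balances
#'
#' Solves for the atoms-per-mole of each listed unknown species, in order,
#' as the unique value that zeroes the elemental residual of a reaction in
#' which every other material participant is already known. This is how the
#' carbon content of lumped products (e.g. an "average" lipid or the
#' functional-biomass unit) is pinned down from the macroscopic reactions
#' that form them.
#'
#' @param net a [drum_network()].
#' @param element single element symbol.
#' @param known named numeric vector of known counts for `element`.
#' @param unknowns species ids to solve for, in solving order.
#' @param ignore species ids excluded from balances (untracked cofactors).
#' @param tolerance allowed disagreement between reactions that both
#'   determine the same unknown.
#' @return `known` extended with the solved counts.
#' @export
infer_composition_by_closure <- function(net, element, known, unknowns,
                                         ignore = character(),
                                         tolerance = 0.05) {
  skip <- union(ignore, net$species$id[net$species$pseudo])
  known <- unlist(known)
  for (u in unknowns) {
    candidates <- numeric(0)
    via <- character(0)
    for (r in net$reactions) {
      if (!(u %in% names(r$stoich)) || r$stoich[[u]] == 0) next
      others <- setdiff(setdiff(names(r$stoich), u), skip)
      if (!all(others %in% names(known))) next
      rest <- sum(r$stoich[others] * known[others])
      candidates <- c(candidates, -rest / r$stoich[[u]])
      via <- c(via, r$id)
    }
    if (length(candidates) == 0L) {
      stop("no reaction determines the ", element, " count of '", u, "'",
           call. = FALSE)
    }
    if (max(candidates) - min(candidates) > tolerance) {
      stop("inconsistent ", element, " count for '", u, "': ",
           paste(sprintf("%s via %s", format(candidates, digits = 6), via),
                 collapse = "; "),
           call. = FALSE)
    }
    known[u] <- candidates[[1L]]
  }
  known
}

# ---------------------------------------------------------------------------
# JSON round-tripping

#' Serialize a network to JSON
#' @param net a [drum_network()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
write_network_json <- function(net, path = NULL) {
  obj <- list(
    species = net$species,
    reactions = lapply(net$reactions, function(r) {
      list(id = r$id, species = names(r$stoich), coeff = unname(r$stoich),
           reversible = r$reversible)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Read a network from JSON written by [write_network_json()]
#' @param path file path or JSON string.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  reactions <- lapply(seq_len(nrow(obj$reactions)), function(i) {
    r <- obj$reactions[i, ]
    stoich <- unlist(r$coeff)
    names(stoich) <- unlist(r$species)
    new_reaction(r$id, stoich, isTRUE(r$reversible))
  })
  drum_network(obj$species, reactions)
}

#' Minimal SBML Level 3 import (species and reactions only)
#'
#' Maps `listOfSpecies` and `listOfReactions` (with `speciesReference`
#' stoichiometries and the `reversible` flag) to a [drum_network()]. Kinetic
#' laws, compartments and annotations are ignored; sub-network membership
#' and accumulating-species sets live in the partition config, not in SBML.
#'
#' @param path SBML file.
#' @return A [drum_network()].
#' @export
read_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML import requires the xml2 package", call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    pseudo = FALSE, stringsAsFactors = FALSE
  )
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(node, xp)
      if (length(sr) == 0L) return(numeric(0))
      st <- xml2::xml_attr(sr, "stoichiometry")
      st[is.na(st)] <- "1"
      v <- sign * as.numeric(st)
      names(v) <- xml2::xml_attr(sr, "species")
      v
    }
    lhs <- refs("./listOfReactants/speciesReference", -1)
    rhs <- refs("./listOfProducts/speciesReference", +1)
    stoich <- lhs
    for (sp in names(rhs)) {
      stoich[sp] <- if (sp %in% names(stoich)) stoich[[sp]] + rhs[[sp]] else rhs[[sp]]
    }
    new_reaction(xml2::xml_attr(node, "id"), stoich,
                 identical(xml2::xml_attr(node, "reversible"), "true"))
  })
  drum_network(species, reactions)
}
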