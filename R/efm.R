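# Elementary flux mode enumeration for sub-network-scale problems.
#
# The engine is a Schuster-style tableau double-description: reversible
# reactions are split into opposed irreversible columns, the quasi-steady-
# state constraints (one per internal species) are processed one at a time
# by pairwise combination of sign-opposed rows, and support-minimality is
# maintained with the classical zero-set inclusion test. The tableau is kept
# in exact integer arithmetic (stoichiometric rows are rescaled to integers
# and every combined row is reduced by its gcd), so no mode is lost to a
# floating tolerance; coefficients are converted to floats only on output.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0L) return(1)
  g <- v[1L]
  for (x in v[-1L]) {
    g <- gcd2(g, x)
    if (g == 1) break
  }
  g
}

# Rescale one constraint row to integers (scaling a row does not change the
# nullspace). Stoichiometries in curated tables carry at most a few
# decimals; anything else is rejected rather than silently rounded.
row_to_integers <- function(row, max_decimals = 6L) {
  for (k in 0:max_decimals) {
    scaled <- row * 10^k
    if (max(abs(scaled - round(scaled))) < 1e-9 * max(1, max(abs(scaled)))) {
      scaled <- round(scaled)
      g <- gcd_vec(scaled)
      if (g > 1) scaled <- scaled / g
      return(scaled)
    }
  }
  stop("stoichiometric coefficients are not decimal fractions ",
       "(more than ", max_decimals, " decimals); cannot use exact arithmetic",
       call. = FALSE)
}

#' Split reversible reactions into opposed irreversible columns
#'
#' Standard EFM preprocessing: each reversible reaction becomes a forward
#' column (original stoichiometry) and a backward column (negated), so that
#' all fluxes can be constrained nonnegative.
#'
#' @param net a [drum_network()].
#' @return list with `net` (all-irreversible network; backward columns are
#'   named `<id>_rev`) and `map` (data frame `orig`, `forward`, `backward`;
#'   `backward` is `NA` for originally irreversible reactions).
#' @export
split_reversible <- function(net) {
  reactions <- list()
  map <- data.frame(orig = character(0), forward = character(0),
                    backward = character(0), stringsAsFactors = FALSE)
  for (r in net$reactions) {
    reactions[[length(reactions) + 1L]] <- new_reaction(r$id, r$stoich, FALSE)
    if (r$reversible) {
      rev_id <- paste0(r$id, "_rev")
      reactions[[length(reactions) + 1L]] <- new_reaction(rev_id, -r$stoich, FALSE)
      map <- rbind(map, data.frame(orig = r$id, forward = r$id,
                                   backward = rev_id, stringsAsFactors = FALSE))
    } else {
      map <- rbind(map, data.frame(orig = r$id, forward = r$id,
                                   backward = NA_character_,
                                   stringsAsFactors = FALSE))
    }
  }
  list(net = drum_network(net$species, reactions), map = map)
}

# Core tableau: S is the internal stoichiometry of an all-irreversible
# network (rows already integer). Returns a matrix whose rows are the EFMs
# of {v >= 0, S v = 0} (unnormalized integer coefficients).
efm_tableau <- function(S) {
  n <- ncol(S)
  R <- diag(n)                       # reaction-space part, rows = candidates
  C <- t(S)                          # residuals of unprocessed constraints
  for (j in seq_len(nrow(S))) {
    res <- C[, 1L, drop = TRUE]
    keep <- which(res == 0)
    pos <- which(res > 0)
    neg <- which(res < 0)
    newR <- list(); newC <- list()
    if (length(pos) > 0L && length(neg) > 0L) {
      zero_sets <- R == 0
      for (i in pos) {
        for (k in neg) {
          # support-minimality (adjacency) test: reject the combination if a
          # third row is zero everywhere rows i and k are both zero
          z <- zero_sets[i, ] & zero_sets[k, ]
          others <- setdiff(seq_len(nrow(R)), c(i, k))
          if (length(others) > 0L && any(z) &&
              any(rowSums(zero_sets[others, z, drop = FALSE]) == sum(z))) {
            next
          }
          if (length(others) > 0L && !any(z)) {
            # a row with empty guaranteed zero set is dominated by any other
            next
          }
          a <- abs(res[k]); b <- abs(res[i])
          rr <- a * R[i, ] + b * R[k, ]
          cc <- a * C[i, , drop = TRUE] + b * C[k, , drop = TRUE]
          g <- gcd_vec(c(rr, cc))
          if (g > 1) { rr <- rr / g; cc <- cc / g }
          if (max(abs(c(rr, cc))) > 2^52) {
            stop("integer overflow in EFM tableau; split the sub-network further",
                 call. = FALSE)
          }
          newR[[length(newR) + 1L]] <- rr
          newC[[length(newC) + 1L]] <- cc
        }
      }
    }
    R <- rbind(R[keep, , drop = FALSE], do.call(rbind, newR))
    C <- rbind(C[keep, -1L, drop = FALSE],
               if (length(newC) > 0L) do.call(rbind, newC)[, -1L, drop = FALSE])
    if (is.null(C)) C <- matrix(0, nrow = 0L, ncol = nrow(S) - j)
    if (nrow(R) > 10000L) {
      warning("more than 10,000 candidate modes; consider a finer ",
              "sub-network split", call. = FALSE)
    }
  }
  R
}

#' Enumerate elementary flux modes
#'
#' Computes all support-minimal flux vectors `v` with `K_internal v = 0` and
#' nonnegative flux through irreversible reactions, where `K_internal` is
#' the stoichiometric matrix restricted to the internal (quasi-steady-state)
#' species. Reversible reactions are split for the enumeration and mapped
#' back to signed fluxes; the spurious two-cycles created by the split
#' (forward plus backward of a single reaction) are removed, while genuine
#' futile cycles spanning two or more distinct reactions are kept.
#'
#' @param net a [drum_network()].
#' @param internal character vector of internal species ids (may be empty).
#' @param normalization `"min"` (default) divides each mode by its
#'   smallest-magnitude nonzero coefficient; `"reaction"` rescales to unit
#'   flux through `reference`.
#' @param reference reaction id used when `normalization = "reaction"`.
#' @return An object of class `drum_efms`: list with `modes` (matrix,
#'   reactions x modes, signed fluxes on the original reactions),
#'   `reaction_ids`, `reversible`, `normalization`. Mode columns are in
#'   canonical order (lexicographic by support, then by sign pattern).
#' @export
enumerate_efms <- function(net, internal = character(),
                           normalization = c("min", "reaction"),
                           reference = NULL) {
  normalization <- match.arg(normalization)
  unknown <- setdiff(internal, species_ids(net))
  if (length(unknown) > 0L) {
    stop("internal set references unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rids <- reaction_ids(net)
  rev_flags <- vapply(net$reactions, `[[`, NA, "reversible")
  if (length(rids) == 0L) {
    return(structure(list(modes = matrix(0, 0, 0), reaction_ids = character(0),
                          reversible = logical(0),
                          normalization = normalization),
                     class = "drum_efms"))
  }
  split <- split_reversible(net)
  S <- stoichiometric_matrix(split$net, rows = internal)
  if (nrow(S) > 0L) {
    S <- t(apply(S, 1L, row_to_integers))
    if (ncol(S) != length(split$net$reactions)) S <- t(S)  # single-row case
  }
  R <- efm_tableau(S)
  split_ids <- reaction_ids(split$net)
  # drop spurious 2-cycles: support exactly {forward, backward} of one split
  keep <- rep(TRUE, nrow(R))
  for (i in seq_len(nrow(R))) {
    supp <- split_ids[R[i, ] != 0]
    if (length(supp) == 2L) {
      m <- split$map[!is.na(split$map$backward), , drop = FALSE]
      if (any(m$forward == supp[1L] & m$backward == supp[2L]) ||
          any(m$forward == supp[2L] & m$backward == supp[1L])) {
        keep[i] <- FALSE
      }
    }
  }
  R <- R[keep, , drop = FALSE]
  # map back to signed fluxes on original reactions
  modes <- matrix(0, nrow = length(rids), ncol = nrow(R),
                  dimnames = list(rids, NULL))
  for (i in seq_len(nrow(R))) {
    v <- R[i, ]
    names(v) <- split_ids
    for (k in seq_len(nrow(split$map))) {
      f <- v[[split$map$forward[k]]]
      b <- if (is.na(split$map$backward[k])) 0 else v[[split$map$backward[k]]]
      modes[split$map$orig[k], i] <- f - b
    }
  }
  modes <- modes[, colSums(modes != 0) > 0, drop = FALSE]
  # canonical column order: lexicographic by support, then sign pattern
  if (ncol(modes) > 0L) {
    key <- apply(modes, 2L, function(v) {
      supp <- which(v != 0)
      paste(sprintf("%03d%s", supp, ifelse(v[supp] > 0, "+", "-")),
            collapse = ",")
    })
    modes <- modes[, order(key), drop = FALSE]
    modes <- apply(modes, 2L, function(v) v / min(abs(v[v != 0])))
    if (is.null(dim(modes))) modes <- matrix(modes, nrow = length(rids),
                                             dimnames = list(rids, NULL))
    if (normalization == "reaction") {
      if (is.null(reference) || !(reference %in% rids)) {
        stop("reference reaction for normalization not found", call. = FALSE)
      }
      ref <- modes[reference, ]
      scal <- ifelse(ref != 0, ref, 1)
      modes <- sweep(modes, 2L, scal, "/")
    }
    colnames(modes) <- paste0("m", seq_len(ncol(modes)))
  }
  structure(list(modes = modes, reaction_ids = rids,
                 reversible = rev_flags,
                 normalization = if (normalization == "reaction")
                   paste0("by-reaction:", reference) else "smallest-coefficient"),
            class = "drum_efms")
}

#' @export
print.drum_efms <- function(x, ...) {
  cat("<drum_efms> ", ncol(x$modes), " modes over ", length(x$reaction_ids),
      " reactions (normalization: ", x$normalization, ")\n", sep = "")
  if (ncol(x$modes) > 0L) print(round(x$modes, 6))
  invisible(x)
}

#' Validate an EFM matrix against its steady-state constraints
#'
#' Checks that every column satisfies `K_internal v = 0` (infinity norm at
#' most `tol` after normalizing the column by its largest coefficient) and
#' that no column's support strictly contains another's (support-minimality,
#' the defining property of an elementary mode).
#'
#' @param efms a `drum_efms` object (or plain matrix).
#' @param K_internal internal stoichiometry with columns aligned to the
#'   EFM rows.
#' @param tol steady-state tolerance (default `1e-9`).
#' @return list with `ok`, `steady_state_violations` (mode indices) and
#'   `support_violations` (data frame of offending column pairs).
#' @export
validate_efms <- function(efms, K_internal, tol = 1e-9) {
  modes <- if (inherits(efms, "drum_efms")) efms$modes else efms
  ss <- integer(0)
  if (nrow(K_internal) > 0L && ncol(modes) > 0L) {
    resid <- K_internal %*% modes
    scale <- apply(abs(modes), 2L, max)
    bad <- apply(abs(resid), 2L, max) > tol * pmax(1, scale)
    ss <- which(bad)
  }
  pairs <- data.frame(contained = integer(0), container = integer(0))
  if (ncol(modes) > 1L) {
    # directional support inclusion: mode i violates minimality of mode j
    # only if, wherever i is nonzero, j is nonzero with the same sign
    # (opposite orientations of a reversible pathway are both elementary)
    sgn <- sign(modes)
    for (i in seq_len(ncol(modes))) {
      for (j in seq_len(ncol(modes))) {
        if (i == j) next
        nz <- sgn[, i] != 0
        if (all(sgn[nz, j] == sgn[nz, i])) {
          pairs <- rbind(pairs, data.frame(contained = i, container = j))
        }
      }
    }
  }
  list(ok = length(ss) == 0L && nrow(pairs) == 0L,
       steady_state_violations = ss, support_violations = pairs)
}

#' Project elementary modes into a substrate/product yield space
#'
#' Rescales each mode to unit flux through a reference reaction (typically
#' the product-forming step) and reports the net consumption of a substrate
#' species against the net production of a by-product species. Used to pick
#' a representative mode when a sub-network has many (e.g. the mode with
#' the best substrate-per-CO2 yield among biomass-forming modes).
#'
#' @param efms a `drum_efms` object.
#' @param net the network the modes were computed on.
#' @param numerator species id whose net consumption is reported.
#' @param denominator species id whose net production is reported.
#' @param reference reaction id used for normalization; modes with zero
#'   reference flux are excluded.
#' @return data frame (`mode`, `numerator`, `denominator`) of class
#'   `drum_yield_table`.
#' @export
yield_projection <- function(efms, net, numerator, denominator, reference) {
  if (!(reference %in% efms$reaction_ids)) {
    stop("reference reaction '", reference, "' not in EFM matrix", call. = FALSE)
  }
  K <- stoichiometric_matrix(net)
  ref_flux <- efms$modes[reference, ]
  keep <- which(abs(ref_flux) > 1e-12)
  out <- data.frame(mode = integer(0), numerator = numeric(0),
                    denominator = numeric(0))
  for (i in keep) {
    v <- efms$modes[, i] / ref_flux[i]
    net_change <- K %*% v
    out <- rbind(out, data.frame(
      mode = i,
      numerator = -net_change[numerator, 1L],
      denominator = net_change[denominator, 1L]))
  }
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  class(out) <- c("drum_yield_table", "data.frame")
  out
}

#' Pick the best-yield mode from a yield table
#'
#' Returns the mode minimizing substrate consumption per unit reference
#' flux; ties are broken by smaller by-product production, then by lowest
#' canonical mode index.
#'
#' @param table a [yield_projection()] result.
#' @return mode index (into the EFM matrix columns).
#' @export
select_best_yield <- function(table) {
  if (nrow(table) == 0L) stop("empty yield table", call. = FALSE)
  ord <- order(table$numerator, table$denominator, table$mode)
  table$mode[ord[1L]]
}

#' Export an EFM matrix as CSV (reactions x modes)
#' @param efms a `drum_efms` object.
#' @param path output file.
#' @export
write_efms_csv <- function(efms, path) {
  df <- as.data.frame(efms$modes)
  df <- cbind(reaction = efms$reaction_ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
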