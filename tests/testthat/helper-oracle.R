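# Brute-force elementary flux mode oracle, independent of the tableau
# engine: enumerate every support subset of the reversibility-split
# network; a support is an EFM support iff the nullspace of the internal
# stoichiometry restricted to it is one-dimensional with a generator that
# is nonzero on the whole support and of a single sign. Feasible only for
# small networks; used to validate the production enumerator.

brute_force_efms <- function(net, internal) {
  split <- drumr::split_reversible(net)
  S <- drumr::stoichiometric_matrix(split$net, rows = internal)
  n <- ncol(S)
  split_ids <- colnames(S)
  modes <- list()
  for (mask in seq_len(2^n - 1)) {
    supp <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    Ssub <- S[, supp, drop = FALSE]
    if (nrow(Ssub) == 0L) {
      # no constraints: nullspace is all of R^|supp|, 1-dimensional only
      # for singleton supports
      if (length(supp) != 1L) next
      g <- 1
    } else {
      sv <- svd(Ssub, nu = 0, nv = length(supp))
      tol <- max(1e-10, max(dim(Ssub)) * max(sv$d) * 1e-12)
      rank <- sum(sv$d > tol)
      if (length(supp) - rank != 1L) next
      g <- sv$v[, length(supp)]
    }
    if (any(abs(g) < 1e-9)) next          # support not exact
    if (!(all(g > 0) || all(g < 0))) next # not sign-feasible
    if (all(g < 0)) g <- -g
    v <- numeric(n)
    v[supp] <- g
    modes[[length(modes) + 1L]] <- v
  }
  if (length(modes) == 0L) {
    return(matrix(0, nrow = length(net$reactions), ncol = 0,
                  dimnames = list(vapply(net$reactions, `[[`, "", "id"), NULL)))
  }
  M <- do.call(cbind, modes)
  rownames(M) <- split_ids
  # drop spurious 2-cycles from the split
  two_cycle <- vapply(seq_len(ncol(M)), function(j) {
    supp <- split_ids[M[, j] != 0]
    if (length(supp) != 2L) return(FALSE)
    m <- split$map[!is.na(split$map$backward), , drop = FALSE]
    any((m$forward == supp[1] & m$backward == supp[2]) |
        (m$forward == supp[2] & m$backward == supp[1]))
  }, NA)
  M <- M[, !two_cycle, drop = FALSE]
  # back to signed fluxes on the original reactions
  rids <- vapply(net$reactions, `[[`, "", "id")
  out <- matrix(0, nrow = length(rids), ncol = ncol(M),
                dimnames = list(rids, NULL))
  for (k in seq_len(nrow(split$map))) {
    f <- M[split$map$forward[k], ]
    b <- if (is.na(split$map$backward[k])) 0 else M[split$map$backward[k], ]
    out[split$map$orig[k], ] <- f - b
  }
  out[, colSums(out != 0) > 0, drop = FALSE]
}

# Canonicalize a mode matrix for comparison: normalize each column by its
# smallest-magnitude nonzero coefficient, then sort columns by support and
# sign pattern.
canon_modes <- function(M) {
  if (ncol(M) == 0L) return(M)
  M <- apply(M, 2L, function(v) v / min(abs(v[abs(v) > 1e-12])))
  if (is.null(dim(M))) M <- matrix(M, ncol = 1)
  key <- apply(M, 2L, function(v) {
    supp <- which(abs(v) > 1e-12)
    paste(sprintf("%03d%s", supp, ifelse(v[supp] > 0, "+", "-")),
          collapse = ",")
  })
  M[, order(key), drop = FALSE]
}

expect_same_modes <- function(a, b, tol = 1e-9) {
  A <- canon_modes(a)
  B <- canon_modes(b)
  expect_equal(ncol(A), ncol(B))
  if (ncol(A) > 0L) expect_lt(max(abs(A - B)), tol)
}
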