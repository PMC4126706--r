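test_that("sub-network extraction restricts reactions and allows duplication", {
  chain <- parse_reaction_table("r1: -> A\nr2: A -> B\nr3: B ->")
  sub <- extract_subnetwork(chain, subnetwork_spec("mid", "r2"))
  expect_length(sub$reactions, 1L)
  expect_setequal(sub$species$id, c("A", "B"))

  # the same reaction may belong to two sub-networks
  s1 <- extract_subnetwork(chain, subnetwork_spec("a", c("r1", "r2"), "A"))
  s2 <- extract_subnetwork(chain, subnetwork_spec("b", c("r2", "r3"), "B"))
  expect_true("r2" %in% vapply(s1$reactions, `[[`, "", "id"))
  expect_true("r2" %in% vapply(s2$reactions, `[[`, "", "id"))

  expect_error(extract_subnetwork(chain, subnetwork_spec("x", "r9")),
               "unknown reactions")
  expect_error(extract_subnetwork(chain, subnetwork_spec("x", "r2", "Z")),
               "not touched")
})

test_that("sub-network reduction collapses pathways and cancels cofactors", {
  chain <- parse_reaction_table("r1: Aext -> X\nr2: X -> Bext")
  sub <- extract_subnetwork(chain, subnetwork_spec("sn", c("r1", "r2"), "X"))
  mrs <- reduce_subnetwork(sub)
  expect_length(mrs, 1L)
  expect_equal(mrs[[1]]$stoich[c("Aext", "Bext")], c(Aext = -1, Bext = 1))
  expect_false("X" %in% names(mrs[[1]]$stoich))

  cof <- toy_network("cofactor-loop")
  sub2 <- extract_subnetwork(cof$network,
                             subnetwork_spec("loop", c("r1", "r2"),
                                             cof$internal))
  mrs2 <- reduce_subnetwork(sub2)
  expect_length(mrs2, 1L)
  expect_equal(sort(names(mrs2[[1]]$stoich)), c("Aext", "Bext"))
  expect_equal(unname(mrs2[[1]]$stoich[c("Aext", "Bext")]), c(-1, 1))

  dead <- toy_network("dead-end")
  sub3 <- extract_subnetwork(dead$network,
                             subnetwork_spec("dead", c("r1", "r2"),
                                             dead$internal))
  expect_warning(mrs3 <- reduce_subnetwork(sub3), "no elementary flux modes")
  expect_length(mrs3, 0L)
})

test_that("best-yield selection keeps a single representative mode", {
  # two routes from Aext to Bext, one wasting carbon to Cext
  net <- parse_reaction_table(paste(
    "r1: Aext -> X", "r2: X -> Bext",
    "r3: 2 Aext -> X + Cext", sep = "\n"))
  sub <- extract_subnetwork(net, subnetwork_spec("sn", c("r1", "r2", "r3"), "X"))
  all_mrs <- reduce_subnetwork(sub)
  expect_length(all_mrs, 2L)
  best <- reduce_subnetwork(sub, selection = list(policy = "best-yield",
                                                  numerator = "Aext",
                                                  denominator = "Cext",
                                                  reference = "r2"))
  expect_length(best, 1L)
  expect_equal(unname(best[[1]]$stoich["Aext"]), -1)
})

test_that("exact opposite macroscopic reactions merge into one reversible entry", {
  a <- drumr:::new_macro_reaction("f", c(A = -1, B = 1))
  b <- drumr:::new_macro_reaction("r", c(A = 1, B = -1))
  merged <- merge_reverse_pairs(list(a, b))
  expect_length(merged, 1L)
  expect_true(merged[[1]]$reversible)

  # G6P formation/consumption differ in their ATP terms: no merge
  mr34 <- as_macro_reactions(tiso$network)[3:4]
  expect_length(merge_reverse_pairs(mr34), 2L)
  expect_false(any(vapply(merge_reverse_pairs(mr34), `[[`, NA, "reversible")))

  expect_length(merge_reverse_pairs(list()), 0L)
})

test_that("reduced model assembly drops cofactor rows and checks contracts", {
  expect_equal(ncol(tiso$model$K), 8L)
  expect_length(tiso$model$species, 15L)
  expect_false(any(drumr:::TISO_COFACTORS %in% tiso$model$species))

  mrs <- as_macro_reactions(tiso$network)
  all_rows <- suppressWarnings(
    assemble_reduced_model(mrs, accumulating = drumr:::TISO_ACCUMULATING,
                           biomass = "B"))
  expect_length(all_rows$species, 21L)   # nothing dropped

  expect_error(
    assemble_reduced_model(mrs, accumulating = "CARB", biomass = "B",
                           drop = c("CARB", "ATP")),
    "overlap")
  expect_error(
    assemble_reduced_model(mrs, accumulating = "CARB", biomass = "B",
                           drop = "B"),
    "biomass")
})

test_that("reduced-mode counting doubles reversible entries", {
  expect_equal(count_reduced_efms(tiso$model), 11L)
  rev1 <- drumr:::new_macro_reaction("m", c(A = -1, B = 1), reversible = TRUE)
  m1 <- suppressWarnings(assemble_reduced_model(list(rev1), "A", "B"))
  expect_equal(count_reduced_efms(m1), 2L)
  expect_equal(sum(vapply(tiso$model$macro_reactions, `[[`, NA, "reversible")),
               3L)  # MR5, MR6, MR7
})

test_that("K' alpha equals the full K E alpha restricted to retained species", {
  # reduce a toy, then compare reduced-model flux images against the
  # sub-network stoichiometry times its modes
  net <- parse_reaction_table(paste(
    "r1: S -> X", "r2: X -> P1", "r3: X -> P2", sep = "\n"))
  sub <- extract_subnetwork(net, subnetwork_spec("sn", c("r1", "r2", "r3"), "X"))
  mrs <- reduce_subnetwork(sub)
  model <- suppressWarnings(
    assemble_reduced_model(mrs, accumulating = c("P1", "P2"), biomass = "P1",
                           substrates = "S"))
  efms <- enumerate_efms(sub, internal = "X")
  K_sub <- stoichiometric_matrix(sub)
  set.seed(7)
  for (k in 1:5) {
    alpha <- runif(length(mrs))
    lhs <- drop(model$K %*% alpha)
    rhs <- drop(K_sub %*% efms$modes %*% alpha)[model$species]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("reduction output is independent of reaction declaration order", {
  net <- toy_network("diamond")$network
  perm <- drum_network(net$species, rev(net$reactions))
  sub1 <- extract_subnetwork(net, subnetwork_spec(
    "sn", vapply(net$reactions, `[[`, "", "id"), toy_network("diamond")$internal))
  sub2 <- extract_subnetwork(perm, subnetwork_spec(
    "sn", vapply(net$reactions, `[[`, "", "id"), toy_network("diamond")$internal))
  m1 <- reduce_subnetwork(sub1)
  m2 <- reduce_subnetwork(sub2)
  s1 <- lapply(m1, function(m) m$stoich[order(names(m$stoich))])
  s2 <- lapply(m2, function(m) m$stoich[order(names(m$stoich))])
  expect_equal(s1, s2)
})

test_that("reducing single-reaction sub-networks reproduces the input table", {
  # idempotence: each packaged macroscopic reaction, fed as its own
  # sub-network with no internal species, comes back unchanged (2 decimals)
  for (r in tiso$network$reactions) {
    sub <- extract_subnetwork(tiso$network, subnetwork_spec(r$id, r$id))
    mrs <- reduce_subnetwork(sub)
    if (r$reversible) {
      mrs <- merge_reverse_pairs(mrs)
    }
    expect_length(mrs, 1L)
    got <- round(mrs[[1]]$stoich[names(r$stoich)], 2)
    scale <- max(abs(r$stoich)) / max(abs(mrs[[1]]$stoich))
    got2 <- round(mrs[[1]]$stoich[names(r$stoich)] * scale, 2)
    expect_true(max(abs(got2 - r$stoich)) <= 0.005 ||
                  max(abs(-got2 - r$stoich)) <= 0.005)
  }
})

test_that("model JSON round-trips", {
  json <- write_model_json(tiso$model)
  back <- suppressWarnings(read_model_json(json))
  expect_equal(back$species, tiso$model$species)
  expect_equal(back$K, tiso$model$K)
  expect_equal(count_reduced_efms(back), 11L)
})

test_that("partition configs load from YAML and JSON", {
  yml <- tempfile(fileext = ".yml")
  writeLines(c(
    "subnetworks:",
    "  - name: upper",
    "    reactions: [MR3, MR4]",
    "    internal: []",
    "accumulating: [GAP, G6P]",
    "biomass: B",
    "drop: [ATP, ADP]",
    "clamp: [Pi]"), yml)
  cfg <- read_partition(yml)
  expect_length(cfg$subnetworks, 1L)
  expect_equal(cfg$subnetworks[[1]]$reactions, c("MR3", "MR4"))
  expect_equal(cfg$biomass, "B")

  js <- tempfile(fileext = ".json")
  writeLines('{"subnetworks":[{"name":"sn","reactions":["r1"],"internal":["X"]}],
               "accumulating":["A"],"biomass":"B"}', js)
  cfg2 <- read_partition(js)
  expect_equal(cfg2$subnetworks[[1]]$internal, "X")
})
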