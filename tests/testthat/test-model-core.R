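# Domain types, GPR logic, stoichiometric matrix, consistency checks.

test_that("stoichiometric matrix matches its definition on toys", {
  m1 <- newMetabolicModel("r1",
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(reaction("R1", c(A = -1, B = 1), lower = 0)))
  S <- stoichiometricMatrix(m1)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(as.vector(S[, "R1"]), c(-1, 1))

  m0 <- newMetabolicModel("empty",
    metabolites = data.frame(id = character()), reactions = list())
  expect_equal(dim(stoichiometricMatrix(m0)), c(0L, 0L))

  m3 <- newMetabolicModel("chain3",
    metabolites = data.frame(id = c("A_ex", "A", "B", "B_ex"),
                             compartment = c("external", "internal",
                                             "internal", "external")),
    reactions = list(
      reaction("t_in", c(A_ex = -1, A = 1), lower = 0, kind = "transport"),
      reaction("cnv", c(A = -1, B = 1), lower = 0),
      reaction("t_out", c(B = -1, B_ex = 1), lower = 0,
               kind = "transport")))
  S3 <- stoichiometricMatrix(m3)
  expect_equal(rownames(S3), c("A", "B"))
  expect_equal(unname(as.matrix(S3)),
               rbind(c(1, -1, 0), c(0, 1, -1)))
})

test_that("concatenating two models block-diagonalizes the matrix", {
  a <- toy_chain()
  b <- toy_parallel()
  met <- rbind(
    data.frame(metabolites(a)[, c("id", "compartment")]),
    within(metabolites(b)[, c("id", "compartment")],
           id <- paste0("b_", id)))
  rx <- c(
    lapply(seq_len(nrow(reactions(a))), function(j) {
      st <- a@stoichiometry[, j]; st <- st[st != 0]
      reaction(reactions(a)$id[j], st, lower = reactions(a)$lower[j],
               upper = reactions(a)$upper[j], kind = reactions(a)$kind[j])
    }),
    lapply(seq_len(nrow(reactions(b))), function(j) {
      st <- b@stoichiometry[, j]; st <- st[st != 0]
      names(st) <- paste0("b_", names(st))
      reaction(paste0("b_", reactions(b)$id[j]), st,
               lower = reactions(b)$lower[j],
               upper = reactions(b)$upper[j], kind = reactions(b)$kind[j])
    }))
  m <- newMetabolicModel("cat", met, rx)
  S <- as.matrix(stoichiometricMatrix(m))
  na <- nrow(metabolites(a)); ra <- nrow(reactions(a))
  expect_equal(S[seq_len(na), seq_len(ra)],
               as.matrix(stoichiometricMatrix(a)),
               ignore_attr = TRUE)
  expect_true(all(S[seq_len(na), -seq_len(ra)] == 0))
  expect_true(all(S[-seq_len(na), seq_len(ra)] == 0))
  expect_equal(unname(S[-seq_len(na), -seq_len(ra)]),
               unname(as.matrix(stoichiometricMatrix(b))))
})

test_that("unknown metabolite references are a structural error", {
  expect_error(
    newMetabolicModel("bad", data.frame(id = "A"),
                      list(reaction("R1", c(A = -1, Z = 1)))),
    "R1.*unknown metabolite|unknown metabolite.*R1")
})

test_that("GPR evaluation implements AND/OR over deletions", {
  expect_false(evaluateGpr("gA and gB", c("gA")))
  expect_true(evaluateGpr("gA or gB", c("gA")))
  expect_false(evaluateGpr("(gA and gB) or gC", c("gA", "gC")))
  expect_true(evaluateGpr("(gA and gB) or gC", c("gC")))
  expect_true(evaluateGpr("", c("gA")))       # no gene association
  expect_true(evaluateGpr(NA_character_, "gA"))
  # empty deletion set: always catalyzable
  for (rule in c("gA", "gA and gB", "(gA or gB) and (gC or gD)"))
    expect_true(evaluateGpr(rule, character()))
  # parse/deparse round trip preserves semantics
  rule <- "(gA and gB) or (gC and gD) or gE"
  expect_identical(parseGpr(deparseGpr(parseGpr(rule))), parseGpr(rule))
  expect_error(parseGpr("gA and (gB"), "parenthes|malformed")
  expect_error(parseGpr("and gA"), "malformed")
})

test_that("elemental balance sums coefficient times atom count", {
  m <- newMetabolicModel("bal",
    metabolites = data.frame(
      id = c("mal", "pyr", "co2", "big", "small", "mys"),
      formula = c("C4H4O5", "C3H3O3", "CO2", "C6", "C3", NA)),
    reactions = list(
      reaction("decarb", c(mal = -1, pyr = 1, co2 = 1), lower = 0),
      reaction("halve", c(big = -1, small = 1), lower = 0),
      reaction("dark", c(mys = -1, small = 1), lower = 0),
      reaction("EX_co2", c(co2 = -1), lower = 0, kind = "exchange")))
  res <- checkElementalBalance(m)
  # carbon and oxygen balance; only the deliberately omitted hydrogen
  # (cofactors left out of the toy) shows up
  expect_false("C" %in% names(res$imbalances$decarb))
  expect_false("O" %in% names(res$imbalances$decarb))
  expect_equal(res$imbalances$decarb[["H"]], -1)
  expect_equal(res$imbalances$halve[["C"]], -3)
  expect_equal(res$unknown, "dark")
  expect_false("EX_co2" %in% names(res$imbalances))  # boundary skipped
})

test_that("parseFormula handles the element grammar and rejects junk", {
  expect_equal(parseFormula("C4H6O5")[["C"]], 4L)
  expect_equal(parseFormula("H2O"),
               c(C = 0L, H = 2L, N = 0L, O = 1L, P = 0L, S = 0L))
  expect_equal(sum(parseFormula("C21H36N7O16P3S")), 84L)
  expect_error(parseFormula("C4X2"), "unsupported element")
  expect_error(parseFormula(NA_character_), "empty")
})

test_that("network gap report finds orphans, dead ends, and cycles", {
  # chain ending in an unconsumed internal metabolite
  m <- newMetabolicModel("gappy",
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(
      reaction("up", c(A = 1), lower = 0, upper = 10, kind = "exchange"),
      reaction("cnv", c(A = -1, B = 1), lower = 0)))
  g <- findNetworkGaps(m)
  expect_equal(g$orphan_never_consumed, "B")
  expect_true("cnv" %in% g$dead_end_reactions)
  expect_false(g$clean)

  # irreversible 2-cycle carries flux with closed boundaries
  g2 <- findNetworkGaps(toy_with_cycle())
  expect_setequal(g2$balanced_cycle_reactions, c("loop_f", "loop_b"))
  expect_false(g2$clean)

  # clean toy
  g3 <- findNetworkGaps(toy_chain())
  expect_true(g3$clean)
})

test_that("model validity enforces the documented invariants", {
  expect_error(
    newMetabolicModel("dup", data.frame(id = "A"),
                      list(reaction("R", c(A = 1)),
                           reaction("R", c(A = -1)))),
    "duplicate reaction")
  expect_error(
    validObject(newMetabolicModel(
      "badb", data.frame(id = "A"),
      list(reaction("R", c(A = 1), lower = 5, upper = 1)))),
    "lower bound exceeds")
  expect_error(
    validObject(newMetabolicModel(
      "badex", data.frame(id = c("A", "B")),
      list(reaction("EX", c(A = -1, B = 1), kind = "exchange")))),
    "exactly one metabolite")
  expect_error(
    validObject(newMetabolicModel(
      "badg", data.frame(id = "A"),
      list(reaction("R", c(A = 1), gpr = "gZ")), genes = "gA")),
    "unknown gene")
})
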