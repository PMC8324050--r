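# FBA, L1 minimization, FVA, shadow prices, phase planes, gene deletion,
# ensembles.

test_that("FBA solves toy problems and reports status honestly", {
  f <- solveFBA(toy_chain(cap = 10), objective = "out")
  expect_equal(f@status, "optimal")
  expect_equal(f@objectiveValue, 10, tolerance = 1e-9)
  expect_equal(unname(f@fluxes[c("up", "cnv", "out")]), c(10, 10, 10),
               tolerance = 1e-9)

  # contradictory equality bounds make the problem infeasible
  m <- toy_chain(cap = 10)
  sc <- scenarioConstraints("bad", data.frame(
    reaction_id = c("up", "out"), lower = c(5, 8), upper = c(5, 8)))
  f2 <- solveFBA(m, sc, objective = "out")
  expect_equal(f2@status, "infeasible")
  expect_length(f2@fluxes, 0)
})

test_that("FBA optimum agrees with a brute-force vertex oracle", {
  set.seed(41)
  checked <- 0
  for (k in 1:40) {
    n <- sample(3:6, 1); mrow <- sample(1:3, 1)
    A <- matrix(round(runif(mrow * n, -2, 2)), mrow, n)
    lb <- round(runif(n, -5, 0)); ub <- lb + round(runif(n, 1, 8))
    x0 <- lb + runif(n) * (ub - lb)
    b0 <- as.vector(A %*% x0)
    cc <- round(runif(n, -5, 5))
    oracle <- brute_lp(A, b0, lb, ub, cc)
    if (is.na(oracle)) next
    r <- BacteroidFBA:::.lp(A, lb, ub, cc, b = b0)
    expect_equal(r$status, "optimal")
    expect_equal(r$obj, oracle, tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 20)
})

test_that("L1 minimization removes cycle flux and preserves the optimum", {
  m <- toy_with_cycle(cap = 5)
  plain <- solveFBA(m, objective = "out")
  l1 <- solveFBAL1(m, objective = "out")
  expect_equal(l1@objectiveValue, plain@objectiveValue,
               tolerance = 1e-9)
  expect_equal(unname(l1@fluxes[c("loop_f", "loop_b")]), c(0, 0),
               tolerance = 1e-9)
  # a unique-optimum toy: L1 result identical to plain FBA
  u <- solveFBAL1(toy_chain(), objective = "out")
  expect_equal(u@fluxes, solveFBA(toy_chain(), objective = "out")@fluxes,
               tolerance = 1e-9)
  # equal parallel paths: total taxicab norm equals the single-path norm
  p <- solveFBAL1(toy_parallel(10), objective = "out")
  expect_equal(sum(abs(p@fluxes)), 4 * 10, tolerance = 1e-8)
})

test_that("FVA brackets fluxes and detects blocked/coupled reactions", {
  m <- newMetabolicModel("blocked",
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = list(
      reaction("up", c(A = 1), lower = 0, upper = 10, kind = "exchange"),
      reaction("cnv", c(A = -1, B = 1), lower = 0),
      reaction("out", c(B = -1), lower = 0, kind = "exchange"),
      reaction("dead", c(B = -1, C = 1), lower = 0)))
  fv <- fluxVariability(m, objective = "out", fractionOfOptimum = 1)
  rng <- fv@ranges
  expect_equal(rng$min[rng$reaction == "dead"], 0, tolerance = 1e-9)
  expect_equal(rng$max[rng$reaction == "dead"], 0, tolerance = 1e-9)
  # unique-path reactions are coupled to the objective at fraction 1
  expect_equal(rng$min[rng$reaction == "cnv"], 10, tolerance = 1e-8)
  expect_equal(rng$max[rng$reaction == "cnv"], 10, tolerance = 1e-8)

  fvp <- fluxVariability(toy_parallel(10), objective = "out",
                         fractionOfOptimum = 1)
  rp <- fvp@ranges
  for (r in c("p1a", "p2a")) {
    expect_equal(rp$min[rp$reaction == r], 0, tolerance = 1e-8)
    expect_equal(rp$max[rp$reaction == r], 10, tolerance = 1e-8)
  }
})

test_that("FVA intervals contain the L1 flux for every reaction", {
  m <- buildCoreBacteroidModel()
  sc <- bacteroidScenario("malate", carbonUptake = 4, o2 = 3)
  l1 <- solveFBAL1(m, sc)
  fv <- fluxVariability(m, sc, objective = "NITROGENASE",
                        fractionOfOptimum = 1)
  rng <- fv@ranges
  v <- l1@fluxes[rng$reaction]
  expect_true(all(v >= rng$min - 1e-6))
  expect_true(all(v <= rng$max + 1e-6))
})

test_that("loopless FVA excludes cycle-only flux", {
  m <- toy_with_cycle(cap = 5)
  fv <- fluxVariability(m, objective = "out", fractionOfOptimum = 1,
                        loopless = TRUE)
  rng <- fv@ranges
  expect_equal(rng$max[rng$reaction == "loop_f"], 0, tolerance = 1e-8)
  expect_equal(rng$cycle_excluded_max[rng$reaction == "loop_f"], 1000,
               tolerance = 1e-6)
  expect_equal(rng$max[rng$reaction == "out"], 5, tolerance = 1e-8)
})

test_that("shadow prices match finite differences and scale with the objective", {
  m <- toy_chain(cap = 10)
  sc <- scenarioConstraints("uptake", data.frame(
    reaction_id = "up", lower = 0, upper = 4))
  # rebuild with 'up' as exchange written in uptake convention
  m2 <- newMetabolicModel("updown",
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(
      reaction("EX_A", c(A = -1), lower = -4, upper = 0,
               kind = "exchange"),
      reaction("cnv", c(A = -1, B = 1), lower = 0),
      reaction("EX_B", c(B = -1), lower = 0, kind = "exchange")))
  sp <- shadowPrices(m2, objective = "EX_B", check = TRUE)
  pA <- sp$price[sp$metabolite == "A"]
  expect_gt(pA, 0)
  expect_false(sp$degenerate[sp$metabolite == "A"])
  # finite-difference oracle at eps = 1e-4
  eps <- 1e-4
  m3 <- setBounds(m2, "EX_A", lower = -4 - eps)
  fd <- (solveFBA(m3, objective = "EX_B")@objectiveValue -
           solveFBA(m2, objective = "EX_B")@objectiveValue) / eps
  expect_equal(pA, fd, tolerance = 1e-6)
  # homogeneity: doubling objective weights doubles every price
  sp2 <- shadowPrices(m2, objective = c(EX_B = 2))
  expect_equal(sp2$price, 2 * sp$price, tolerance = 1e-9)
  # non-binding bound has zero price
  m4 <- setBounds(m2, "EX_A", lower = -1000)
  m4 <- setBounds(m4, "cnv", upper = 3)
  sp4 <- shadowPrices(m4, objective = "EX_B")
  expect_equal(sp4$price[sp4$metabolite == "A"], 0)
})

test_that("phase plane segmentation labels connected sign regions", {
  # single substrate: B axis never limiting -> one phase
  m <- newMetabolicModel("two_ex",
    metabolites = data.frame(id = c("A", "B", "P")),
    reactions = list(
      reaction("EX_A", c(A = -1), lower = -10, upper = 0,
               kind = "exchange"),
      reaction("EX_B", c(B = -1), lower = -10, upper = 0,
               kind = "exchange"),
      reaction("useA", c(A = -1, P = 1), lower = 0),
      reaction("sinkB", c(B = -1), lower = 0, kind = "demand"),
      reaction("EX_P", c(P = -1), lower = 0, kind = "exchange")))
  pp <- phasePlane(m, "EX_A", "EX_B", seq(1, 5, 1), seq(1, 5, 1),
                   objective = "EX_P")
  expect_equal(nPhases(pp), 1L)
  expect_equal(pp@objective[3, 2], 3, tolerance = 1e-9)

  # two substrates consumed by one product reaction in 1:1 ratio:
  # switchover at the diagonal gives exactly two phases
  m2 <- newMetabolicModel("switch",
    metabolites = data.frame(id = c("A", "B", "P")),
    reactions = list(
      reaction("EX_A", c(A = -1), lower = -10, upper = 0,
               kind = "exchange"),
      reaction("EX_B", c(B = -1), lower = -10, upper = 0,
               kind = "exchange"),
      reaction("mix", c(A = -1, B = -1, P = 1), lower = 0),
      reaction("spillA", c(A = -1), lower = 0, kind = "demand"),
      reaction("spillB", c(B = -1), lower = 0, kind = "demand"),
      reaction("EX_P", c(P = -1), lower = 0, kind = "exchange")))
  grid <- c(1, 2, 3.5, 5)
  pp2 <- phasePlane(m2, "EX_A", "EX_B", grid, grid, objective = "EX_P")
  expect_equal(nPhases(pp2), 2L)
  # objective is min(a, b); duals match the analytic solution off the
  # diagonal: limiting substrate has price 1, the other 0
  expect_equal(pp2@objective[1, 3], 1, tolerance = 1e-9)
  expect_equal(pp2@shadowA[1, 3], 1, tolerance = 1e-6)
  expect_equal(pp2@shadowB[1, 3], 0, tolerance = 1e-6)
  expect_equal(pp2@shadowA[3, 1], 0, tolerance = 1e-6)
  expect_equal(pp2@shadowB[3, 1], 1, tolerance = 1e-6)
})

test_that("gene deletion follows GPR logic", {
  m <- newMetabolicModel("gpr",
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(
      reaction("up", c(A = 1), lower = 0, upper = 10, kind = "exchange"),
      reaction("nit", c(A = -1, B = 1), lower = 0,
               gpr = "(g1 and g2) or g3"),
      reaction("out", c(B = -1), lower = 0, kind = "exchange")),
    nitrogenase = "nit")
  del <- singleGeneDeletion(m)
  ess <- setNames(del$essential, del$gene)
  expect_false(ess[["g1"]])  # isozyme g3 still works
  expect_false(ess[["g3"]])
  m2 <- m
  m2@reactions$gpr[2] <- "g1 and g2"
  m2@genes <- c("g1", "g2")
  del2 <- singleGeneDeletion(m2)
  expect_true(all(del2$essential))
  expect_lt(max(del2$max_flux), 1e-6)
})

test_that("seeded ensembles are reproducible and respect blocked reactions", {
  m <- newMetabolicModel("ens",
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = list(
      reaction("up", c(A = 1), lower = 0, upper = 10, kind = "exchange"),
      reaction("r1", c(A = -1, B = 1), lower = 0),
      reaction("out", c(B = -1), lower = 0, kind = "exchange"),
      reaction("blocked", c(B = -1, C = 1), lower = 0)))
  spec <- ensembleSpec(nObjectives = 25, seed = 7, minNitrogenase = NA)
  e1 <- randomObjectiveEnsemble(m, spec, "up", c(2, 5))
  e2 <- randomObjectiveEnsemble(m, spec, "up", c(2, 5))
  expect_identical(e1, e2)   # bitwise reproducible
  s <- e1$summary
  expect_equal(s$mean[s$reaction == "blocked"], c(0, 0), tolerance = 1e-9)
  expect_equal(s$sd[s$reaction == "blocked"], c(0, 0), tolerance = 1e-9)
})

test_that("ensemble means are stable under doubling on a toy", {
  m <- toy_parallel(10)
  run <- function(n) {
    spec <- ensembleSpec(nObjectives = n, seed = 5, minNitrogenase = NA)
    randomObjectiveEnsemble(m, spec, "up", 6, track = "out")$summary
  }
  a <- run(60); b <- run(120)
  se <- a$sd / sqrt(a$n_feasible)
  expect_lt(abs(a$mean - b$mean), 3 * max(se, 1e-12))
})
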