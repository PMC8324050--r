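# Elementary conversion mode enumeration.

test_that("single-path and branched toys enumerate correctly", {
  e <- enumerateEcms(toy_chain(), ecmConfig(inputs = "A", outputs = "B"))
  expect_equal(conversionMatrix(e),
               matrix(c(-1, 1), 1, dimnames = list(NULL, c("A", "B"))))

  m2 <- newMetabolicModel("branch",
    metabolites = data.frame(id = c("M", "P", "X", "C")),
    reactions = list(
      reaction("EX_M", c(M = -1), lower = -10, upper = 0,
               kind = "exchange"),
      reaction("r1", c(M = -1, P = 1, C = 1), lower = 0),
      reaction("r2", c(P = -1, C = 3), lower = 0),
      reaction("r3", c(P = -1, X = 1), lower = 0),
      reaction("EX_X", c(X = -1), lower = 0, kind = "exchange"),
      reaction("EX_C", c(C = -1), lower = 0, kind = "exchange")))
  cfg <- ecmConfig(inputs = "M", outputs = c("X", "C"))
  got <- conversionMatrix(enumerateEcms(m2, cfg))
  expect_same_conversions(got, brute_ecms(m2, cfg))
})

test_that("enumeration equals the brute-force oracle on assorted toys", {
  toys <- list(
    list(model = toy_parallel(),
         cfg = ecmConfig(inputs = "A", outputs = "B")),
    list(model = toy_with_cycle(),
         cfg = ecmConfig(inputs = "A", outputs = "B")),
    # reversible interconversion with two boundary metabolites
    list(model = newMetabolicModel("rev",
      metabolites = data.frame(id = c("A", "B", "C")),
      reactions = list(
        reaction("EX_A", c(A = -1), lower = -5, upper = 5,
                 kind = "exchange"),
        reaction("r1", c(A = -1, B = 1), lower = -1000),
        reaction("r2", c(B = -1, C = 2), lower = 0),
        reaction("EX_C", c(C = -1), lower = 0, kind = "exchange"))),
      cfg = ecmConfig(free = "A", outputs = "C")),
    # diamond with unequal route stoichiometry and a byproduct
    list(model = newMetabolicModel("diamond",
      metabolites = data.frame(id = c("S", "I1", "I2", "P", "W")),
      reactions = list(
        reaction("EX_S", c(S = -1), lower = -10, upper = 0,
                 kind = "exchange"),
        reaction("a1", c(S = -1, I1 = 1), lower = 0),
        reaction("a2", c(I1 = -1, P = 1, W = 1), lower = 0),
        reaction("b1", c(S = -2, I2 = 1), lower = 0),
        reaction("b2", c(I2 = -1, P = 3), lower = 0),
        reaction("EX_P", c(P = -1), lower = 0, kind = "exchange"),
        reaction("EX_W", c(W = -1), lower = 0, kind = "exchange"))),
      cfg = ecmConfig(inputs = "S", outputs = c("P", "W"))),
    # cofactor-coupled pair of conversions
    list(model = newMetabolicModel("cof",
      metabolites = data.frame(id = c("A", "B", "X", "Y", "N", "NH")),
      reactions = list(
        reaction("EX_A", c(A = -1), lower = -10, upper = 0,
                 kind = "exchange"),
        reaction("EX_X", c(X = -1), lower = -10, upper = 0,
                 kind = "exchange"),
        reaction("ra", c(A = -1, N = -1, B = 1, NH = 1), lower = 0),
        reaction("rx", c(X = -1, NH = -1, Y = 1, N = 1), lower = 0),
        reaction("EX_B", c(B = -1), lower = 0, kind = "exchange"),
        reaction("EX_Y", c(Y = -1), lower = 0, kind = "exchange"))),
      cfg = ecmConfig(inputs = c("A", "X"), outputs = c("B", "Y")))
  )
  for (t in toys) {
    got <- conversionMatrix(enumerateEcms(t$model, t$cfg))
    want <- brute_ecms(t$model, t$cfg)
    expect_same_conversions(got, want)
  }
})

test_that("hiding a metabolite equals giving it a free boundary", {
  m <- newMetabolicModel("hide",
    metabolites = data.frame(id = c("M", "P", "X", "C")),
    reactions = list(
      reaction("EX_M", c(M = -1), lower = -10, upper = 0,
               kind = "exchange"),
      reaction("r1", c(M = -1, P = 1, C = 1), lower = 0),
      reaction("r2", c(P = -1, C = 3), lower = 0),
      reaction("r3", c(P = -1, C = -1, X = 2), lower = 0),
      reaction("EX_X", c(X = -1), lower = 0, kind = "exchange"),
      reaction("EX_C", c(C = -1), lower = -10, upper = 10,
               kind = "exchange")))
  hidden <- enumerateEcms(m, ecmConfig(inputs = "M", outputs = "X",
                                       hidden = "C"))
  # reference: C tracked as free, then projected away and re-reduced
  freeC <- enumerateEcms(m, ecmConfig(inputs = "M", outputs = "X",
                                      free = "C"))
  proj <- conversionMatrix(freeC)[, c("M", "X"), drop = FALSE]
  proj <- proj[rowSums(abs(proj)) > 0, , drop = FALSE]
  # the hidden-run ECMs must all appear in the projection and vice versa
  # up to conic reduction; compare the generated cones via membership
  norm_rows <- function(M) unique(t(apply(M, 1, function(v)
    v / max(abs(v)))))
  H <- norm_rows(conversionMatrix(hidden))
  Pm <- norm_rows(proj)
  in_cone <- function(v, G) {
    p <- tryCatch(pracma::linprog(rep(0, nrow(G)), Aeq = t(G), beq = v,
                                  maxiter = 500),
                  error = function(e) NULL)
    !is.null(p) && p$errno == 1 && max(abs(t(G) %*% p$x - v)) < 1e-6
  }
  expect_true(all(apply(H, 1, in_cone, G = Pm)))
  expect_true(all(apply(Pm, 1, in_cone, G = H)))
  expect_false("C" %in% colnames(conversionMatrix(hidden)))
})

test_that("every synthetic-model conversion conserves C, N and O", {
  m <- buildCoreBacteroidModel()
  e <- enumerateEcms(m, ecmConfig(
    inputs = c("mal", "succ", "o2", "n2", "gaba"),
    outputs = c("nh3", "ala", "asp", "phb", "glycg", "palm", "lipid",
                "co2", "h2"),
    free = "h2o"))
  cm <- conversionMatrix(e)
  expect_gt(nrow(cm), 0)
  for (el in c("C", "N", "O", "H")) {
    counts <- vapply(colnames(cm), function(id)
      parseFormula(e@formulas[[id]])[[el]], numeric(1))
    net <- as.vector(cm %*% counts)
    expect_equal(net, rep(0, nrow(cm)), tolerance = 1e-9,
                 label = paste("net", el))
  }
  # conversions exist producing each expected product
  for (prod in c("nh3", "ala", "asp", "phb", "glycg", "palm", "lipid"))
    expect_gt(sum(cm[, prod] > 0), 0, label = prod)
})

test_that("returned conversions are elementary: none decomposes into the others", {
  m <- buildCoreBacteroidModel()
  e <- enumerateEcms(m, ecmConfig(
    inputs = c("mal", "o2", "n2"),
    outputs = c("nh3", "ala", "phb", "co2", "h2"), free = "h2o"))
  cm <- conversionMatrix(e)
  expect_gt(nrow(cm), 2)
  # no duplicated rays up to positive scaling
  norm <- t(apply(cm, 1, function(v) v / max(abs(v))))
  expect_equal(nrow(unique(round(norm, 8))), nrow(cm))
  # independent LP: no conversion is a nonnegative combination of the
  # others (extremality in the conversion cone)
  for (i in seq_len(nrow(cm))) {
    others <- t(cm[-i, , drop = FALSE])
    p <- tryCatch(
      pracma::linprog(rep(0, ncol(others)), Aeq = others,
                      beq = cm[i, ], maxiter = 500),
      error = function(e) NULL)
    decomposable <- !is.null(p) && p$errno == 1 &&
      max(abs(others %*% p$x - cm[i, ])) < 1e-6
    expect_false(decomposable, label = paste("conversion", i))
  }
})

test_that("flux trackers report the tracked reaction's flux", {
  m <- buildCoreBacteroidModel()
  mt <- addFluxTracker(m, "GS", "gs_trk")
  expect_error(addFluxTracker(m, "GS", "mal"), "collides")
  expect_error(addFluxTracker(m, "NOPE", "t"), "unknown reaction")
  cfg <- ecmConfig(inputs = c("mal", "o2", "n2"),
                   outputs = c("nh3", "ala", "asp", "glu", "phb", "co2",
                               "h2", "gs_trk"),
                   free = "h2o")
  e <- enumerateEcms(mt, cfg)
  cm <- conversionMatrix(e)
  expect_true("gs_trk" %in% colnames(cm))
  expect_true(all(cm[, "gs_trk"] >= 0))
  # conversions without glutamine-route nitrogen carry a zero tracker
  expect_gt(sum(cm[, "gs_trk"] == 0), 0)
  expect_gt(sum(cm[, "gs_trk"] > 0), 0)

  # forced-tracking toy: tracked reaction carries the whole input flux
  mtoy <- addFluxTracker(toy_chain(), "cnv", "trk")
  e2 <- enumerateEcms(mtoy, ecmConfig(inputs = "A",
                                      outputs = c("B", "trk")))
  cm2 <- conversionMatrix(e2)
  expect_equal(unname(cm2[1, "trk"]), unname(abs(cm2[1, "A"])))

  # deleting the tracker column recovers the untracked ECM set
  cfg0 <- ecmConfig(inputs = c("mal", "o2", "n2"),
                    outputs = c("nh3", "ala", "asp", "glu", "phb", "co2",
                                "h2"),
                    free = "h2o")
  e0 <- enumerateEcms(m, cfg0)
  projected <- conversionMatrix(e)[, colnames(conversionMatrix(e0)),
                                   drop = FALSE]
  key <- function(M) sort(unique(apply(M, 1, function(v) {
    v <- v / max(abs(v)); paste(round(v, 6), collapse = ",")
  })))
  expect_true(all(key(conversionMatrix(e0)) %in% key(projected)))
})

test_that("conversion normalization preserves ratios and metrics", {
  cs <- new("ConversionSet",
            coefficients = matrix(c(-2, 8), 1,
                                  dimnames = list(NULL, c("mal", "co2"))),
            formulas = c(mal = "C4H6O5", co2 = "CO2"),
            trackers = character(), normalization = "none")
  n1 <- normalizeConversions(cs, "unit_carbon_input")
  expect_equal(unname(n1@coefficients[1, ]), c(-0.25, 1))
  n2 <- normalizeConversions(cs, "unit_max_coeff")
  expect_equal(unname(n2@coefficients[1, ]), c(-0.25, 1))

  m <- buildCoreBacteroidModel()
  e <- enumerateEcms(m, ecmConfig(inputs = c("mal", "o2", "n2"),
                                  outputs = c("nh3", "ala", "phb", "co2",
                                              "h2"),
                                  free = "h2o"))
  raw <- conversionMetrics(e, polymer_ids = "phb",
                           amino_acid_ids = "ala")
  nrm <- conversionMetrics(normalizeConversions(e, "unit_carbon_input"),
                           polymer_ids = "phb", amino_acid_ids = "ala")
  expect_equal(nrm$o2_per_carbon, raw$o2_per_carbon, tolerance = 1e-9)
  expect_equal(nrm$carbon_cost_g_per_g_n, raw$carbon_cost_g_per_g_n,
               tolerance = 1e-9)

  zero <- new("ConversionSet",
              coefficients = matrix(0, 1, 2,
                                    dimnames = list(NULL, c("a", "b"))),
              formulas = c(a = "C1", b = "C1"),
              trackers = character(), normalization = "none")
  expect_error(normalizeConversions(zero, "unit_max_coeff"), "all-zero")
  expect_error(normalizeConversions(zero, "unit_carbon_input"),
               "no carbon")
})
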