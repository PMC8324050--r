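# Conversion metrics, classification, filters, Spearman correlation.

.mk_set <- function(rows, formulas, trackers = character()) {
  new("ConversionSet",
      coefficients = rows, formulas = formulas, trackers = trackers,
      normalization = "none")
}

.FORM <- c(mal = "C4H6O5", co2 = "CO2", nh3 = "NH3", n2 = "N2",
           o2 = "O2", ala = "C3H7NO2", asp = "C4H7NO4", ser = "C3H7NO3",
           gaba = "C4H9NO2", phb = "C4H6O2", h2o = "H2O")

.row <- function(...) {
  v <- c(...)
  full <- setNames(numeric(length(.FORM)), names(.FORM))
  full[names(v)] <- v
  matrix(full, 1, dimnames = list(NULL, names(full)))
}

test_that("element flux sums atoms per side", {
  s <- .mk_set(.row(mal = -1, co2 = 4), .FORM)
  expect_equal(elementFlux(s, "C", "input"), 4)
  expect_equal(elementFlux(s, "C", "output"), 4)
  s2 <- .mk_set(.row(n2 = -1, nh3 = 2), .FORM)
  expect_equal(elementFlux(s2, "N", "output"), 2)
  expect_equal(elementFlux(s2, "C", "input"), 0)
  # missing formula on a participant is an error naming the metabolite
  bad <- .mk_set(.row(mal = -1, co2 = 4),
                 replace(.FORM, "mal", NA_character_))
  expect_error(elementFlux(bad, "C", "input"), "'mal'")
})

test_that("carbon cost follows the crediting rule", {
  # all carbon to CO2 (uncredited): 4 C in, 2 N out
  s1 <- .mk_set(.row(mal = -1, n2 = -1, nh3 = 2, co2 = 4, o2 = -3),
                .FORM)
  cost1 <- carbonCostPerNitrogen(s1)
  expect_equal(cost1$carbon_cost_g_per_g_n,
               12.011 * 4 / (14.007 * 2), tolerance = 1e-9)
  expect_equal(cost1$net_n_out, 2)
  # secreted alanine is credited
  s2 <- .mk_set(.row(mal = -1, n2 = -0.5, ala = 1, co2 = 1, o2 = -2),
                .FORM)
  cost2 <- carbonCostPerNitrogen(s2)
  expect_equal(cost2$carbon_cost_g_per_g_n,
               12.011 * (4 - 3) / (14.007 * 1), tolerance = 1e-9)
  # polymers are NOT credited: their carbon counts toward the cost
  s3 <- .mk_set(.row(mal = -2, n2 = -1, nh3 = 2, phb = 1, co2 = 4,
                     o2 = -3), .FORM)
  cost3 <- carbonCostPerNitrogen(s3, polymer_ids = "phb")
  expect_equal(cost3$carbon_cost_g_per_g_n,
               12.011 * 8 / (14.007 * 2), tolerance = 1e-9)
  cost3b <- carbonCostPerNitrogen(s3, polymer_ids = "phb",
                                  credit_polymers = TRUE)
  expect_equal(cost3b$carbon_cost_g_per_g_n,
               12.011 * 4 / (14.007 * 2), tolerance = 1e-9)
  # organic N input reduces net N; N2 itself does not count as organic
  s4 <- .mk_set(.row(ser = -2, n2 = -1, nh3 = 3, co2 = 6, o2 = -3),
                .FORM)
  expect_equal(carbonCostPerNitrogen(s4)$net_n_out, 1)
  # no net nitrogen: undefined cost, still reportable
  s5 <- .mk_set(.row(mal = -1, co2 = 4, o2 = -3), .FORM)
  expect_true(is.na(carbonCostPerNitrogen(s5)$carbon_cost_g_per_g_n))
})

test_that("classification flags follow their definitions", {
  rows <- rbind(
    .row(mal = -1, n2 = -1, nh3 = 2, phb = 1, co2 = 2, o2 = -2),
    .row(mal = -1, n2 = -1, nh3 = 2, co2 = 4, o2 = -3),
    .row(mal = -1, n2 = -1, ala = 1, nh3 = 1, co2 = 1, o2 = -2),
    .row(gaba = -1, mal = -1, n2 = -1, nh3 = 3, co2 = 8, o2 = -4))
  s <- .mk_set(rows, .FORM)
  cls <- classifyConversion(s, polymer_ids = "phb",
                            amino_acid_ids = c("ala", "asp", "gaba"))
  expect_equal(cls$polymer_producing, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cls$ammonia_only, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(cls$amino_acid_secreting, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(cls$amino_acid_consuming, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("biological filters reject on cost, amino inputs and net N", {
  rows <- rbind(
    ok = .row(mal = -1, n2 = -1, nh3 = 2, co2 = 4, o2 = -3),
    # 45 g C per g N: 2 mal in, all to CO2, tiny N out
    costly = .row(mal = -2.625, n2 = -0.1, nh3 = 0.2, co2 = 10.5,
                  o2 = -7),
    twoaa = .row(ala = -1, gaba = -1, n2 = -1, nh3 = 4, co2 = 7,
                 o2 = -4),
    negn = .row(ser = -2, nh3 = 1, co2 = 6, o2 = -3))
  s <- .mk_set(rows, .FORM)
  res <- filterConversions(s, polymer_ids = "phb",
                           amino_acid_ids = c("ala", "gaba", "ser"))
  expect_equal(res$kept_index, 1L)
  expect_true(any(res$rejections$conversion == 2 &
                    res$rejections$reason == "cost"))
  expect_true(any(res$rejections$conversion == 3 &
                    res$rejections$reason == "amino_acid_inputs"))
  expect_true(any(res$rejections$conversion == 4 &
                    res$rejections$reason == "net_nitrogen"))
  # check the costly row really is ~45 g/g
  expect_gt(carbonCostPerNitrogen(s)$carbon_cost_g_per_g_n[2], 40)
})

test_that("Spearman correlation matches limits and the permutation oracle", {
  up <- spearmanCorrelation(1:8, (1:8)^2)
  expect_equal(up$rho, 1)
  down <- spearmanCorrelation(1:8, -(1:8)^3)
  expect_equal(down$rho, -1)
  # tied data, n = 6: exact p equals exhaustive permutation
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(2, 1, 3, 3, 5, 4)
  got <- spearmanCorrelation(x, y)
  oracle <- spearman_perm_oracle(x, y)
  expect_equal(got$rho, oracle$rho, tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(got$method, "exact permutation")
  # rho itself agrees with the standard implementation
  expect_equal(got$rho,
               suppressWarnings(cor.test(x, y,
                                         method = "spearman")$estimate),
               tolerance = 1e-12, ignore_attr = TRUE)
  # large n: t approximation
  set.seed(2)
  xx <- rnorm(40); yy <- xx + rnorm(40)
  big <- spearmanCorrelation(xx, yy)
  expect_equal(big$method, "t approximation")
  ct <- suppressWarnings(cor.test(xx, yy, method = "spearman"))
  expect_equal(big$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_lt(big$p_value, 0.01)
  # constant vector flagged
  expect_warning(res <- spearmanCorrelation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})
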