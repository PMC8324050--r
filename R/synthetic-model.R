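# Programmatic generator of a fully specified synthetic core-bacteroid
# model, plus ground-truth essentiality and mock experimental calls.
#
# The network emulates the pathway content of a nitrogen-fixing rhizobial
# bacteroid: dicarboxylate uptake, a full TCA cycle, malic enzyme and
# pyruvate dehydrogenase, gluconeogenesis, a lumped pentose phosphate
# branch, electron transport with configurable P/O ratios, nitrogenase,
# GS-GOGAT, alanine dehydrogenase, aspartate transaminase, storage polymer
# synthesis (PHB, glycogen, palmitate, glycerolipid), GABA and sugar
# catabolism, and amino-acid demand reactions.
#
# Element bookkeeping: real metabolites carry their free-acid formulas.
# Redox carriers are modeled as conserved moiety pairs whose reduced form
# carries the transferred hydrogens (NADH stands for NADH + H+, i.e. the
# pair differs by H2; ferredoxin is a one-electron carrier differing by
# H). This makes every internal reaction exactly balanced in C/H/N/O/P/S,
# which checkElementalBalance() verifies.

#' Configuration for the synthetic core-bacteroid model
#'
#' @param carbon_sources subset of \code{c("malate", "succinate",
#'   "sucrose", "glucose", "arabinose", "GABA")}; uptake routes are built
#'   for each (bounds are set by scenarios, not here).
#' @param include_polymers subset of \code{c("PHB", "glycogen",
#'   "palmitate", "glycerolipid")}.
#' @param p_o_nadh ATP formed per 2-electron transfer from NADH to O2.
#' @param p_o_fadh2 same for FADH2.
#' @param nitrogenase_atp_per_n2 ATP hydrolyzed per N2 fixed (textbook
#'   stoichiometry: 16).
#' @param seed integer seed for the randomized GPR assignment.
#' @return list with class \code{"CoreModelConfig"}.
#' @export
coreModelConfig <- function(carbon_sources = c("malate", "succinate",
                                               "sucrose", "glucose",
                                               "arabinose", "GABA"),
                            include_polymers = c("PHB", "glycogen",
                                                 "palmitate",
                                                 "glycerolipid"),
                            p_o_nadh = 1.5, p_o_fadh2 = 1.0,
                            nitrogenase_atp_per_n2 = 16, seed = 323L) {
  carbon_sources <- match.arg(carbon_sources, several.ok = TRUE)
  if (length(include_polymers))
    include_polymers <- match.arg(include_polymers, several.ok = TRUE)
  stopifnot(p_o_nadh > 0, p_o_fadh2 > 0, length(carbon_sources) >= 1,
            nitrogenase_atp_per_n2 > 0)
  structure(list(carbon_sources = carbon_sources,
                 include_polymers = include_polymers,
                 p_o_nadh = p_o_nadh, p_o_fadh2 = p_o_fadh2,
                 nitrogenase_atp_per_n2 = nitrogenase_atp_per_n2,
                 seed = as.integer(seed)),
            class = "CoreModelConfig")
}

.core_metabolites <- function() {
  m <- function(id, name, formula) data.frame(id = id, name = name,
                                              formula = formula,
                                              stringsAsFactors = FALSE)
  rbind(
    m("mal",     "(S)-malate",            "C4H6O5"),
    m("succ",    "succinate",             "C4H6O4"),
    m("fum",     "fumarate",              "C4H4O4"),
    m("oaa",     "oxaloacetate",          "C4H4O5"),
    m("cit",     "citrate",               "C6H8O7"),
    m("icit",    "isocitrate",            "C6H8O7"),
    m("akg",     "2-oxoglutarate",        "C5H6O5"),
    m("succoa",  "succinyl-CoA",          "C25H40N7O19P3S"),
    m("pyr",     "pyruvate",              "C3H4O3"),
    m("accoa",   "acetyl-CoA",            "C23H38N7O17P3S"),
    m("coa",     "coenzyme A",            "C21H36N7O16P3S"),
    m("pep",     "phosphoenolpyruvate",   "C3H5O6P"),
    m("g6p",     "glucose 6-phosphate",   "C6H13O9P"),
    m("ru5p",    "ribulose 5-phosphate",  "C5H11O8P"),
    m("glc",     "glucose",               "C6H12O6"),
    m("sucr",    "sucrose",               "C12H22O11"),
    m("ara",     "arabinose",             "C5H10O5"),
    m("gaba",    "4-aminobutyrate",       "C4H9NO2"),
    m("nad",     "NAD+ (carrier)",        "C21H26N7O14P2"),
    m("nadh",    "NADH (carrier, +H+)",   "C21H28N7O14P2"),
    m("fad",     "FAD (carrier)",         "C27H33N9O15P2"),
    m("fadh2",   "FADH2 (carrier)",       "C27H35N9O15P2"),
    m("fdox",    "ferredoxin (oxidized)", "C10H10S8"),
    m("fdred",   "ferredoxin (reduced)",  "C10H11S8"),
    m("atp",     "ATP",                   "C10H16N5O13P3"),
    m("adp",     "ADP",                   "C10H15N5O10P2"),
    m("pi",      "orthophosphate",        "H3O4P"),
    m("h2o",     "water",                 "H2O"),
    m("co2",     "carbon dioxide",        "CO2"),
    m("o2",      "dioxygen",              "O2"),
    m("n2",      "dinitrogen",            "N2"),
    m("nh3",     "ammonia",               "NH3"),
    m("h2",      "dihydrogen",            "H2"),
    m("glu",     "L-glutamate",           "C5H9NO4"),
    m("gln",     "L-glutamine",           "C5H10N2O3"),
    m("ala",     "L-alanine",             "C3H7NO2"),
    m("asp",     "L-aspartate",           "C4H7NO4"),
    m("phb",     "poly-3-hydroxybutyrate (monomer)", "C4H6O2"),
    m("glycg",   "glycogen (glucosyl unit)",         "C6H10O5"),
    m("palm",    "palmitate",             "C16H32O2"),
    m("lipid",   "glycerolipid (dipalmitoyl-glycerol)", "C35H68O5")
  )
}

#' Build the synthetic core-bacteroid metabolic model
#'
#' Constructs a fully elementally balanced core model of bacteroid
#' metabolism (see the package vignette for the complete reaction list and
#' the lumping choices). Every non-boundary reaction carries a GPR rule
#' drawn from a seeded scheme mixing single-gene, AND-complex and
#' OR-isozyme patterns; the nitrogenase is a fixed three-subunit AND
#' complex and citrate synthase a fixed isozyme pair, so that canonical
#' essentiality cases are always present.
#'
#' @param config a [coreModelConfig()].
#' @return a [MetabolicModel-class] with nitrogenase designated.
#' @examples
#' model <- buildCoreBacteroidModel()
#' checkElementalBalance(model)$imbalances   # empty: all balanced
#' @export
buildCoreBacteroidModel <- function(config = coreModelConfig()) {
  met <- .core_metabolites()
  pn <- config$p_o_nadh
  pf <- config$p_o_fadh2
  natp <- config$nitrogenase_atp_per_n2

  R <- list()
  add <- function(id, stoich, lower = 0, upper = 1000, name = id,
                  kind = "metabolic") {
    R[[length(R) + 1]] <<- reaction(id, stoich, lower = lower,
                                    upper = upper, name = name, kind = kind)
  }

  ## --- TCA cycle ---
  add("MDH", c(mal = -1, nad = -1, oaa = 1, nadh = 1), lower = -1000,
      name = "malate dehydrogenase")
  add("CS", c(oaa = -1, accoa = -1, h2o = -1, cit = 1, coa = 1),
      name = "citrate synthase")
  add("ACONT", c(cit = -1, icit = 1), lower = -1000, name = "aconitase")
  add("ICDH", c(icit = -1, nad = -1, akg = 1, co2 = 1, nadh = 1),
      name = "isocitrate dehydrogenase")
  add("AKGDH", c(akg = -1, nad = -1, coa = -1, succoa = 1, co2 = 1,
                 nadh = 1), name = "2-oxoglutarate dehydrogenase")
  add("SUCOAS", c(succoa = -1, adp = -1, pi = -1, succ = 1, coa = 1,
                  atp = 1), name = "succinyl-CoA synthetase")
  add("SDH", c(succ = -1, fad = -1, fum = 1, fadh2 = 1),
      name = "succinate dehydrogenase")
  add("FUM", c(fum = -1, h2o = -1, mal = 1), lower = -1000,
      name = "fumarase")

  ## --- anaplerosis / pyruvate metabolism ---
  add("ME", c(mal = -1, nad = -1, pyr = 1, co2 = 1, nadh = 1),
      name = "malic enzyme")
  add("PDH", c(pyr = -1, coa = -1, nad = -1, accoa = 1, co2 = 1,
               nadh = 1), name = "pyruvate dehydrogenase")
  add("PEPCK", c(oaa = -1, atp = -1, pep = 1, co2 = 1, adp = 1),
      name = "PEP carboxykinase")
  add("PPC", c(pep = -1, co2 = -1, h2o = -1, oaa = 1, pi = 1),
      name = "PEP carboxylase (anaplerosis)")
  add("PYK", c(pep = -1, adp = -1, pyr = 1, atp = 1),
      name = "pyruvate kinase")

  ## --- gluconeogenesis / glycolysis / pentose phosphate (lumped) ---
  add("GLUCONEO", c(pep = -2, nadh = -2, atp = -2, h2o = -3, g6p = 1,
                    nad = 2, adp = 2, pi = 3),
      name = "gluconeogenesis (lumped PEP -> G6P)")
  add("GLYCOLYSIS", c(g6p = -1, nad = -2, pi = -2, adp = -1, pep = 2,
                      nadh = 2, h2o = 2, atp = 1),
      name = "glycolysis (lumped G6P -> 2 PEP)")
  add("PPPOX", c(g6p = -1, nad = -2, h2o = -1, ru5p = 1, co2 = 1,
                 nadh = 2),
      name = "pentose phosphate, oxidative branch (lumped)")
  add("PPPRET", c(ru5p = -6, h2o = -1, g6p = 5, pi = 1),
      name = "pentose phosphate, non-oxidative return (lumped)")

  ## --- electron transport and energy ---
  add("ETC_NADH", c(nadh = -1, o2 = -0.5, adp = -pn, pi = -pn, nad = 1,
                    atp = pn, h2o = 1 + pn),
      name = "NADH oxidase / oxidative phosphorylation")
  add("ETC_FADH2", c(fadh2 = -1, o2 = -0.5, adp = -pf, pi = -pf, fad = 1,
                     atp = pf, h2o = 1 + pf),
      name = "FADH2 oxidase / oxidative phosphorylation")
  add("FNR", c(nadh = -1, fdox = -2, nad = 1, fdred = 2),
      name = "ferredoxin-NAD+ reductase")
  add("ATPM", c(atp = -1, h2o = -1, adp = 1, pi = 1),
      name = "ATP maintenance")

  ## --- nitrogen fixation and assimilation ---
  add("NITROGENASE",
      c(n2 = -1, fdred = -8, atp = -natp, h2o = -natp, nh3 = 2, h2 = 1,
        fdox = 8, adp = natp, pi = natp),
      name = "nitrogenase")
  add("GS", c(glu = -1, nh3 = -1, atp = -1, gln = 1, adp = 1, pi = 1),
      name = "glutamine synthetase")
  add("GOGAT", c(gln = -1, akg = -1, nadh = -1, glu = 2, nad = 1),
      name = "glutamate synthase (GOGAT)")
  add("ALADH", c(pyr = -1, nh3 = -1, nadh = -1, ala = 1, nad = 1,
                 h2o = 1), name = "alanine dehydrogenase")
  add("AAT", c(oaa = -1, glu = -1, asp = 1, akg = 1), lower = -1000,
      name = "aspartate transaminase")

  ## --- carbon source catabolism (per config) ---
  cs <- config$carbon_sources
  if ("sucrose" %in% cs)
    add("SUCR_HYD", c(sucr = -1, h2o = -1, glc = 2),
        name = "sucrose hydrolysis (fructose lumped as glucose)")
  if (any(c("sucrose", "glucose") %in% cs))
    add("HEX", c(glc = -1, atp = -1, g6p = 1, adp = 1),
        name = "hexokinase")
  if ("arabinose" %in% cs)
    add("ARA_CAT", c(ara = -1, nad = -2, akg = 1, nadh = 2),
        name = "arabinose catabolism (lumped, via 2-oxoglutarate)")
  if ("GABA" %in% cs)
    add("GABA_CAT", c(gaba = -1, akg = -1, nad = -1, h2o = -1, glu = 1,
                      succ = 1, nadh = 1),
        name = "GABA transaminase + SSA dehydrogenase (lumped)")

  ## --- storage polymers (per config) ---
  pol <- config$include_polymers
  if ("PHB" %in% pol)
    add("PHB_SYN", c(accoa = -2, nadh = -1, phb = 1, coa = 2, nad = 1),
        name = "PHB synthesis (per monomer)")
  if ("glycogen" %in% pol)
    add("GLYC_SYN", c(g6p = -1, atp = -1, h2o = -1, glycg = 1, adp = 1,
                      pi = 2), name = "glycogen synthesis (per unit)")
  if ("palmitate" %in% pol || "glycerolipid" %in% pol)
    add("FAS", c(accoa = -8, nadh = -14, atp = -7, h2o = -1, palm = 1,
                 coa = 8, nad = 14, adp = 7, pi = 7),
        name = "fatty acid synthesis (palmitate)")
  if ("glycerolipid" %in% pol)
    add("LIPID_SYN", c(palm = -2, g6p = -0.5, nadh = -1, atp = -1,
                       lipid = 1, nad = 1, adp = 1, pi = 1.5, h2o = 0.5),
        name = "glycerolipid synthesis (lumped)")

  ## --- boundary reactions ---
  ex_map <- c(malate = "mal", succinate = "succ", sucrose = "sucr",
              glucose = "glc", arabinose = "ara", GABA = "gaba")
  for (src in names(ex_map))
    if (src %in% cs)
      add(paste0("EX_", ex_map[[src]]),
          stats::setNames(-1, ex_map[[src]]), lower = -1000, upper = 0,
          name = paste(src, "exchange"), kind = "exchange")
  add("EX_o2", c(o2 = -1), lower = -1000, upper = 0, kind = "exchange",
      name = "O2 exchange")
  add("EX_n2", c(n2 = -1), lower = -1000, upper = 0, kind = "exchange",
      name = "N2 exchange")
  add("EX_nh3", c(nh3 = -1), lower = 0, upper = 1000, kind = "exchange",
      name = "ammonia exchange")
  add("EX_ala", c(ala = -1), lower = 0, upper = 1000, kind = "exchange",
      name = "alanine exchange")
  add("EX_asp", c(asp = -1), lower = 0, upper = 1000, kind = "exchange",
      name = "aspartate exchange")
  add("EX_co2", c(co2 = -1), lower = 0, upper = 1000, kind = "exchange",
      name = "CO2 exchange")
  add("EX_h2", c(h2 = -1), lower = 0, upper = 1000, kind = "exchange",
      name = "H2 exchange")
  add("EX_h2o", c(h2o = -1), lower = -1000, upper = 1000,
      kind = "exchange", name = "water exchange")
  for (aa in c("glu", "gln", "ala", "asp"))
    add(paste0("DM_", aa), stats::setNames(-1, aa), lower = 0,
        upper = 1000, name = paste(aa, "demand (protein synthesis)"),
        kind = "demand")
  for (p in c(PHB = "phb", glycogen = "glycg", palmitate = "palm",
              glycerolipid = "lipid")[pol])
    add(paste0("SK_", p), stats::setNames(-1, p), lower = 0,
        upper = 1000, name = paste(p, "storage sink"), kind = "sink")

  ## --- seeded GPR assignment ---
  rids <- vapply(R, `[[`, character(1), "id")
  kinds <- vapply(R, `[[`, character(1), "kind")
  set.seed(config$seed)
  gene_counter <- 0L
  next_gene <- function(n = 1) {
    out <- sprintf("g%03d", gene_counter + seq_len(n))
    gene_counter <<- gene_counter + n
    out
  }
  fixed <- list(
    NITROGENASE = function() paste(next_gene(3), collapse = " and "),
    CS = function() paste(next_gene(2), collapse = " or "),
    MDH = function() next_gene(1)
  )
  for (k in seq_along(R)) {
    if (kinds[k] %in% .BOUNDARY_KINDS) next
    id <- rids[k]
    if (!is.null(fixed[[id]])) {
      R[[k]]$gpr <- fixed[[id]]()
      next
    }
    pat <- sample(c("single", "or", "and", "mixed"), 1,
                  prob = c(0.55, 0.2, 0.18, 0.07))
    R[[k]]$gpr <- switch(pat,
      single = next_gene(1),
      or = paste(next_gene(2), collapse = " or "),
      and = paste(next_gene(2), collapse = " and "),
      mixed = {
        g <- next_gene(4)
        sprintf("(%s and %s) or (%s and %s)", g[1], g[2], g[3], g[4])
      })
  }

  used <- sort(unique(unlist(lapply(R, function(r) gprGenes(r$gpr)))))
  newMetabolicModel(
    id = "coreBacteroid",
    metabolites = data.frame(met, compartment = "internal",
                             charge = NA_integer_,
                             stringsAsFactors = FALSE),
    reactions = R, genes = used, nitrogenase = "NITROGENASE")
}

#' Ground-truth gene essentiality by exhaustive deletion
#'
#' Independent oracle for [singleGeneDeletion()]: for each gene it
#' disables the reactions knocked out by the deletion and tests, by an LP
#' feasibility (phase-1 only) check, whether any steady-state flux vector
#' with nitrogenase flux at or above \code{threshold} exists. This avoids
#' the optimization path used by \code{singleGeneDeletion}.
#'
#' @param model a [MetabolicModel-class] with GPRs and a nitrogenase.
#' @param scenario optional [ScenarioConstraints-class].
#' @param threshold flux level whose unattainability defines essentiality.
#' @return named character vector, gene id -> \code{"essential"} /
#'   \code{"nonessential"}.
#' @export
groundTruthEssentiality <- function(model, scenario = NULL,
                                    threshold = 1e-6) {
  if (is.na(model@nitrogenase))
    stop("model has no designated nitrogenase reaction")
  sys <- .fba_system(model, scenario, numeric())
  rxn <- sys$model@reactions
  nj <- match(model@nitrogenase, rxn$id)
  trees <- lapply(rxn$gpr, parseGpr)
  A <- as.matrix(sys$S)
  out <- stats::setNames(character(length(sys$model@genes)),
                         sys$model@genes)
  for (g in sys$model@genes) {
    hit <- which(vapply(trees, function(t) {
      !is.null(t) && (g %in% gprGenes(t)) && !evaluateGpr(t, g)
    }, logical(1)))
    lb <- sys$lb; ub <- sys$ub
    lb[hit] <- ub[hit] <- 0
    lb[nj] <- max(lb[nj], threshold)
    r <- .lp(A, lb, ub, numeric(ncol(A)))
    out[g] <- if (r$status == "infeasible") "essential" else "nonessential"
  }
  out
}

#' Mock experimental essentiality calls
#'
#' Emulates an experimental essentiality screen with a controlled
#' agreement level: exactly \code{round((1 - agreement) * n)} randomly
#' chosen calls are flipped. Fully reproducible from the seed.
#'
#' @param truth named character vector of \code{"essential"} /
#'   \code{"nonessential"} calls.
#' @param agreement fraction in \[0, 1\] of calls to preserve.
#' @param seed integer seed.
#' @return named character vector of the same shape.
#' @export
makeMockExperimentalCalls <- function(truth, agreement, seed = 1) {
  stopifnot(agreement >= 0, agreement <= 1)
  n <- length(truth)
  nflip <- round((1 - agreement) * n)
  set.seed(seed)
  flip <- sample(seq_len(n), nflip)
  out <- truth
  out[flip] <- ifelse(truth[flip] == "essential", "nonessential",
                      "essential")
  out
}
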