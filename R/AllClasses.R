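#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t rowSums colSums
NULL

#' MetabolicModel: a stoichiometric model of core metabolism
#'
#' An S4 container for a constraint-based metabolic model: metabolites with
#' elemental formulas, reactions with stoichiometry, flux bounds and
#' gene-protein-reaction (GPR) rules, the gene list, and the id of the
#' designated nitrogenase reaction (the default analysis objective for
#' bacteroid models).
#'
#' Metabolites live in one of two compartments. \code{"internal"} metabolites
#' are balanced at steady state (their rows make up the stoichiometric matrix
#' used by FBA); \code{"external"} metabolites are unbalanced boundary pools,
#' used by toy models that represent the environment explicitly and by the
#' conversion-cone machinery. Exchange, demand and sink reactions touch
#' exactly one metabolite; following the dominant community convention they
#' are written as "metabolite ->", so export is a positive flux and uptake a
#' negative one.
#'
#' @slot modelId single character, the model name.
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} (\code{"internal"} or \code{"external"}),
#'   \code{formula} (Hill-style element string over C/H/N/O/P/S, or
#'   \code{NA}), \code{charge} (integer or \code{NA}).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower}, \code{upper} (flux units), \code{gpr} (boolean rule over
#'   gene ids; \code{""} means no gene association) and \code{kind} (one of
#'   \code{"metabolic"}, \code{"transport"}, \code{"exchange"},
#'   \code{"demand"}, \code{"sink"}).
#' @slot stoichiometry sparse Matrix, metabolites x reactions, signed
#'   coefficients (negative = consumed).
#' @slot genes character vector of gene ids.
#' @slot nitrogenase reaction id of the nitrogenase reaction, or
#'   \code{NA_character_} for models without one.
#'
#' @seealso [newMetabolicModel()], [buildCoreBacteroidModel()],
#'   [stoichiometricMatrix()]
#' @export
setClass("MetabolicModel",
  representation(
    modelId = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    genes = "character",
    nitrogenase = "character"
  )
)

.BOUNDARY_KINDS <- c("exchange", "demand", "sink")
.REACTION_KINDS <- c("metabolic", "transport", .BOUNDARY_KINDS)
.ELEMENTS <- c("C", "H", "N", "O", "P", "S")

setValidity("MetabolicModel", function(object) {
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  msgs <- character()
  if (anyDuplicated(met$id)) {
    msgs <- c(msgs, paste("duplicate metabolite id:",
                          met$id[duplicated(met$id)][1]))
  }
  if (anyDuplicated(rxn$id)) {
    msgs <- c(msgs, paste("duplicate reaction id:",
                          rxn$id[duplicated(rxn$id)][1]))
  }
  if (!all(met$compartment %in% c("internal", "external"))) {
    msgs <- c(msgs, "metabolite compartment must be 'internal' or 'external'")
  }
  if (!all(rxn$kind %in% .REACTION_KINDS)) {
    msgs <- c(msgs, "unknown reaction kind")
  }
  if (any(rxn$lower > rxn$upper)) {
    bad <- rxn$id[rxn$lower > rxn$upper][1]
    msgs <- c(msgs, paste0("lower bound exceeds upper bound for '", bad, "'"))
  }
  if (nrow(met) > 0 || nrow(rxn) > 0) {
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id)) {
      msgs <- c(msgs, "stoichiometry dimnames must match metabolite/reaction ids")
    }
  }
  if (nrow(rxn) > 0) {
    nz <- Matrix::colSums(S != 0)
    if (any(nz == 0)) {
      msgs <- c(msgs, paste0("reaction '", rxn$id[nz == 0][1],
                             "' has empty stoichiometry"))
    }
    bk <- rxn$kind %in% .BOUNDARY_KINDS
    if (any(bk & nz != 1)) {
      bad <- rxn$id[bk & nz != 1][1]
      msgs <- c(msgs, paste0("boundary reaction '", bad,
                             "' must touch exactly one metabolite"))
    }
    gpr_genes <- unique(unlist(lapply(rxn$gpr, gprGenes)))
    if (length(gpr_genes) && !all(gpr_genes %in% object@genes)) {
      bad <- setdiff(gpr_genes, object@genes)[1]
      msgs <- c(msgs, paste0("GPR references unknown gene '", bad, "'"))
    }
  }
  if (!is.na(object@nitrogenase) &&
      !(object@nitrogenase %in% rxn$id)) {
    msgs <- c(msgs, paste0("nitrogenase reaction '", object@nitrogenase,
                           "' not in model"))
  }
  for (f in met$formula[!is.na(met$formula)]) {
    ok <- tryCatch({ parseFormula(f); TRUE }, error = function(e) FALSE)
    if (!ok) msgs <- c(msgs, paste("unparseable formula:", f))
  }
  if (length(msgs)) msgs else TRUE
})

#' ScenarioConstraints: bound overrides encoding a biological condition
#'
#' A named set of flux-bound overrides (and optionally an objective) that,
#' applied to a model, encodes a condition such as "bacteroid on malate" or
#' "forced glutamate demand". Applying a scenario is idempotent.
#'
#' @slot name scenario name.
#' @slot bounds data.frame with columns \code{reaction_id}, \code{lower},
#'   \code{upper} (flux units); \code{NA} leaves the corresponding bound
#'   untouched.
#' @slot objective named numeric vector of reaction weights (may be empty).
#' @slot notes free text.
#' @export
setClass("ScenarioConstraints",
  representation(name = "character", bounds = "data.frame",
                 objective = "numeric", notes = "character")
)

setValidity("ScenarioConstraints", function(object) {
  b <- object@bounds
  if (!all(c("reaction_id", "lower", "upper") %in% names(b)))
    return("bounds needs columns reaction_id, lower, upper")
  bad <- !is.na(b$lower) & !is.na(b$upper) & b$lower > b$upper
  if (any(bad))
    return(paste0("lower > upper for '", b$reaction_id[bad][1], "'"))
  TRUE
})

#' FluxDistribution: the result of one FBA solve
#'
#' @slot fluxes named numeric vector of per-reaction fluxes (empty unless
#'   status is \code{"optimal"}).
#' @slot objectiveValue optimal objective value (\code{NA} if not optimal).
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @slot method \code{"fba"} or \code{"fba_l1"}.
#' @export
setClass("FluxDistribution",
  representation(fluxes = "numeric", objectiveValue = "numeric",
                 status = "character", method = "character")
)

#' FVAResult: per-reaction flux ranges at near-optimal objective
#'
#' @slot ranges data.frame with columns \code{reaction}, \code{min},
#'   \code{max} and, for loopless FVA, \code{cycle_excluded_min} /
#'   \code{cycle_excluded_max} (cycle-only flux removed from each extreme).
#' @slot fractionOfOptimum fraction of the optimum enforced (in (0, 1]).
#' @slot loopless logical.
#' @export
setClass("FVAResult",
  representation(ranges = "data.frame", fractionOfOptimum = "numeric",
                 loopless = "logical")
)

#' PhasePlane: objective and shadow prices over a 2-D grid of uptake rates
#'
#' Grid cells hold the FBA optimum and the shadow price of each axis
#' metabolite; phases are maximal 4-connected regions with identical
#' shadow-price sign signature. Infeasible cells carry phase label 0.
#'
#' @slot axes the two exchange reaction ids.
#' @slot gridA,gridB uptake magnitudes along each axis (flux units).
#' @slot objective matrix of optima (rows = gridA, cols = gridB).
#' @slot shadowA,shadowB matrices of shadow prices for the two axis bounds.
#' @slot phases integer matrix of phase labels (0 = infeasible).
#' @export
setClass("PhasePlane",
  representation(axes = "character", gridA = "numeric", gridB = "numeric",
                 objective = "matrix", shadowA = "matrix",
                 shadowB = "matrix", phases = "matrix")
)

#' ConversionSet: elementary conversion modes of a model
#'
#' Each row of \code{coefficients} is one elementary conversion mode (ECM):
#' the net input/output stoichiometry over the tracked boundary metabolites,
#' with consumption negative. Tracker (virtual) metabolites added with
#' [addFluxTracker()] appear as additional columns and report the tracked
#' reaction's flux per unit conversion.
#'
#' @slot coefficients numeric matrix, conversions x tracked metabolites.
#' @slot formulas named character vector of elemental formulas for the
#'   tracked metabolites (\code{NA} for virtual trackers).
#' @slot trackers character vector of tracker metabolite ids.
#' @slot normalization \code{"none"}, \code{"unit_carbon_input"} or
#'   \code{"unit_max_coeff"}.
#' @export
setClass("ConversionSet",
  representation(coefficients = "matrix", formulas = "character",
                 trackers = "character", normalization = "character")
)

#' EssentialityComparison: in-silico vs experimental gene essentiality
#'
#' @slot table data.frame with columns \code{gene}, \code{in_silico},
#'   \code{experimental} (both \code{"essential"}/\code{"nonessential"}).
#' @slot counts named integer vector TP/TN/FP/FN ("essential" = positive).
#' @slot agreement integer, number of concordant genes (TP + TN).
#' @slot agreementFraction agreement / genes compared.
#' @export
setClass("EssentialityComparison",
  representation(table = "data.frame", counts = "integer",
                 agreement = "integer", agreementFraction = "numeric")
)

setMethod("show", "MetabolicModel", function(object) {
  met <- object@metabolites
  rxn <- object@reactions
  cat("MetabolicModel '", object@modelId, "'\n", sep = "")
  cat("  metabolites: ", nrow(met), " (",
      sum(met$compartment == "internal"), " internal)\n", sep = "")
  kinds <- table(factor(rxn$kind, levels = .REACTION_KINDS))
  cat("  reactions:   ", nrow(rxn), " (",
      paste(paste(kinds, names(kinds)), collapse = ", "), ")\n", sep = "")
  cat("  genes:       ", length(object@genes), "\n", sep = "")
  cat("  nitrogenase: ", object@nitrogenase, "\n", sep = "")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@method, "): status ", object@status,
      ", objective ", format(object@objectiveValue), "\n", sep = "")
})

setMethod("show", "FVAResult", function(object) {
  cat("FVAResult: ", nrow(object@ranges), " reactions, fraction ",
      object@fractionOfOptimum,
      if (object@loopless) ", loopless" else "", "\n", sep = "")
})

setMethod("show", "PhasePlane", function(object) {
  feas <- object@phases[object@phases > 0]
  cat("PhasePlane ", object@axes[1], " x ", object@axes[2], ": ",
      length(object@gridA), "x", length(object@gridB), " grid, ",
      length(unique(feas)), " phases, ",
      sum(object@phases == 0), " infeasible cells\n", sep = "")
})

setMethod("show", "ConversionSet", function(object) {
  cat("ConversionSet: ", nrow(object@coefficients), " conversions over ",
      ncol(object@coefficients), " metabolites",
      if (length(object@trackers))
        paste0(" (trackers: ", paste(object@trackers, collapse = ", "), ")"),
      "; normalization ", object@normalization, "\n", sep = "")
})

setMethod("show", "EssentialityComparison", function(object) {
  cat("EssentialityComparison: ", nrow(object@table), " genes, agreement ",
      object@agreement, " (", round(100 * object@agreementFraction, 1),
      "%)\n  ", paste(names(object@counts), object@counts, sep = "=",
                      collapse = " "), "\n", sep = "")
})
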