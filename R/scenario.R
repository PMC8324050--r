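# Scenario constraints: named bound overrides encoding a condition.

#' Create a ScenarioConstraints object
#'
#' @param name scenario name.
#' @param bounds data.frame with columns \code{reaction_id}, \code{lower},
#'   \code{upper}; \code{NA} leaves that bound untouched.
#' @param objective named numeric vector of reaction weights (optional).
#' @param notes free text.
#' @return a [ScenarioConstraints-class] object.
#' @export
scenarioConstraints <- function(name = "scenario",
                                bounds = data.frame(reaction_id = character(),
                                                    lower = numeric(),
                                                    upper = numeric()),
                                objective = numeric(), notes = "") {
  bounds <- as.data.frame(bounds, stringsAsFactors = FALSE)
  new("ScenarioConstraints", name = name, bounds = bounds,
      objective = objective, notes = notes)
}

#' Apply a scenario's bound overrides to a model
#'
#' Referenced reactions must exist; unspecified reactions are untouched.
#' Application is idempotent.
#'
#' @param model a [MetabolicModel-class].
#' @param scenario a [ScenarioConstraints-class] (or \code{NULL} for a
#'   no-op).
#' @return the constrained model.
#' @export
applyScenario <- function(model, scenario) {
  if (is.null(scenario)) return(model)
  b <- scenario@bounds
  if (nrow(b) == 0) return(model)
  missing <- setdiff(b$reaction_id, model@reactions$id)
  if (length(missing))
    stop("scenario '", scenario@name, "' references unknown reaction '",
         missing[1], "'")
  setBounds(model, b$reaction_id, b$lower, b$upper)
}

#' Read scenario constraints from TSV or YAML
#'
#' TSV files need columns \code{reaction_id}, \code{lower}, \code{upper}
#' (tab-separated, header required; empty cells or \code{NA} leave a bound
#' untouched). YAML files carry the same fields, optionally with
#' \code{name}, \code{notes} and an \code{objective} map.
#'
#' @param path file path; format chosen by extension
#'   (\code{.yml}/\code{.yaml} vs anything else = TSV).
#' @param name scenario name (TSV only; defaults to the file name).
#' @return a [ScenarioConstraints-class] object.
#' @export
readScenario <- function(path, name = NULL) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    rows <- y$bounds
    b <- data.frame(
      reaction_id = vapply(rows, function(r) as.character(r$reaction_id),
                           character(1)),
      lower = vapply(rows, function(r)
        if (is.null(r$lower)) NA_real_ else as.numeric(r$lower), numeric(1)),
      upper = vapply(rows, function(r)
        if (is.null(r$upper)) NA_real_ else as.numeric(r$upper), numeric(1)),
      stringsAsFactors = FALSE)
    obj <- if (is.null(y$objective)) numeric() else unlist(y$objective)
    return(scenarioConstraints(
      name = if (is.null(y$name)) basename(path) else y$name,
      bounds = b, objective = obj,
      notes = if (is.null(y$notes)) "" else y$notes))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0 && ncol(tab) <= 1) {
    return(scenarioConstraints(name = if (is.null(name)) basename(path)
                               else name))
  }
  need <- c("reaction_id", "lower", "upper")
  extra <- setdiff(names(tab), c(need, "notes"))
  if (length(extra))
    stop("unknown column '", extra[1], "' in scenario file ", path)
  if (!all(need %in% names(tab)))
    stop("scenario file needs columns reaction_id, lower, upper: ", path)
  num <- function(x) {
    x[!nzchar(trimws(x))] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad))
      stop("non-numeric bound '", x[bad][1], "' in scenario file ", path)
    v
  }
  scenarioConstraints(
    name = if (is.null(name)) basename(path) else name,
    bounds = data.frame(reaction_id = tab$reaction_id,
                        lower = num(tab$lower), upper = num(tab$upper),
                        stringsAsFactors = FALSE))
}

#' Standard bacteroid scenario for the synthetic core model
#'
#' Encodes the bacteroid condition used throughout: one carbon source with
#' bounded uptake, open N2, bounded O2 uptake, free secretion of ammonia,
#' alanine and aspartate, low protein-synthesis demands on the other amino
#' acids (0.01-0.05 flux units), and all alternative carbon sources closed.
#' Uptake bounds are negative lower bounds on the exchange reactions.
#'
#' @param carbon one of \code{"malate"}, \code{"succinate"},
#'   \code{"sucrose"}, \code{"glucose"}, \code{"arabinose"}, \code{"GABA"}.
#' @param carbonUptake maximum uptake of the carbon source (flux units;
#'   the default 4 matches a typical bacteroid malate supply).
#' @param o2 maximum oxygen uptake (flux units). Oxygen bounds are a
#'   required choice in any bacteroid simulation; there is no meaningful
#'   universal default, so the argument has none.
#' @param demandLower,demandUpper bounds applied to the glutamate and
#'   glutamine demand reactions.
#' @param minNitrogenase optional lower bound on nitrogenase flux.
#' @param fixCarbon if TRUE the carbon uptake is fixed at
#'   \code{carbonUptake} (plant-controlled supply) instead of being an
#'   upper limit; used by flux-variability and ensemble analyses where
#'   excess carbon must be accommodated, not refused.
#' @return a [ScenarioConstraints-class] object with the nitrogenase
#'   objective.
#' @export
bacteroidScenario <- function(carbon = "malate", carbonUptake = 4, o2,
                              demandLower = 0.01, demandUpper = 0.05,
                              minNitrogenase = NA, fixCarbon = FALSE) {
  sources <- c(malate = "EX_mal", succinate = "EX_succ",
               sucrose = "EX_sucr", glucose = "EX_glc",
               arabinose = "EX_ara", GABA = "EX_gaba")
  carbon <- match.arg(carbon, names(sources))
  b <- data.frame(reaction_id = character(), lower = numeric(),
                  upper = numeric(), stringsAsFactors = FALSE)
  add <- function(b, id, lower, upper)
    rbind(b, data.frame(reaction_id = id, lower = lower, upper = upper))
  for (ex in sources) {
    b <- if (ex == sources[[carbon]]) {
      add(b, ex, -carbonUptake, if (fixCarbon) -carbonUptake else 0)
    } else {
      add(b, ex, 0, 0)
    }
  }
  b <- add(b, "EX_o2", -o2, 0)
  b <- add(b, "EX_n2", -1000, 0)
  for (ex in c("EX_nh3", "EX_ala", "EX_asp", "EX_h2"))
    b <- add(b, ex, 0, 1000)
  b <- add(b, "EX_co2", 0, 1000)
  b <- add(b, "EX_h2o", -1000, 1000)
  for (dm in c("DM_glu", "DM_gln")) b <- add(b, dm, demandLower, demandUpper)
  for (dm in c("DM_ala", "DM_asp")) b <- add(b, dm, 0, 1000)
  if (!is.na(minNitrogenase)) b <- add(b, "NITROGENASE", minNitrogenase, NA)
  scenarioConstraints(
    name = paste0("bacteroid_", carbon),
    bounds = b, objective = c(NITROGENASE = 1),
    notes = paste0("bacteroid on ", carbon, ", uptake <= ", carbonUptake,
                   ", O2 uptake <= ", o2))
}
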