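# Scenario orchestration: the computational experiments of the study,
# reproducible end-to-end, plus the essentiality comparison.

#' Compare in-silico and experimental essentiality calls
#'
#' Restricts to the genes present in both maps (non-overlap is reported
#' via a message), tabulates the confusion counts with "essential" as the
#' positive class, and reports agreement. A false negative is a gene
#' called nonessential in silico but essential experimentally.
#'
#' @param in_silico,experimental named character vectors of
#'   \code{"essential"}/\code{"nonessential"} calls.
#' @return an [EssentialityComparison-class].
#' @export
compareEssentiality <- function(in_silico, experimental) {
  common <- intersect(names(in_silico), names(experimental))
  if (!length(common))
    stop("no genes in common between the two call sets")
  dropped <- length(in_silico) + length(experimental) - 2 * length(common)
  if (dropped > 0)
    message(dropped, " call(s) outside the gene intersection ignored")
  is_ <- in_silico[common]; ex <- experimental[common]
  tab <- data.frame(gene = common, in_silico = unname(is_),
                    experimental = unname(ex), stringsAsFactors = FALSE)
  counts <- c(
    TP = sum(is_ == "essential" & ex == "essential"),
    TN = sum(is_ == "nonessential" & ex == "nonessential"),
    FP = sum(is_ == "essential" & ex == "nonessential"),
    FN = sum(is_ == "nonessential" & ex == "essential"))
  agreement <- unname(counts["TP"] + counts["TN"])
  new("EssentialityComparison", table = tab,
      counts = as.integer(counts) |> stats::setNames(names(counts)),
      agreement = as.integer(agreement),
      agreementFraction = agreement / length(common))
}

#' @describeIn compareEssentiality comparison table accessor
#' @param x an EssentialityComparison.
#' @export
comparisonTable <- function(x) x@table

#' @describeIn compareEssentiality confusion counts accessor
#' @export
confusionCounts <- function(x) x@counts

#' Names of the registered analysis scenarios
#' @export
scenarioRegistry <- function() {
  c("fba_max_nitrogenase", "fva_phases", "phase_plane", "ecm_survey",
    "ensemble", "essentiality", "glutamate_forcing",
    "carbon_source_compare")
}

.carbon_atoms <- c(malate = 4, succinate = 4, sucrose = 12, glucose = 6,
                   arabinose = 5, GABA = 4)

# default id sets for the synthetic core model
.POLYMER_IDS <- c("phb", "glycg", "palm", "lipid")
.AMINO_IDS <- c("ala", "asp", "glu", "gln", "gaba")

#' Run a named analysis scenario end-to-end
#'
#' Reproduces one of the study's computational experiments on a model and
#' writes a result bundle to \code{outDir}: the resolved constraints, the
#' analysis outputs as TSV, and a plain-text log including solver
#' statuses and the seed. Every scenario is deterministic given (model,
#' config, seed).
#'
#' Config entries (all optional unless noted): \code{carbon},
#' \code{carbonUptake}, \code{o2} (required by the FBA-type scenarios),
#' \code{o2_grid}, \code{malate_grid}, \code{nitrogenaseFlux} (required
#' by \code{glutamate_forcing}), \code{glutamateDemand},
#' \code{nEnsemble}, \code{agreement}, \code{fractionOfOptimum},
#' \code{reactions}.
#'
#' @param name scenario name; see [scenarioRegistry()].
#' @param model a [MetabolicModel-class] (the synthetic core-bacteroid
#'   model for the id conventions used by \code{ecm_survey} and
#'   \code{carbon_source_compare}).
#' @param config named list of scenario parameters.
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the randomized scenarios.
#' @return named list of results, invisibly; files in \code{outDir}.
#' @export
runScenario <- function(name, model, config = list(), outDir = tempdir(),
                        seed = 1) {
  if (!(name %in% scenarioRegistry()))
    stop("unknown scenario '", name, "'; available: ",
         paste(scenarioRegistry(), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  log_lines <- c(paste("scenario:", name),
                 paste("model:", model@modelId),
                 paste("seed:", seed),
                 paste("time:", format(Sys.time())))
  out <- list()
  path <- function(f) file.path(outDir, f)

  base_scenario <- function(fix = FALSE, minN = NA) {
    bacteroidScenario(carbon = cfg("carbon", "malate"),
                      carbonUptake = cfg("carbonUptake", 4),
                      o2 = cfg("o2", stop("config$o2 is required for ",
                                          name, call. = FALSE)),
                      minNitrogenase = minN, fixCarbon = fix)
  }
  dump_constraints <- function(sc) {
    resolved <- applyScenario(model, sc)@reactions
    writeResults(resolved[, c("id", "lower", "upper")],
                 path("resolved_constraints.tsv"))
    stopifnot(all(resolved$lower <= resolved$upper))
  }

  if (name == "fba_max_nitrogenase") {
    sc <- base_scenario()
    dump_constraints(sc)
    fd <- solveFBAL1(model, sc)
    log_lines <- c(log_lines, paste("solver status:", fd@status))
    writeResults(fd, path("flux_distribution.tsv"))
    out$flux <- fd
  } else if (name == "fva_phases") {
    rxns <- cfg("reactions", c("CS", "ALADH", "PHB_SYN", "FAS"))
    o2_grid <- cfg("o2_grid", c(7, 5, 3.5, 2.5))
    acc <- list()
    for (o2 in o2_grid) {
      sc <- bacteroidScenario(carbon = cfg("carbon", "malate"),
                              carbonUptake = cfg("carbonUptake", 4),
                              o2 = o2, fixCarbon = TRUE)
      fv <- fluxVariability(model, sc, objective = model@nitrogenase,
                            fractionOfOptimum = cfg("fractionOfOptimum", 1),
                            loopless = cfg("loopless", TRUE),
                            reactions = rxns)
      acc[[length(acc) + 1]] <- cbind(o2_uptake = o2, fv@ranges)
    }
    out$fva <- do.call(rbind, acc)
    writeResults(out$fva, path("fva_vs_o2.tsv"))
  } else if (name == "phase_plane") {
    sc <- base_scenario()
    dump_constraints(sc)
    pp <- phasePlane(model, cfg("rxnA", "EX_mal"), cfg("rxnB", "EX_o2"),
                     cfg("malate_grid", seq(0.5, 6, length.out = 12)),
                     cfg("o2_grid", seq(0.5, 6, length.out = 12)),
                     objective = model@nitrogenase, scenario = sc)
    writeResults(pp, path("phase_plane.tsv"))
    log_lines <- c(log_lines, paste("phases:", nPhases(pp)))
    out$phase_plane <- pp
  } else if (name == "ecm_survey") {
    cfg_ecm <- ecmConfig(
      inputs = cfg("inputs", c("mal", "succ", "o2", "n2", "gaba")),
      outputs = cfg("outputs", c("nh3", "ala", "asp", .POLYMER_IDS,
                                 "co2", "h2")),
      free = cfg("free", "h2o"),
      hidden = cfg("hidden", character()))
    ecms <- enumerateEcms(model, cfg_ecm)
    writeResults(ecms, path("conversions.tsv"))
    metrics <- conversionMetrics(ecms, cfg("polymer_ids", .POLYMER_IDS),
                                 cfg("amino_acid_ids", .AMINO_IDS))
    flt <- filterConversions(ecms, cfg("polymer_ids", .POLYMER_IDS),
                             cfg("amino_acid_ids", .AMINO_IDS))
    metrics$kept <- seq_len(nrow(metrics)) %in% flt$kept_index
    writeResults(metrics, path("conversion_metrics.tsv"))
    writeResults(flt$rejections, path("rejections.tsv"))
    log_lines <- c(log_lines,
                   paste("conversions:", nrow(conversionMatrix(ecms))),
                   paste("kept after filters:", length(flt$kept_index)))
    out$ecms <- ecms; out$metrics <- metrics; out$filtered <- flt
  } else if (name == "ensemble") {
    sc <- bacteroidScenario(carbon = cfg("carbon", "malate"),
                            carbonUptake = cfg("carbonUptake", 4),
                            o2 = 1000, fixCarbon = TRUE)
    spec <- ensembleSpec(nObjectives = cfg("nEnsemble", 50000),
                         seed = seed, minNitrogenase = 0.01,
                         scenario = sc)
    ens <- randomObjectiveEnsemble(
      model, spec, sweepReaction = "EX_o2",
      sweepBounds = cfg("o2_bounds", c(-7, -5, -3.5, -2.5)),
      track = cfg("reactions", c("CS", "ALADH", "PHB_SYN", "FAS",
                                 "LIPID_SYN")))
    writeResults(ens$summary, path("ensemble.tsv"))
    log_lines <- c(log_lines,
                   paste("skipped draws:",
                         paste(ens$skipped, collapse = ",")))
    out$ensemble <- ens
  } else if (name == "essentiality") {
    sc <- base_scenario()
    dump_constraints(sc)
    del <- singleGeneDeletion(model, sc)
    in_silico <- stats::setNames(
      ifelse(del$essential, "essential", "nonessential"), del$gene)
    truth <- groundTruthEssentiality(model, sc)
    mock <- makeMockExperimentalCalls(truth, cfg("agreement", 0.87),
                                      seed = seed)
    cmp <- compareEssentiality(in_silico, mock)
    writeResults(del, path("gene_deletion.tsv"))
    writeResults(cmp@table, path("essentiality_comparison.tsv"))
    log_lines <- c(log_lines,
                   paste("agreement:", cmp@agreement, "/",
                         nrow(cmp@table)))
    out$deletion <- del; out$comparison <- cmp
  } else if (name == "glutamate_forcing") {
    nflux <- cfg("nitrogenaseFlux",
                 stop("config$nitrogenaseFlux is required",
                      call. = FALSE))
    for (forced in c(FALSE, TRUE)) {
      sc <- bacteroidScenario(carbon = cfg("carbon", "malate"),
                              carbonUptake = cfg("carbonUptake", 4),
                              o2 = 1000)
      b <- sc@bounds
      b <- rbind(b, data.frame(reaction_id = model@nitrogenase,
                               lower = nflux, upper = nflux))
      if (forced) {
        b$lower[b$reaction_id == "DM_glu"] <- cfg("glutamateDemand", 0.5)
        b$upper[b$reaction_id == "DM_glu"] <- 1000
      }
      sc@bounds <- b
      fd <- solveFBA(model, sc, objective = c(EX_o2 = 1))
      key <- if (forced) "forced" else "unforced"
      out[[key]] <- if (fd@status == "optimal")
        -fd@fluxes[["EX_o2"]] else NA_real_
      log_lines <- c(log_lines, paste0(key, " status: ", fd@status))
    }
    writeResults(data.frame(condition = c("unforced", "forced"),
                            min_o2_uptake = c(out$unforced, out$forced)),
                 path("glutamate_forcing.tsv"))
  } else if (name == "carbon_source_compare") {
    sources <- cfg("sources", c("malate", "sucrose"))
    cAtoms <- cfg("carbonAtoms", 12)
    nPerC <- cfg("nitrogenasePerC", 0.04)
    rows <- list()
    for (src in sources) {
      up <- cAtoms / .carbon_atoms[[src]]
      sc <- bacteroidScenario(src, carbonUptake = up, o2 = cfg("o2", 4))
      fmax <- solveFBA(model, sc)
      sc2 <- bacteroidScenario(src, carbonUptake = up, o2 = 1000)
      sc2@bounds <- rbind(sc2@bounds,
                          data.frame(reaction_id = model@nitrogenase,
                                     lower = nPerC * cAtoms,
                                     upper = nPerC * cAtoms))
      fo2 <- solveFBA(model, sc2, objective = c(EX_o2 = 1))
      rows[[src]] <- data.frame(
        carbon_source = src, carbon_atoms = cAtoms, uptake = up,
        max_nitrogenase_per_c =
          if (fmax@status == "optimal") fmax@objectiveValue / cAtoms
          else NA_real_,
        min_o2_per_c =
          if (fo2@status == "optimal") -fo2@fluxes[["EX_o2"]] / cAtoms
          else NA_real_)
      log_lines <- c(log_lines, paste0(src, ": ", fmax@status, "/",
                                       fo2@status))
    }
    out$comparison <- do.call(rbind, rows)
    writeResults(out$comparison, path("carbon_source_compare.tsv"))
  }

  writeLines(log_lines, path("run.log"))
  invisible(out)
}
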