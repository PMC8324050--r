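# LP-based analyses: FBA, taxicab-norm (L1) minimization, FVA (optionally
# loopless), shadow prices, phase planes, gene deletion, ensembles.

#' Flux balance analysis
#'
#' Maximizes a linear objective over the steady-state flux cone
#' \{v : S v = 0, lb <= v <= ub\}, with S the internal-metabolite
#' stoichiometric matrix. Infeasibility and unboundedness are reported in
#' the \code{status} slot; no fluxes are fabricated.
#'
#' @param model a [MetabolicModel-class].
#' @param scenario optional [ScenarioConstraints-class] applied first.
#' @param objective named numeric vector of reaction weights, or a
#'   character vector of reaction ids (weight 1 each). Default: the
#'   scenario objective if present, else the model's nitrogenase reaction.
#' @param maximize maximize (default) or minimize.
#' @return a [FluxDistribution-class].
#' @examples
#' m <- newMetabolicModel("chain",
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = list(
#'     reaction("up",  c(A = 1), lower = 0, upper = 10, kind = "exchange"),
#'     reaction("cnv", c(A = -1, B = 1), lower = 0),
#'     reaction("out", c(B = -1), lower = 0, kind = "exchange")))
#' solveFBA(m, objective = "out")   # objective value 10
#' @export
solveFBA <- function(model, scenario = NULL, objective = NULL,
                     maximize = TRUE) {
  sys <- .fba_system(model, scenario, objective)
  res <- .lp(sys$S, sys$lb, sys$ub, sys$obj, maximize = maximize)
  if (res$status != "optimal") {
    return(new("FluxDistribution", fluxes = numeric(),
               objectiveValue = NA_real_, status = res$status,
               method = "fba"))
  }
  new("FluxDistribution", fluxes = res$x, objectiveValue = res$obj,
      status = "optimal", method = "fba")
}

#' @describeIn solveFBA flux vector accessor
#' @param x a FluxDistribution.
#' @export
fluxes <- function(x) x@fluxes

#' @describeIn solveFBA objective value accessor
#' @export
objectiveValue <- function(x) x@objectiveValue

# Build the flux-splitting system used for L1 minimization:
# variables (v, p, q); rows S v = 0, v - p + q = 0, and optionally an
# objective-fixing row obj'v - s = 0 with slack s bounded below.
.l1_system <- function(S, lb, ub, obj = NULL, obj_floor = NULL) {
  m <- nrow(S); n <- ncol(S)
  Sv <- cbind(as.matrix(S), matrix(0, m, 2 * n))
  split <- cbind(diag(n), -diag(n), diag(n))
  A <- rbind(Sv, split)
  lbs <- c(lb, rep(0, 2 * n))
  ubs <- c(ub, pmax(ub, 0), pmax(-lb, 0))
  cost <- c(rep(0, n), rep(1, 2 * n))
  if (!is.null(obj)) {
    A <- rbind(A, c(obj, rep(0, 2 * n)))
    A <- cbind(A, c(rep(0, m + n), -1))
    lbs <- c(lbs, obj_floor)
    ubs <- c(ubs, Inf)
    cost <- c(cost, 0)
  }
  rownames(A) <- NULL
  colnames(A) <- c(colnames(S), paste0(".p", seq_len(n)),
                   paste0(".q", seq_len(n)),
                   if (!is.null(obj)) ".s")
  list(A = A, lb = lbs, ub = ubs, cost = cost, n = n)
}

#' FBA with taxicab-norm minimization
#'
#' Two-stage LP: first the FBA optimum is computed, then, holding the
#' objective at its optimum (relative tolerance \code{1e-9}), the sum of
#' absolute fluxes is minimized by splitting every flux into nonnegative
#' forward and backward parts. This removes thermodynamically infeasible
#' internal cycles from the reported flux distribution while preserving
#' the objective value.
#'
#' @inheritParams solveFBA
#' @return a [FluxDistribution-class] with method \code{"fba_l1"}.
#' @export
solveFBAL1 <- function(model, scenario = NULL, objective = NULL) {
  sys <- .fba_system(model, scenario, objective)
  stage1 <- .lp(sys$S, sys$lb, sys$ub, sys$obj)
  if (stage1$status != "optimal") {
    return(new("FluxDistribution", fluxes = numeric(),
               objectiveValue = NA_real_, status = stage1$status,
               method = "fba_l1"))
  }
  opt <- stage1$obj
  # hold the objective at its optimum; the slack only needs to absorb
  # double-precision round-off, keeping the L1 objective well inside the
  # documented 1e-9 relative tolerance
  floor <- opt - 1e-12 * max(1, abs(opt))
  l1 <- .l1_system(sys$S, sys$lb, sys$ub, obj = sys$obj, obj_floor = floor)
  res <- .lp(l1$A, l1$lb, l1$ub, l1$cost, maximize = FALSE)
  if (res$status != "optimal")
    stop("L1 stage unexpectedly ", res$status)
  v <- res$x[seq_len(l1$n)]
  names(v) <- colnames(sys$S)
  new("FluxDistribution", fluxes = v,
      objectiveValue = sum(sys$obj * v), status = "optimal",
      method = "fba_l1")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective staying
#' within \code{fractionOfOptimum} of its optimum. With
#' \code{loopless = TRUE} each extreme solution is post-processed by L1
#' minimization with the boundary fluxes of that solution fixed
#' (CycleFreeFlux-style); flux that can only circulate in internal cycles
#' is removed from the reported extreme and reported separately.
#'
#' @inheritParams solveFBA
#' @param objective as in [solveFBA()]; \code{NULL} here means no
#'   objective constraint (plain flux ranges).
#' @param fractionOfOptimum number in (0, 1].
#' @param loopless logical.
#' @param reactions reaction ids to analyze (default: all).
#' @return an [FVAResult-class].
#' @export
fluxVariability <- function(model, scenario = NULL, objective = NULL,
                            fractionOfOptimum = 1, loopless = FALSE,
                            reactions = NULL) {
  noobj <- is.null(objective)
  sys <- .fba_system(model, scenario,
                     if (noobj) numeric() else objective)
  rxn_ids <- colnames(sys$S)
  if (is.null(reactions)) reactions <- rxn_ids
  idx <- match(reactions, rxn_ids)
  if (anyNA(idx)) stop("unknown reaction '", reactions[is.na(idx)][1], "'")

  A <- as.matrix(sys$S)
  lb <- sys$lb; ub <- sys$ub
  if (!noobj) {
    base <- .lp(A, lb, ub, sys$obj)
    if (base$status != "optimal")
      stop("FVA: base FBA problem is ", base$status)
    floor <- fractionOfOptimum * base$obj -
      1e-9 * max(1, abs(base$obj))
    # append row obj'v - s = 0 with s >= floor
    A <- rbind(A, sys$obj)
    A <- cbind(A, c(rep(0, nrow(A) - 1), -1))
    lb <- c(lb, floor); ub <- c(ub, Inf)
  }
  nv <- length(rxn_ids)
  res <- data.frame(reaction = reactions,
                    min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  if (loopless) res$cycle_excluded_min <- res$cycle_excluded_max <- NA_real_
  boundary <- model@reactions$kind %in% .BOUNDARY_KINDS

  for (k in seq_along(idx)) {
    j <- idx[k]
    cvec <- numeric(ncol(A)); cvec[j] <- 1
    for (dir in c("min", "max")) {
      r <- .lp(A, lb, ub, cvec, maximize = (dir == "max"))
      if (r$status == "infeasible")
        stop("FVA subproblem infeasible for reaction '", rxn_ids[j], "'")
      val <- if (r$status == "unbounded") {
        if (dir == "max") Inf else -Inf
      } else r$x[j]
      if (loopless && is.finite(val) && r$status == "optimal") {
        v <- r$x[seq_len(nv)]
        clean <- .strip_cycles(sys$S, sys$lb, sys$ub, v, boundary)
        res[[paste0("cycle_excluded_", dir)]][k] <- val - clean[j]
        val <- clean[j]
      }
      res[[dir]][k] <- val
    }
  }
  # guard against solver jitter producing min slightly above max
  swap <- !is.na(res$min) & !is.na(res$max) & res$min > res$max
  if (any(swap)) {
    mid <- (res$min[swap] + res$max[swap]) / 2
    res$min[swap] <- res$max[swap] <- mid
  }
  new("FVAResult", ranges = res,
      fractionOfOptimum = if (noobj) NA_real_ else fractionOfOptimum,
      loopless = loopless)
}

# Remove internal-cycle flux from a flux vector: fix all boundary fluxes
# at their current values and minimize the taxicab norm of the rest.
.strip_cycles <- function(S, lb, ub, v, boundary) {
  lb2 <- lb; ub2 <- ub
  lb2[boundary] <- ub2[boundary] <- v[boundary]
  l1 <- .l1_system(S, lb2, ub2)
  res <- .lp(l1$A, l1$lb, l1$ub, l1$cost, maximize = FALSE)
  if (res$status != "optimal") return(v)  # keep original if stripping fails
  out <- res$x[seq_len(l1$n)]
  names(out) <- colnames(S)
  out
}

#' Shadow prices of boundary metabolites
#'
#' Reports, for every metabolite touched by an exchange reaction, the
#' marginal increase of the FBA optimum per unit relaxation of that
#' exchange's binding uptake bound (the LP dual of the bound constraint).
#' The sign convention is fixed so that a limiting resource has a positive
#' price and a non-binding bound has price zero.
#'
#' Degenerate optima can have non-unique duals; with \code{check = TRUE}
#' each price is compared against a finite-difference perturbation of the
#' bound and flagged when the two disagree.
#'
#' @inheritParams solveFBA
#' @param check logical: verify each price by perturbation.
#' @param eps perturbation size for the check.
#' @return data.frame with columns \code{metabolite}, \code{exchange},
#'   \code{price} and (if checked) \code{degenerate}.
#' @export
shadowPrices <- function(model, scenario = NULL, objective = NULL,
                         check = FALSE, eps = 1e-4) {
  sys <- .fba_system(model, scenario, objective)
  res <- .lp(sys$S, sys$lb, sys$ub, sys$obj)
  if (res$status != "optimal")
    stop("shadow prices undefined: FBA status ", res$status)
  rxn <- sys$model@reactions
  ex <- which(rxn$kind == "exchange")
  Sall <- sys$model@stoichiometry
  out <- data.frame(metabolite = character(), exchange = character(),
                    price = numeric(), stringsAsFactors = FALSE)
  for (j in ex) {
    met <- rownames(Sall)[which(Sall[, j] != 0)][1]
    # uptake bound binding <=> exchange flux nonbasic at its lower bound
    price <- if (res$vstat[j] == 0L && is.finite(sys$lb[j]))
      -res$d[j] else 0
    if (abs(price) < 1e-12) price <- 0
    out <- rbind(out, data.frame(metabolite = met, exchange = rxn$id[j],
                                 price = price, stringsAsFactors = FALSE))
  }
  if (check) {
    out$degenerate <- FALSE
    for (k in seq_len(nrow(out))) {
      j <- match(out$exchange[k], rxn$id)
      lb2 <- sys$lb; lb2[j] <- lb2[j] - eps
      r2 <- .lp(sys$S, lb2, sys$ub, sys$obj)
      fd <- if (r2$status == "optimal") (r2$obj - res$obj) / eps else NA
      if (is.na(fd) || abs(fd - out$price[k]) > 1e-4 * max(1, abs(fd)))
        out$degenerate[k] <- TRUE
    }
  }
  out
}

#' Phenotype phase plane analysis
#'
#' For every combination of uptake rates of two exchange reactions, the
#' uptake fluxes are fixed at the grid values (the classic phenotype
#' phase plane construction), the FBA optimum is computed, and the shadow
#' price of each axis metabolite is recorded: the marginal change of the
#' optimum per unit additional uptake. Prices can be negative in regions
#' where the cell is forced to dissipate excess substrate. Prices are
#' quantized to sign (zero within \code{tol}, else +/-) and phases are
#' the maximal 4-connected grid regions with identical sign signature;
#' infeasible cells are labeled 0.
#'
#' @inheritParams solveFBA
#' @param rxnA,rxnB exchange reaction ids for the two axes.
#' @param gridA,gridB uptake magnitudes (nonnegative; the exchange flux
#'   is fixed to \code{-g}).
#' @param tol shadow-price sign tolerance.
#' @return a [PhasePlane-class].
#' @export
phasePlane <- function(model, rxnA, rxnB, gridA, gridB, objective = NULL,
                       scenario = NULL, tol = 1e-6) {
  sys <- .fba_system(model, scenario, objective)
  rxn <- sys$model@reactions
  ia <- match(rxnA, rxn$id); ib <- match(rxnB, rxn$id)
  if (is.na(ia) || is.na(ib)) stop("unknown exchange reaction")
  if (!all(rxn$kind[c(ia, ib)] == "exchange"))
    stop("phase plane axes must be exchange reactions")
  nA <- length(gridA); nB <- length(gridB)
  objm <- sA <- sB <- matrix(NA_real_, nA, nB)
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      lb <- sys$lb; ub <- sys$ub
      lb[ia] <- ub[ia] <- -gridA[i]
      lb[ib] <- ub[ib] <- -gridB[j]
      r <- .lp(sys$S, lb, ub, sys$obj)
      if (r$status != "optimal") next
      objm[i, j] <- r$obj
      # uptake +1 unit means exchange flux -1 unit: price = -reduced cost
      sA[i, j] <- -r$d[ia]
      sB[i, j] <- -r$d[ib]
    }
  }
  sig <- function(x) ifelse(is.na(x), NA_integer_,
                            ifelse(abs(x) <= tol, 0L, ifelse(x > 0, 1L, -1L)))
  sigA <- sig(sA); sigB <- sig(sB)
  phases <- matrix(0L, nA, nB)
  lab <- 0L
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    if (is.na(objm[i, j]) || phases[i, j] != 0L) next
    lab <- lab + 1L
    queue <- list(c(i, j))
    phases[i, j] <- lab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        p <- cur + d
        if (p[1] < 1 || p[1] > nA || p[2] < 1 || p[2] > nB) next
        if (phases[p[1], p[2]] != 0L || is.na(objm[p[1], p[2]])) next
        if (identical(sigA[p[1], p[2]], sigA[cur[1], cur[2]]) &&
            identical(sigB[p[1], p[2]], sigB[cur[1], cur[2]])) {
          phases[p[1], p[2]] <- lab
          queue <- c(queue, list(p))
        }
      }
    }
  }
  new("PhasePlane", axes = c(rxnA, rxnB), gridA = gridA, gridB = gridB,
      objective = objm, shadowA = sA, shadowB = sB, phases = phases)
}

#' @describeIn phasePlane number of feasible phases
#' @param x a PhasePlane.
#' @export
nPhases <- function(x) length(setdiff(unique(as.vector(x@phases)), 0L))

#' In silico single-gene deletion
#'
#' For each gene, every reaction whose GPR rule evaluates FALSE under the
#' deletion is disabled, and the maximum nitrogenase flux is computed. A
#' gene is essential when its deletion prevents flux through nitrogenase
#' (optimum below \code{threshold}, or infeasibility of the constrained
#' problem).
#'
#' @inheritParams solveFBA
#' @param genes genes to delete (default: all model genes).
#' @param threshold essentiality flux threshold (flux units).
#' @return data.frame with columns \code{gene}, \code{status},
#'   \code{max_flux}, \code{essential}.
#' @export
singleGeneDeletion <- function(model, scenario = NULL,
                               genes = NULL, threshold = 1e-6) {
  if (is.na(model@nitrogenase))
    stop("model has no designated nitrogenase reaction")
  sys <- .fba_system(model, scenario,
                     stats::setNames(1, model@nitrogenase))
  if (is.null(genes)) genes <- sys$model@genes
  rxn <- sys$model@reactions
  trees <- lapply(rxn$gpr, parseGpr)
  gene_of <- lapply(trees, function(t) if (is.null(t)) character()
                    else gprGenes(t))
  out <- data.frame(gene = genes, status = NA_character_,
                    max_flux = NA_real_, essential = NA,
                    stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    g <- genes[k]
    hit <- which(vapply(seq_along(trees), function(j) {
      (g %in% gene_of[[j]]) && !evaluateGpr(trees[[j]], g)
    }, logical(1)))
    lb <- sys$lb; ub <- sys$ub
    lb[hit] <- ub[hit] <- 0
    r <- .lp(sys$S, lb, ub, sys$obj)
    out$status[k] <- r$status
    if (r$status == "optimal") {
      out$max_flux[k] <- r$obj
      out$essential[k] <- r$obj < threshold
    } else if (r$status == "infeasible") {
      out$essential[k] <- TRUE
    } else {
      stop("gene deletion LP ", r$status, " for gene '", g, "'")
    }
  }
  out
}

#' Specification of a random-objective ensemble
#'
#' @param nObjectives number of random objectives (the study-scale default
#'   is 50000; tests and examples use far fewer).
#' @param seed integer seed; the objective draws are fully reproducible.
#' @param pool candidate reaction ids for objective membership (default:
#'   all reactions).
#' @param minNitrogenase lower bound imposed on the nitrogenase reaction
#'   during ensemble solves (flux units).
#' @param scenario optional [ScenarioConstraints-class] applied to every
#'   solve.
#' @return list with class \code{"EnsembleSpec"}.
#' @export
ensembleSpec <- function(nObjectives = 50000, seed = 1, pool = NULL,
                         minNitrogenase = 0.01, scenario = NULL) {
  stopifnot(nObjectives >= 1)
  structure(list(nObjectives = as.integer(nObjectives),
                 seed = as.integer(seed), pool = pool,
                 minNitrogenase = minNitrogenase, scenario = scenario),
            class = "EnsembleSpec")
}

#' Ensemble-evolutionary FBA
#'
#' Probes general network properties without committing to one objective:
#' each ensemble member maximizes a random objective (a uniformly drawn
#' number of reactions, each with a uniform (0, 1] weight), subject to the
#' scenario bounds and a minimum nitrogenase flux. The sweep sets the
#' lower bound of one reaction (typically the oxygen exchange) to each
#' value in turn. Infeasible draws are skipped, not resampled, so the
#' draw stream is seed-stable; their count is reported.
#'
#' @param model a [MetabolicModel-class].
#' @param spec an [ensembleSpec()].
#' @param sweepReaction reaction id whose lower bound is swept.
#' @param sweepBounds numeric vector of lower-bound values (e.g. negative
#'   oxygen uptake limits).
#' @param track reaction ids to aggregate (default: all).
#' @return list with \code{summary} (data.frame: sweep value, reaction,
#'   mean, sd, n_feasible) and \code{skipped} (infeasible draw count per
#'   sweep point).
#' @export
randomObjectiveEnsemble <- function(model, spec, sweepReaction,
                                    sweepBounds, track = NULL) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  sys <- .fba_system(model, spec$scenario, numeric())
  rxn_ids <- colnames(sys$S)
  pool <- if (is.null(spec$pool)) rxn_ids else spec$pool
  stopifnot(all(pool %in% rxn_ids))
  if (is.null(track)) track <- rxn_ids
  sj <- match(sweepReaction, rxn_ids)
  if (is.na(sj)) stop("unknown sweep reaction '", sweepReaction, "'")
  nitro <- model@nitrogenase
  lb0 <- sys$lb; ub0 <- sys$ub
  if (!is.na(nitro) && !is.na(spec$minNitrogenase)) {
    nj <- match(nitro, rxn_ids)
    lb0[nj] <- max(lb0[nj], spec$minNitrogenase)
  }
  # pre-draw the whole objective stream once, so that every sweep point
  # sees the same ensemble
  set.seed(spec$seed)
  draws <- vector("list", spec$nObjectives)
  for (k in seq_len(spec$nObjectives)) {
    m <- sample.int(length(pool), 1)
    ids <- sample(pool, m)
    w <- 1 - stats::runif(m)  # uniform on (0, 1]
    draws[[k]] <- stats::setNames(w, ids)
  }
  A <- as.matrix(sys$S)
  out <- list(); skipped <- integer(length(sweepBounds))
  ti <- match(track, rxn_ids)
  for (s in seq_along(sweepBounds)) {
    lb <- lb0; lb[sj] <- sweepBounds[s]
    ub <- ub0
    acc <- matrix(NA_real_, spec$nObjectives, length(track))
    for (k in seq_len(spec$nObjectives)) {
      obj <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
      obj[names(draws[[k]])] <- draws[[k]]
      r <- .lp(A, lb, ub, obj)
      if (r$status == "optimal") {
        acc[k, ] <- r$x[ti]
      } else {
        skipped[s] <- skipped[s] + 1L
      }
    }
    ok <- !is.na(acc[, 1])
    out[[s]] <- data.frame(
      sweep = sweepBounds[s], reaction = track,
      mean = if (any(ok)) colMeans(acc[ok, , drop = FALSE]) else NA_real_,
      sd = if (sum(ok) > 1) apply(acc[ok, , drop = FALSE], 2, stats::sd)
           else 0,
      n_feasible = sum(ok), stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, out), skipped = skipped)
}
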