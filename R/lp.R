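# Thin R wrapper around the C++ bounded-variable simplex.

.LP_STATUS <- c(`0` = "optimal", `1` = "infeasible", `2` = "unbounded",
                `3` = "maxiter", `4` = "singular")

# Solve  max/min  obj' v  s.t.  A v = b,  lb <= v <= ub.
# A may be a sparse Matrix; names are carried through to the solution.
.lp <- function(A, lb, ub, obj, maximize = TRUE, b = NULL, tol = 1e-9) {
  A <- as.matrix(A)
  if (is.null(b)) b <- numeric(nrow(A))
  res <- cpp_simplex(A, b, as.numeric(lb), as.numeric(ub),
                     as.numeric(obj), maximize, tol)
  status <- .LP_STATUS[[as.character(res$status)]]
  if (status %in% c("maxiter", "singular"))
    stop("LP solver failed (", status, ") on a ", nrow(A), "x", ncol(A),
         " problem")
  out <- list(status = status)
  if (status == "optimal") {
    x <- as.numeric(res$x)
    names(x) <- colnames(A)
    y <- as.numeric(res$y)
    names(y) <- rownames(A)
    d <- as.numeric(res$d)
    names(d) <- colnames(A)
    vstat <- as.integer(res$vstat)
    names(vstat) <- colnames(A)
    out <- c(out, list(x = x, obj = as.numeric(res$obj), y = y, d = d,
                       vstat = vstat))
  }
  out
}

# Assemble the FBA constraint system for a model under a scenario:
# internal-metabolite rows of S, reaction bounds, named objective vector.
.fba_system <- function(model, scenario = NULL, objective = NULL) {
  model <- applyScenario(model, scenario)
  rxn <- model@reactions
  S <- stoichiometricMatrix(model, rows = "internal")
  obj <- stats::setNames(numeric(nrow(rxn)), rxn$id)
  if (is.character(objective))
    objective <- stats::setNames(rep(1, length(objective)), objective)
  if (is.null(objective)) {
    objective <- if (!is.null(scenario) && length(scenario@objective)) {
      scenario@objective
    } else if (!is.na(model@nitrogenase)) {
      stats::setNames(1, model@nitrogenase)
    } else {
      numeric()
    }
  }
  if (length(objective)) {
    idx <- match(names(objective), rxn$id)
    if (anyNA(idx))
      stop("objective references unknown reaction '",
           names(objective)[is.na(idx)][1], "'")
    obj[idx] <- objective
  }
  list(model = model, S = S, lb = rxn$lower, ub = rxn$upper, obj = obj)
}
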