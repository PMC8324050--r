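# Model construction, accessors, and network consistency checks.

#' Describe one reaction for model construction
#'
#' @param id reaction id.
#' @param stoich named numeric vector of signed coefficients
#'   (negative = consumed), names are metabolite ids.
#' @param lower,upper flux bounds (flux units).
#' @param name free-text name.
#' @param gpr GPR rule string (\code{""} = no gene association).
#' @param kind one of \code{"metabolic"}, \code{"transport"},
#'   \code{"exchange"}, \code{"demand"}, \code{"sink"}.
#' @return a list consumed by [newMetabolicModel()].
#' @export
reaction <- function(id, stoich, lower = -1000, upper = 1000, name = id,
                     gpr = "", kind = "metabolic") {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), length(stoich) > 0)
  list(id = id, stoich = stoich, lower = lower, upper = upper,
       name = name, gpr = gpr, kind = kind)
}

#' Construct a MetabolicModel
#'
#' @param id model name.
#' @param metabolites data.frame with column \code{id} and optionally
#'   \code{name}, \code{compartment} (default \code{"internal"}),
#'   \code{formula}, \code{charge}.
#' @param reactions list of [reaction()] descriptions.
#' @param genes gene id vector; defaults to the union of all GPR genes.
#' @param nitrogenase id of the nitrogenase reaction (or \code{NA}).
#' @return a validated [MetabolicModel-class] object.
#' @examples
#' m <- newMetabolicModel("toy",
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = list(
#'     reaction("up",  c(A = 1),        lower = 0, upper = 10, kind = "exchange"),
#'     reaction("cnv", c(A = -1, B = 1), lower = 0),
#'     reaction("out", c(B = -1),       lower = 0, kind = "exchange")))
#' @export
newMetabolicModel <- function(id, metabolites, reactions, genes = NULL,
                              nitrogenase = NA_character_) {
  met <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$compartment))
    met$compartment <- rep_len("internal", nrow(met))
  if (is.null(met$formula)) met$formula <- rep_len(NA_character_, nrow(met))
  if (is.null(met$charge)) met$charge <- rep_len(NA_integer_, nrow(met))
  met <- met[, c("id", "name", "compartment", "formula", "charge")]
  rownames(met) <- NULL

  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id: '", rids[duplicated(rids)][1], "'")
  rxn <- data.frame(
    id = rids,
    name = vapply(reactions, `[[`, character(1), "name"),
    lower = vapply(reactions, `[[`, numeric(1), "lower"),
    upper = vapply(reactions, `[[`, numeric(1), "upper"),
    gpr = vapply(reactions, `[[`, character(1), "gpr"),
    kind = vapply(reactions, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE
  )

  ii <- jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(reactions)) {
    st <- reactions[[k]]$stoich
    idx <- match(names(st), met$id)
    if (anyNA(idx))
      stop("reaction '", rids[k], "' references unknown metabolite '",
           names(st)[is.na(idx)][1], "'")
    ii <- c(ii, idx); jj <- c(jj, rep(k, length(st))); xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(met), nrow(rxn)),
                            dimnames = list(met$id, rxn$id))
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(rxn$gpr, gprGenes))))
  new("MetabolicModel", modelId = id, metabolites = met, reactions = rxn,
      stoichiometry = S, genes = as.character(genes),
      nitrogenase = as.character(nitrogenase))
}

#' @describeIn newMetabolicModel metabolite table accessor
#' @param model a MetabolicModel.
#' @export
metabolites <- function(model) model@metabolites

#' @describeIn newMetabolicModel reaction table accessor
#' @export
reactions <- function(model) model@reactions

#' @describeIn newMetabolicModel gene id accessor
#' @export
genes <- function(model) model@genes

#' @describeIn newMetabolicModel nitrogenase reaction id accessor
#' @export
nitrogenaseReaction <- function(model) model@nitrogenase

#' Stoichiometric matrix over internal metabolites
#'
#' Returns the matrix S with one row per internal metabolite and one column
#' per reaction; entry (i, j) is the coefficient of metabolite i in reaction
#' j. External (boundary-pool) metabolites are excluded from the rows: they
#' are not balanced at steady state. All constraint-based analyses in this
#' package operate on the flux cone \{v : S v = 0, bounds\}.
#'
#' @param model a [MetabolicModel-class].
#' @param rows \code{"internal"} (default), \code{"external"} or
#'   \code{"all"}.
#' @return a sparse Matrix with dimnames.
#' @export
stoichiometricMatrix <- function(model,
                                 rows = c("internal", "external", "all")) {
  rows <- match.arg(rows)
  S <- model@stoichiometry
  if (rows == "all") return(S)
  keep <- model@metabolites$compartment == rows
  S[keep, , drop = FALSE]
}

#' Update flux bounds of named reactions
#'
#' @param model a MetabolicModel.
#' @param id reaction id(s).
#' @param lower,upper new bounds (recycled; \code{NA} leaves a bound
#'   untouched).
#' @return the modified model.
#' @export
setBounds <- function(model, id, lower = NA, upper = NA) {
  idx <- match(id, model@reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id: '", id[is.na(idx)][1], "'")
  lower <- rep_len(lower, length(idx))
  upper <- rep_len(upper, length(idx))
  sel <- !is.na(lower)
  model@reactions$lower[idx[sel]] <- lower[sel]
  sel <- !is.na(upper)
  model@reactions$upper[idx[sel]] <- upper[sel]
  if (any(model@reactions$lower[idx] > model@reactions$upper[idx])) {
    bad <- idx[model@reactions$lower[idx] > model@reactions$upper[idx]][1]
    stop("lower bound exceeds upper bound for '", model@reactions$id[bad], "'")
  }
  model
}

#' Parse a Hill-style elemental formula
#'
#' @param x formula string such as \code{"C4H6O5"}; only C, H, N, O, P, S
#'   are accepted and counts must be nonnegative integers.
#' @return named integer vector over C, H, N, O, P, S.
#' @examples
#' parseFormula("C4H6O5")
#' @export
parseFormula <- function(x) {
  out <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (is.na(x) || !nzchar(x)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (!nzchar(gsub("([A-Z][a-z]?)([0-9]*)", "", x))) {
    for (t in toks) {
      el <- gsub("[0-9]", "", t)
      n <- gsub("[^0-9]", "", t)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!(el %in% .ELEMENTS))
        stop("unsupported element '", el, "' in formula '", x, "'")
      out[el] <- out[el] + n
    }
    return(out)
  }
  stop("unparseable formula '", x, "'")
}

#' Check elemental balance of every reaction
#'
#' Sums coefficient x atom count over the participants of each metabolic
#' and transport reaction. Boundary reactions (exchange/demand/sink) are by
#' construction unbalanced and skipped; reactions touching a metabolite
#' without a formula are reported separately under \code{unknown} and no
#' imbalance is claimed for them.
#'
#' @param model a [MetabolicModel-class].
#' @param tol absolute tolerance below which an element is considered
#'   balanced.
#' @return list with \code{imbalances} (named list: reaction id -> named
#'   numeric vector of nonzero per-element imbalances; balanced reactions
#'   report an empty vector and are omitted) and \code{unknown} (reaction
#'   ids skipped for missing formulas).
#' @export
checkElementalBalance <- function(model, tol = 1e-9) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  fm <- matrix(NA_real_, nrow(met), length(.ELEMENTS),
               dimnames = list(met$id, .ELEMENTS))
  has_formula <- !is.na(met$formula)
  for (i in which(has_formula)) fm[i, ] <- parseFormula(met$formula[i])

  imb <- list(); unknown <- character()
  check <- which(!(rxn$kind %in% .BOUNDARY_KINDS))
  for (j in check) {
    coef <- S[, j]
    part <- which(coef != 0)
    if (any(!has_formula[part])) {
      unknown <- c(unknown, rxn$id[j])
      next
    }
    net <- as.vector(coef[part] %*% fm[part, , drop = FALSE])
    names(net) <- .ELEMENTS
    net <- net[abs(net) > tol]
    if (length(net)) imb[[rxn$id[j]]] <- net
  }
  list(imbalances = imb, unknown = unknown)
}

#' Detect orphan metabolites, dead-end reactions, and balanced cycles
#'
#' Three consistency checks on a model:
#' \itemize{
#' \item \emph{Orphan metabolites} (structural): internal metabolites with
#'   no producing or no consuming reaction, taking reversibility into
#'   account.
#' \item \emph{Dead-end (blocked) reactions} (functional): reactions that
#'   cannot carry any steady-state flux when every boundary reaction is
#'   opened wide, found by flux variability with a zero objective.
#' \item \emph{Stoichiometrically balanced cycles}: reactions that still
#'   admit a nonzero flux range when every exchange, demand and sink is
#'   fixed to zero; such flux can only circulate in internal loops.
#' }
#'
#' @param model a [MetabolicModel-class].
#' @param tol flux-range threshold above which a closed-boundary range is
#'   flagged as a cycle (model flux units).
#' @param open magnitude used to open boundary reactions for the blocked
#'   check.
#' @return list with character vectors \code{orphan_never_produced},
#'   \code{orphan_never_consumed}, \code{dead_end_reactions},
#'   \code{balanced_cycle_reactions}, and logical \code{clean}.
#' @export
findNetworkGaps <- function(model, tol = 1e-6, open = 1000) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  internal <- met$compartment == "internal"

  # structural orphans: a reaction produces m if coef>0 and upper>0, or
  # coef<0 and lower<0 (it can run backwards); mirrored for consumption
  produced <- consumed <- rep(FALSE, nrow(met))
  for (j in seq_len(nrow(rxn))) {
    coef <- S[, j]
    fw <- rxn$upper[j] > 0
    bw <- rxn$lower[j] < 0
    produced <- produced | (coef > 0 & fw) | (coef < 0 & bw)
    consumed <- consumed | (coef < 0 & fw) | (coef > 0 & bw)
  }
  # boundary reactions make their sole metabolite exchangeable either way
  never_prod <- met$id[internal & !produced]
  never_cons <- met$id[internal & !consumed]

  boundary <- rxn$kind %in% .BOUNDARY_KINDS
  # blocked reactions: FVA with zero objective, boundaries wide open
  m_open <- model
  m_open@reactions$lower[boundary] <- pmin(rxn$lower[boundary], -open)
  m_open@reactions$lower[boundary & rxn$lower >= 0] <- 0
  m_open@reactions$upper[boundary] <- pmax(rxn$upper[boundary], open)
  fva <- fluxVariability(m_open, objective = NULL)
  rng <- fva@ranges
  dead <- rng$reaction[pmax(abs(rng$min), abs(rng$max)) < tol]

  # balanced cycles: close every boundary reaction, repeat
  m_closed <- model
  m_closed@reactions$lower[boundary] <- 0
  m_closed@reactions$upper[boundary] <- 0
  fva2 <- fluxVariability(m_closed, objective = NULL)
  rng2 <- fva2@ranges
  cyc <- rng2$reaction[pmax(abs(rng2$min), abs(rng2$max)) > tol]

  out <- list(orphan_never_produced = never_prod,
              orphan_never_consumed = never_cons,
              dead_end_reactions = setdiff(dead, rxn$id[boundary]),
              balanced_cycle_reactions = cyc)
  out$clean <- all(lengths(out[1:4]) == 0)
  out
}
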