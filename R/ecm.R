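# Elementary conversion mode (ECM) enumeration.
#
# The conversion cone is {c : c = S_ext v, S_int v = 0, v in the
# irreversibility cone, direction constraints on c}. Reversible reactions
# are split into irreversible pairs, the flux cone's extreme rays are
# computed by an incremental double description method in exact integer
# arithmetic (stoichiometric coefficients are cleared of denominators
# first; spurious rays from rounding are impossible), rays using both
# directions of a split reaction are discarded as cycle artifacts, the
# rays are projected onto the tracked (external) metabolites, and the
# projected generators are reduced to the extreme rays of the conversion
# cone: deduplication up to positive scaling in exact arithmetic, then
# removal of any generator that is a nonnegative combination of the
# others (LP test).

#' Configuration of an ECM analysis
#'
#' Partitions the tracked boundary metabolites. Listing an internal
#' metabolite externalizes it explicitly (its steady-state constraint is
#' replaced by conversion bookkeeping, standing in for its boundary
#' reaction). Hidden metabolites are removed from the bookkeeping
#' entirely, i.e. treated as freely exchangeable cofactor pools. Tracked
#' and hidden metabolites must be disjoint; unlisted metabolites remain
#' balanced.
#'
#' @param inputs metabolite ids usable only as net consumption.
#' @param outputs ids usable only as net production.
#' @param free ids usable in either direction.
#' @param hidden ids dropped from the bookkeeping.
#' @return list with class \code{"EcmConfig"}.
#' @export
ecmConfig <- function(inputs = character(), outputs = character(),
                      free = character(), hidden = character()) {
  all_ids <- c(inputs, outputs, free, hidden)
  if (anyDuplicated(all_ids))
    stop("ECM config sets must be disjoint; duplicated: '",
         all_ids[duplicated(all_ids)][1], "'")
  structure(list(inputs = inputs, outputs = outputs, free = free,
                 hidden = hidden), class = "EcmConfig")
}

# continued-fraction rational approximation; errors if x is not (close
# to) a small rational, which would make exact arithmetic meaningless
.rationalize <- function(x, maxden = 1e6, tol = 1e-9) {
  n0 <- 0; d0 <- 1; n1 <- 1; d1 <- 0; b <- x
  repeat {
    a <- floor(b)
    n2 <- a * n1 + n0; d2 <- a * d1 + d0
    if (d2 > maxden) break
    n0 <- n1; d0 <- d1; n1 <- n2; d1 <- d2
    if (abs(x - n1 / d1) < tol * max(1, abs(x))) return(c(num = n1, den = d1))
    if (b == a) break
    b <- 1 / (b - a)
  }
  stop("coefficient ", x, " is not a small rational; rescale the model")
}

.gcd2 <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}
.gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  Reduce(.gcd2, v)
}

.OVERFLOW_LIMIT <- 2^40

# reduce an integer ray by its gcd; guard against double-precision loss
.reduce_ray <- function(r) {
  g <- .gcd_vec(r)
  if (g > 1) r <- r / g
  if (max(abs(r)) > .OVERFLOW_LIMIT)
    stop("exact arithmetic overflow during ECM enumeration; ",
         "rescale the model to smaller integer coefficients")
  r
}

# Double description: extreme rays of {v >= 0, E v = 0, I v >= 0}.
# E, I integer matrices (rows are constraints). Returns integer matrix
# with one column per ray.
.dd_rays <- function(nvar, E, I) {
  rays <- diag(nvar)
  # zero-set bookkeeping: rows = nonneg constraints + processed rows
  zero <- rays == 0
  nE <- if (is.null(E)) 0L else nrow(E)
  nI <- if (is.null(I)) 0L else nrow(I)
  rows <- rbind(if (nE) cbind(E, type = 0) else NULL,
                if (nI) cbind(I, type = 1) else NULL)
  remaining <- seq_len(nE + nI)
  while (length(remaining)) {
    # greedy: process the row minimizing |P| * |N| (fewest candidate
    # combinations first)
    scores <- vapply(remaining, function(k) {
      s <- as.vector(rows[k, seq_len(nvar)] %*% rays)
      sum(s > 0) * sum(s < 0)
    }, numeric(1))
    k <- remaining[which.min(scores)]
    remaining <- setdiff(remaining, k)
    a <- rows[k, seq_len(nvar)]
    is_eq <- rows[k, nvar + 1] == 0
    s <- as.vector(a %*% rays)
    if (max(abs(s)) > .OVERFLOW_LIMIT)
      stop("exact arithmetic overflow during ECM enumeration; ",
           "rescale the model")
    P <- which(s > 0); N <- which(s < 0); Z <- which(s == 0)
    keep <- if (is_eq) Z else c(Z, P)
    new_rays <- list(); new_zero <- list()
    if (length(P) && length(N)) {
      for (p in P) {
        Tp <- zero[, p]
        for (n in N) {
          tset <- Tp & zero[, n]
          # combinatorial adjacency: no third ray's zero set contains tset
          cand <- colSums(!zero[tset, , drop = FALSE]) == 0
          if (sum(cand) != 2L) next
          r <- s[p] * rays[, n] - s[n] * rays[, p]
          r <- .reduce_ray(r)
          new_rays[[length(new_rays) + 1]] <- r
        }
      }
    }
    rays <- cbind(rays[, keep, drop = FALSE],
                  if (length(new_rays)) do.call(cbind, new_rays))
    if (ncol(rays) == 0) break
    # rebuild zero sets: coordinates, then all processed rows
    done <- setdiff(seq_len(nE + nI), remaining)
    zero <- rays == 0
    for (kk in done) {
      sv <- as.vector(rows[kk, seq_len(nvar)] %*% rays)
      zero <- rbind(zero, sv == 0)
    }
  }
  rays
}

#' Enumerate elementary conversion modes
#'
#' Computes the extreme rays of the conversion cone of \code{model} under
#' the input/output/free/hidden partition in \code{config}. Boundary
#' reactions (exchange/demand/sink) are removed first: the conversion
#' coefficients themselves take over their role. Every returned
#' conversion is reachable (a steady-state flux vector realizing it
#' exists; checked by LP when \code{verify = TRUE}) and elementary (not a
#' nonnegative combination of the other returned conversions).
#'
#' @param model a [MetabolicModel-class].
#' @param config an [ecmConfig()].
#' @param verify run the LP reachability check on every returned
#'   conversion (an assertion; failures are a bug, not a data property).
#' @return a [ConversionSet-class]; rows are integer-normalized (each
#'   divided by the gcd of its entries), consumption negative.
#' @examples
#' m <- newMetabolicModel("chain",
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = list(
#'     reaction("up",  c(A = 1),  lower = 0, upper = 10, kind = "exchange"),
#'     reaction("cnv", c(A = -1, B = 1), lower = 0),
#'     reaction("out", c(B = -1), lower = 0, kind = "exchange")))
#' enumerateEcms(m, ecmConfig(inputs = "A", outputs = "B"))
#' @export
enumerateEcms <- function(model, config, verify = TRUE) {
  stopifnot(inherits(config, "EcmConfig"))
  met <- model@metabolites
  rxn <- model@reactions
  tracked <- c(config$inputs, config$outputs, config$free)
  unknown <- setdiff(c(tracked, config$hidden), met$id)
  if (length(unknown))
    stop("ECM config references unknown metabolite '", unknown[1], "'")

  keep_rxn <- !(rxn$kind %in% .BOUNDARY_KINDS)
  S <- as.matrix(model@stoichiometry[, keep_rxn, drop = FALSE])
  rxn_ids <- rxn$id[keep_rxn]
  lb <- rxn$lower[keep_rxn]; ub <- rxn$upper[keep_rxn]

  # direction handling: reversed-only reactions are flipped; reversible
  # reactions are split into forward/backward parts
  fwd <- ub > 0
  bwd <- lb < 0
  cols <- list(); orig <- integer(); dir <- integer()
  for (j in seq_along(rxn_ids)) {
    if (fwd[j]) {
      cols[[length(cols) + 1]] <- S[, j]
      orig <- c(orig, j); dir <- c(dir, 1L)
    }
    if (bwd[j]) {
      cols[[length(cols) + 1]] <- -S[, j]
      orig <- c(orig, j); dir <- c(dir, -1L)
    }
  }
  Ssplit <- do.call(cbind, cols)
  nvar <- ncol(Ssplit)

  int_rows <- setdiff(met$id, c(tracked, config$hidden))

  # clear denominators per column (reaction): rescaling a reaction's flux
  # unit leaves both the flux cone and the projected conversions intact,
  # unlike row scaling, which would corrupt conversion coefficients
  for (j in seq_len(ncol(Ssplit))) {
    col <- Ssplit[, j]
    dens <- vapply(col[col != 0], function(x) .rationalize(x)[["den"]],
                   numeric(1))
    if (length(dens)) {
      l <- Reduce(function(a, b) a / .gcd2(a, b) * b, dens)
      Ssplit[, j] <- round(col * l)
    }
  }
  Sint_i <- Ssplit[int_rows, , drop = FALSE]
  Sext_i <- Ssplit[tracked, , drop = FALSE]

  # direction constraints on the conversion: inputs consumed, outputs
  # produced
  Ineq <- NULL
  for (id in config$inputs)
    Ineq <- rbind(Ineq, -Sext_i[id, ])
  for (id in config$outputs)
    Ineq <- rbind(Ineq, Sext_i[id, ])

  rays <- .dd_rays(nvar,
                   E = if (nrow(Sint_i)) Sint_i else NULL,
                   I = Ineq)

  # discard futile recombinations that use both directions of one reaction
  if (ncol(rays)) {
    both <- vapply(seq_len(ncol(rays)), function(k) {
      act <- orig[rays[, k] != 0]
      anyDuplicated(act) > 0
    }, logical(1))
    rays <- rays[, !both, drop = FALSE]
  }

  conv <- if (ncol(rays)) Sext_i %*% rays else
    matrix(0, length(tracked), 0, dimnames = list(tracked, NULL))
  # drop pure-internal rays and deduplicate up to positive scaling
  nz <- colSums(conv != 0) > 0
  conv <- conv[, nz, drop = FALSE]
  rays <- rays[, nz, drop = FALSE]
  if (ncol(conv)) {
    red <- apply(conv, 2, .reduce_ray)
    conv <- matrix(red, nrow = nrow(conv),
                   dimnames = list(tracked, NULL))
    key <- apply(conv, 2, paste, collapse = ",")
    first <- !duplicated(key)
    conv <- conv[, first, drop = FALSE]
    rays <- rays[, first, drop = FALSE]
  }

  # elementarity: drop any generator expressible as a nonnegative
  # combination of the remaining ones
  drop_composites <- function(conv) {
    repeat {
      k <- ncol(conv)
      if (k <= 1) return(conv)
      supp <- colSums(conv != 0)
      ord <- order(-supp)
      dropped <- FALSE
      for (i in ord) {
        others <- conv[, -i, drop = FALSE]
        r <- .lp(others, lb = rep(0, ncol(others)),
                 ub = rep(Inf, ncol(others)),
                 obj = rep(0, ncol(others)), b = conv[, i])
        if (r$status == "optimal") {
          conv <- conv[, -i, drop = FALSE]
          dropped <- TRUE
          break
        }
      }
      if (!dropped) return(conv)
    }
  }
  conv <- drop_composites(conv)

  if (verify && ncol(conv)) {
    for (i in seq_len(ncol(conv))) {
      A <- rbind(Sint_i, Sext_i)
      r <- .lp(A, lb = rep(0, nvar), ub = rep(Inf, nvar),
               obj = rep(0, nvar), b = c(numeric(nrow(Sint_i)), conv[, i]))
      if (r$status != "optimal")
        stop("internal error: conversion ", i,
             " failed the LP reachability check")
    }
  }

  trackers <- tracked[grepl("^flux tracker", met$name[match(tracked,
                                                            met$id)])]
  fm <- stats::setNames(met$formula[match(tracked, met$id)], tracked)
  new("ConversionSet", coefficients = t(conv), formulas = fm,
      trackers = trackers, normalization = "none")
}

#' @describeIn enumerateEcms conversion coefficient matrix accessor
#' @param x a ConversionSet.
#' @export
conversionMatrix <- function(x) x@coefficients

#' Add a virtual flux-tracking metabolite to a reaction
#'
#' Appends a virtual metabolite with coefficient +1 to the products of
#' \code{reaction_id} and registers it as an output-only external
#' metabolite. In any conversion, the tracker's coefficient equals the
#' tracked reaction's flux per unit conversion (the device used to read
#' glutamine synthetase activity off ECMs).
#'
#' @param model a [MetabolicModel-class].
#' @param reaction_id reaction to track.
#' @param tracker_id fresh metabolite id for the tracker.
#' @return the augmented model.
#' @export
addFluxTracker <- function(model, reaction_id, tracker_id) {
  if (tracker_id %in% model@metabolites$id)
    stop("tracker id '", tracker_id, "' collides with an existing ",
         "metabolite")
  j <- match(reaction_id, model@reactions$id)
  if (is.na(j)) stop("unknown reaction '", reaction_id, "'")
  met <- rbind(model@metabolites,
               data.frame(id = tracker_id,
                          name = paste0("flux tracker (", reaction_id, ")"),
                          compartment = "external",
                          formula = NA_character_, charge = NA_integer_,
                          stringsAsFactors = FALSE))
  S <- rbind(model@stoichiometry,
             Matrix::sparseMatrix(i = integer(), j = integer(),
                                  x = numeric(),
                                  dims = c(1, ncol(model@stoichiometry))))
  rownames(S) <- met$id
  S[tracker_id, j] <- 1
  model@metabolites <- met
  model@stoichiometry <- S
  methods::validObject(model)
  model
}

#' Rescale conversions to a common normalization
#'
#' Scales each conversion by a positive factor: either so that the total
#' carbon input is one mol C (\code{"unit_carbon_input"}) or so that the
#' largest absolute coefficient is one (\code{"unit_max_coeff"}). Ratios
#' between coefficients, and hence all conversion metrics, are preserved.
#'
#' @param x a [ConversionSet-class].
#' @param mode normalization mode.
#' @return the rescaled ConversionSet.
#' @export
normalizeConversions <- function(x, mode = c("unit_carbon_input",
                                             "unit_max_coeff")) {
  mode <- match.arg(mode)
  cf <- x@coefficients
  if (nrow(cf) == 0) { x@normalization <- mode; return(x) }
  fac <- if (mode == "unit_carbon_input") {
    cin <- .element_side(cf, x@formulas, "C", "input")
    if (any(cin <= 0))
      stop("conversion ", which(cin <= 0)[1],
           " has no carbon input; cannot normalize")
    cin
  } else {
    mx <- apply(abs(cf), 1, max)
    if (any(mx == 0)) stop("all-zero conversion cannot be normalized")
    mx
  }
  x@coefficients <- cf / fac
  x@normalization <- mode
  x
}
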