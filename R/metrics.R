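# Bacteroid-specific metrics over conversions, classification, biological
# filters, and Spearman rank correlation.

# per-conversion summed atom flux on one side; cf = conversions x mets
.element_side <- function(cf, formulas, element, side) {
  ids <- colnames(cf)
  counts <- vapply(ids, function(id) {
    f <- formulas[[id]]
    if (is.na(f)) NA_real_ else parseFormula(f)[[element]]
  }, numeric(1))
  part <- if (side == "input") pmin(cf, 0) else pmax(cf, 0)
  used <- abs(part) > 1e-12
  for (i in seq_len(nrow(cf))) {
    bad <- used[i, ] & is.na(counts)
    if (any(bad))
      stop("metabolite '", ids[bad][1], "' participates in conversion ",
           i, " but has no formula")
  }
  counts[is.na(counts)] <- 0
  as.vector(abs(part) %*% counts)
}

#' Summed elemental flux of conversions
#'
#' Sums |coefficient| x atom count over the metabolites on one side of
#' each conversion (inputs: negative coefficients; outputs: positive).
#' Virtual tracker metabolites carry no formula and must not participate;
#' a missing formula on a participating metabolite is an error naming it.
#'
#' @param x a [ConversionSet-class].
#' @param element one of C, H, N, O, P, S.
#' @param side \code{"input"} or \code{"output"}.
#' @return numeric vector, mol atoms per unit conversion.
#' @export
elementFlux <- function(x, element, side = c("input", "output")) {
  side <- match.arg(side)
  stopifnot(element %in% .ELEMENTS)
  cf <- x@coefficients
  keep <- setdiff(colnames(cf), x@trackers)
  .element_side(cf[, keep, drop = FALSE], x@formulas[keep], element, side)
}

#' Carbon cost per nitrogen secreted
#'
#' Cost in grams of carbon invested per gram of nitrogen delivered:
#' \deqn{cost = 12.011 (C_{in} - C_{out,credited}) / (14.007 (N_{out} -
#' N_{in,organic}))}
#' Credited carbon outputs are the secreted organic metabolites; CO2 is
#' waste and storage polymers are retained by the bacteroid, so neither
#' is credited by default and polymer carbon counts toward the cost.
#' Organic nitrogen input excludes N2 itself (the substrate being fixed).
#' Conversions with no net nitrogen secretion have an undefined cost
#' (NA, flagged) but remain reportable.
#'
#' @param x a [ConversionSet-class].
#' @param polymer_ids metabolite ids of storage polymers (uncredited).
#' @param credit_co2,credit_polymers alternative crediting rules, off by
#'   default.
#' @param masses atomic masses used for the gram conversion.
#' @return data.frame with columns \code{carbon_cost_g_per_g_n} and
#'   \code{net_n_out} (mol N secreted).
#' @export
carbonCostPerNitrogen <- function(x, polymer_ids = character(),
                                  credit_co2 = FALSE,
                                  credit_polymers = FALSE,
                                  masses = c(C = 12.011, N = 14.007)) {
  cf <- x@coefficients
  keep <- setdiff(colnames(cf), x@trackers)
  cf <- cf[, keep, drop = FALSE]
  fm <- x@formulas[keep]
  c_in <- .element_side(cf, fm, "C", "input")
  n_out <- .element_side(cf, fm, "N", "output")
  n_in <- .element_side(cf, fm, "N", "input")
  # organic N input: exclude N2
  if ("n2" %in% colnames(cf)) {
    n2 <- pmin(cf[, "n2"], 0)
    n_in <- n_in - abs(n2) * 2
  }
  uncred <- character()
  if (!credit_co2) {
    is_co2 <- vapply(colnames(cf), function(id) {
      f <- fm[[id]]
      !is.na(f) && all(parseFormula(f) == c(C = 1, H = 0, N = 0, O = 2,
                                            P = 0, S = 0))
    }, logical(1))
    uncred <- c(uncred, colnames(cf)[is_co2])
  }
  if (!credit_polymers) uncred <- c(uncred, polymer_ids)
  cred_cols <- setdiff(colnames(cf), uncred)
  c_out <- .element_side(cf[, cred_cols, drop = FALSE], fm[cred_cols],
                         "C", "output")
  net_n <- n_out - n_in
  cost <- ifelse(net_n > 1e-12,
                 masses[["C"]] * (c_in - c_out) / (masses[["N"]] * net_n),
                 NA_real_)
  data.frame(carbon_cost_g_per_g_n = cost, net_n_out = net_n)
}

#' Classify conversions by product type
#'
#' @param x a [ConversionSet-class].
#' @param polymer_ids storage polymer metabolite ids.
#' @param amino_acid_ids amino acid metabolite ids (GABA counts as an
#'   amino acid here).
#' @param nh3_id id of the ammonia metabolite.
#' @param tol coefficient magnitude below which participation is ignored.
#' @return data.frame of logical flags: \code{polymer_producing},
#'   \code{ammonia_only} (no polymer and NH3 the sole nitrogen product),
#'   \code{amino_acid_secreting}, \code{amino_acid_consuming}.
#' @export
classifyConversion <- function(x, polymer_ids, amino_acid_ids,
                               nh3_id = "nh3", tol = 1e-9) {
  cf <- x@coefficients
  keep <- setdiff(colnames(cf), x@trackers)
  cf <- cf[, keep, drop = FALSE]
  fm <- x@formulas[keep]
  has_n <- vapply(colnames(cf), function(id) {
    f <- fm[[id]]
    !is.na(f) && parseFormula(f)[["N"]] > 0
  }, logical(1))
  pol <- intersect(polymer_ids, colnames(cf))
  aa <- intersect(amino_acid_ids, colnames(cf))
  polymer_producing <- if (length(pol))
    rowSums(cf[, pol, drop = FALSE] > tol) > 0 else rep(FALSE, nrow(cf))
  aa_sec <- if (length(aa))
    rowSums(cf[, aa, drop = FALSE] > tol) > 0 else rep(FALSE, nrow(cf))
  aa_con <- if (length(aa))
    rowSums(cf[, aa, drop = FALSE] < -tol) > 0 else rep(FALSE, nrow(cf))
  n_prod <- colnames(cf)[has_n]
  other_n <- setdiff(n_prod, nh3_id)
  other_n_out <- if (length(other_n))
    rowSums(cf[, other_n, drop = FALSE] > tol) > 0 else rep(FALSE, nrow(cf))
  nh3_out <- if (nh3_id %in% colnames(cf)) cf[, nh3_id] > tol
             else rep(FALSE, nrow(cf))
  data.frame(polymer_producing = polymer_producing,
             ammonia_only = !polymer_producing & nh3_out & !other_n_out,
             amino_acid_secreting = aa_sec,
             amino_acid_consuming = aa_con)
}

#' Biological filtering of conversions
#'
#' Retains conversions that (i) have a positive carbon cost below
#' \code{max_cost} grams of carbon per gram of nitrogen, (ii) consume at
#' most \code{max_amino_inputs} amino acids, and (iii) secrete net
#' nitrogen. Rejected conversions carry machine-readable reasons.
#'
#' @param x a [ConversionSet-class].
#' @param polymer_ids,amino_acid_ids id sets as in [classifyConversion()].
#' @param max_cost cost threshold (g C / g N).
#' @param max_amino_inputs maximum number of amino acid inputs.
#' @param require_positive_net_n logical.
#' @return list with \code{kept} (a ConversionSet), \code{kept_index},
#'   and \code{rejections} (data.frame: conversion index, reason).
#' @export
filterConversions <- function(x, polymer_ids, amino_acid_ids,
                              max_cost = 40, max_amino_inputs = 1,
                              require_positive_net_n = TRUE) {
  cf <- x@coefficients
  cost <- carbonCostPerNitrogen(x, polymer_ids)
  aa <- intersect(amino_acid_ids, colnames(cf))
  n_aa_in <- if (length(aa))
    rowSums(cf[, aa, drop = FALSE] < -1e-9) else rep(0, nrow(cf))
  reasons <- vector("list", nrow(cf))
  for (i in seq_len(nrow(cf))) {
    r <- character()
    if (require_positive_net_n && cost$net_n_out[i] <= 1e-12)
      r <- c(r, "net_nitrogen")
    if (n_aa_in[i] > max_amino_inputs) r <- c(r, "amino_acid_inputs")
    if (is.na(cost$carbon_cost_g_per_g_n[i])) {
      if (!("net_nitrogen" %in% r)) r <- c(r, "cost_undefined")
    } else if (cost$carbon_cost_g_per_g_n[i] <= 0 ||
               cost$carbon_cost_g_per_g_n[i] >= max_cost) {
      r <- c(r, "cost")
    }
    reasons[[i]] <- r
  }
  keep <- lengths(reasons) == 0
  kept <- x
  kept@coefficients <- cf[keep, , drop = FALSE]
  rej <- data.frame(
    conversion = rep(which(!keep), lengths(reasons[!keep])),
    reason = unlist(reasons[!keep]))
  list(kept = kept, kept_index = which(keep), rejections = rej)
}

#' Full metrics table for a conversion set
#'
#' One row per conversion: oxygen per carbon input, oxygen per N2 fixed,
#' carbon cost per nitrogen, net nitrogen output, class flags, and the
#' tracked flux per unit conversion when a tracker is present.
#'
#' @param x a [ConversionSet-class].
#' @param polymer_ids,amino_acid_ids id sets as in [classifyConversion()].
#' @param o2_id,n2_id metabolite ids of dioxygen and dinitrogen.
#' @return data.frame.
#' @export
conversionMetrics <- function(x, polymer_ids, amino_acid_ids,
                              o2_id = "o2", n2_id = "n2") {
  cf <- x@coefficients
  o2_in <- if (o2_id %in% colnames(cf)) abs(pmin(cf[, o2_id], 0))
           else rep(0, nrow(cf))
  n2_in <- if (n2_id %in% colnames(cf)) abs(pmin(cf[, n2_id], 0))
           else rep(0, nrow(cf))
  c_in <- elementFlux(x, "C", "input")
  cost <- carbonCostPerNitrogen(x, polymer_ids)
  cls <- classifyConversion(x, polymer_ids, amino_acid_ids)
  out <- data.frame(
    o2_per_carbon = ifelse(c_in > 1e-12, o2_in / c_in, NA_real_),
    o2_per_n2 = ifelse(n2_in > 1e-12, o2_in / n2_in, NA_real_),
    carbon_cost_g_per_g_n = cost$carbon_cost_g_per_g_n,
    net_n_out = cost$net_n_out)
  out <- cbind(out, cls)
  for (tr in x@trackers) out[[paste0("flux_", tr)]] <- cf[, tr]
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho from average-ranked data (midranks for ties). The
#' two-sided p-value uses the exact permutation distribution (full
#' enumeration of all n! pairings) for n <= 10 and the t approximation
#' with n - 2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p_value}, \code{method}; a
#'   constant vector gives \code{rho = NA} with a warning.
#' @export
spearmanCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    res <- cpp_spearman_exact(rx, ry)
    list(rho = rho, p_value = res$count / res$total,
         method = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho,
         p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
         method = "t approximation")
  }
}
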