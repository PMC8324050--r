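# TSV writers for analysis results.

#' Write analysis results to TSV
#'
#' Writes tab-separated tables with a deterministic column order.
#' Conversion sets produce one row per ECM with one signed column per
#' tracked metabolite, plus a companion file (suffix \code{_indexed}) in
#' which values are indexed to -1/0/+1 for input/nonparticipating/output.
#'
#' @param object a [FluxDistribution-class], [FVAResult-class],
#'   [ConversionSet-class], [PhasePlane-class], or plain data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writeResults", function(object, path)
  standardGeneric("writeResults"))

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write results to '", path, "': ",
         conditionMessage(ok))
  invisible(path)
}

#' @rdname writeResults
setMethod("writeResults", "FluxDistribution", function(object, path) {
  df <- data.frame(reaction = names(object@fluxes),
                   flux = unname(object@fluxes))
  attr <- data.frame(reaction = c(".objective_value", ".status",
                                  ".method"),
                     flux = c(object@objectiveValue, object@status,
                              object@method))
  .write_tsv(rbind(data.frame(reaction = df$reaction,
                              flux = as.character(df$flux)), attr), path)
})

#' @rdname writeResults
setMethod("writeResults", "FVAResult", function(object, path) {
  .write_tsv(object@ranges, path)
})

#' @rdname writeResults
setMethod("writeResults", "ConversionSet", function(object, path) {
  cf <- object@coefficients
  df <- data.frame(conversion = seq_len(nrow(cf)))
  for (j in colnames(cf)) df[[j]] <- cf[, j]
  .write_tsv(df, path)
  idx <- df
  for (j in colnames(cf))
    idx[[j]] <- ifelse(cf[, j] < -1e-9, -1L, ifelse(cf[, j] > 1e-9, 1L, 0L))
  ipath <- sub("(\\.[A-Za-z0-9]+)?$", "_indexed\\1", path)
  if (identical(ipath, path)) ipath <- paste0(path, "_indexed")
  .write_tsv(idx, ipath)
  invisible(path)
})

#' @rdname writeResults
setMethod("writeResults", "PhasePlane", function(object, path) {
  grid <- expand.grid(a = seq_along(object@gridA),
                      b = seq_along(object@gridB))
  df <- data.frame(
    axisA = object@axes[1], uptakeA = object@gridA[grid$a],
    axisB = object@axes[2], uptakeB = object@gridB[grid$b],
    objective = object@objective[cbind(grid$a, grid$b)],
    shadow_priceA = object@shadowA[cbind(grid$a, grid$b)],
    shadow_priceB = object@shadowB[cbind(grid$a, grid$b)],
    phase = object@phases[cbind(grid$a, grid$b)])
  .write_tsv(df, path)
})

#' @rdname writeResults
setMethod("writeResults", "data.frame", function(object, path) {
  .write_tsv(object, path)
})
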