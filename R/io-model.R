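# Model serialization: SBML Level 3 + fbc, and the community JSON dialect.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML ids must start with a letter/underscore; our ids already comply,
# but prefix defensively on write and strip on read
.sbml_id <- function(x) ifelse(grepl("^[A-Za-z_]", x), x, paste0("_", x))

#' Write a model to SBML or JSON
#'
#' SBML output is Level 3 Version 1 with the fbc version 2 extension
#' (flux-bound parameters, gene products and nested gene-product
#' associations). JSON output mirrors the de-facto community model schema
#' (top-level \code{metabolites}, \code{reactions} with
#' \code{lower_bound}/\code{upper_bound}/\code{gene_reaction_rule},
#' \code{genes}); compartments are written as \code{"c"} (internal) and
#' \code{"e"} (external). Both formats round-trip through
#' [readModel()].
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @param format \code{"sbml"}, \code{"json"}, or \code{"auto"} (by
#'   extension).
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") .write_json_model(model, path)
  else .write_sbml_model(model, path)
  invisible(path)
}

.write_json_model <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  comp_map <- c(internal = "c", external = "e")
  mets <- lapply(seq_len(nrow(met)), function(i) {
    out <- list(id = met$id[i], name = met$name[i],
                compartment = comp_map[[met$compartment[i]]])
    if (!is.na(met$formula[i])) out$formula <- met$formula[i]
    if (!is.na(met$charge[i])) out$charge <- met$charge[i]
    out
  })
  rxns <- lapply(seq_len(nrow(rxn)), function(j) {
    st <- S[, j]
    st <- st[st != 0]
    list(id = rxn$id[j], name = rxn$name[j],
         metabolites = as.list(st),
         lower_bound = rxn$lower[j], upper_bound = rxn$upper[j],
         gene_reaction_rule = rxn$gpr[j],
         kind = rxn$kind[j])
  })
  doc <- list(id = model@modelId,
              metabolites = mets, reactions = rxns,
              genes = lapply(model@genes, function(g) list(id = g)),
              notes = list(nitrogenase = model@nitrogenase))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

.write_sbml_model <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE,
                            trim = TRUE)
  # one parameter per distinct bound value
  vals <- sort(unique(c(rxn$lower, rxn$upper)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)), num(vals))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), .SBML_NS, .FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model@modelId)),
    '    <notes>',
    '      <body xmlns="http://www.w3.org/1999/xhtml">',
    sprintf('        <p>nitrogenase: %s</p>', esc(model@nitrogenase)),
    '      </body>',
    '    </notes>',
    '    <listOfCompartments>',
    '      <compartment id="internal" constant="true"/>',
    '      <compartment id="external" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(met))) {
    attrs <- sprintf(paste0('id="%s" name="%s" compartment="%s" ',
                            'hasOnlySubstanceUnits="false" ',
                            'boundaryCondition="%s" constant="false"'),
                     .sbml_id(met$id[i]), esc(met$name[i]),
                     met$compartment[i],
                     if (met$compartment[i] == "external") "true"
                     else "false")
    if (!is.na(met$formula[i]))
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"',
                                     met$formula[i]))
    if (!is.na(met$charge[i]))
      attrs <- paste0(attrs, sprintf(' fbc:charge="%d"',
                                     as.integer(met$charge[i])))
    lines <- c(lines, sprintf('      <species %s/>', attrs))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_along(vals))
    lines <- c(lines, sprintf(
      paste0('      <parameter id="%s" value="%s" constant="true" ',
             'units="dimensionless"/>'),
      pid[[k]], num(vals[k])))
  lines <- c(lines, '    </listOfParameters>',
             '    <fbc:listOfGeneProducts>')
  for (g in model@genes)
    lines <- c(lines, sprintf(
      '      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
      .sbml_id(g), esc(g)))
  lines <- c(lines, '    </fbc:listOfGeneProducts>',
             '    <listOfReactions>')
  gpa_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (is.character(node))
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                     pad, .sbml_id(node)))
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(node$args, gpa_xml, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }
  for (j in seq_len(nrow(rxn))) {
    st <- S[, j]; st <- st[st != 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      .sbml_id(rxn$id[j]), esc(rxn$name[j]),
      if (rxn$lower[j] < 0) "true" else "false",
      pid[[num(rxn$lower[j])]], pid[[num(rxn$upper[j])]]))
    lines <- c(lines, sprintf('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>kind: %s</p></body></notes>',
                              rxn$kind[j]))
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>')
      for (mname in names(reac))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          .sbml_id(mname), num(-reac[[mname]])))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>')
      for (mname in names(prod))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          .sbml_id(mname), num(prod[[mname]])))
      lines <- c(lines, '        </listOfProducts>')
    }
    tree <- parseGpr(rxn$gpr[j])
    if (!is.null(tree)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpa_xml(tree, 10),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
}

#' Read a model from SBML or JSON
#'
#' Accepts SBML Level 3 with the fbc extension (flux-bound parameters and
#' gene-product associations) or the community JSON dialect. Reactions
#' without explicit bounds default to (-1000, 1000) when marked
#' reversible and (0, 1000) otherwise (reported via a message). Reaction
#' kind is taken from the serialized annotation when present, else
#' inferred from the DM_/SK_/EX_ id prefix or a single-metabolite
#' stoichiometry.
#'
#' @param path input file.
#' @param format \code{"sbml"}, \code{"json"}, or \code{"auto"}.
#' @return a [MetabolicModel-class].
#' @export
readModel <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") .read_json_model(path) else .read_sbml_model(path)
}

.infer_kind <- function(id, kind, n_met) {
  if (!is.na(kind) && kind %in% .REACTION_KINDS) return(kind)
  if (grepl("^DM_", id)) return("demand")
  if (grepl("^SK_", id)) return("sink")
  if (grepl("^EX_", id)) return("exchange")
  if (n_met == 1) return("exchange")
  "metabolic"
}

.read_json_model <- function(path) {
  doc <- jsonlite::read_json(path)
  comp_map <- c(c = "internal", e = "external",
                internal = "internal", external = "external")
  met <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "internal"
                             else comp_map[[m$compartment]],
               formula = if (is.null(m$formula)) NA_character_
                         else m$formula,
               charge = if (is.null(m$charge)) NA_integer_
                        else as.integer(m$charge),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(met$id))
    stop("duplicate metabolite id '", met$id[duplicated(met$id)][1],
         "' in ", path)
  seen <- character()
  defaulted <- FALSE
  rxns <- lapply(doc$reactions, function(r) {
    if (r$id %in% seen)
      stop("duplicate reaction id '", r$id, "' in ", path)
    seen <<- c(seen, r$id)
    st <- unlist(r$metabolites)
    lower <- r$lower_bound; upper <- r$upper_bound
    if (is.null(lower) || is.null(upper)) {
      defaulted <<- TRUE
      rev <- isTRUE(r$reversible)
      if (is.null(lower)) lower <- if (rev) -1000 else 0
      if (is.null(upper)) upper <- 1000
    }
    reaction(r$id, st, lower = lower, upper = upper,
             name = if (is.null(r$name)) r$id else r$name,
             gpr = if (is.null(r$gene_reaction_rule)) ""
                   else r$gene_reaction_rule,
             kind = .infer_kind(r$id,
                                if (is.null(r$kind)) NA_character_
                                else r$kind,
                                length(st)))
  })
  if (defaulted)
    message("some reactions lacked explicit bounds; defaults applied")
  genes <- vapply(doc$genes, function(g) g$id, character(1))
  nitro <- if (!is.null(doc$notes$nitrogenase) &&
               !is.null(doc$notes$nitrogenase))
    doc$notes$nitrogenase else NA_character_
  if (length(nitro) == 0 || is.null(nitro)) nitro <- NA_character_
  newMetabolicModel(if (is.null(doc$id)) basename(path) else doc$id,
                    met, rxns, genes = genes, nitrogenase = nitro)
}

.read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse SBML file ", path, ": ", conditionMessage(e)))
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing"))
    stop("no <model> element in ", path)
  att <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else v
  }
  strip <- function(x) sub("^_", "", x)

  sp <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  met <- do.call(rbind, lapply(sp, function(n) {
    data.frame(
      id = strip(xml2::xml_attr(n, "id")),
      name = ifelse(is.na(xml2::xml_attr(n, "name")),
                    strip(xml2::xml_attr(n, "id")),
                    xml2::xml_attr(n, "name")),
      compartment = ifelse(identical(att(n, "compartment"), "external"),
                           "external", "internal"),
      formula = xml2::xml_attr(n, "chemicalFormula"),
      charge = suppressWarnings(as.integer(xml2::xml_attr(n, "charge"))),
      stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(met$id))
    stop("duplicate species id '", met$id[duplicated(met$id)][1],
         "' in ", path)

  pars <- xml2::xml_find_all(model_node,
                             ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  gps <- xml2::xml_find_all(model_node, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(xml2::xml_attr(gps, "label"),
                              xml2::xml_attr(gps, "id"))
  gp_name <- function(id) {
    lb <- gp_label[[id]]
    if (is.null(lb) || is.na(lb)) strip(id) else lb
  }

  gpa_parse <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(gp_name(xml2::xml_attr(node, "geneProduct")))
    kids <- xml2::xml_children(node)
    list(op = if (nm == "and") "and" else "or",
         args = lapply(kids, gpa_parse))
  }

  rx <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction",
                           ns)
  seen <- character(); defaulted <- FALSE
  rxns <- lapply(rx, function(n) {
    id <- strip(xml2::xml_attr(n, "id"))
    if (id %in% seen) stop("duplicate reaction id '", id, "' in ", path)
    seen <<- c(seen, id)
    refs <- function(xp, sgn) {
      rr <- xml2::xml_find_all(n, xp, ns)
      if (!length(rr)) return(numeric())
      stats::setNames(sgn * as.numeric(xml2::xml_attr(rr,
                                                      "stoichiometry")),
                      strip(xml2::xml_attr(rr, "species")))
    }
    st_r <- refs("./s:listOfReactants/s:speciesReference", -1)
    st_p <- refs("./s:listOfProducts/s:speciesReference", 1)
    st <- c(st_r, st_p)
    if (anyDuplicated(names(st)))
      st <- tapply(st, names(st), sum)[unique(names(st))]
    lb_ref <- att(n, "lowerFluxBound"); ub_ref <- att(n, "upperFluxBound")
    if (is.null(lb_ref) || is.null(ub_ref)) {
      defaulted <<- TRUE
      rev <- identical(att(n, "reversible"), "true")
      lower <- if (rev) -1000 else 0; upper <- 1000
    } else {
      lower <- pval[[lb_ref]]; upper <- pval[[ub_ref]]
    }
    gpa <- xml2::xml_find_first(n, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      deparseGpr(gpa_parse(xml2::xml_child(gpa)))
    kind_note <- xml2::xml_find_first(n, ".//s:notes//*[contains(text(), 'kind:')]", ns)
    kind <- if (!inherits(kind_note, "xml_missing"))
      trimws(sub("kind:", "", xml2::xml_text(kind_note))) else NA_character_
    reaction(id, st, lower = lower, upper = upper,
             name = ifelse(is.na(xml2::xml_attr(n, "name")), id,
                           xml2::xml_attr(n, "name")),
             gpr = gpr, kind = .infer_kind(id, kind, length(st)))
  })
  if (defaulted)
    message("some reactions lacked explicit flux bounds; defaults applied")
  nitro_note <- xml2::xml_find_first(
    model_node, "./s:notes//*[contains(text(), 'nitrogenase:')]", ns)
  nitro <- if (!inherits(nitro_note, "xml_missing"))
    trimws(sub("nitrogenase:", "", xml2::xml_text(nitro_note)))
    else NA_character_
  if (identical(nitro, "NA")) nitro <- NA_character_
  genes <- unname(vapply(names(gp_label), gp_name, character(1)))
  newMetabolicModel(
    ifelse(is.na(xml2::xml_attr(model_node, "id")), basename(path),
           xml2::xml_attr(model_node, "id")),
    met, rxns, genes = genes, nitrogenase = nitro)
}
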