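# SBML reading/writing built directly on xml2. Covers the subset of SBML
# L2/L3 (with the fbc extension) that constraint-based models actually use:
# species, reactions with stoichiometric speciesReferences, flux bounds from
# fbc attributes + global parameters or from COBRA-style kineticLaw local
# parameters, boundary species, and SUBSYSTEM notes. Gene associations are
# ignored.

xml_attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit) == 0) NA_character_ else unname(at[hit[1]])
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 2 and Level 3 with the `fbc` package. Flux bounds are
#' taken from `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameter references
#' when present, otherwise from COBRA-convention `LOWER_BOUND`/`UPPER_BOUND`
#' kinetic-law parameters, otherwise from the `reversible` attribute with the
#' default cap (a message is emitted in that case). Species flagged
#' `boundaryCondition="true"` are excluded from the stoichiometric matrix.
#' Reaction `SUBSYSTEM:` notes are read into the subsystem annotation.
#'
#' @param path SBML file path.
#' @param default_bound finite cap applied to missing/infinite bounds
#'   (default 1000 mmol gDW^-1 h^-1).
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, default_bound = 1000) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0) stop("no species found in ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in%
    c("true", "1")
  mets <- sp_id[!sp_boundary]
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) stop("no reactions found in ", path)
  r <- length(rx_nodes)
  rxn_id <- xml2::xml_attr(rx_nodes, "id")
  S <- matrix(0, length(mets), r, dimnames = list(mets, rxn_id))
  lb <- rep(NA_real_, r); ub <- rep(NA_real_, r)
  subsystem <- rep(NA_character_, r)
  defaulted <- character(0)
  for (j in seq_len(r)) {
    rx <- rx_nodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (sp %in% mets) S[sp, j] <- S[sp, j] + sign * st
      }
    }
    lb_ref <- xml_attr_any(rx, "lowerFluxBound")
    ub_ref <- xml_attr_any(rx, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb[j] <- par_val[lb_ref]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub[j] <- par_val[ub_ref]
    if (is.na(lb[j]) || is.na(ub[j])) {
      loc <- xml2::xml_find_all(rx, ".//kineticLaw//parameter")
      if (length(loc) > 0) {
        ids <- xml2::xml_attr(loc, "id")
        vals <- as.numeric(xml2::xml_attr(loc, "value"))
        if (is.na(lb[j]) && "LOWER_BOUND" %in% ids)
          lb[j] <- vals[match("LOWER_BOUND", ids)]
        if (is.na(ub[j]) && "UPPER_BOUND" %in% ids)
          ub[j] <- vals[match("UPPER_BOUND", ids)]
      }
    }
    if (is.na(lb[j]) || is.na(ub[j])) {
      defaulted <- c(defaulted, rxn_id[j])
      reversible <- !xml2::xml_attr(rx, "reversible") %in% c("false", "0")
      if (is.na(lb[j])) lb[j] <- if (reversible) -default_bound else 0
      if (is.na(ub[j])) ub[j] <- default_bound
    }
    notes <- xml2::xml_text(xml2::xml_find_first(rx, "./notes"))
    if (!is.na(notes) && grepl("SUBSYSTEM:", notes)) {
      subsystem[j] <- trimws(sub(".*SUBSYSTEM:\\s*([^\n<]*).*", "\\1", notes))
    }
  }
  if (length(defaulted) > 0)
    message("no flux bounds declared for ", length(defaulted),
            " reaction(s); applied defaults of +/-", default_bound,
            " (first: ", defaulted[1], ")")
  if (all(is.na(subsystem))) subsystem <- NULL
  metabolic_model(S, lb, ub, subsystem = subsystem,
                  default_bound = default_bound)
}

#' Write a metabolic model to SBML
#'
#' Emits SBML Level 3 Version 1 with the `fbc` (version 2) extension: one
#' compartment, species, reactions with stoichiometric species references,
#' and per-reaction flux bound parameters referenced through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`. Subsystem annotations are
#' stored as `SUBSYSTEM:` notes.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (met in model$metabolites) {
    lines <- c(lines, paste0(
      '      <species id="', esc(met), '" compartment="c" ',
      'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"/>'))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (j in seq_along(model$reactions)) {
    rid <- esc(model$reactions[j])
    lines <- c(lines,
      paste0('      <parameter id="lb_', rid, '" value="',
             num(model$lower_bounds[j]), '" constant="true"/>'),
      paste0('      <parameter id="ub_', rid, '" value="',
             num(model$upper_bounds[j]), '" constant="true"/>'))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_along(model$reactions)) {
    rid <- esc(model$reactions[j])
    col <- model$S[, j]
    rev <- model$lower_bounds[j] < 0
    lines <- c(lines, paste0(
      '      <reaction id="', rid, '" reversible="',
      if (rev) "true" else "false", '" fast="false" ',
      'fbc:lowerFluxBound="lb_', rid, '" fbc:upperFluxBound="ub_', rid, '">'))
    if (!is.null(model$subsystem) && !is.na(model$subsystem[j])) {
      lines <- c(lines,
        '        <notes>',
        '          <body xmlns="http://www.w3.org/1999/xhtml">',
        paste0('            <p>SUBSYSTEM: ', esc(model$subsystem[j]), '</p>'),
        '          </body>',
        '        </notes>')
    }
    for (side in c(-1, 1)) {
      idx <- which(if (side < 0) col < 0 else col > 0)
      if (length(idx) == 0) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, paste0('        <', tag, '>'))
      for (i in idx) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', esc(model$metabolites[i]),
          '" stoichiometry="', num(abs(col[i])), '" constant="true"/>'))
      }
      lines <- c(lines, paste0('        </', tag, '>'))
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
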