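#' Read a metabolic model from SBML or toy JSON
#'
#' Dispatches on file extension: `.xml`/`.sbml` are parsed as SBML Level 3
#' with the flux-bounds/objective (fbc) extension; `.json` uses the
#' package's toy-model dialect (see [write_model()]).
#'
#' @param path file path.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_model_json(path)
  else read_model_sbml(path)
}

#' Write a metabolic model to SBML or toy JSON
#'
#' The toy JSON dialect is a single object with fields `id`, `metabolites`
#' (array of `{id, name, compartment, formula}`), `reactions` (array of
#' `{id, stoichiometry: {met: coefficient}, lower_bound, upper_bound}`),
#' `objective` and `extracellular`. Round-tripping through either format
#' preserves stoichiometry, bounds and objective.
#'
#' @param model a `metabolic_model`.
#' @param path destination; extension selects the format as in
#'   [read_model()].
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$objective)) stop("model file has no objective: ", path)
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               formula = m$formula %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(j$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoichiometry),
         lb = as.numeric(r$lower_bound), ub = as.numeric(r$upper_bound))
  })
  metabolic_model(j$id %||% "model", mets, rxns, j$objective,
                  extracellular = j$extracellular %||% "e")
}

write_model_json <- function(model, path) {
  j <- list(
    id = model$id,
    extracellular = model$extracellular,
    objective = model$objective,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      out
    }),
    reactions = unname(lapply(model$reactions, function(r) {
      list(id = r$id, stoichiometry = as.list(r$stoich),
           lower_bound = r$lb, upper_bound = r$ub)
    })))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.sbml_core <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .sbml_core, fbc = .sbml_fbc)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing")) stop("not an SBML Level 3 file: ", path)

  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0) stop("SBML model has no species: ", path)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    refs <- function(side, sign) {
      nodes <- xml2::xml_find_all(
        r, paste0("./s:", side, "/s:speciesReference"), ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
                      xml2::xml_attr(nodes, "species"))
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    if (length(st) > 0) {
      st <- tapply(st, names(st), sum)         # merge duplicate references
      st <- stats::setNames(as.numeric(st), names(st))
    } else st <- stats::setNames(numeric(0), character(0))
    bound <- function(attr, default) {
      pid <- xml2::xml_attr(r, attr, ns = ns)
      if (is.na(pid)) return(default)
      if (!pid %in% names(parval))
        stop("reaction ", rid, " references unknown bound parameter ", pid)
      parval[[pid]]
    }
    list(id = rid, stoich = st,
         lb = bound("fbc:lowerFluxBound", -1000),
         ub = bound("fbc:upperFluxBound", 1000))
  })

  obj_list <- xml2::xml_find_first(mod, ".//fbc:listOfObjectives", ns)
  if (inherits(obj_list, "xml_missing"))
    stop("SBML model has no fbc objective: ", path)
  active <- xml2::xml_attr(obj_list, "fbc:activeObjective", ns = ns)
  objs <- xml2::xml_find_all(obj_list, ".//fbc:objective", ns)
  oid <- xml2::xml_attr(objs, "fbc:id", ns = ns)
  obj_node <- if (!is.na(active) && active %in% oid)
    objs[[which(oid == active)]] else objs[[1]]
  fo <- xml2::xml_find_first(obj_node, ".//fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing"))
    stop("SBML objective lists no flux objective: ", path)
  objective <- xml2::xml_attr(fo, "fbc:reaction", ns = ns)

  unknown <- setdiff(unlist(lapply(rxns, function(r) names(r$stoich))), mets$id)
  if (length(unknown) > 0)
    stop("speciesReference to unknown species: ", unknown[1])

  comps <- unique(mets$compartment)
  extra <- if ("e" %in% comps) "e" else comps[length(comps)]
  metabolic_model(xml2::xml_attr(mod, "id") %||% "model",
                  mets, rxns, objective, extracellular = extra)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  bounds <- sort(unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                          vapply(model$reactions, `[[`, 0, "ub"))))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)),
                         format(bounds, digits = 17, trim = TRUE))
  pref <- function(v) pid[[format(v, digits = 17, trim = TRUE)]]

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), .sbml_core, .sbml_fbc),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    f <- if (is.na(m$formula)) "" else
      sprintf(' fbc:chemicalFormula="%s"', esc(m$formula))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s"',
             ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
             ' constant="false"%s/>'),
      esc(m$id), esc(m$name), esc(m$compartment), f))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>',
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     pid, names(pid)),
             '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r$id), if (r$lb < 0) "true" else "false", pref(r$lb), pref(r$ub)))
    neg <- r$stoich[r$stoich < 0]
    pos <- r$stoich[r$stoich > 0]
    if (length(neg) > 0)
      lines <- c(lines, '        <listOfReactants>',
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(names(neg)),
                         format(-neg, digits = 17, trim = TRUE)),
                 '        </listOfReactants>')
    if (length(pos) > 0)
      lines <- c(lines, '        <listOfProducts>',
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(names(pos)),
                         format(pos, digits = 17, trim = TRUE)),
                 '        </listOfProducts>')
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(
    lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                   'fbc:coefficient="1"/>'), esc(model$objective)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>', '</sbml>')
  writeLines(lines, path)
}
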