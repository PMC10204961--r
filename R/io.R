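# Model serialization: the native JSON dialect ("ecflux-model v1") and a
# minimal SBML Level 3 import/export. The JSON dialect is canonical; SBML
# covers species/reactions/bounds and gene-association notes, dropping
# unsupported constructs with a warning.

#' Load a metabolic model from disk
#'
#' @param path file path.
#' @param format `"json"` (native dialect) or `"sbml"` (Level 3 core with
#'   flux bounds as reaction attributes or kinetic-law-free bound parameters).
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") load_model_json(path) else load_model_sbml(path)
}

#' Write a metabolic model to disk
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"`.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") write_model_json(model, path) else
    write_model_sbml(model, path)
  invisible(path)
}

load_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("JSON parse failure in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  for (f in c("metabolites", "reactions", "objective")) {
    if (is.null(doc[[f]])) {
      stop("model JSON missing required element '", f, "'", call. = FALSE)
    }
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoich)
    gr <- lapply(r$gene_rule %||% list(), function(iso) unlist(iso))
    new_reaction(r$id, st, lb = r$lb %||% -DEFAULT_BOUND,
                 ub = r$ub %||% DEFAULT_BOUND, name = r$name %||% r$id,
                 gene_rule = gr, subsystem = r$subsystem %||% "")
  })
  enz <- if (length(doc$enzymes)) {
    do.call(rbind, lapply(doc$enzymes, function(e) {
      data.frame(id = e$id, genes = paste(unlist(e$genes), collapse = ";"),
                 mw = e$mw, ec = paste(unlist(e$ec), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  comp <- unlist(doc$compartments)
  new_model(doc$id %||% "model", comp, mets, rxns, enzymes = enz,
            objective = doc$objective,
            annotations = doc$annotations %||% list())
}

write_model_json <- function(model, path) {
  doc <- list(
    format = MODEL_FORMAT,
    id = model$id,
    compartments = as.list(model$compartments),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, name = r$name, stoich = as.list(r$stoich),
           lb = r$lb, ub = r$ub,
           gene_rule = lapply(r$gene_rule, as.list),
           subsystem = r$subsystem)
    }),
    enzymes = if (nrow(model$enzymes)) {
      lapply(seq_len(nrow(model$enzymes)), function(i) {
        e <- model$enzymes[i, ]
        list(id = e$id, genes = as.list(strsplit(e$genes, ";")[[1]]),
             mw = e$mw, ec = as.list(strsplit(e$ec, ";")[[1]]))
      })
    } else list(),
    objective = model$objective,
    annotations = model$annotations
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- minimal SBML Level 3 ---------------------------------------------------

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

attr_or <- function(node, attr, default = NA_character_) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    `xmlns:ecflux` = "https://ecfluxr.example.org/sbml-annotations",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$id))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in names(model$compartments)) {
    xml2::xml_add_child(lc, "compartment", id = sbml_id(cid),
                        name = model$compartments[[cid]], constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      ls, "species", id = sbml_id(m$id), name = m$name,
      compartment = sbml_id(m$compartment), constant = "false",
      boundaryCondition = "false", hasOnlySubstanceUnits = "false")
    if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula",
                                              m$formula)
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(
      lr, "reaction", id = sbml_id(r$id), name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false")
    # bounds and metadata carried as custom attributes; a full fbc plugin is
    # out of scope, but load_model_sbml understands these
    xml2::xml_set_attr(rx, "ecflux:lowerBound", format(r$lb, digits = 17))
    xml2::xml_set_attr(rx, "ecflux:upperBound", format(r$ub, digits = 17))
    if (nzchar(r$subsystem)) xml2::xml_set_attr(rx, "ecflux:subsystem",
                                                r$subsystem)
    if (length(r$gene_rule)) {
      rule <- paste(vapply(r$gene_rule,
                           function(iso) paste(iso, collapse = " and "), ""),
                    collapse = " or ")
      xml2::xml_set_attr(rx, "ecflux:geneAssociation", rule)
    }
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lrt <- xml2::xml_add_child(rx, "listOfReactants")
      for (mid in names(subs)) {
        xml2::xml_add_child(lrt, "speciesReference", species = sbml_id(mid),
                            stoichiometry = format(-subs[[mid]], digits = 17),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lpt <- xml2::xml_add_child(rx, "listOfProducts")
      for (mid in names(prods)) {
        xml2::xml_add_child(lpt, "speciesReference", species = sbml_id(mid),
                            stoichiometry = format(prods[[mid]], digits = 17),
                            constant = "true")
      }
    }
  }
  xml2::xml_set_attr(mdl, "ecflux:objective", sbml_id(model$objective))
  xml2::write_xml(doc, path)
  invisible(path)
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  ns <- xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) {
    stop("SBML file has no <model> element", call. = FALSE)
  }
  dropped <- character()
  for (unsupported in c("listOfRules", "listOfEvents", "listOfConstraints",
                        "listOfInitialAssignments", "listOfFunctionDefinitions")) {
    if (!inherits(xml2::xml_find_first(mdl, paste0("./", unsupported)),
                  "xml_missing")) {
      dropped <- c(dropped, unsupported)
    }
  }
  if (length(dropped)) {
    warning("SBML import dropped unsupported construct(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  comps <- xml2::xml_find_all(mdl, "./listOfCompartments/compartment")
  compartments <- setNames(
    vapply(comps, function(x) attr_or(x, "name", xml2::xml_attr(x, "id")), ""),
    vapply(comps, xml2::xml_attr, "", attr = "id"))
  sps <- xml2::xml_find_all(mdl, "./listOfSpecies/species")
  mets <- data.frame(
    id = vapply(sps, xml2::xml_attr, "", attr = "id"),
    name = vapply(sps, function(x)
      attr_or(x, "name", xml2::xml_attr(x, "id")), ""),
    compartment = vapply(sps, xml2::xml_attr, "", attr = "compartment"),
    formula = vapply(sps, function(x) attr_or(x, "chemicalFormula"), ""),
    charge = NA_real_, stringsAsFactors = FALSE)
  rxn_nodes <- xml2::xml_find_all(mdl, "./listOfReactions/reaction")
  rxns <- lapply(rxn_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    reactants <- xml2::xml_find_all(rx, "./listOfReactants/speciesReference")
    products <- xml2::xml_find_all(rx, "./listOfProducts/speciesReference")
    st <- c(
      setNames(-as.numeric(vapply(reactants, xml2::xml_attr, "",
                                  attr = "stoichiometry")),
               vapply(reactants, xml2::xml_attr, "", attr = "species")),
      setNames(as.numeric(vapply(products, xml2::xml_attr, "",
                                 attr = "stoichiometry")),
               vapply(products, xml2::xml_attr, "", attr = "species")))
    lb <- xml2::xml_attr(rx, "lowerBound")
    ub <- xml2::xml_attr(rx, "upperBound")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb <- if (!is.na(lb)) as.numeric(lb) else if (rev) -DEFAULT_BOUND else 0
    ub <- if (!is.na(ub)) as.numeric(ub) else DEFAULT_BOUND
    rule <- xml2::xml_attr(rx, "geneAssociation")
    gr <- if (!is.na(rule) && nzchar(rule)) {
      lapply(strsplit(rule, " or ", fixed = TRUE)[[1]],
             function(iso) strsplit(iso, " and ", fixed = TRUE)[[1]])
    } else list()
    new_reaction(id, st, lb = lb, ub = ub,
                 name = attr_or(rx, "name", id), gene_rule = gr,
                 subsystem = attr_or(rx, "subsystem", ""))
  })
  objective <- xml2::xml_attr(mdl, "objective")
  if (is.na(objective)) {
    # fall back: a reaction named/flagged as biomass, else the last reaction
    cand <- grep("biomass", vapply(rxns, `[[`, "", "id"), ignore.case = TRUE,
                 value = TRUE)
    objective <- if (length(cand)) cand[1] else rxns[[length(rxns)]]$id
  }
  new_model(attr_or(mdl, "id", "model"), compartments, mets, rxns,
            objective = objective)
}
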