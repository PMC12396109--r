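#' Read and write metabolic models (SBML L3/fbc and COBRA JSON)
#'
#' `read_model()` loads a genome-scale metabolic model from either SBML
#' Level 3 with the fbc package (bounds as flux-bound parameters, GPRs as
#' `geneProductAssociation`s, biomass as the active objective) or the
#' COBRA/BIGG JSON dialect (`gene_reaction_rule`, `objective_coefficient`).
#' `write_model()` is its inverse; reading back a written file reproduces
#' the model (ids, bounds, stoichiometry, GPR rules).
#'
#' SBML identifiers are written with the conventional `R_`/`M_`/`G_`
#' prefixes (stripped on read). Identifiers must be SBML-SId compatible
#' (letters, digits, underscore); gene ids are carried in `fbc:label` and
#' may be arbitrary. The JSON dialect is fully lossless, including the
#' `subsystem` field, which SBML carries in reaction notes.
#'
#' @param path file to read or write.
#' @param dialect `"sbml"`, `"json"`, or `"auto"` (by file extension:
#'   `.json` is JSON, anything else SBML).
#' @param biomass optional reaction id to use as biomass when the file
#'   does not designate an objective.
#' @return `read_model()`: a [metabolic_model]. `write_model()`: the path,
#'   invisibly.
#' @export
read_model <- function(path, dialect = c("auto", "sbml", "json"), biomass = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  switch(dialect,
         json = read_model_json(path, biomass),
         sbml = read_model_sbml(path, biomass))
}

#' @rdname read_model
#' @param model a [metabolic_model].
#' @export
write_model <- function(model, path, dialect = c("auto", "sbml", "json")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  switch(dialect,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

no_biomass_error <- function(path) {
  stop("model file '", path, "' does not designate a biomass/objective ",
       "reaction; pass one explicitly (function argument `biomass`, ",
       "CLI flag --biomass)", call. = FALSE)
}

## ---- COBRA JSON ------------------------------------------------------------

read_model_json <- function(path, biomass = NULL) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse JSON model '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  for (fld in c("metabolites", "reactions"))
    if (is.null(doc[[fld]]))
      stop("JSON model '", path, "': missing required element '", fld, "'",
           call. = FALSE)
  chr0 <- function(x, d = "") if (is.null(x)) d else as.character(x)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("JSON model '", path, "': metabolite without id", call. = FALSE)
    data.frame(id = m$id, name = chr0(m$name, m$id),
               compartment = chr0(m$compartment), stringsAsFactors = FALSE)
  }))
  stoich <- list()
  obj_rxn <- character()
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("JSON model '", path, "': reaction without id", call. = FALSE)
    coef <- unlist(r$metabolites)
    stoich[[r$id]] <<- if (length(coef)) coef else stats::setNames(numeric(0), character(0))
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      obj_rxn <<- c(obj_rxn, r$id)
    data.frame(id = r$id, name = chr0(r$name, r$id),
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               gpr = chr0(r$gene_reaction_rule),
               subsystem = chr0(r$subsystem), stringsAsFactors = FALSE)
  }))
  biomass_id <- if (length(obj_rxn)) obj_rxn[1L] else biomass
  if (is.null(biomass_id)) no_biomass_error(path)
  metabolic_model(id = if (is.null(doc$id)) tools::file_path_sans_ext(basename(path)) else doc$id,
                  metabolites = mets, reactions = rxns, stoich = stoich,
                  biomass_id = biomass_id)
}

write_model_json <- function(model, path) {
  rx <- model$reactions
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i], name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(seq_len(nrow(rx)), function(i) {
      sj <- model$stoich[[i]]
      list(id = rx$id[i], name = rx$name[i],
           metabolites = as.list(sj),
           lower_bound = rx$lower_bound[i], upper_bound = rx$upper_bound[i],
           gene_reaction_rule = rx$gpr[i], subsystem = rx$subsystem[i],
           objective_coefficient = if (rx$id[i] == model$biomass_id) 1 else 0)
    }),
    genes = lapply(model$genes, function(g) list(id = g, name = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## ---- SBML L3 + fbc ---------------------------------------------------------

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sid_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)

require_sid <- function(ids, what) {
  bad <- ids[!sid_ok(ids)]
  if (length(bad))
    stop("cannot write SBML: ", what, " id(s) not SId-compatible: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (use the JSON dialect for arbitrary ids)", call. = FALSE)
}

write_model_sbml <- function(model, path) {
  rx <- model$reactions
  require_sid(model$metabolites$id, "metabolite")
  require_sid(rx$id, "reaction")
  xesc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

  comps <- unique(model$metabolites$compartment)
  comps[!nzchar(comps)] <- "default"
  comps <- unique(comps)

  # one flux-bound parameter per distinct bound value
  bvals <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  bid <- stats::setNames(sprintf("cf_bound_%d", seq_along(bvals)), num(bvals))
  pref <- function(p, x) paste0(p, x)

  gene_sid <- gsub("[^A-Za-z0-9_]", "_", model$genes)
  gene_sid <- paste0("G_", gene_sid)
  if (anyDuplicated(gene_sid))
    stop("cannot write SBML: gene ids collide after SId sanitization", call. = FALSE)
  gmap <- stats::setNames(gene_sid, model$genes)

  gpr_xml <- function(expr) {
    if (!is.list(expr))
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', gmap[[expr]]))
    inner <- paste(vapply(expr$args, gpr_xml, character(1L)), collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", expr$op, inner, expr$op)
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE_NS, SBML_FBC_NS),
    sprintf('<model id="%s" fbc:strict="false">', gsub("[^A-Za-z0-9_]", "_", model$id)),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>', gsub("[^A-Za-z0-9_]", "_", comps)),
    "</listOfCompartments>",
    "<listOfSpecies>")
  mc <- model$metabolites$compartment
  mc[!nzchar(mc)] <- "default"
  lines <- c(lines, sprintf(
    '<species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    pref("M_", model$metabolites$id), xesc(model$metabolites$name),
    gsub("[^A-Za-z0-9_]", "_", mc)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="%s" value="%s" constant="true"/>', bid, names(bid)),
    "</listOfParameters>",
    sprintf('<fbc:listOfObjectives fbc:activeObjective="obj"><fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/></fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
            pref("R_", model$biomass_id)),
    "<listOfReactions>")
  for (i in seq_len(nrow(rx))) {
    sj <- model$stoich[[i]]
    open <- sprintf('<reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
                    pref("R_", rx$id[i]), xesc(rx$name[i]),
                    tolower(rx$lower_bound[i] < 0),
                    bid[[num(rx$lower_bound[i])]], bid[[num(rx$upper_bound[i])]])
    body <- character()
    if (nzchar(rx$subsystem[i]))
      body <- c(body, sprintf(
        '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: %s</p></body></notes>',
        xesc(rx$subsystem[i])))
    reac <- sj[sj < 0]
    prod <- sj[sj > 0]
    if (length(reac))
      body <- c(body, "<listOfReactants>",
                sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                        pref("M_", names(reac)), num(-unname(reac))),
                "</listOfReactants>")
    if (length(prod))
      body <- c(body, "<listOfProducts>",
                sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                        pref("M_", names(prod)), num(unname(prod))),
                "</listOfProducts>")
    if (nzchar(rx$gpr[i]))
      body <- c(body, "<fbc:geneProductAssociation>",
                gpr_xml(parse_gpr(rx$gpr[i])),
                "</fbc:geneProductAssociation>")
    lines <- c(lines, open, body, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>")
  if (length(model$genes))
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s" fbc:name="%s"/>',
                       gmap, xesc(names(gmap)), xesc(names(gmap))),
               "</fbc:listOfGeneProducts>")
  lines <- c(lines, "</model>", "</sbml>")
  # validate well-formedness before writing
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

read_model_sbml <- function(path, biomass = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML model '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  ln <- function(node, name) # namespace-agnostic child lookup
    xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", name))
  ln1 <- function(node, name)
    xml2::xml_find_first(node, sprintf("./*[local-name()='%s']", name))
  attr_any <- function(node, name) { # attribute in any namespace
    at <- xml2::xml_attrs(node)
    hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
    if (length(hit)) at[[hit[1L]]] else NA_character_
  }
  model_node <- ln1(doc, "model")
  if (inherits(model_node, "xml_missing"))
    stop("SBML model '", path, "': no <model> element", call. = FALSE)

  params <- ln(ln1(model_node, "listOfParameters"), "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  sp <- ln(ln1(model_node, "listOfSpecies"), "species")
  if (!length(sp)) stop("SBML model '", path, "': empty listOfSpecies", call. = FALSE)
  strip <- function(x, p) ifelse(startsWith(x, p), substring(x, nchar(p) + 1L), x)
  mids_raw <- xml2::xml_attr(sp, "id")
  mets <- data.frame(id = strip(mids_raw, "M_"),
                     name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                                   strip(mids_raw, "M_"), xml2::xml_attr(sp, "name")),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)
  midmap <- stats::setNames(mets$id, mids_raw)

  # gene products: SId -> label
  gps <- ln(ln1(model_node, "listOfGeneProducts"), "geneProduct")
  glabel <- character()
  if (length(gps)) {
    gid <- vapply(gps, attr_any, character(1L), name = "id")
    lab <- vapply(gps, attr_any, character(1L), name = "label")
    lab[is.na(lab)] <- strip(gid[is.na(lab)], "G_")
    glabel <- stats::setNames(lab, gid)
  }

  gpr_from_xml <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(node, "geneProduct")
      g <- if (ref %in% names(glabel)) glabel[[ref]] else strip(ref, "G_")
      return(g)
    }
    kids <- xml2::xml_children(node)
    gpr_node(nm, lapply(kids, gpr_from_xml))
  }

  # objective -> biomass
  biomass_id <- biomass
  fobj <- xml2::xml_find_first(
    model_node, ".//*[local-name()='fluxObjective']")
  if (!inherits(fobj, "xml_missing")) {
    co <- attr_any(fobj, "coefficient")
    if (is.na(co) || as.numeric(co) != 0)
      biomass_id <- strip(attr_any(fobj, "reaction"), "R_")
  }
  if (is.null(biomass_id)) no_biomass_error(path)

  rnodes <- ln(ln1(model_node, "listOfReactions"), "reaction")
  if (!length(rnodes)) stop("SBML model '", path, "': empty listOfReactions", call. = FALSE)
  stoich <- list()
  rxns <- do.call(rbind, lapply(rnodes, function(rn) {
    rid_raw <- xml2::xml_attr(rn, "id")
    rid <- strip(rid_raw, "R_")
    lb_ref <- attr_any(rn, "lowerFluxBound")
    ub_ref <- attr_any(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else -Inf
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else Inf
    coef <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sref <- ln(ln1(rn, side), "speciesReference")
      if (length(sref)) {
        s <- as.numeric(xml2::xml_attr(sref, "stoichiometry"))
        s[is.na(s)] <- 1
        if (side == "listOfReactants") s <- -s
        ids <- midmap[xml2::xml_attr(sref, "species")]
        coef <- c(coef, stats::setNames(s, ids))
      }
    }
    coef <- tapply(coef, names(coef), sum) # merge duplicated species refs
    stoich[[rid]] <<- stats::setNames(as.numeric(coef), names(coef))
    gpa <- ln1(rn, "geneProductAssociation")
    gpr_txt <- ""
    if (!inherits(gpa, "xml_missing")) {
      tree <- gpr_from_xml(xml2::xml_children(gpa)[[1L]])
      gpr_txt <- render_gpr(structure(tree, class = "gpr"))
    }
    notes <- ln1(rn, "notes")
    subsystem <- ""
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      m <- regmatches(txt, regexpr("SUBSYSTEM:\\s*[^\n]*", txt))
      if (length(m)) subsystem <- trimws(sub("SUBSYSTEM:\\s*", "", m))
    }
    nm <- xml2::xml_attr(rn, "name")
    data.frame(id = rid, name = ifelse(is.na(nm), rid, nm),
               lower_bound = lb, upper_bound = ub, gpr = gpr_txt,
               subsystem = subsystem, stringsAsFactors = FALSE)
  }))
  mid <- xml2::xml_attr(model_node, "id")
  metabolic_model(id = if (is.na(mid)) tools::file_path_sans_ext(basename(path)) else mid,
                  metabolites = mets, reactions = rxns,
                  stoich = stoich[rxns$id], biomass_id = biomass_id)
}
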