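# SBML Level 3 Version 1 + fbc-v2 reader/writer built on xml2. Covers the
# subset genome-scale models rely on: species with charge/formula, reactions
# with parameter-backed flux bounds, gene-product associations, an active
# flux objective, and the COBRA notes convention for subsystem labels.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds cannot contain '-'; escape it reversibly
sbml_escape <- function(x) gsub("-", "__", x, fixed = TRUE)
sbml_unescape <- function(x) gsub("__", "-", x, fixed = TRUE)

write_model_sbml <- function(model, path) {
  validate_model(model)
  root <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(root, "model", id = sbml_escape(model$id),
                             "fbc:strict" = "true")

  comps <- unique(model$mets$compartment)
  comps[!nzchar(comps)] <- "default"
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(comps))
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    sp <- xml2::xml_add_child(
      los, "species", id = paste0("M_", sbml_escape(m$id)), name = m$name,
      compartment = if (nzchar(m$compartment)) m$compartment else "default",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$charge))
      xml2::xml_set_attr(sp, "fbc:charge", format(as.integer(m$charge)))
    if (!is.na(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
  }

  # one shared parameter per distinct bound value
  vals <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  pid <- stats::setNames(sprintf("rgem_bnd_%d", seq_along(vals)),
                         vapply(vals, format, character(1), digits = 17))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(vals))
    xml2::xml_add_child(lop, "parameter", id = pid[[k]],
                        value = format(vals[k], digits = 17),
                        constant = "true", sboTerm = "SBO:0000626")

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    rx <- xml2::xml_add_child(
      lor, "reaction", id = paste0("R_", sbml_escape(r$id)), name = r$name,
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = pid[[format(r$lb, digits = 17)]],
      "fbc:upperFluxBound" = pid[[format(r$ub, digits = 17)]])
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    s <- r$stoichiometry[[1]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(reac))
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sbml_escape(names(reac)[k])),
                            stoichiometry = format(-unname(reac[k]), digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod))
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sbml_escape(names(prod)[k])),
                            stoichiometry = format(unname(prod[k]), digits = 17),
                            constant = "true")
    }
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_assoc <- function(node, tr) {
        if (is.character(tr)) {
          xml2::xml_add_child(node, "fbc:geneProductRef",
                              "fbc:geneProduct" = paste0("G_", sbml_escape(tr)))
        } else {
          sub <- xml2::xml_add_child(node, paste0("fbc:", tr$op))
          for (a in tr$args) add_assoc(sub, a)
        }
      }
      add_assoc(gpa, tree)
    }
  }

  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", sbml_escape(model$objective)),
                      "fbc:coefficient" = "1")

  if (length(model$genes)) {
    log_ <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(log_, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_escape(g)),
                          "fbc:label" = g)
  }

  xml2::write_xml(root, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  nsmap <- c(c = SBML_CORE_NS, fbc = SBML_FBC_NS)

  mdl <- xml2::xml_find_first(doc, "./c:model", nsmap)
  if (inherits(mdl, "xml_missing"))
    abort_rgem("SBML file has no <model> element", "rgem_io_error")

  sp <- xml2::xml_find_all(mdl, ".//c:listOfSpecies/c:species", nsmap)
  strip <- function(x, prefix) sbml_unescape(sub(paste0("^", prefix), "", x))
  num_or_na <- function(x) ifelse(is.na(x), NA_real_, suppressWarnings(as.numeric(x)))
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = nsmap),
    charge = num_or_na(xml2::xml_attr(sp, "fbc:charge", ns = nsmap)),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets$compartment[is.na(mets$compartment)] <- ""

  params <- xml2::xml_find_all(mdl, ".//c:listOfParameters/c:parameter", nsmap)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rnodes <- xml2::xml_find_all(mdl, ".//c:listOfReactions/c:reaction", nsmap)
  n <- length(rnodes)
  sto <- vector("list", n)
  rxns <- data.frame(id = character(n), name = character(n),
                     lb = NA_real_, ub = NA_real_, gpr = "",
                     subsystem = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    nd <- rnodes[[i]]
    rid <- strip(xml2::xml_attr(nd, "id"), "R_")
    rxns$id[i] <- rid
    nm <- xml2::xml_attr(nd, "name")
    rxns$name[i] <- if (is.na(nm)) rid else nm
    for (bd in c("lowerFluxBound", "upperFluxBound")) {
      ref <- xml2::xml_attr(nd, paste0("fbc:", bd), ns = nsmap)
      if (is.na(ref) || !ref %in% names(pval))
        abort_rgem(sprintf("reaction '%s' is missing a resolvable fbc:%s", rid, bd),
                   "rgem_io_error")
      if (bd == "lowerFluxBound") rxns$lb[i] <- pval[[ref]] else rxns$ub[i] <- pval[[ref]]
    }
    reac <- xml2::xml_find_all(nd, "./c:listOfReactants/c:speciesReference", nsmap)
    prod <- xml2::xml_find_all(nd, "./c:listOfProducts/c:speciesReference", nsmap)
    ids <- c(strip(xml2::xml_attr(reac, "species"), "M_"),
             strip(xml2::xml_attr(prod, "species"), "M_"))
    coefs <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
               as.numeric(xml2::xml_attr(prod, "stoichiometry")))
    unknown <- setdiff(ids, mets$id)
    if (length(unknown))
      abort_rgem(sprintf("reaction '%s' references undeclared metabolite '%s'",
                         rid, unknown[1]), "rgem_io_error")
    sto[[i]] <- stats::setNames(coefs, ids)
    note <- xml2::xml_text(xml2::xml_find_first(nd, ".//c:notes", nsmap))
    if (!is.na(note) && grepl("SUBSYSTEM:", note))
      rxns$subsystem[i] <- trimws(sub(".*SUBSYSTEM:\\s*", "", note))
    gpa <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation", nsmap)
    if (!inherits(gpa, "xml_missing")) {
      to_rule <- function(node) {
        nm <- xml2::xml_name(node)
        if (nm == "geneProductRef")
          return(strip(xml2::xml_attr(node, "fbc:geneProduct", ns = nsmap), "G_"))
        kids <- xml2::xml_children(node)
        parts <- vapply(kids, to_rule, character(1))
        paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
      }
      rxns$gpr[i] <- to_rule(xml2::xml_children(gpa)[[1]])
    }
  }
  rxns$stoichiometry <- sto

  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    nsmap)
  if (inherits(fo, "xml_missing"))
    abort_rgem("SBML model has no fbc:fluxObjective (missing fbc objective)",
               "rgem_io_error")
  objective <- strip(xml2::xml_attr(fo, "fbc:reaction", ns = nsmap), "R_")

  mid <- xml2::xml_attr(mdl, "id")
  metabolic_model(mets, rxns, objective,
                  id = if (is.na(mid)) "model" else sbml_unescape(mid))
}

#' Read a metabolic model from disk
#'
#' @param path file path.
#' @param format `"json"` (COBRA-style JSON dialect) or `"sbml"` (Level 3
#'   with the fbc version 2 extension); default guesses from the extension.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' `write_model` followed by [read_model()] is the identity on ids,
#' stoichiometry, bounds, GPR semantics and subsystem labels.
#'
#' @param model a `metabolic_model`.
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guesses from the extension.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  switch(format, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
}
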