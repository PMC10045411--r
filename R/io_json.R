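# Model serialisation in the COBRA-style JSON layout (metabolites /
# reactions / genes arrays), so third-party models load without conversion.

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    abort_rgem("JSON model must contain 'metabolites' and 'reactions' arrays",
               "rgem_io_error")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, character(1)),
    name = vapply(doc$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(doc$metabolites,
                         function(m) m$compartment %||% compartment_of(m$id),
                         character(1)),
    formula = vapply(doc$metabolites,
                     function(m) m$formula %||% NA_character_, character(1)),
    charge = vapply(doc$metabolites,
                    function(m) as.numeric(m$charge %||% NA_real_), numeric(1)),
    stringsAsFactors = FALSE)

  objective <- NULL
  rlist <- doc$reactions
  get_num <- function(x, field, rid) {
    if (is.null(x[[field]]))
      abort_rgem(sprintf("reaction '%s' is missing %s", rid, field),
                 "rgem_io_error")
    as.numeric(x[[field]])
  }
  sto <- vector("list", length(rlist))
  rxns <- data.frame(
    id = vapply(rlist, function(r) r$id, character(1)),
    name = vapply(rlist, function(r) r$name %||% r$id, character(1)),
    lb = NA_real_, ub = NA_real_,
    gpr = vapply(rlist, function(r) r$gene_reaction_rule %||% "", character(1)),
    subsystem = vapply(rlist, function(r) r$subsystem %||% "", character(1)),
    stringsAsFactors = FALSE)
  for (i in seq_along(rlist)) {
    r <- rlist[[i]]
    rxns$lb[i] <- get_num(r, "lower_bound", r$id)
    rxns$ub[i] <- get_num(r, "upper_bound", r$id)
    s <- unlist(r$metabolites)
    if (is.null(s) || !length(s))
      abort_rgem(sprintf("reaction '%s' has no metabolites", r$id), "rgem_io_error")
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      abort_rgem(sprintf("reaction '%s' references undeclared metabolite '%s'",
                         r$id, unknown[1]), "rgem_io_error")
    sto[[i]] <- s
    oc <- r$objective_coefficient %||% 0
    if (!is.null(oc) && as.numeric(oc) != 0) objective <- r$id
  }
  rxns$stoichiometry <- sto
  if (is.null(objective))
    abort_rgem("JSON model declares no objective (objective_coefficient)",
               "rgem_io_error")
  metabolic_model(mets, rxns, objective, id = doc$id %||% "model")
}

write_model_json <- function(model, path) {
  validate_model(model)
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    m <- model$mets[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(i) {
    r <- model$rxns[i, ]
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoichiometry[[1]]),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = r$gpr, subsystem = r$subsystem,
         objective_coefficient = if (identical(r$id, model$objective)) 1 else 0)
  })
  genes <- lapply(model$genes, function(g) list(id = g))
  jsonlite::write_json(
    list(id = model$id, metabolites = mets, reactions = rxns, genes = genes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
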