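# Context-specific subnetwork extraction: penalize flux through reactions
# whose expression is below cutoff while forcing a required fraction of the
# optimal metabolic objective, i.e.
#
#   minimize  sum_j c_j |v_j|
#   s.t.      S v = 0,  vl <= v <= vu,  v_obj >= fraction * optimum
#
# solved as an LP on the split variables (|v_j| = v+_j + v-_j). The optimal
# value is the inconsistency score: 0 means the expression data and the
# required metabolic functionality are perfectly compatible.

#' Build an expression-calls object
#'
#' @param calls logical or `"P"`/`"A"` character matrix, genes in rows
#'   (rownames = gene ids), one column per replicate.
#' @param condition condition label (e.g. `"WT"` or `"KO"`).
#' @return an `expression_calls` object.
#' @export
expression_calls <- function(calls, condition = "unknown") {
  if (is.character(calls)) {
    mat <- toupper(calls) == "P"
    dim(mat) <- dim(calls); dimnames(mat) <- dimnames(calls)
    calls <- mat
  }
  stopifnot(is.logical(calls), !is.null(rownames(calls)))
  structure(list(calls = calls, condition = condition),
            class = "expression_calls")
}

#' Consensus present/absent calls across replicates
#'
#' A gene is called present when it is present in at least `min_present`
#' replicates (the 2-of-3 rule at the defaults). Genes missing from a
#' replicate count as absent in that replicate.
#'
#' @param calls an [expression_calls()] object.
#' @param min_present minimum number of present replicates.
#' @return named logical vector (`TRUE` = present).
#' @export
consensus_presence <- function(calls, min_present = 2) {
  stopifnot(inherits(calls, "expression_calls"))
  mat <- calls$calls
  if (ncol(mat) < min_present)
    abort_rgem(sprintf("need at least %d replicates, got %d",
                       min_present, ncol(mat)), "rgem_expression_error")
  n_present <- rowSums(mat, na.rm = TRUE)
  stats::setNames(n_present >= min_present, rownames(mat))
}

#' Map gene presence through an ortholog table
#'
#' Translates source-organism presence calls to target (model) gene ids.
#' Many-to-one mappings use an any-of rule: the target is present when any
#' mapped source gene is present.
#'
#' @param presence named logical vector over source gene ids.
#' @param table data.frame with columns `source_id`, `target_id`.
#' @param model_genes optional character vector; when given, model genes
#'   without any mapping are reported in a warning and returned as absent.
#' @return named logical vector over target gene ids.
#' @export
map_orthologs <- function(presence, table, model_genes = NULL) {
  stopifnot(all(c("source_id", "target_id") %in% names(table)))
  if (!nrow(table)) {
    warn_rgem("empty ortholog table: no genes mapped")
    tgt <- logical()
  } else {
    if (any(!nzchar(table$target_id) | is.na(table$target_id)))
      abort_rgem("ortholog table contains empty target ids", "rgem_expression_error")
    src_p <- presence[table$source_id]
    src_p[is.na(src_p)] <- FALSE
    tgt <- tapply(src_p, table$target_id, any)
    tgt <- stats::setNames(as.logical(tgt), names(tgt))
  }
  if (!is.null(model_genes)) {
    unmapped <- setdiff(model_genes, names(tgt))
    if (length(unmapped))
      warn_rgem(sprintf("%d model gene(s) not covered by the ortholog table (e.g. %s)",
                        length(unmapped), unmapped[1]))
    extra <- stats::setNames(rep(FALSE, length(unmapped)), unmapped)
    tgt <- c(tgt, extra)
  }
  tgt
}

#' Reaction-level presence from gene presence via GPR logic
#'
#' OR requires any operand present, AND requires all operands. Reactions
#' without a GPR are classed `"no_gpr"` and are never penalized.
#'
#' @param model a `metabolic_model`.
#' @param gene_presence named logical vector (`TRUE` = present); genes not
#'   listed count as absent.
#' @return named character vector over reaction ids with values
#'   `"present"`, `"absent"`, `"no_gpr"`.
#' @export
gpr_presence <- function(model, gene_presence) {
  out <- character(nrow(model$rxns))
  for (i in seq_len(nrow(model$rxns))) {
    tree <- tryCatch(parse_gpr(model$rxns$gpr[i]), rgem_gpr_error = function(e)
      abort_rgem(sprintf("reaction '%s': %s", model$rxns$id[i], conditionMessage(e)),
                 "rgem_gpr_error"))
    val <- eval_gpr(tree, gene_presence)
    out[i] <- if (is.na(val)) "no_gpr" else if (val) "present" else "absent"
  }
  stats::setNames(out, model$rxns$id)
}

#' Penalty weights from reaction presence
#'
#' Encodes presence as binary expression `x` (1 = present or no GPR, 0 =
#' absent) against the cutoff `xcutoff`, giving weights
#' `c = max(xcutoff - x, 0)`: a constant positive penalty for absent
#' reactions and zero otherwise. With binary calls any positive constant is
#' argmin-equivalent.
#'
#' @param reaction_presence result of [gpr_presence()].
#' @param xcutoff expression cutoff (default 0.5).
#' @return a `penalty_vector`: list with `c`, `x`, `xcutoff`.
#' @export
compute_penalties <- function(reaction_presence, xcutoff = 0.5) {
  x <- ifelse(reaction_presence == "absent", 0, 1)
  cc <- pmax(xcutoff - x, 0)
  structure(list(c = stats::setNames(cc, names(reaction_presence)),
                 x = stats::setNames(x, names(reaction_presence)),
                 xcutoff = xcutoff),
            class = "penalty_vector")
}

#' Run the GIMME linear program
#'
#' @param model a `metabolic_model` (finite bounds).
#' @param penalties a [compute_penalties()] result, or a named nonnegative
#'   numeric vector of weights over reaction ids.
#' @param required_fraction fraction of the unconstrained objective optimum
#'   that the context-specific flux state must attain (default 0.9).
#' @param flux_tol smallest penalized flux magnitude that keeps a reaction
#'   in the active set.
#' @return a `gimme_result`: list with `active_reactions`,
#'   `inconsistency_score`, `flux_solution` (a `flux_distribution`),
#'   `required_fraction`, `objective_optimum`.
#' @export
run_gimme <- function(model, penalties, required_fraction = 0.9,
                      flux_tol = FLUX_TOL) {
  cvec <- if (inherits(penalties, "penalty_vector")) penalties$c else penalties
  cvec <- cvec[model$rxns$id]
  cvec[is.na(cvec)] <- 0
  stopifnot(all(cvec >= 0), required_fraction >= 0, required_fraction <= 1)

  split <- split_reversible(model)
  fba <- solve_fba(model, split = split)
  if (fba$status != "optimal")
    abort_rgem(sprintf("objective FBA is %s; cannot run GIMME", fba$status),
               "rgem_gimme_error")
  extra_rows <- NULL; extra_rhs <- NULL
  if (fba$objective_value > FLUX_TOL) {
    extra_rows <- obj_vector(split, model$objective)
    extra_rhs <- required_fraction * fba$objective_value
  } else {
    warn_rgem("objective optimum is ~0: the required-fraction constraint is vacuous")
  }

  obj <- cvec[split$cols$rxn]                 # both split columns add |v|
  res <- solve_split_lp(split, obj, maximize = FALSE,
                        extra_rows = extra_rows, extra_rhs = extra_rhs)
  if (res$status != "optimal")
    abort_rgem(sprintf("GIMME LP is %s with required_fraction = %g",
                       res$status, required_fraction), "rgem_gimme_error")
  fluxes <- split_to_fluxes(split, res$x)
  active <- model$rxns$id[cvec == 0 | abs(fluxes) > flux_tol]
  structure(list(
    active_reactions = active,
    inconsistency_score = res$objective,
    flux_solution = structure(list(fluxes = fluxes,
                                   objective_value = unname(fluxes[model$objective]),
                                   objective_id = model$objective,
                                   status = "optimal"),
                              class = "flux_distribution"),
    required_fraction = required_fraction,
    objective_optimum = fba$objective_value),
    class = "gimme_result")
}

#' @export
print.gimme_result <- function(x, ...) {
  cat(sprintf("<gimme_result> score %.6g, %d active reactions, objective >= %.3g * %.6g\n",
              x$inconsistency_score, length(x$active_reactions),
              x$required_fraction, x$objective_optimum))
  invisible(x)
}

#' Export a GIMME result
#'
#' Writes the active reaction set and score as JSON and, optionally, the
#' flux solution as TSV.
#'
#' @param result a `gimme_result`.
#' @param json_path output JSON file.
#' @param flux_tsv_path optional TSV of the flux solution.
#' @return `json_path`, invisibly.
#' @export
write_gimme_result <- function(result, json_path, flux_tsv_path = NULL) {
  jsonlite::write_json(
    list(inconsistency_score = result$inconsistency_score,
         required_fraction = result$required_fraction,
         objective_optimum = result$objective_optimum,
         active_reactions = result$active_reactions),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(flux_tsv_path)) {
    fl <- result$flux_solution$fluxes
    write_tsv(data.frame(reaction = names(fl), flux = unname(fl)),
              flux_tsv_path)
  }
  invisible(json_path)
}
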