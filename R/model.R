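# The in-memory representation of a stoichiometric metabolic network.
#
# A `metabolic_model` is a list with
#   id        model name
#   mets      data.frame: id, name, compartment, formula, charge
#   rxns      data.frame: id, name, lb, ub, gpr, subsystem, plus a
#             list-column `stoichiometry` of named numeric vectors
#             (metabolite id -> signed coefficient)
#   objective reaction id optimised by FBA/GIMME
#   genes     character vector of gene ids appearing in GPRs
#
# Reaction order is explicit (row order of `rxns`) and preserved by all
# operations; the reorder-ensemble procedure depends on it.

#' Construct a metabolic model
#'
#' @param mets data.frame with columns `id` (unique, compartment-suffixed,
#'   e.g. `"o2s_c"`), and optionally `name`, `compartment` (derived from the
#'   id suffix when missing), `formula`, `charge`.
#' @param rxns data.frame with columns `id`, `lb`, `ub` (flux bounds,
#'   mmol/gDW/h), a list-column `stoichiometry` of named numeric vectors,
#'   and optionally `name`, `gpr`, `subsystem`.
#' @param objective id of the reaction optimised by default (e.g. an ATP
#'   demand).
#' @param id model name.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(mets, rxns, objective, id = "model") {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$compartment)) mets$compartment <- compartment_of(mets$id)
  if (is.null(mets$formula)) mets$formula <- NA_character_
  if (is.null(mets$charge)) mets$charge <- NA_real_
  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  if (is.null(rxns$subsystem)) rxns$subsystem <- ""
  rxns$subsystem[is.na(rxns$subsystem) | rxns$subsystem == ""] <- "unassigned"
  rownames(mets) <- NULL; rownames(rxns) <- NULL

  # prune coefficients below the zero tolerance
  rxns$stoichiometry <- lapply(rxns$stoichiometry, function(s) {
    s <- stats::setNames(as.numeric(s), names(s))
    s <- s[abs(s) > ZERO_TOL]
    if (!length(s)) abort_rgem("reaction with empty stoichiometry", "rgem_model_error")
    s
  })

  genes <- unique(unlist(lapply(rxns$gpr, function(g) gpr_genes(parse_gpr(g)))))
  model <- structure(
    list(id = id, mets = mets, rxns = rxns,
         objective = objective, genes = genes %||% character()),
    class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a declared
#' metabolite, bound ordering, and that the objective resolves to a reaction.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  mets <- model$mets; rxns <- model$rxns
  if (anyDuplicated(mets$id))
    abort_rgem(sprintf("duplicate metabolite id '%s'",
                       mets$id[duplicated(mets$id)][1]), "rgem_model_error")
  if (anyDuplicated(rxns$id))
    abort_rgem(sprintf("duplicate reaction id '%s'",
                       rxns$id[duplicated(rxns$id)][1]), "rgem_model_error")
  bad <- which(rxns$lb > rxns$ub)
  if (length(bad))
    abort_rgem(sprintf("reaction '%s' has lower bound above upper bound",
                       rxns$id[bad[1]]), "rgem_model_error")
  for (i in seq_len(nrow(rxns))) {
    unknown <- setdiff(names(rxns$stoichiometry[[i]]), mets$id)
    if (length(unknown))
      abort_rgem(sprintf("reaction '%s' references undeclared metabolite '%s'",
                         rxns$id[i], unknown[1]), "rgem_model_error")
  }
  if (!model$objective %in% rxns$id)
    abort_rgem(sprintf("objective '%s' is not a reaction id", model$objective),
               "rgem_model_error")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s'>\n", x$id))
  cat(sprintf("  %d metabolites, %d reactions, %d genes\n",
              nrow(x$mets), nrow(x$rxns), length(x$genes)))
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

#' Parse a reaction equation string
#'
#' Understands the conventional arrow notation, e.g.
#' `"2 h_c + 2 o2s_c -> o2_c + h2o2_c"`. `"->"`/`"-->"` denote an
#' irreversible and `"<->"`/`"<=>"` a reversible reaction. An empty side
#' encodes a boundary (exchange/demand) reaction, e.g. `"lac-L_e ->"`.
#'
#' @param eq equation string.
#' @return list with `stoichiometry` (named numeric, negative = consumed)
#'   and `reversible` (logical).
#' @export
parse_reaction_equation <- function(eq) {
  m <- regexec("^(.*?)(<=>|<->|-->|->)(.*)$", eq)
  parts <- regmatches(eq, m)[[1]]
  if (!length(parts)) abort_rgem(sprintf("cannot parse equation '%s'", eq),
                                 "rgem_model_error")
  side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- trimws(strsplit(txt, "\\s+\\+\\s+")[[1]])
    out <- numeric(); nm <- character()
    for (tm in terms) {
      tk <- strsplit(tm, "\\s+")[[1]]
      if (length(tk) == 2L) { coef <- as.numeric(tk[1]); met <- tk[2] }
      else if (length(tk) == 1L) { coef <- 1; met <- tk }
      else abort_rgem(sprintf("cannot parse term '%s'", tm), "rgem_model_error")
      out <- c(out, sign * coef); nm <- c(nm, met)
    }
    stats::setNames(out, nm)
  }
  lhs <- side(parts[2], -1); rhs <- side(parts[4], +1)
  sto <- c(lhs, rhs)
  # merge duplicated metabolites across sides, keeping first-seen order
  agg <- tapply(sto, names(sto), sum)
  sto <- stats::setNames(as.numeric(agg), names(agg))[unique(names(sto))]
  list(stoichiometry = sto[abs(sto) > ZERO_TOL],
       reversible = parts[3] %in% c("<->", "<=>"))
}

#' Build the stoichiometric matrix S
#'
#' Returns the m-by-n sparse matrix whose entry (i, j) is the coefficient of
#' metabolite i in reaction j, with rows and columns in model order.
#'
#' @param model a `metabolic_model`.
#' @return a sparse `Matrix::dgCMatrix` with metabolite/reaction dimnames.
#' @export
build_stoichiometric_matrix <- function(model) {
  validate_model(model)
  met_idx <- stats::setNames(seq_len(nrow(model$mets)), model$mets$id)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_len(nrow(model$rxns))) {
    s <- model$rxns$stoichiometry[[j]]
    ii <- c(ii, met_idx[names(s)])
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(model$mets), nrow(model$rxns)),
                       dimnames = list(model$mets$id, model$rxns$id))
}

#' Binarize a stoichiometric matrix
#'
#' Replaces every entry of magnitude above the zero tolerance by 1; the
#' result is the incidence matrix Sb used by connectivity analysis.
#'
#' @param S numeric or sparse matrix.
#' @param tol zero tolerance (default 1e-12, below LP solver precision).
#' @return sparse 0/1 matrix of the same shape and dimnames.
#' @export
binarize <- function(S, tol = ZERO_TOL) {
  B <- as(S, "CsparseMatrix")
  B@x <- as.numeric(abs(B@x) > tol)
  Matrix::drop0(B)
}

#' Exchange reactions of a model
#'
#' Boundary pseudo-reactions are identified by their single-metabolite
#' stoichiometry, written as `met ->` with positive flux = secretion and
#' negative flux = uptake.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  n1 <- vapply(model$rxns$stoichiometry, length, integer(1)) == 1L
  model$rxns$id[n1]
}

#' Metabolite carried by each exchange reaction
#' @param model a `metabolic_model`.
#' @return named character vector: exchange reaction id -> metabolite id.
#' @export
exchange_metabolites <- function(model) {
  ex <- exchange_reactions(model)
  stats::setNames(
    vapply(ex, function(r) names(rxn_stoich(model, r))[1], character(1)), ex)
}

rxn_index <- function(model, rxn_id) {
  i <- match(rxn_id, model$rxns$id)
  if (anyNA(i))
    abort_rgem(sprintf("unknown reaction id '%s'", rxn_id[which(is.na(i))[1]]),
               "rgem_model_error")
  i
}

rxn_stoich <- function(model, rxn_id) model$rxns$stoichiometry[[rxn_index(model, rxn_id)]]

#' Set flux bounds on a reaction
#' @param model a `metabolic_model`.
#' @param rxn_id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, rxn_id, lb = NULL, ub = NULL) {
  i <- rxn_index(model, rxn_id)
  if (!is.null(lb)) model$rxns$lb[i] <- lb
  if (!is.null(ub)) model$rxns$ub[i] <- ub
  if (model$rxns$lb[i] > model$rxns$ub[i])
    abort_rgem(sprintf("reaction '%s': lower bound above upper bound", rxn_id),
               "rgem_model_error")
  model
}

#' Reorder the reactions of a model
#'
#' Permutes reaction (column) order only; used by the reorder-ensemble
#' robustness procedure.
#'
#' @param model a `metabolic_model`.
#' @param perm integer permutation of `seq_len(nrow(model$rxns))`.
#' @return the permuted model.
#' @export
permute_reactions <- function(model, perm) {
  stopifnot(length(perm) == nrow(model$rxns),
            all(sort(perm) == seq_len(nrow(model$rxns))))
  model$rxns <- model$rxns[perm, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model
}

#' Cap non-finite flux bounds
#'
#' Replaces infinite bounds by +/-`cap` (default 1000 mmol/gDW/h, the
#' conventional "unlimited" flux), making the split-variable reformulation
#' well defined.
#'
#' @param model a `metabolic_model`.
#' @param cap magnitude for unbounded fluxes.
#' @return the capped model.
#' @export
cap_bounds <- function(model, cap = 1000) {
  model$rxns$lb <- pmax(model$rxns$lb, -cap)
  model$rxns$ub <- pmin(model$rxns$ub, cap)
  model
}
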