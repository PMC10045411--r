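# Elemental and charge balance checking. Exchange/demand reactions are
# boundary pseudo-reactions and exempt by construction.

#' Parse an elemental formula
#'
#' @param formula Hill-notation formula, e.g. `"C21H26N7O14P2"`.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    abort_rgem(sprintf("cannot parse formula '%s'", formula), "rgem_model_error")
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)[unique(el)]
}

#' Check mass and charge balance of model reactions
#'
#' For every non-boundary reaction whose metabolites all carry formulas (and
#' charges, when charge balance is assessed) the per-element residual
#' `sum(coefficient * count)` and the charge residual are reported. A
#' reaction is balanced when every residual is zero. Exchange and demand
#' reactions (single-metabolite stoichiometries) are exempt.
#'
#' @param model a `metabolic_model`.
#' @param tol residual magnitude treated as zero.
#' @return data.frame with columns `reaction`, `checked` (FALSE when data
#'   was missing), `balanced`, `mass_residual` (largest element residual
#'   magnitude), `charge_residual`, `detail` (per-element residuals as text).
#' @export
validate_mass_charge_balance <- function(model, tol = 1e-9) {
  ex <- exchange_reactions(model)
  formulas <- stats::setNames(model$mets$formula, model$mets$id)
  charges <- stats::setNames(model$mets$charge, model$mets$id)
  out <- data.frame(reaction = model$rxns$id, checked = FALSE, balanced = NA,
                    mass_residual = NA_real_, charge_residual = NA_real_,
                    detail = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(model$rxns))) {
    rid <- model$rxns$id[i]
    if (rid %in% ex) next
    s <- model$rxns$stoichiometry[[i]]
    f <- formulas[names(s)]
    if (any(is.na(f) | !nzchar(f))) next
    elems <- lapply(f, parse_formula)
    all_el <- unique(unlist(lapply(elems, names)))
    resid <- stats::setNames(numeric(length(all_el)), all_el)
    for (k in seq_along(s)) {
      e <- elems[[k]]
      resid[names(e)] <- resid[names(e)] + s[k] * e
    }
    ch <- charges[names(s)]
    charge_resid <- if (any(is.na(ch))) NA_real_ else sum(s * ch)
    out$checked[i] <- TRUE
    out$mass_residual[i] <- if (length(resid)) max(abs(resid)) else 0
    out$charge_residual[i] <- charge_resid
    out$balanced[i] <- out$mass_residual[i] <= tol &&
      (is.na(charge_resid) || abs(charge_resid) <= tol)
    nz <- resid[abs(resid) > tol]
    out$detail[i] <- if (length(nz))
      paste(sprintf("%s:%+g", names(nz), nz), collapse = " ") else ""
  }
  out
}
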