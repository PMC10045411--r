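# Flux-balance analysis on the split-variable (nonnegative) reformulation
# v = v+ - v-. All LPs in the package go through solve_split_lp(), which
# shifts box constraints to the solver's 0 <= x <= u form and dispatches to
# the compiled two-phase simplex.

#' Split reversible reactions into nonnegative forward/reverse columns
#'
#' Rewrites every flux as `v = v+ - v-` with `0 <= v+ <= vu` and
#' `0 <= v- <= -vl`; the reverse column is absent when `vl >= 0` and the
#' forward column when `vu <= 0`. A positive `vl` (or negative `vu`)
#' becomes a lower bound on the surviving column, so forced fluxes are
#' representable. Mapping back reproduces the original feasible set.
#'
#' @param model a `metabolic_model` with finite bounds.
#' @return a `split_model`: list with the signed column matrix `A`
#'   (metabolites x split columns), column boxes `lo`/`up`, and the
#'   column map `cols` (reaction index, sign).
#' @export
split_reversible <- function(model) {
  if (any(!is.finite(model$rxns$lb)) || any(!is.finite(model$rxns$ub)))
    abort_rgem(paste("model contains infinite bounds; cap them first,",
                     "e.g. cap_bounds(model, 1000)"), "rgem_lp_error")
  S <- as.matrix(build_stoichiometric_matrix(model))
  n <- nrow(model$rxns)
  idx <- integer(); sgn <- numeric(); lo <- numeric(); up <- numeric()
  for (j in seq_len(n)) {
    lb <- model$rxns$lb[j]; ub <- model$rxns$ub[j]
    if (ub > 0) {
      idx <- c(idx, j); sgn <- c(sgn, 1)
      lo <- c(lo, max(lb, 0)); up <- c(up, ub)
    }
    if (lb < 0) {
      idx <- c(idx, j); sgn <- c(sgn, -1)
      lo <- c(lo, max(-ub, 0)); up <- c(up, -lb)
    }
    if (ub <= 0 && lb >= 0) {  # pinned at exactly zero: keep a dummy column
      idx <- c(idx, j); sgn <- c(sgn, 1); lo <- c(lo, 0); up <- c(up, 0)
    }
  }
  A <- S[, idx, drop = FALSE] * rep(sgn, each = nrow(S))
  structure(list(model = model, A = A, lo = lo, up = up,
                 cols = data.frame(rxn = idx, sign = sgn)),
            class = "split_model")
}

# recover net fluxes (model reaction order) from split-column values;
# forward and reverse columns of one reaction must be summed, so the
# accumulation cannot use plain indexed assignment (duplicate indices)
split_to_fluxes <- function(split, x) {
  v <- numeric(nrow(split$model$rxns))
  agg <- tapply(split$cols$sign * x, split$cols$rxn, sum)
  v[as.integer(names(agg))] <- as.numeric(agg)
  stats::setNames(v, split$model$rxns$id)
}

# min/max obj'x over {A x = 0 (+extra rows), lo <= x <= up}.
# extra rows are inequalities  row'x >= rhs, implemented with surplus columns.
solve_split_lp <- function(split, obj, maximize,
                           extra_rows = NULL, extra_rhs = NULL) {
  A <- split$A
  lo <- split$lo; up <- split$up
  b <- rep(0, nrow(A))
  if (!is.null(extra_rows)) {
    extra_rows <- matrix(extra_rows, ncol = ncol(A))
    big <- 1e7
    ns <- nrow(extra_rows)
    A <- rbind(A, extra_rows)
    surplus <- matrix(0, nrow(A), ns)
    for (k in seq_len(ns)) surplus[nrow(split$A) + k, k] <- -1
    A <- cbind(A, surplus)
    obj <- c(obj, rep(0, ns))
    lo <- c(lo, rep(0, ns)); up <- c(up, rep(big, ns))
    b <- c(b, extra_rhs)
  }
  # shift lower bounds to zero
  shift <- lo
  b_eff <- b - as.vector(A %*% shift)
  res <- .simplex_bounded(A, b_eff, obj, up - lo, maximize, 0L)
  x <- res$x + shift
  list(status = c("optimal", "infeasible", "iteration_limit")[res$status + 1L],
       x = x[seq_len(ncol(split$A))],
       objective = if (res$status == 0) sum(obj * x) else NA_real_)
}

obj_vector <- function(split, rxn_id) {
  j <- rxn_index(split$model, rxn_id)
  as.numeric(split$cols$sign * (split$cols$rxn == j))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through a reaction subject to
#' steady-state mass balance `S v = 0` and the flux bounds, returning an
#' optimal vertex of the flux polytope.
#'
#' @param model a `metabolic_model` (finite bounds; see [cap_bounds()]).
#' @param objective_id reaction to optimise; defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @param split optional precomputed [split_reversible()] result.
#' @return a `flux_distribution`: list with `fluxes` (named vector,
#'   mmol/gDW/h), `objective_value`, and `status` (`"optimal"` /
#'   `"infeasible"` / `"iteration_limit"`).
#' @export
solve_fba <- function(model, objective_id = model$objective,
                      sense = c("max", "min"), split = NULL) {
  sense <- match.arg(sense)
  if (is.null(split)) split <- split_reversible(model)
  obj <- obj_vector(split, objective_id)
  res <- solve_split_lp(split, obj, maximize = sense == "max")
  fluxes <- if (res$status == "optimal") split_to_fluxes(split, res$x) else
    stats::setNames(rep(NA_real_, nrow(model$rxns)), model$rxns$id)
  structure(list(fluxes = fluxes, objective_value = res$objective,
                 objective_id = objective_id, status = res$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> %s: objective %s = %s\n", x$status,
              x$objective_id, format(x$objective_value)))
  invisible(x)
}

#' Flux variability analysis
#'
#' Per reaction, the minimum and maximum attainable flux subject to mass
#' balance, bounds, and (when `fraction_of_optimum > 0`) the constraint
#' that the model objective attains at least that fraction of its FBA
#' optimum.
#'
#' @param model a `metabolic_model`.
#' @param fraction_of_optimum number in \[0, 1\].
#' @param reaction_ids reactions to analyse (default all).
#' @return data.frame with columns `reaction`, `min_flux`, `max_flux`.
#' @export
run_fva <- function(model, fraction_of_optimum = 0, reaction_ids = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  split <- split_reversible(model)
  reaction_ids <- reaction_ids %||% model$rxns$id
  extra_rows <- NULL; extra_rhs <- NULL
  if (fraction_of_optimum > 0) {
    fba <- solve_fba(model, split = split)
    if (fba$status != "optimal")
      abort_rgem(sprintf("FVA requires an FBA optimum but the model is %s",
                         fba$status), "rgem_lp_error")
    extra_rows <- obj_vector(split, model$objective)
    extra_rhs <- fraction_of_optimum * fba$objective_value
  }
  out <- data.frame(reaction = reaction_ids, min_flux = NA_real_,
                    max_flux = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(reaction_ids)) {
    obj <- obj_vector(split, reaction_ids[k])
    for (sense in c("min", "max")) {
      res <- solve_split_lp(split, obj, maximize = sense == "max",
                            extra_rows = extra_rows, extra_rhs = extra_rhs)
      if (res$status != "optimal")
        abort_rgem(sprintf("FVA subproblem for '%s' is %s",
                           reaction_ids[k], res$status), "rgem_lp_error")
      if (sense == "min") out$min_flux[k] <- res$objective
      else out$max_flux[k] <- res$objective
    }
  }
  out
}
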