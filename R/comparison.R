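# Wildtype-versus-knockout comparison layer: reorder-ensemble GIMME model
# construction, reaction/metabolite set differences, subsystem breakdown,
# and the stoichiometric metabolite-connectivity ranking cm = diag(Sb Sb').

#' Reorder-ensemble GIMME models
#'
#' Reaction order can affect which of several equivalent-penalty subnetworks
#' the LP returns. The ensemble reruns GIMME on `n_runs` seeded random
#' reaction permutations and keeps the intersection of all active sets, so
#' only order-robust reactions are reported.
#'
#' @param model a `metabolic_model`.
#' @param penalties a `penalty_vector` or named weight vector.
#' @param required_fraction GIMME objective fraction.
#' @param n_runs ensemble size (conventionally 10).
#' @param base_seed seeds `base_seed .. base_seed + n_runs - 1` drive the
#'   permutations.
#' @return an `ensemble_result`: list with `active_sets` (per run),
#'   `consensus_active` (intersection), `scores`, `seeds`.
#' @export
build_ensemble <- function(model, penalties, required_fraction = 0.9,
                           n_runs = 10, base_seed = 1) {
  seeds <- base_seed + seq_len(n_runs) - 1L
  active_sets <- vector("list", n_runs)
  scores <- numeric(n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(seeds[k])
    perm <- sample(nrow(model$rxns))
    pm <- permute_reactions(model, perm)
    res <- tryCatch(
      run_gimme(pm, penalties, required_fraction),
      error = function(e)
        abort_rgem(sprintf("ensemble run with seed %d failed: %s",
                           seeds[k], conditionMessage(e)), "rgem_ensemble_error"))
    active_sets[[k]] <- sort(res$active_reactions)
    scores[k] <- res$inconsistency_score
  }
  structure(list(active_sets = active_sets,
                 consensus_active = sort(Reduce(intersect, active_sets)),
                 scores = scores, seeds = seeds),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d runs, consensus %d reactions, scores %.4g..%.4g\n",
              length(x$active_sets), length(x$consensus_active),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Compare two context-specific active reaction sets
#'
#' Partitions the union of the two active sets into shared / unique-WT /
#' unique-KO reactions, induces the corresponding metabolite sets, and
#' reports per-compartment metabolite counts with KO/WT ratios.
#'
#' @param wt_active,ko_active character vectors of active reaction ids.
#' @param model the common parent `metabolic_model`.
#' @return a `model_diff`: lists of shared/unique reactions and
#'   metabolites plus a `compartments` data.frame (`compartment`,
#'   `n_wt`, `n_ko`, `ratio`; 0/0 counts as ratio 1, x/0 as Inf).
#' @export
diff_models <- function(wt_active, ko_active, model) {
  stopifnot(all(wt_active %in% model$rxns$id), all(ko_active %in% model$rxns$id))
  shared <- sort(intersect(wt_active, ko_active))
  u_wt <- sort(setdiff(wt_active, ko_active))
  u_ko <- sort(setdiff(ko_active, wt_active))
  mets_of <- function(rids) {
    if (!length(rids)) return(character())
    sort(unique(unlist(lapply(rids, function(r) names(rxn_stoich(model, r))))))
  }
  m_wt <- mets_of(wt_active); m_ko <- mets_of(ko_active)
  comps <- sort(unique(model$mets$compartment))
  cw <- table(factor(model$mets$compartment[model$mets$id %in% m_wt], comps))
  ck <- table(factor(model$mets$compartment[model$mets$id %in% m_ko], comps))
  ratio <- ifelse(cw == 0 & ck == 0, 1, as.numeric(ck) / as.numeric(cw))
  structure(list(
    shared_reactions = shared, unique_wt = u_wt, unique_ko = u_ko,
    shared_metabolites = sort(intersect(m_wt, m_ko)),
    unique_met_wt = sort(setdiff(m_wt, m_ko)),
    unique_met_ko = sort(setdiff(m_ko, m_wt)),
    compartments = data.frame(compartment = comps, n_wt = as.integer(cw),
                              n_ko = as.integer(ck), ratio = as.numeric(ratio),
                              stringsAsFactors = FALSE)),
    class = "model_diff")
}

#' @export
print.model_diff <- function(x, ...) {
  cat(sprintf("<model_diff> shared %d | unique WT %d | unique KO %d reactions\n",
              length(x$shared_reactions), length(x$unique_wt), length(x$unique_ko)))
  invisible(x)
}

#' Subsystem breakdown of model differences
#'
#' Counts unique-WT and unique-KO reactions per subsystem and reports the
#' affected fraction of each subsystem, which counters the size bias of raw
#' counts. Unlabeled reactions group under `"unassigned"`.
#'
#' @param diff a [diff_models()] result.
#' @param model the parent `metabolic_model`.
#' @return data.frame `subsystem`, `n_unique_wt`, `n_unique_ko`, `size`,
#'   `fraction_affected`, sorted by decreasing fraction.
#' @export
subsystem_breakdown <- function(diff, model) {
  subs <- model$rxns$subsystem
  subs[!nzchar(subs)] <- "unassigned"
  sub_of <- stats::setNames(subs, model$rxns$id)
  lv <- sort(unique(subs))
  nw <- table(factor(sub_of[diff$unique_wt], lv))
  nk <- table(factor(sub_of[diff$unique_ko], lv))
  size <- table(factor(subs, lv))
  out <- data.frame(subsystem = lv, n_unique_wt = as.integer(nw),
                    n_unique_ko = as.integer(nk), size = as.integer(size),
                    stringsAsFactors = FALSE)
  out$fraction_affected <- (out$n_unique_wt + out$n_unique_ko) / out$size
  out[order(-out$fraction_affected, out$subsystem), , drop = FALSE]
}

#' Metabolite connectivity of a reaction subset
#'
#' Binarizes the stoichiometric matrix, zeroes all columns except the
#' reactions of interest, and computes the connectivity
#' `cm = diag(Sb Sb')`: for each metabolite, the number of subset
#' reactions involving it. Ranking ties break lexicographically by
#' metabolite id.
#'
#' @param model a `metabolic_model`.
#' @param reaction_subset reaction ids defining the columns kept (e.g. the
#'   KO-unique reactions).
#' @return a `connectivity_report`: data.frame `metabolite`, `cm`, ranked
#'   by decreasing connectivity.
#' @export
metabolite_connectivity <- function(model, reaction_subset) {
  stopifnot(all(reaction_subset %in% model$rxns$id))
  if (!length(reaction_subset))
    warn_rgem("empty reaction subset: connectivity is identically zero")
  Sb <- binarize(build_stoichiometric_matrix(model))
  drop_cols <- setdiff(colnames(Sb), reaction_subset)
  if (length(drop_cols)) Sb[, drop_cols] <- 0
  cm <- Matrix::diag(Matrix::tcrossprod(Sb))
  out <- data.frame(metabolite = rownames(Sb), cm = as.integer(round(cm)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cm, out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("connectivity_report", "data.frame")
  out
}
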