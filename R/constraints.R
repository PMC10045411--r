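# Metabolomic data integration: plasma fold changes (KO relative to WT)
# become exchange-reaction bound constraints. Exchanges are first classified
# by FVA into secretion-only / uptake-only / bidirectional / blocked, then
# one of four rules applies per significantly changed metabolite:
#
#   R1  up,   secretion-only: force secretion  (lb := 10% of max secretion)
#   R2  up,   uptake-only:    restrict uptake  (lb := 10% of max uptake)
#   R3  down, secretion-only: restrict secretion (ub := 10% of max secretion)
#   R4  down, uptake-only:    force uptake     (ub := 90% of max uptake)
#
# The 10% marks for R2/R3 are configurable; only the R1 (10%) and R4 (90%)
# fractions are canonical. Every modification is recorded in a constraint
# ledger for auditability.

FREE_ION_BASES <- c("o2", "na1", "k", "fe2", "mg2", "hco3", "h", "h2o")

validate_measurements <- function(df) {
  stopifnot(all(c("metabolite_id", "fold_change", "p_value") %in% names(df)))
  if (any(!is.finite(df$fold_change)) || any(df$fold_change <= 0))
    abort_rgem("fold changes must be finite and positive", "rgem_measurement_error")
  if (any(is.na(df$p_value)) || any(df$p_value < 0 | df$p_value > 1))
    abort_rgem("p values must lie in [0, 1]", "rgem_measurement_error")
  df$direction <- ifelse(df$fold_change > 1, "up",
                         ifelse(df$fold_change < 1, "down", "unchanged"))
  df
}

new_ledger <- function() {
  data.frame(reaction = character(), rule = character(),
             old_lb = numeric(), old_ub = numeric(),
             new_lb = numeric(), new_ub = numeric(),
             note = character(), stringsAsFactors = FALSE)
}

ledger_add <- function(ledger, reaction, rule, old_lb, old_ub, new_lb, new_ub,
                       note = "") {
  rbind(ledger, data.frame(reaction = reaction, rule = rule,
                           old_lb = old_lb, old_ub = old_ub,
                           new_lb = new_lb, new_ub = new_ub, note = note,
                           stringsAsFactors = FALSE))
}

#' Fold changes and ANOVA p-values from raw intensities
#'
#' Computes per-metabolite KO/WT fold changes as the ratio of geometric
#' means and p-values from a two-way ANOVA of the log intensities on
#' condition and batch (no interaction), mirroring how plasma metabolomics
#' panels are summarised.
#'
#' @param intensities positive numeric matrix, metabolites in rows
#'   (rownames = ids), samples in columns.
#' @param design data.frame with one row per sample: columns `condition`
#'   (values `"WT"`/`"KO"`) and `batch`.
#' @return a measurement table: `metabolite_id`, `fold_change`, `p_value`,
#'   `direction`.
#' @export
compute_fold_changes <- function(intensities, design) {
  stopifnot(ncol(intensities) == nrow(design),
            all(c("condition", "batch") %in% names(design)))
  if (any(is.na(intensities))) warn_rgem("missing intensities: using complete pairs")
  if (any(intensities <= 0, na.rm = TRUE))
    abort_rgem("intensities must be positive", "rgem_measurement_error")
  cond <- factor(design$condition, levels = c("WT", "KO"))
  if (any(table(cond) < 2))
    abort_rgem("need at least 2 samples per condition", "rgem_measurement_error")
  batch <- factor(design$batch)
  out <- data.frame(metabolite_id = rownames(intensities),
                    fold_change = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  two_batches <- nlevels(droplevels(batch)) > 1
  for (i in seq_len(nrow(intensities))) {
    y <- log(intensities[i, ])
    ok <- is.finite(y)
    out$fold_change[i] <- exp(mean(y[ok & cond == "KO"]) - mean(y[ok & cond == "WT"]))
    fit <- if (two_batches) lm(y ~ cond + batch, subset = ok) else lm(y ~ cond, subset = ok)
    tab <- anova(fit)
    out$p_value[i] <- tab[["Pr(>F)"]][rownames(tab) == "cond"]
  }
  validate_measurements(out)
}

#' Classify exchange reactions by FVA flux sign
#'
#' An exchange is `secretion_only` when its feasible flux range is
#' nonnegative with positive maximum, `uptake_only` when nonpositive with
#' negative minimum, `bidirectional` when both signs are feasible, and
#' `blocked` when the range collapses to zero.
#'
#' @param model a `metabolic_model`.
#' @param fraction_of_optimum FVA objective fraction; 0 (pure feasibility)
#'   is the default since classification precedes objective imposition.
#' @return data.frame: `reaction`, `metabolite`, `class`, `fva_min`, `fva_max`.
#' @export
classify_exchanges <- function(model, fraction_of_optimum = 0) {
  ex <- exchange_reactions(model)
  fva <- run_fva(model, fraction_of_optimum, reaction_ids = ex)
  tol <- 1e-9
  cls <- ifelse(fva$min_flux >= -tol & fva$max_flux > tol, "secretion_only",
         ifelse(fva$max_flux <= tol & fva$min_flux < -tol, "uptake_only",
         ifelse(fva$max_flux > tol & fva$min_flux < -tol, "bidirectional",
                "blocked")))
  data.frame(reaction = fva$reaction,
             metabolite = unname(exchange_metabolites(model)[fva$reaction]),
             class = cls, fva_min = fva$min_flux, fva_max = fva$max_flux,
             stringsAsFactors = FALSE)
}

#' Constrain exchange bounds from metabolite fold changes
#'
#' Applies the four fold-change rules (see the module header) to the
#' exchanges of significantly changed metabolites. Bidirectional and
#' blocked exchanges are logged untouched. The constrained model's
#' feasibility is re-verified.
#'
#' @param model a `metabolic_model`.
#' @param measurements measurement table (`metabolite_id`, `fold_change`,
#'   `p_value`).
#' @param classes result of [classify_exchanges()].
#' @param mapping data.frame `metabolite_id` -> `exchange_id`; defaults to
#'   matching measurement ids against exchange metabolite ids directly.
#' @param alpha significance cutoff on the measurement p-values.
#' @param r2_fraction,r3_fraction fractions for the uptake-restricting (R2)
#'   and secretion-restricting (R3) rules; the canonical values for R1/R4
#'   are fixed at 10% and 90%.
#' @return list with `model` (new bounds) and `ledger` (constraint audit
#'   trail).
#' @export
apply_fold_change_constraints <- function(model, measurements, classes,
                                          mapping = NULL, alpha = 0.05,
                                          r2_fraction = 0.10,
                                          r3_fraction = 0.10) {
  measurements <- validate_measurements(measurements)
  ledger <- new_ledger()
  if (is.null(mapping))
    mapping <- data.frame(metabolite_id = classes$metabolite,
                          exchange_id = classes$reaction,
                          stringsAsFactors = FALSE)
  sel <- measurements$p_value < alpha & measurements$direction != "unchanged"
  applied <- character()
  for (i in which(sel)) {
    mid <- measurements$metabolite_id[i]
    ex <- mapping$exchange_id[mapping$metabolite_id == mid]
    if (!length(ex)) next
    ex <- ex[1]
    row <- classes[classes$reaction == ex, ]
    if (!nrow(row)) {
      warn_rgem(sprintf("measurement '%s' maps to unknown exchange '%s'", mid, ex))
      next
    }
    old_lb <- model$rxns$lb[rxn_index(model, ex)]
    old_ub <- model$rxns$ub[rxn_index(model, ex)]
    up <- measurements$direction[i] == "up"
    if (row$class == "secretion_only" && up) {
      new_lb <- 0.10 * row$fva_max
      model <- set_bounds(model, ex, lb = new_lb)
      ledger <- ledger_add(ledger, ex, "R1", old_lb, old_ub, new_lb, old_ub, mid)
    } else if (row$class == "uptake_only" && up) {
      new_lb <- r2_fraction * row$fva_min
      model <- set_bounds(model, ex, lb = new_lb)
      ledger <- ledger_add(ledger, ex, "R2", old_lb, old_ub, new_lb, old_ub, mid)
    } else if (row$class == "secretion_only" && !up) {
      new_ub <- r3_fraction * row$fva_max
      model <- set_bounds(model, ex, ub = new_ub)
      ledger <- ledger_add(ledger, ex, "R3", old_lb, old_ub, old_lb, new_ub, mid)
    } else if (row$class == "uptake_only" && !up) {
      new_ub <- 0.90 * row$fva_min
      model <- set_bounds(model, ex, ub = new_ub)
      ledger <- ledger_add(ledger, ex, "R4", old_lb, old_ub, old_lb, new_ub, mid)
    } else {
      ledger <- ledger_add(ledger, ex, "skipped", old_lb, old_ub, old_lb, old_ub,
                           sprintf("%s: class %s", mid, row$class))
      next
    }
    applied <- c(applied, ex)
  }
  if (length(applied)) {
    chk <- solve_fba(model)
    if (chk$status != "optimal")
      abort_rgem(sprintf("constrained model is %s; conflicting rules on: %s",
                         chk$status, paste(unique(applied), collapse = ", ")),
                 "rgem_constraint_error")
  }
  list(model = model, ledger = ledger)
}

#' Set reference uptakes and free ion exchanges
#'
#' Substrate exchanges mapped from the measured metabolite panel receive a
#' reference uptake bound (default 0.25 mmol/gDW/h); the conventional freely
#' exchanged species (oxygen, sodium, potassium, iron, magnesium,
#' bicarbonate, protons, water) get unconstrained bounds of +/-1000.
#'
#' @param model a `metabolic_model`.
#' @param mapped_metabolite_ids metabolite ids whose exchanges get the
#'   reference uptake.
#' @param reference_uptake uptake magnitude (mmol/gDW/h).
#' @param free_ions base metabolite names given free exchange.
#' @return list with `model` and `ledger`.
#' @export
set_reference_exchanges <- function(model, mapped_metabolite_ids,
                                    reference_uptake = 0.25,
                                    free_ions = FREE_ION_BASES) {
  exmet <- exchange_metabolites(model)
  ledger <- new_ledger()
  for (mid in mapped_metabolite_ids) {
    ex <- names(exmet)[exmet == mid]
    if (!length(ex)) {
      warn_rgem(sprintf("no exchange found for metabolite '%s'; skipped", mid))
      next
    }
    i <- rxn_index(model, ex[1])
    if (model$rxns$lb[i] >= 0) next  # secretion-only exchange: not a substrate
    ledger <- ledger_add(ledger, ex[1], "reference_uptake",
                         model$rxns$lb[i], model$rxns$ub[i],
                         -reference_uptake, model$rxns$ub[i], mid)
    model <- set_bounds(model, ex[1], lb = -reference_uptake)
  }
  base <- strip_compartment(unname(exmet))
  for (k in which(base %in% free_ions)) {
    ex <- names(exmet)[k]
    i <- rxn_index(model, ex)
    ledger <- ledger_add(ledger, ex, "free_ion",
                         model$rxns$lb[i], model$rxns$ub[i], -1000, 1000,
                         unname(exmet[k]))
    model <- set_bounds(model, ex, lb = -1000, ub = 1000)
  }
  list(model = model, ledger = ledger)
}
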