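# End-to-end WT-versus-KO workflow: expression presence -> GPR penalties ->
# reference/metabolomic exchange constraints -> reorder-ensemble GIMME ->
# model diff, subsystem breakdown, connectivity -> (optionally) flux
# sampling with KS differential reactions and co-sets. Fully deterministic
# given the configured seed; all reports are written as TSV/JSON.

#' Assemble a pipeline configuration
#'
#' @param model a `metabolic_model` or path to a model file.
#' @param wt_calls,ko_calls [expression_calls()] objects or TSV paths.
#' @param measurements measurement table (`metabolite_id`, `fold_change`,
#'   `p_value`) or TSV path.
#' @param mapping measurement-to-exchange mapping data.frame or TSV path.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param ... overrides: `ortholog_table`, `ko_blocked_exchange`, `alpha`
#'   (0.05), `required_fraction` (0.9), `n_runs` (10), `p_threshold`
#'   (0.001), `r_cutoff` (0.95), `reference_uptake` (0.25), `min_present`
#'   (2), `do_sampling` (TRUE), `thinning` (defaults to the dimension-scaled
#'   sampler thinning), `n_points` (2n),
#'   `out_dir`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(model, wt_calls, ko_calls, measurements, mapping,
                            seed = 1, ...) {
  cfg <- list(model = model, wt_calls = wt_calls, ko_calls = ko_calls,
              measurements = measurements, mapping = mapping, seed = seed,
              ortholog_table = NULL, ko_blocked_exchange = NULL,
              alpha = 0.05, required_fraction = 0.9, n_runs = 10L,
              p_threshold = 0.001, r_cutoff = 0.95, reference_uptake = 0.25,
              min_present = 2L, do_sampling = TRUE, thinning = NULL,
              n_points = NULL, out_dir = NULL)
  structure(modifyList(cfg, list(...)), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML/JSON
#'
#' File paths inside the configuration are resolved relative to the
#' configuration file's directory.
#'
#' @param path YAML or JSON configuration file.
#' @return a `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.character(p) && !file.exists(p) &&
                         file.exists(file.path(base, p))) file.path(base, p) else p
  for (k in c("model", "wt_calls", "ko_calls", "measurements", "mapping",
              "ortholog_table"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- rel(cfg[[k]])
  do.call(pipeline_config, cfg)
}

load_stage <- function(x, loader) if (is.character(x)) loader(x) else x

#' Run the full comparison pipeline
#'
#' Executes presence consensus, ortholog mapping (when configured), GPR
#' penalty computation, reference and fold-change exchange constraints (the
#' knockout model receives the metabolomic constraints and the optional
#' blocked exchange), reorder-ensemble GIMME for both conditions, model
#' difference / subsystem / connectivity analyses, and (optionally)
#' solution-space sampling with KS differential reactions and co-sets.
#'
#' @param config a [pipeline_config()] list, or a path to a YAML/JSON file.
#' @return a `comparison_report` list; reports are also written under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  model <- load_stage(config$model, read_model)
  wt_calls <- load_stage(config$wt_calls,
                         function(p) read_expression_tsv(p, "WT"))
  ko_calls <- load_stage(config$ko_calls,
                         function(p) read_expression_tsv(p, "KO"))
  measurements <- validate_measurements(
    load_stage(config$measurements, read_measurements_tsv))
  mapping <- load_stage(config$mapping, read_exchange_map_tsv)
  ortho <- if (!is.null(config$ortholog_table))
    load_stage(config$ortholog_table, read_ortholog_tsv) else NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_rgem(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), "rgem_pipeline_error"))
  }

  # expression -> penalties
  presence <- stage("presence", lapply(
    list(WT = wt_calls, KO = ko_calls), function(cl) {
      pres <- consensus_presence(cl, config$min_present)
      if (!is.null(ortho)) pres <- map_orthologs(pres, ortho, model$genes)
      pres
    }))
  penalties <- stage("penalties", lapply(presence, function(pres)
    compute_penalties(gpr_presence(model, pres))))

  # exchange constraints
  exmet <- exchange_metabolites(model)
  mapped_mets <- unname(exmet[intersect(mapping$exchange_id, names(exmet))])
  ref <- stage("reference_exchanges",
               set_reference_exchanges(model, mapped_mets,
                                       config$reference_uptake))
  wt_model <- ref$model
  ko_model <- wt_model
  if (!is.null(config$ko_blocked_exchange))
    ko_model <- stage("knockout", plant_knockout(ko_model,
                                                 config$ko_blocked_exchange))
  classes_ko <- stage("classify_exchanges", classify_exchanges(ko_model))
  cons <- stage("fold_change_constraints",
                apply_fold_change_constraints(ko_model, measurements,
                                              classes_ko, mapping,
                                              alpha = config$alpha))
  ko_model <- cons$model
  ledger <- rbind(ref$ledger, cons$ledger)

  # context-specific models (reorder ensemble)
  ens_wt <- stage("ensemble_wt",
                  build_ensemble(wt_model, penalties$WT,
                                 config$required_fraction, config$n_runs,
                                 base_seed = derive_seed(config$seed, 100L)))
  ens_ko <- stage("ensemble_ko",
                  build_ensemble(ko_model, penalties$KO,
                                 config$required_fraction, config$n_runs,
                                 base_seed = derive_seed(config$seed, 200L)))

  # comparisons
  diff <- stage("diff", diff_models(ens_wt$consensus_active,
                                    ens_ko$consensus_active, model))
  subsys <- stage("subsystems", subsystem_breakdown(diff, model))
  conn_ko <- stage("connectivity",
                   metabolite_connectivity(model, diff$unique_ko))

  differential <- NULL; cosets <- NULL
  if (isTRUE(config$do_sampling)) {
    context_model <- function(mdl, active) {
      off <- setdiff(mdl$rxns$id, active)
      mdl$rxns$lb[mdl$rxns$id %in% off] <- 0
      mdl$rxns$ub[mdl$rxns$id %in% off] <- 0
      mdl
    }
    wt_ctx <- context_model(wt_model, ens_wt$consensus_active)
    ko_ctx <- context_model(ko_model, ens_ko$consensus_active)
    samp <- stage("sampling", list(
      WT = normalize_samples(sample_fluxes(wt_ctx, config$n_points,
                                           seed = derive_seed(config$seed, 301L),
                                           thinning = config$thinning)),
      KO = normalize_samples(sample_fluxes(ko_ctx, config$n_points,
                                           seed = derive_seed(config$seed, 302L),
                                           thinning = config$thinning))))
    differential <- stage("differential",
                          differential_reactions(samp$WT, samp$KO,
                                                 config$p_threshold))
    cosets <- stage("cosets", list(
      WT = compute_cosets(samp$WT, config$r_cutoff),
      KO = compute_cosets(samp$KO, config$r_cutoff)))
  }

  report <- structure(list(
    consensus_wt = ens_wt$consensus_active,
    consensus_ko = ens_ko$consensus_active,
    ensembles = list(WT = ens_wt, KO = ens_ko),
    diff = diff, subsystems = subsys, connectivity_ko_unique = conn_ko,
    differential = differential, cosets = cosets, ledger = ledger,
    penalties = penalties,
    config = config[setdiff(names(config), c("model", "wt_calls", "ko_calls",
                                             "measurements", "mapping",
                                             "ortholog_table"))]),
    class = "comparison_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> WT %d | KO %d consensus reactions; unique WT %d, KO %d\n",
              length(x$consensus_wt), length(x$consensus_ko),
              length(x$diff$unique_wt), length(x$diff$unique_ko)))
  if (!is.null(x$differential))
    cat(sprintf("  %d differential reactions (KS)\n", nrow(x$differential)))
  invisible(x)
}

#' Write all pipeline reports to a directory
#'
#' @param report a `comparison_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  num <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)

  all_rxn <- sort(unique(c(report$consensus_wt, report$consensus_ko)))
  status <- ifelse(all_rxn %in% report$diff$shared_reactions, "shared",
                   ifelse(all_rxn %in% report$diff$unique_wt, "wt_only",
                          "ko_only"))
  write_tsv(data.frame(reaction = all_rxn, status = status), fp("active_reactions.tsv"))
  write_tsv(report$diff$compartments, fp("compartment_metabolites.tsv"))
  write_tsv(report$subsystems, fp("subsystem_breakdown.tsv"))
  write_tsv(as.data.frame(report$connectivity_ko_unique),
            fp("connectivity_ko_unique.tsv"))
  lg <- report$ledger
  for (cc in c("old_lb", "old_ub", "new_lb", "new_ub")) lg[[cc]] <- num(lg[[cc]])
  write_tsv(lg, fp("constraint_ledger.tsv"))
  if (!is.null(report$differential)) {
    dd <- report$differential
    dd$ks_statistic <- num(dd$ks_statistic)
    dd$p_value <- format(report$differential$p_value, digits = 6)
    write_tsv(dd, fp("differential_reactions.tsv"))
  }
  if (!is.null(report$cosets)) {
    for (cond in names(report$cosets)) {
      cs <- report$cosets[[cond]]
      df <- if (length(cs))
        data.frame(coset = rep(seq_along(cs), lengths(cs)),
                   reaction = unlist(cs))
      else data.frame(coset = integer(), reaction = character())
      write_tsv(df, fp(sprintf("cosets_%s.tsv", tolower(cond))))
    }
  }
  summary <- list(
    n_consensus_wt = length(report$consensus_wt),
    n_consensus_ko = length(report$consensus_ko),
    n_shared = length(report$diff$shared_reactions),
    n_unique_wt = length(report$diff$unique_wt),
    n_unique_ko = length(report$diff$unique_ko),
    unique_wt = report$diff$unique_wt,
    unique_ko = report$diff$unique_ko,
    inconsistency_scores = list(WT = report$ensembles$WT$scores,
                                KO = report$ensembles$KO$scores),
    n_differential = if (is.null(report$differential)) NULL
                     else nrow(report$differential),
    config = report$config[setdiff(names(report$config), "out_dir")])
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
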