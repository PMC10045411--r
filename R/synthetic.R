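# Synthetic study system: a designed kidney-redox toy network plus
# generators for presence/absence transcriptomic calls and log-normally
# noisy plasma metabolite intensities with planted fold changes.
#
# The network couples ATP production (the objective) to mitochondrial
# respiration with a small obligatory electron leak to superoxide. The
# wildtype disposes of superoxide through urate scavenging fed by a
# reabsorption-style urate uptake ("Urat1-like"). When that uptake is lost,
# disposal must run through the capacity-limited enzymatic branch:
# superoxide dismutases in five compartments, the ascorbate cycle (with
# NADPH- and glutathione-dependent regeneration), glutathione/thioredoxin
# peroxidases, and transhydrogenase-backed NADPH supply. Those reactions
# carry low-expression penalties, so they surface as KO-unique model
# content -- the designed analogue of redox-cofactor enrichment after loss
# of a urate transporter. Capacities are sized so that at 90% of optimal
# ATP production every branch member is forced; this is a designed test
# harness, not a claim of biological realism.

# electron leak: fraction of complex-I electron pairs diverted to superoxide
TOY_LEAK <- 0.02
TOY_SPODM_CAP <- 0.006   # per-isoform superoxide dismutase capacity
TOY_DASCBR_CAP <- 0.002  # NADPH-dependent ascorbate regeneration capacity
TOY_CATX_CAP <- 0.012    # peroxisomal catalase capacity
TOY_TRXR_CAP <- 0.008    # thioredoxin-route peroxide capacity
TOY_G6PD_CAP <- 0.001    # oxidative PPP capacity (12 NADPH per unit)

toy_metabolites <- function() {
  m <- function(id, formula, charge) data.frame(id = id, formula = formula,
                                                charge = charge,
                                                stringsAsFactors = FALSE)
  rbind(
    # extracellular
    m("glc-D_e", "C6H12O6", 0), m("o2_e", "O2", 0), m("co2_e", "CO2", 0),
    m("h_e", "H", 1), m("h2o_e", "H2O", 0), m("lac-L_e", "C3H5O3", -1),
    m("pyr_e", "C3H3O3", -1), m("ascb-L_e", "C6H7O6", -1),
    m("urat_e", "C5H3N4O3", -1), m("urtox_e", "C5H5N4O5", 0),
    m("o2s_e", "O2", -1), m("h2o2_e", "H2O2", 0),
    m("gthrd_e", "C10H16N3O6S", -1), m("gthox_e", "C20H30N6O12S2", -2),
    m("na1_e", "Na", 1), m("k_e", "K", 1), m("fe2_e", "Fe", 2),
    m("mg2_e", "Mg", 2), m("hco3_e", "CHO3", -1),
    m("kynu_e", "C10H12N2O3", 0), m("man_e", "C6H12O6", 0),
    m("crtn_e", "C4H7N3O", 0), m("c10und_e", "C11H19O2", -1),
    m("olecrn_e", "C25H48NO4", 0),
    # cytosol
    m("glc-D_c", "C6H12O6", 0), m("g6p_c", "C6H11O9P", -2),
    m("pyr_c", "C3H3O3", -1), m("lac-L_c", "C3H5O3", -1),
    m("atp_c", "C10H12N5O13P3", -4), m("adp_c", "C10H12N5O10P2", -3),
    m("pi_c", "HO4P", -2), m("h_c", "H", 1), m("h2o_c", "H2O", 0),
    m("o2_c", "O2", 0), m("co2_c", "CO2", 0),
    m("nad_c", "C21H26N7O14P2", -1), m("nadh_c", "C21H27N7O14P2", -2),
    m("nadp_c", "C21H25N7O17P3", -3), m("nadph_c", "C21H26N7O17P3", -4),
    m("ascb-L_c", "C6H7O6", -1), m("dhdascb_c", "C6H6O6", 0),
    m("gthrd_c", "C10H16N3O6S", -1), m("gthox_c", "C20H30N6O12S2", -2),
    m("o2s_c", "O2", -1), m("h2o2_c", "H2O2", 0),
    m("urat_c", "C5H3N4O3", -1), m("urtox_c", "C5H5N4O5", 0),
    m("hco3_c", "CHO3", -1),
    # mitochondria
    m("pyr_m", "C3H3O3", -1), m("coa_m", "C21H32N7O16P3S", -4),
    m("accoa_m", "C23H34N7O17P3S", -4),
    m("nad_m", "C21H26N7O14P2", -1), m("nadh_m", "C21H27N7O14P2", -2),
    m("q10_m", "C59H90O4", 0), m("q10h2_m", "C59H92O4", 0),
    m("atp_m", "C10H12N5O13P3", -4), m("adp_m", "C10H12N5O10P2", -3),
    m("pi_m", "HO4P", -2), m("h_m", "H", 1), m("h2o_m", "H2O", 0),
    m("o2_m", "O2", 0), m("co2_m", "CO2", 0),
    m("o2s_m", "O2", -1), m("h2o2_m", "H2O2", 0),
    # nucleus
    m("h_n", "H", 1), m("o2s_n", "O2", -1), m("h2o2_n", "H2O2", 0),
    m("o2_n", "O2", 0),
    # peroxisome
    m("h_x", "H", 1), m("o2s_x", "O2", -1), m("h2o2_x", "H2O2", 0),
    m("o2_x", "O2", 0), m("h2o_x", "H2O", 0))
}

toy_reactions <- function(leak = TOY_LEAK) {
  r <- function(id, eq, lb, ub, gpr = "", subsystem = "")
    data.frame(id = id, eq = eq, lb = lb, ub = ub, gpr = gpr,
               subsystem = subsystem, stringsAsFactors = FALSE)
  lk <- function(x) format(x, digits = 12)
  rbind(
    # exchanges (positive flux = secretion, negative = uptake)
    r("EX_glc-D_e", "glc-D_e ->", -0.25, 0, "", "Exchange"),
    r("EX_o2_e", "o2_e ->", -1000, 1000, "", "Exchange"),
    r("EX_co2_e", "co2_e ->", 0, 1000, "", "Exchange"),
    r("EX_h_e", "h_e ->", -1000, 1000, "", "Exchange"),
    r("EX_h2o_e", "h2o_e ->", -1000, 1000, "", "Exchange"),
    r("EX_na1_e", "na1_e ->", -1000, 1000, "", "Exchange"),
    r("EX_k_e", "k_e ->", -1000, 1000, "", "Exchange"),
    r("EX_fe2_e", "fe2_e ->", -1000, 1000, "", "Exchange"),
    r("EX_mg2_e", "mg2_e ->", -1000, 1000, "", "Exchange"),
    r("EX_hco3_e", "hco3_e ->", -1000, 1000, "", "Exchange"),
    r("EX_lac-L_e", "lac-L_e ->", 0, 1000, "", "Exchange"),
    r("EX_pyr_e", "pyr_e ->", -0.25, 0, "", "Exchange"),
    r("EX_ascb-L_e", "ascb-L_e ->", -0.25, 0, "", "Exchange"),
    r("EX_urat_e", "urat_e ->", -0.25, 0, "", "Exchange"),
    r("EX_urtox_e", "urtox_e ->", 0, 1000, "", "Exchange"),
    r("EX_kynu_e", "kynu_e ->", -0.25, 0, "", "Exchange"),
    r("EX_man_e", "man_e ->", -0.25, 0, "", "Exchange"),
    r("EX_crtn_e", "crtn_e ->", -0.25, 0, "", "Exchange"),
    r("EX_c10und_e", "c10und_e ->", -0.25, 0, "", "Exchange"),
    r("EX_olecrn_e", "olecrn_e ->", -0.25, 0, "", "Exchange"),
    # transports
    r("GLCt", "glc-D_e -> glc-D_c", 0, 1000, "glut2", "Transport"),
    r("PYRt2", "pyr_e + h_e -> pyr_c + h_c", 0, 1000, "mct1", "Transport"),
    r("LACt", "lac-L_c + h_c -> lac-L_e + h_e", 0, 1000, "mct4", "Transport"),
    r("ASCBt", "ascb-L_e -> ascb-L_c", 0, 1000, "svct1", "Vitamin C metabolism"),
    r("URAT1", "urat_e -> urat_c", 0, 1000, "urat1", "Urate metabolism"),
    r("URTOXt", "urtox_c -> urtox_e", 0, 1000, "", "Urate metabolism"),
    r("O2t", "o2_e <=> o2_c", -1000, 1000, "", "Transport"),
    r("O2tm", "o2_c <=> o2_m", -1000, 1000, "", "Transport"),
    r("O2tn", "o2_c <=> o2_n", -1000, 1000, "", "Transport"),
    r("O2tx", "o2_c <=> o2_x", -1000, 1000, "", "Transport"),
    r("CO2tm", "co2_m <=> co2_c", -1000, 1000, "", "Transport"),
    r("CO2t", "co2_c <=> co2_e", -1000, 1000, "", "Transport"),
    r("H2Ot", "h2o_e <=> h2o_c", -1000, 1000, "", "Transport"),
    r("H2Otm", "h2o_c <=> h2o_m", -1000, 1000, "", "Transport"),
    r("H2Otx", "h2o_c <=> h2o_x", -1000, 1000, "", "Transport"),
    r("Ht", "h_e <=> h_c", -1000, 1000, "", "Transport"),
    r("Htm", "h_c <=> h_m", -1000, 1000, "", "Transport"),
    r("Htn", "h_c <=> h_n", -1000, 1000, "", "Transport"),
    r("Htx", "h_c <=> h_x", -1000, 1000, "", "Transport"),
    r("PIt2m", "pi_c + h_c -> pi_m + h_m", 0, 1000, "slc25a3", "Transport"),
    r("ATPtm", "atp_m + adp_c -> atp_c + adp_m", 0, 1000, "slc25a4",
      "Oxidative phosphorylation"),
    r("PYRt2m", "pyr_c + h_c -> pyr_m + h_m", 0, 1000, "mpc1", "Transport"),
    r("O2Stm", "o2s_m -> o2s_c", 0, 1000, "", "Transport"),
    r("O2Stn", "o2s_c -> o2s_n", 0, 1000, "", "Transport"),
    r("O2Stx", "o2s_c -> o2s_x", 0, 1000, "", "Transport"),
    r("O2Ste", "o2s_c -> o2s_e", 0, 1000, "", "Transport"),
    r("H2O2tm", "h2o2_m <=> h2o2_c", -1000, 1000, "", "Transport"),
    r("H2O2tn", "h2o2_n <=> h2o2_c", -1000, 1000, "", "Transport"),
    r("H2O2tx", "h2o2_c <=> h2o2_x", -1000, 1000, "", "Transport"),
    r("H2O2te", "h2o2_e <=> h2o2_c", -1000, 1000, "", "Transport"),
    r("HCO3t", "hco3_e <=> hco3_c", -1000, 1000, "", "Transport"),
    r("CAc", "co2_c + h2o_c <=> h_c + hco3_c", -1000, 1000, "ca2",
      "Bicarbonate buffering"),
    # core metabolism (constitutively expressed)
    r("HEX1", "glc-D_c + atp_c -> g6p_c + adp_c + h_c", 0, 1000, "hk1",
      "Glycolysis"),
    r("GLYCL",
      "g6p_c + 3 adp_c + 2 pi_c + 2 nad_c -> 2 pyr_c + 3 atp_c + 2 nadh_c + h_c + 2 h2o_c",
      0, 1000, "pfkl and gapdh", "Glycolysis"),
    r("LDH_L", "pyr_c + nadh_c + h_c <=> lac-L_c + nad_c", -1000, 1000,
      "ldha", "Glycolysis"),
    r("G6PDH2", "g6p_c + 12 nadp_c + 7 h2o_c -> 6 co2_c + 12 nadph_c + 12 h_c + pi_c",
      0, TOY_G6PD_CAP, "g6pd", "Pentose phosphate pathway"),
    r("PDHm", "pyr_m + coa_m + nad_m -> accoa_m + co2_m + nadh_m",
      0, 1000, "pdha1 and dlat", "TCA cycle"),
    r("TCA",
      "accoa_m + 3 nad_m + q10_m + 2 h2o_m + adp_m + pi_m -> coa_m + 3 nadh_m + q10h2_m + 2 co2_m + atp_m + 2 h_m",
      0, 1000, "cs", "TCA cycle"),
    r("NADH5",
      sprintf("nadh_m + h_m + %s q10_m + %s o2_m -> nad_m + %s q10h2_m + %s o2s_m + %s h_m",
              lk(1 - leak), lk(2 * leak), lk(1 - leak), lk(2 * leak), lk(2 * leak)),
      0, 1000, "ndufa1 and ndufs2", "Oxidative phosphorylation"),
    r("GPDSH", "nadh_c + h_c + q10_m -> nad_c + q10h2_m", 0, 1000, "gpd2",
      "Oxidative phosphorylation"),
    r("CYOO",
      "2 q10h2_m + o2_m + 5 adp_m + 5 pi_m + 5 h_m -> 2 q10_m + 7 h2o_m + 5 atp_m",
      0, 1000, "uqcrc1 and cox4i1", "Oxidative phosphorylation"),
    r("ATPM", "atp_c + h2o_c -> adp_c + pi_c + h_c", 0, 1000, "",
      "Energy demand"),
    r("USCAV", "urat_c + o2s_c + 2 h_c -> urtox_c", 0, 1000, "",
      "Urate metabolism"),
    r("CATx", "2 h2o2_x -> 2 h2o_x + o2_x", 0, TOY_CATX_CAP, "cat",
      "Peroxisomal metabolism"),
    r("DM_ascb", "ascb-L_c ->", 0, 1000, "", "Vitamin C metabolism"),
    r("GTHPe", "2 gthrd_e + h2o2_e -> gthox_e + 2 h2o_e", 0, 1000, "gpx3",
      "Glutathione metabolism"),
    # penalized redox branch (low-expression in kidney at baseline)
    r("SPODM", "2 h_c + 2 o2s_c -> o2_c + h2o2_c", 0, TOY_SPODM_CAP,
      "sod1_a and sod1_b", "ROS detoxification"),
    r("SPODMe", "2 h_e + 2 o2s_e -> h2o2_e + o2_e", 0, TOY_SPODM_CAP,
      "sod3_a and sod3_b", "ROS detoxification"),
    r("SPODMm", "2 h_m + 2 o2s_m -> o2_m + h2o2_m", 0, TOY_SPODM_CAP,
      "sod2_a and sod2_b", "ROS detoxification"),
    r("SPODMn", "2 h_n + 2 o2s_n -> h2o2_n + o2_n", 0, TOY_SPODM_CAP,
      "sodn_a and sodn_b", "ROS detoxification"),
    r("SPODMx", "2 h_x + 2 o2s_x -> o2_x + h2o2_x", 0, TOY_SPODM_CAP,
      "sodx_a and sodx_b", "ROS detoxification"),
    r("ASCBOX", "3 h_c + ascb-L_c + 2 o2s_c -> 2 h2o2_c + dhdascb_c",
      0, 1000, "ascbox_a and ascbox_b", "Vitamin C metabolism"),
    r("DASCBR", "nadph_c + dhdascb_c -> nadp_c + ascb-L_c",
      0, TOY_DASCBR_CAP, "dascbr_a and dascbr_b", "Vitamin C metabolism"),
    r("DHAOX", "dhdascb_c + 2 gthrd_c -> h_c + ascb-L_c + gthox_c",
      0, 1000, "dhaox_a and dhaox_b", "Vitamin C metabolism"),
    r("GTHP", "2 gthrd_c + h2o2_c -> gthox_c + 2 h2o_c", 0, 1000,
      "gpx1_a and gpx1_b", "Glutathione metabolism"),
    r("GTHOr", "gthox_c + nadph_c + h_c -> 2 gthrd_c + nadp_c", 0, 1000,
      "gsr_a and gsr_b", "Glutathione metabolism"),
    r("TRXR", "h2o2_c + nadph_c + h_c -> 2 h2o_c + nadp_c", 0, TOY_TRXR_CAP,
      "txnrd_a and txnrd_b", "Glutathione metabolism"),
    r("NADTRHD", "nadh_c + nadp_c -> nad_c + nadph_c", 0, 1000,
      "nnt_a and nnt_b", "Oxidative phosphorylation"))
}

# reactions removed when the ROS branch is toggled off
TOY_ROS_BRANCH <- c("SPODM", "SPODMe", "SPODMm", "SPODMn", "SPODMx",
                    "ASCBOX", "DASCBR", "DHAOX", "GTHP", "GTHOr", "TRXR",
                    "NADTRHD")

# genes of the penalized redox branch: planted absent in both conditions
TOY_REDOX_GENES <- c("sod1_a", "sod1_b", "sod2_a", "sod2_b", "sod3_a",
                     "sod3_b", "sodn_a", "sodn_b", "sodx_a", "sodx_b",
                     "ascbox_a", "ascbox_b", "dascbr_a", "dascbr_b",
                     "dhaox_a", "dhaox_b", "gpx1_a", "gpx1_b",
                     "gsr_a", "gsr_b", "txnrd_a", "txnrd_b",
                     "nnt_a", "nnt_b")

#' Build the synthetic kidney-redox toy network
#'
#' A deterministic ~70-reaction model with a glucose-fed glycolysis /
#' TCA / oxidative-phosphorylation backbone, an obligatory superoxide leak
#' at complex I, urate-scavenging superoxide disposal fed by a
#' reabsorption-style urate uptake, and a capacity-limited enzymatic
#' redox-detoxification branch (superoxide dismutase isoforms in five
#' compartments, the ascorbate cycle, glutathione and thioredoxin
#' peroxide routes, transhydrogenase). ATP demand (`ATPM`) is the
#' objective. The network is fully mass- and charge-balanced outside of
#' boundary reactions.
#'
#' @param ros_branch include the enzymatic redox branch (default TRUE).
#' @param include_glyox also include the glyoxalase fixture reaction
#'   (arrives blocked; for connectivity/fixture tests).
#' @param leak fraction of complex-I electron pairs lost to superoxide.
#' @return a `metabolic_model`.
#' @export
build_redox_toy_model <- function(ros_branch = TRUE, include_glyox = FALSE,
                                  leak = TOY_LEAK) {
  mets <- toy_metabolites()
  rx <- toy_reactions(leak)
  if (!ros_branch) rx <- rx[!rx$id %in% TOY_ROS_BRANCH, , drop = FALSE]
  if (include_glyox) {
    mets <- rbind(mets, data.frame(id = c("lgt-S_c", "lac-D_c"),
                                   formula = c("C13H20N3O8S", "C3H5O3"),
                                   charge = c(-2, -1), stringsAsFactors = FALSE))
    rx <- rbind(rx, data.frame(id = "GLYOX",
                               eq = "h2o_c + lgt-S_c -> h_c + gthrd_c + lac-D_c",
                               lb = 0, ub = 1000, gpr = "hagh",
                               subsystem = "Pyruvate metabolism",
                               stringsAsFactors = FALSE))
  }
  parsed <- lapply(rx$eq, parse_reaction_equation)
  rxns <- data.frame(id = rx$id, lb = rx$lb, ub = rx$ub, gpr = rx$gpr,
                     subsystem = rx$subsystem, stringsAsFactors = FALSE)
  rxns$stoichiometry <- lapply(parsed, `[[`, "stoichiometry")
  metabolic_model(mets, rxns, objective = "ATPM", id = "redox_toy")
}

#' Default simulation configuration for the synthetic study
#'
#' Defaults encode the designed study conditions: 3 expression replicates
#' and 6 metabolomics samples per condition, a 0.9 per-replicate
#' absent-call rate for planted-absent genes, a small 0.02 dropout rate
#' for expressed genes, 6 metabolites planted up at fold 2.0 and 2 down at
#' fold 0.5 (the rest unchanged), and log-intensity noise sigma 0.25.
#'
#' @param seed integer seed driving all generators.
#' @param ... overrides for any configuration entry.
#' @return a named list.
#' @export
simulation_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    expression_replicates = 3L,
    metabolomics_replicates = 6L,
    dropout = 0.02,
    absent_call_rate = 0.9,
    planted_absent_wt = TOY_REDOX_GENES,
    planted_absent_ko = c(TOY_REDOX_GENES, "urat1"),
    ko_blocked_exchange = "EX_urat_e",
    planted_up = c("lac-L", "pyr", "kynu", "man", "c10und", "olecrn"),
    planted_down = c("ascb-L", "urtox"),
    null_metabolites = c("glc-D", "urat", "co2", "crtn"),
    fold_up = 2.0,
    fold_down = 0.5,
    sigma_log = 0.25,
    batch_effect = 0.10)
  modifyList(cfg, list(...))
}

#' Simulate present/absent expression calls
#'
#' Per replicate, planted-absent genes are called absent with probability
#' `absent_call_rate` (default 0.9); all other model genes are called
#' present with probability `1 - dropout`.
#'
#' @param model a `metabolic_model`.
#' @param config a [simulation_config()] list.
#' @param condition `"WT"` or `"KO"` (selects the planted-absent gene set).
#' @return an [expression_calls()] object.
#' @export
simulate_expression <- function(model, config, condition = c("WT", "KO")) {
  condition <- match.arg(condition)
  planted <- if (condition == "WT") config$planted_absent_wt else config$planted_absent_ko
  missing_genes <- setdiff(planted, model$genes)
  if (length(missing_genes))
    abort_rgem(sprintf("planted-absent gene '%s' is not in the model",
                       missing_genes[1]), "rgem_synthetic_error")
  genes <- sort(model$genes)
  nrep <- config$expression_replicates
  set.seed(derive_seed(config$seed, if (condition == "WT") 11L else 12L))
  p_present <- ifelse(genes %in% planted, 1 - config$absent_call_rate,
                      1 - config$dropout)
  calls <- matrix(runif(length(genes) * nrep) < rep(p_present, nrep),
                  nrow = length(genes), ncol = nrep,
                  dimnames = list(genes, paste0(condition, "_rep", seq_len(nrep))))
  expression_calls(calls, condition)
}

#' Simulate plasma metabolite intensities with planted fold changes
#'
#' Log-normal intensities: log-intensity = baseline + condition effect
#' (log fold) + batch effect + N(0, sigma^2), over the measured panel of
#' the toy network. Batches are balanced across conditions.
#'
#' @param model a `metabolic_model` (the toy network).
#' @param config a [simulation_config()] list.
#' @return list with `intensities` (matrix metabolites x samples),
#'   `design` (sample data.frame), `truth` (planted folds), and `mapping`
#'   (measurement id -> exchange reaction id).
#' @export
simulate_metabolomics <- function(model, config) {
  panel <- c(config$planted_up, config$planted_down, config$null_metabolites)
  fold <- c(rep(config$fold_up, length(config$planted_up)),
            rep(config$fold_down, length(config$planted_down)),
            rep(1.0, length(config$null_metabolites)))
  exmet <- exchange_metabolites(model)
  ex_of <- function(mid) {
    hit <- names(exmet)[strip_compartment(unname(exmet)) == mid]
    if (!length(hit))
      abort_rgem(sprintf("planted metabolite '%s' has no exchange", mid),
                 "rgem_synthetic_error")
    hit[1]
  }
  mapping <- data.frame(metabolite_id = panel,
                        exchange_id = vapply(panel, ex_of, character(1)),
                        stringsAsFactors = FALSE)
  nrep <- config$metabolomics_replicates
  design <- data.frame(
    sample = c(paste0("WT_s", seq_len(nrep)), paste0("KO_s", seq_len(nrep))),
    condition = rep(c("WT", "KO"), each = nrep),
    batch = rep(rep(c("b1", "b2"), length.out = nrep), 2),
    stringsAsFactors = FALSE)
  set.seed(derive_seed(config$seed, 21L))
  baseline <- runif(length(panel), log(1e3), log(1e5))
  eff <- log(fold)
  logint <- matrix(NA_real_, length(panel), nrow(design),
                   dimnames = list(panel, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- baseline +
      (design$condition[j] == "KO") * eff +
      (design$batch[j] == "b2") * config$batch_effect
    logint[, j] <- mu + rnorm(length(panel), 0, config$sigma_log)
  }
  list(intensities = exp(logint), design = design,
       truth = data.frame(metabolite_id = panel, true_fold = fold,
                          direction = ifelse(fold > 1, "up",
                                             ifelse(fold < 1, "down", "unchanged")),
                          stringsAsFactors = FALSE),
       mapping = mapping)
}

#' Block a reabsorption-style exchange (the in silico knockout)
#'
#' @param model a `metabolic_model`.
#' @param exchange_id exchange reaction to block (bounds set to `[0, 0]`).
#' @return the knocked-out model.
#' @export
plant_knockout <- function(model, exchange_id) {
  i <- rxn_index(model, exchange_id)
  if (model$rxns$lb[i] == 0 && model$rxns$ub[i] == 0) {
    warn_rgem(sprintf("exchange '%s' is already blocked", exchange_id))
    return(model)
  }
  set_bounds(model, exchange_id, lb = 0, ub = 0)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates the toy model plus WT/KO expression calls, metabolite
#' intensities, the measurement table (fold changes and ANOVA p-values),
#' the exchange mapping and the truth table, writing everything under
#' `out_dir` as JSON/TSV.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [simulation_config()] list.
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(out_dir, config = simulation_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_redox_toy_model()
  wt <- simulate_expression(model, config, "WT")
  ko <- simulate_expression(model, config, "KO")
  met <- simulate_metabolomics(model, config)
  meas <- compute_fold_changes(met$intensities, met$design)
  write_model(model, file.path(out_dir, "model.json"))
  write_expression_tsv(wt, file.path(out_dir, "expression_wt.tsv"))
  write_expression_tsv(ko, file.path(out_dir, "expression_ko.tsv"))
  write_tsv(data.frame(metabolite_id = rownames(met$intensities),
                       round(met$intensities, 4), check.names = FALSE),
            file.path(out_dir, "intensities.tsv"))
  write_tsv(met$design, file.path(out_dir, "design.tsv"))
  write_tsv(meas, file.path(out_dir, "measurements.tsv"))
  write_tsv(met$mapping, file.path(out_dir, "exchange_map.tsv"))
  jsonlite::write_json(met$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, wt_calls = wt, ko_calls = ko,
                 metabolomics = met, measurements = meas))
}
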