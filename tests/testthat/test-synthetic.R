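test_that("the toy network carries the canonical redox fixture reactions", {
  m <- build_redox_toy_model()
  sto <- function(r) m$rxns$stoichiometry[[match(r, m$rxns$id)]]
  srt <- function(x) x[sort(names(x))]
  expect_equal(srt(sto("SPODM")),
               srt(c(h_c = -2, o2s_c = -2, o2_c = 1, h2o2_c = 1)))
  expect_equal(srt(sto("SPODMe")),
               srt(c(h_e = -2, o2s_e = -2, h2o2_e = 1, o2_e = 1)))
  expect_equal(srt(sto("SPODMm")),
               srt(c(h_m = -2, o2s_m = -2, o2_m = 1, h2o2_m = 1)))
  expect_equal(srt(sto("SPODMn")),
               srt(c(h_n = -2, o2s_n = -2, h2o2_n = 1, o2_n = 1)))
  expect_equal(srt(sto("SPODMx")),
               srt(c(h_x = -2, o2s_x = -2, o2_x = 1, h2o2_x = 1)))
  expect_equal(srt(sto("ASCBOX")),
               srt(c(h_c = -3, `ascb-L_c` = -1, o2s_c = -2, h2o2_c = 2,
                     dhdascb_c = 1)))
  expect_equal(srt(sto("DASCBR")),
               srt(c(nadph_c = -1, dhdascb_c = -1, nadp_c = 1, `ascb-L_c` = 1)))
  expect_equal(srt(sto("DHAOX")),
               srt(c(dhdascb_c = -1, gthrd_c = -2, h_c = 1, `ascb-L_c` = 1,
                     gthox_c = 1)))
})

test_that("the toy network is balanced, functional and deterministic", {
  m <- build_redox_toy_model()
  bal <- validate_mass_charge_balance(m)
  expect_true(all(bal$balanced[bal$checked]))
  expect_gt(solve_fba(m)$objective_value, 0)
  expect_identical(build_redox_toy_model()$rxns$stoichiometry,
                   m$rxns$stoichiometry)
  # optional glyoxalase fixture arrives intact
  mg <- build_redox_toy_model(include_glyox = TRUE)
  g <- mg$rxns$stoichiometry[[match("GLYOX", mg$rxns$id)]]
  expect_equal(g[sort(names(g))],
               c(`gthrd_c` = 1, h2o_c = -1, h_c = 1, `lac-D_c` = 1,
                 `lgt-S_c` = -1)[sort(names(g))])
})

test_that("disabling the redox branch blocks superoxide export", {
  m <- build_redox_toy_model(ros_branch = FALSE)
  expect_gt(solve_fba(m)$objective_value, 0)
  fva <- run_fva(m, 0, "O2Ste")
  expect_lt(abs(fva$min_flux), 1e-9)
  expect_lt(abs(fva$max_flux), 1e-9)
})

test_that("expression simulation respects dropout and planted absences", {
  m <- build_redox_toy_model()
  cfg <- simulation_config(seed = 5, dropout = 0)
  wt <- simulate_expression(m, cfg, "WT")
  non_planted <- setdiff(rownames(wt$calls), cfg$planted_absent_wt)
  expect_true(all(wt$calls[non_planted, ]))
  # KO plants the urate transporter gene absent
  ko <- simulate_expression(m, cfg, "KO")
  expect_true("urat1" %in% rownames(ko$calls))
  pres <- consensus_presence(ko)
  pen <- compute_penalties(gpr_presence(m, pres))
  if (!pres[["urat1"]]) expect_gt(pen$c[["URAT1"]], 0)
  # determinism
  wt2 <- simulate_expression(m, cfg, "WT")
  expect_identical(wt$calls, wt2$calls)
})

test_that("planted genes go consensus-absent at the binomial rate", {
  # P(>= 2 of 3 absent) at per-replicate absent probability 0.9 is 0.972
  m <- build_redox_toy_model()
  absent <- 0; n_draws <- 500
  for (s in seq_len(n_draws)) {
    cfg <- simulation_config(seed = s)
    wt <- simulate_expression(m, cfg, "WT")
    pres <- consensus_presence(wt)
    absent <- absent + !pres[["sod1_a"]]
  }
  expect_gte(absent / n_draws, 0.95)
  expect_lt(abs(absent / n_draws - 0.972), 0.03)
})

test_that("metabolomics simulation plants the configured fold structure", {
  m <- build_redox_toy_model()
  cfg <- simulation_config(seed = 2)
  met <- simulate_metabolomics(m, cfg)
  expect_equal(sum(met$truth$direction == "up"), 6)
  expect_equal(sum(met$truth$direction == "down"), 2)
  expect_true(all(met$mapping$exchange_id %in% exchange_reactions(m)))
  # a planted 2-fold metabolite lands in the [1.6, 2.5] window at the
  # analytic log-normal rate: the log fold estimate is N(log 2, sigma^2/3),
  # giving P(window) = 2 * pnorm(log(1.25) / (0.25 * sqrt(1/3))) - 1 ~ 0.88
  p_window <- 2 * stats::pnorm(log(1.25) / (0.25 * sqrt(2 / 6))) - 1
  single <- 0; n_runs <- 100
  for (s in seq_len(n_runs)) {
    sim <- simulate_metabolomics(m, simulation_config(seed = 200 + s))
    meas <- compute_fold_changes(sim$intensities, sim$design)
    fc <- meas$fold_change[meas$metabolite_id == "lac-L"]
    single <- single + (fc > 1.6 && fc < 2.5)
  }
  expect_lt(abs(single / n_runs - p_window), 3 * sqrt(p_window * (1 - p_window) / n_runs) + 0.01)
})

test_that("null metabolites trip the 0.05 filter at the nominal rate", {
  m <- build_redox_toy_model()
  fp <- 0; n_runs <- 200
  for (s in seq_len(n_runs)) {
    sim <- simulate_metabolomics(m, simulation_config(seed = 300 + s))
    meas <- compute_fold_changes(sim$intensities, sim$design)
    fp <- fp + (meas$p_value[meas$metabolite_id == "glc-D"] < 0.05)
  }
  expect_lt(abs(fp / n_runs - 0.05), 0.05)
})

test_that("planting the knockout blocks the exchange and frees the redox branch", {
  m <- build_redox_toy_model()
  ko <- plant_knockout(m, "EX_urat_e")
  fva <- run_fva(ko, 0, "EX_urat_e")
  expect_equal(fva$min_flux, 0)
  expect_equal(fva$max_flux, 0)
  expect_warning(plant_knockout(ko, "EX_urat_e"), "already blocked")
  expect_error(plant_knockout(m, "EX_nope"), "unknown reaction")
  # with urate scavenging gone and the dismutases capacity-limited, the
  # ascorbate route becomes obligatory at 90% of optimal ATP in the KO
  fw <- run_fva(m, 0.9, "ASCBOX")
  fk <- run_fva(ko, 0.9, "ASCBOX")
  expect_lt(fw$min_flux, 1e-6)
  expect_gt(fk$min_flux, 1e-6)
})

test_that("simulate_dataset writes a complete readable bundle", {
  out <- withr::local_tempdir()
  res <- simulate_dataset(out, simulation_config(seed = 3))
  files <- c("model.json", "expression_wt.tsv", "expression_ko.tsv",
             "intensities.tsv", "design.tsv", "measurements.tsv",
             "exchange_map.tsv", "truth.json")
  expect_true(all(file.exists(file.path(out, files))))
  m2 <- read_model(file.path(out, "model.json"))
  expect_identical(m2$rxns$id, res$model$rxns$id)
  calls <- read_expression_tsv(file.path(out, "expression_wt.tsv"), "WT")
  expect_identical(calls$calls, res$wt_calls$calls)
  meas <- read_measurements_tsv(file.path(out, "measurements.tsv"))
  expect_equal(nrow(meas), 12)
})
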