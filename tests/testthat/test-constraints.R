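test_that("fold changes are exact geometric-mean ratios with ANOVA p-values", {
  design <- data.frame(condition = rep(c("WT", "KO"), each = 4),
                       batch = rep(c("b1", "b2"), 4))
  wt_vals <- c(100, 120, 90, 110)
  x <- rbind(doubled = c(wt_vals, 2 * wt_vals), flat = c(wt_vals, wt_vals))
  colnames(x) <- paste0("s", 1:8)
  out <- compute_fold_changes(x, design)
  expect_equal(out$fold_change[out$metabolite_id == "doubled"], 2.0,
               tolerance = 1e-12)
  expect_equal(out$fold_change[out$metabolite_id == "flat"], 1.0,
               tolerance = 1e-12)
  # identical groups: zero condition effect, F = 0, p = 1
  expect_equal(out$p_value[out$metabolite_id == "flat"], 1, tolerance = 1e-9)
  expect_error(compute_fold_changes(x * 0, design), "positive")
})

test_that("a planted 2-fold shift is detected with high power (Monte Carlo)", {
  design <- data.frame(condition = rep(c("WT", "KO"), each = 6),
                       batch = rep(rep(c("b1", "b2"), each = 3), 2))
  set.seed(99)
  hits <- 0
  n_sim <- 500
  for (i in seq_len(n_sim)) {
    mu <- log(1000) + (design$condition == "KO") * log(2) +
      (design$batch == "b2") * 0.1
    y <- matrix(exp(mu + rnorm(12, 0, 0.2)), 1, 12,
                dimnames = list("m1", paste0("s", 1:12)))
    hits <- hits + (compute_fold_changes(y, design)$p_value < 0.05)
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("exchanges classify into the three groups plus blocked", {
  m <- build_redox_toy_model()
  cls <- classify_exchanges(m)
  get <- function(r) cls$class[cls$reaction == r]
  expect_identical(get("EX_lac-L_e"), "secretion_only")
  expect_identical(get("EX_glc-D_e"), "uptake_only")
  expect_identical(get("EX_h2o_e"), "bidirectional")
  expect_identical(get("EX_kynu_e"), "blocked")
})

test_that("the four fold-change rules set the canonical bound fractions", {
  m <- build_redox_toy_model()
  cls <- classify_exchanges(m)
  meas <- data.frame(
    metabolite_id = c("lac-L", "pyr", "urtox", "ascb-L", "glc-D", "man"),
    fold_change = c(2.0, 2.0, 0.4, 0.5, 1.0, 2.0),
    p_value = c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 0.5))
  mapping <- data.frame(
    metabolite_id = c("lac-L", "pyr", "urtox", "ascb-L", "glc-D", "man"),
    exchange_id = c("EX_lac-L_e", "EX_pyr_e", "EX_urtox_e", "EX_ascb-L_e",
                    "EX_glc-D_e", "EX_man_e"))
  res <- apply_fold_change_constraints(m, meas, cls, mapping, alpha = 0.05)
  lg <- res$ledger
  row <- function(r) lg[lg$reaction == r, ]
  fva <- function(r, w) cls[[w]][cls$reaction == r]

  expect_identical(row("EX_lac-L_e")$rule, "R1")     # up + secretion-only
  expect_equal(row("EX_lac-L_e")$new_lb, 0.10 * fva("EX_lac-L_e", "fva_max"))
  expect_identical(row("EX_pyr_e")$rule, "R2")       # up + uptake-only
  expect_equal(row("EX_pyr_e")$new_lb, 0.10 * fva("EX_pyr_e", "fva_min"))
  expect_identical(row("EX_urtox_e")$rule, "R3")     # down + secretion-only
  expect_equal(row("EX_urtox_e")$new_ub, 0.10 * fva("EX_urtox_e", "fva_max"))
  expect_identical(row("EX_ascb-L_e")$rule, "R4")    # down + uptake-only
  expect_equal(row("EX_ascb-L_e")$new_ub, 0.90 * fva("EX_ascb-L_e", "fva_min"))
  # fold 1.0 and p >= alpha leave no trace
  expect_false("EX_glc-D_e" %in% lg$reaction)
  expect_false("EX_man_e" %in% lg$reaction)
  # new bounds are live in the model and the model stays feasible
  i <- match("EX_lac-L_e", res$model$rxns$id)
  expect_equal(res$model$rxns$lb[i], 0.10 * fva("EX_lac-L_e", "fva_max"))
  expect_identical(solve_fba(res$model)$status, "optimal")
})

test_that("rules never fire on bidirectional or blocked exchanges", {
  m <- build_redox_toy_model()
  cls <- classify_exchanges(m)
  meas <- data.frame(metabolite_id = c("h2o", "kynu"),
                     fold_change = c(2.0, 0.5), p_value = c(1e-4, 1e-4))
  mapping <- data.frame(metabolite_id = c("h2o", "kynu"),
                        exchange_id = c("EX_h2o_e", "EX_kynu_e"))
  res <- apply_fold_change_constraints(m, meas, cls, mapping)
  expect_true(all(res$ledger$rule == "skipped"))
  expect_identical(res$model$rxns$lb, m$rxns$lb)
  expect_identical(res$model$rxns$ub, m$rxns$ub)
})

test_that("relaxing alpha only appends ledger rows", {
  m <- build_redox_toy_model()
  cls <- classify_exchanges(m)
  meas <- data.frame(metabolite_id = c("lac-L", "pyr", "ascb-L"),
                     fold_change = c(2.0, 1.8, 0.5),
                     p_value = c(0.01, 0.08, 0.001))
  mapping <- data.frame(metabolite_id = c("lac-L", "pyr", "ascb-L"),
                        exchange_id = c("EX_lac-L_e", "EX_pyr_e", "EX_ascb-L_e"))
  strict <- apply_fold_change_constraints(m, meas, cls, mapping, alpha = 0.05)
  relaxed <- apply_fold_change_constraints(m, meas, cls, mapping, alpha = 0.10)
  expect_gte(nrow(relaxed$ledger), nrow(strict$ledger))
  common <- merge(strict$ledger, relaxed$ledger, by = "reaction")
  expect_identical(common$rule.x, common$rule.y)
  expect_identical(common$new_lb.x, common$new_lb.y)
  expect_identical(common$new_ub.x, common$new_ub.y)
})

test_that("identical inputs give byte-identical ledgers", {
  m <- build_redox_toy_model()
  cls <- classify_exchanges(m)
  meas <- data.frame(metabolite_id = c("lac-L", "ascb-L"),
                     fold_change = c(2.0, 0.5), p_value = c(1e-3, 1e-3))
  mapping <- data.frame(metabolite_id = c("lac-L", "ascb-L"),
                        exchange_id = c("EX_lac-L_e", "EX_ascb-L_e"))
  a <- apply_fold_change_constraints(m, meas, cls, mapping)
  b <- apply_fold_change_constraints(m, meas, cls, mapping)
  expect_identical(a$ledger, b$ledger)
})

test_that("reference uptakes and the free ion list are applied", {
  m <- build_redox_toy_model()
  res <- set_reference_exchanges(m, c("glc-D_e", "pyr_e"),
                                 reference_uptake = 0.25)
  i <- match("EX_glc-D_e", res$model$rxns$id)
  expect_equal(res$model$rxns$lb[i], -0.25)
  expect_equal(res$model$rxns$ub[i], m$rxns$ub[i])
  # water is on the free list
  j <- match("EX_h2o_e", res$model$rxns$id)
  expect_equal(res$model$rxns$lb[j], -1000)
  expect_equal(res$model$rxns$ub[j], 1000)
  # empty mapped list: only the ion list is touched
  res2 <- set_reference_exchanges(m, character())
  expect_true(all(res2$ledger$rule == "free_ion"))
  ion_rxns <- res2$ledger$reaction
  expect_setequal(ion_rxns, c("EX_o2_e", "EX_na1_e", "EX_k_e", "EX_fe2_e",
                              "EX_mg2_e", "EX_hco3_e", "EX_h_e", "EX_h2o_e"))
  expect_warning(set_reference_exchanges(m, "nonexistent_e"), "no exchange")
})
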