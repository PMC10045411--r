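make_calls <- function(mat, condition = "WT") expression_calls(mat, condition)

test_that("consensus presence implements the 2-of-3 rule", {
  mat <- rbind(g1 = c(TRUE, TRUE, FALSE),   # P,P,A -> present
               g2 = c(TRUE, FALSE, FALSE),  # P,A,A -> absent
               g3 = c(FALSE, FALSE, FALSE)) # A,A,A -> absent
  colnames(mat) <- paste0("rep", 1:3)
  pres <- consensus_presence(make_calls(mat))
  expect_identical(unname(pres), c(TRUE, FALSE, FALSE))
  expect_error(consensus_presence(make_calls(mat[, 1, drop = FALSE])),
               "replicates")
})

test_that("ortholog mapping follows the any-of rule and reports gaps", {
  tab <- data.frame(source_id = c("gA", "gB1", "gB2"),
                    target_id = c("hA", "hB", "hB"))
  pres <- c(gA = TRUE, gB1 = FALSE, gB2 = TRUE)
  out <- map_orthologs(pres, tab)
  expect_true(out[["hA"]])
  expect_true(out[["hB"]])  # one of two sources present suffices
  out2 <- map_orthologs(c(gA = TRUE, gB1 = FALSE, gB2 = FALSE), tab)
  expect_false(out2[["hB"]])
  expect_warning(map_orthologs(pres, tab[0, ], model_genes = c("hA", "hZ")),
                 "empty ortholog table")
  expect_warning(out3 <- map_orthologs(pres, tab, model_genes = c("hA", "hZ")),
                 "hZ")
  expect_false(out3[["hZ"]])
})

test_that("GPR evaluation uses OR = any, AND = all, empty = no_gpr", {
  mets <- data.frame(id = "A_c")
  rxns <- data.frame(id = c("R1", "R2", "R3"), lb = 0, ub = 1,
                     gpr = c("g1 or g2", "g1 and g2", ""))
  rxns$stoichiometry <- list(c(A_c = 1), c(A_c = 1), c(A_c = -1))
  m <- metabolic_model(mets, rxns, "R3")
  pres <- gpr_presence(m, c(g1 = FALSE, g2 = TRUE))
  expect_identical(unname(pres), c("present", "absent", "no_gpr"))

  m_bad <- m; m_bad$rxns$gpr[1] <- "g1 and (g2"
  expect_error(gpr_presence(m_bad, c(g1 = TRUE, g2 = TRUE)), "R1")
})

test_that("penalties are the positive part of xcutoff - x", {
  pen <- compute_penalties(c(R1 = "present", R2 = "absent", R3 = "no_gpr"))
  expect_equal(unname(pen$c), c(0, 0.5, 0))
  expect_equal(unname(pen$x), c(1, 0, 1))
  expect_equal(pen$xcutoff, 0.5)
  all_p <- compute_penalties(c(R1 = "present", R2 = "no_gpr"))
  expect_true(all(all_p$c == 0))
})

test_that("GIMME prefers free routes and scores forced penalized flux", {
  # parallel A -> B: R1 present, R2 absent; demand met by R1 alone
  m <- parallel_model(10)
  pen <- c(EX_A = 0, R1 = 0, R2 = 0.5, DM_B = 0)
  res <- run_gimme(m, pen, required_fraction = 1)
  expect_equal(res$inconsistency_score, 0, tolerance = 1e-9)
  expect_false("R2" %in% res$active_reactions)
  expect_true(all(c("EX_A", "R1", "DM_B") %in% res$active_reactions))

  # both routes absent and capped at 5: each forced to carry 5
  m2 <- parallel_model(10, cap1 = 5, cap2 = 5)
  pen2 <- c(EX_A = 0, R1 = 0.5, R2 = 0.5, DM_B = 0)
  res2 <- run_gimme(m2, pen2, required_fraction = 1)
  expect_equal(res2$inconsistency_score, 0.5 * (5 + 5), tolerance = 1e-8)
  expect_true(all(c("R1", "R2") %in% res2$active_reactions))

  # no penalties: score 0 and everything active
  res3 <- run_gimme(m, stats::setNames(rep(0, 4), m$rxns$id))
  expect_equal(res3$inconsistency_score, 0)
  expect_identical(sort(res3$active_reactions), sort(m$rxns$id))
})

test_that("GIMME optimum matches the brute-force orthant oracle", {
  n_checked <- 0
  for (s in 41:55) {
    m <- random_network(s)
    set.seed(s + 500)
    cvec <- stats::setNames(rep(0, nrow(m$rxns)), m$rxns$id)
    cvec[sample(nrow(m$rxns), 3)] <- 0.5
    o <- oracle_gimme_score(m, cvec, 0.9)
    if (!is.finite(o)) next
    res <- tryCatch(suppressWarnings(run_gimme(m, cvec, 0.9)),
                    error = function(e) NULL)
    if (is.null(res)) next
    n_checked <- n_checked + 1
    expect_equal(res$inconsistency_score, o, tolerance = 1e-6)
  }
  expect_gte(n_checked, 10)
})

test_that("score is monotone in penalties and required fraction", {
  m <- parallel_model(10, cap1 = 5, cap2 = 5)
  base <- c(EX_A = 0, R1 = 0.5, R2 = 0, DM_B = 0)
  s1 <- run_gimme(m, base, 0.9)$inconsistency_score
  # adding a penalty to a reaction the optimum does not use leaves the score
  with_unused <- base; with_unused[["DM_B"]] <- 0   # DM_B is used; instead
  m3 <- metabolic_model(
    data.frame(id = c("A_c", "B_c", "C_c")),
    {
      r <- data.frame(id = c("EX_A", "R1", "DM_B", "RX"),
                      lb = c(-10, 0, 0, 0), ub = c(0, 1000, 1000, 1000))
      r$stoichiometry <- list(c(A_c = -1), c(A_c = -1, B_c = 1), c(B_c = -1),
                              c(C_c = 1))
      r
    }, "DM_B")
  p0 <- c(EX_A = 0, R1 = 0, DM_B = 0, RX = 0)
  p1 <- c(EX_A = 0, R1 = 0, DM_B = 0, RX = 0.5)
  expect_equal(run_gimme(m3, p0, 0.9)$inconsistency_score,
               run_gimme(m3, p1, 0.9)$inconsistency_score)
  # increasing the required fraction can only increase the score
  scores <- vapply(c(0.25, 0.5, 0.75, 1), function(f)
    run_gimme(m, base, f)$inconsistency_score, numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
  expect_gt(scores[4], s1 - 1e-9)
})

test_that("the active subnetwork retains the required objective fraction", {
  model <- build_redox_toy_model()
  pres <- stats::setNames(!(model$genes %in% rgem:::TOY_REDOX_GENES),
                          model$genes)
  pen <- compute_penalties(gpr_presence(model, pres))
  res <- run_gimme(model, pen, 0.9)
  sub <- model
  off <- setdiff(sub$rxns$id, res$active_reactions)
  sub$rxns$lb[sub$rxns$id %in% off] <- 0
  sub$rxns$ub[sub$rxns$id %in% off] <- 0
  f <- solve_fba(sub)
  expect_identical(f$status, "optimal")
  expect_gte(f$objective_value, 0.9 * res$objective_optimum - 1e-6)
})

test_that("zero score exactly when a penalty-free feasible flux exists", {
  m <- parallel_model(10, cap1 = 5, cap2 = 5)
  # free route capacity (5) insufficient for demand 10 at fraction 1
  pen <- c(EX_A = 0, R1 = 0, R2 = 0.5, DM_B = 0)
  expect_gt(run_gimme(m, pen, 1)$inconsistency_score, 0)
  # at fraction 0.5 the free route alone suffices
  expect_equal(run_gimme(m, pen, 0.5)$inconsistency_score, 0, tolerance = 1e-9)
})

test_that("GIMME results export as JSON plus flux TSV", {
  m <- parallel_model(10)
  res <- run_gimme(m, c(EX_A = 0, R1 = 0, R2 = 0.5, DM_B = 0), 1)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_gimme_result(res, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$inconsistency_score, res$inconsistency_score)
  expect_setequal(back$active_reactions, res$active_reactions)
  fl <- read.delim(tp)
  expect_equal(fl$flux[fl$reaction == "DM_B"],
               unname(res$flux_solution$fluxes["DM_B"]), tolerance = 1e-9)
})
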