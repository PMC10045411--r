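test_that("stoichiometric matrix reproduces reaction definitions", {
  mets <- data.frame(id = c("A_c", "B_c"))
  rxns <- data.frame(id = c("R1", "R2"), lb = 0, ub = 10)
  rxns$stoichiometry <- list(c(A_c = -1, B_c = 1), c(B_c = -1))
  m <- metabolic_model(mets, rxns, "R2")
  S <- as.matrix(build_stoichiometric_matrix(m))
  expect_equal(unname(S), rbind(c(-1, 0), c(1, -1)))
  expect_identical(rownames(S), c("A_c", "B_c"))
  expect_identical(colnames(S), c("R1", "R2"))
})

test_that("matrix build is faithful on random networks (reconstruction oracle)", {
  for (s in 1:100) {
    m <- random_network(s, n_rxns = sample(4:8, 1))
    S <- build_stoichiometric_matrix(m)
    for (j in seq_len(nrow(m$rxns))) {
      col <- S[, j]
      rebuilt <- col[col != 0]
      orig <- m$rxns$stoichiometry[[j]]
      expect_equal(rebuilt[sort(names(rebuilt))], orig[sort(names(orig))])
    }
  }
})

test_that("duplicate ids and unknown metabolite references are rejected", {
  mets <- data.frame(id = c("A_c", "A_c"))
  rxns <- data.frame(id = "R1", lb = 0, ub = 1)
  rxns$stoichiometry <- list(c(A_c = 1))
  expect_error(metabolic_model(mets, rxns, "R1"), "duplicate metabolite")
  mets2 <- data.frame(id = "A_c")
  rxns2 <- data.frame(id = "R1", lb = 0, ub = 1)
  rxns2$stoichiometry <- list(c(x_c = 1))
  expect_error(metabolic_model(mets2, rxns2, "R1"), "x_c")
})

test_that("binarize erases sign and magnitude and is idempotent", {
  S <- Matrix::Matrix(rbind(c(-1, 0), c(2, -1)), sparse = TRUE)
  B <- binarize(S)
  expect_equal(unname(as.matrix(B)), rbind(c(1, 0), c(1, 1)))
  expect_equal(as.matrix(binarize(B)), as.matrix(B))
  Z <- Matrix::Matrix(0, 3, 2, sparse = TRUE)
  expect_equal(sum(binarize(Z)), 0)
  set.seed(42)
  for (i in 1:20) {
    M <- Matrix::rsparsematrix(15, 10, density = 0.2)
    expect_equal(sum(binarize(M)), sum(abs(as.matrix(M)) > 1e-12))
  }
})

test_that("compartments derive from id suffixes", {
  expect_identical(compartment_of(c("o2s_c", "h2o2_m", "ascb-L_c", "q10h2_m")),
                   c("c", "m", "c", "m"))
  expect_identical(strip_compartment(c("o2s_c", "ascb-L_e")), c("o2s", "ascb-L"))
})

test_that("JSON round-trip is the identity on model content", {
  m <- build_redox_toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$mets$id, m$mets$id)
  expect_identical(m2$rxns$id, m$rxns$id)
  expect_identical(m2$rxns$stoichiometry, m$rxns$stoichiometry)
  expect_identical(m2$rxns$lb, m$rxns$lb)
  expect_identical(m2$rxns$ub, m$rxns$ub)
  expect_identical(m2$rxns$gpr, m$rxns$gpr)
  expect_identical(m2$rxns$subsystem, m$rxns$subsystem)
  expect_identical(m2$objective, m$objective)
})

test_that("SBML round-trip preserves ids, bounds, GPR semantics and subsystems", {
  m <- build_redox_toy_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$mets$id, m$mets$id)
  expect_identical(m2$mets$charge, m$mets$charge)
  expect_identical(m2$mets$formula, m$mets$formula)
  expect_identical(m2$rxns$id, m$rxns$id)
  expect_identical(m2$rxns$stoichiometry, m$rxns$stoichiometry)
  expect_identical(m2$rxns$lb, m$rxns$lb)
  expect_identical(m2$rxns$ub, m$rxns$ub)
  expect_identical(m2$rxns$subsystem, m$rxns$subsystem)
  expect_identical(m2$objective, m$objective)
  # GPR semantics survive (textual form may gain parentheses)
  for (i in seq_len(nrow(m$rxns))) {
    g1 <- parse_gpr(m$rxns$gpr[i]); g2 <- parse_gpr(m2$rxns$gpr[i])
    expect_identical(sort(gpr_genes(g1)), sort(gpr_genes(g2)))
  }
})

test_that("malformed model files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(id = "bad",
              metabolites = list(list(id = "A_c")),
              reactions = list(list(id = "R1", metabolites = list(x_c = 1),
                                    lower_bound = 0, upper_bound = 1,
                                    objective_coefficient = 1)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path), "x_c")

  doc$reactions[[1]]$metabolites <- list(A_c = 1)
  doc$reactions[[1]]$lower_bound <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path), "lower_bound")

  # SBML without an fbc objective
  m <- chain_model()
  xpath <- withr::local_tempfile(fileext = ".xml")
  write_model(m, xpath)
  doc2 <- xml2::read_xml(xpath)
  obj <- xml2::xml_find_first(doc2, ".//fbc:listOfObjectives", xml2::xml_ns(doc2))
  xml2::xml_remove(obj)
  xml2::write_xml(doc2, xpath)
  expect_error(read_model(xpath), "objective")
})

test_that("superoxide dismutase fixture is mass and charge balanced", {
  m <- build_redox_toy_model()
  bal <- validate_mass_charge_balance(m)
  spodm <- bal[bal$reaction == "SPODM", ]
  expect_true(spodm$checked)
  expect_true(spodm$balanced)
  expect_equal(spodm$mass_residual, 0)
  expect_equal(spodm$charge_residual, 0)
  # every checked internal reaction of the toy network balances
  expect_true(all(bal$balanced[bal$checked]))
})

test_that("formula perturbations and autocatalytic reactions are flagged", {
  mets <- data.frame(id = c("nadph_c", "dhdascb_c", "nadp_c", "ascb-L_c"),
                     formula = c("C21H26N7O17P3", "C6H6O6", "C21H25N7O17P3",
                                 "C6H7O6"),
                     charge = c(-4, 0, -3, -1))
  rxns <- data.frame(id = "DASCBR", lb = 0, ub = 10)
  rxns$stoichiometry <- list(c(nadph_c = -1, dhdascb_c = -1, nadp_c = 1,
                               `ascb-L_c` = 1))
  m <- metabolic_model(mets, rxns, "DASCBR")
  expect_true(validate_mass_charge_balance(m)$balanced[1])
  # disagreeing formula -> flagged
  mets$formula[2] <- "C6H8O6"
  m2 <- metabolic_model(mets, rxns, "DASCBR")
  expect_false(validate_mass_charge_balance(m2)$balanced[1])

  mets3 <- data.frame(id = c("A_c", "B_c"), formula = c("C1", "C1"),
                      charge = c(0, 0))
  rxns3 <- data.frame(id = c("R", "DM_B"), lb = 0, ub = 10)
  rxns3$stoichiometry <- list(c(A_c = -1, B_c = 2), c(B_c = -1))
  m3 <- metabolic_model(mets3, rxns3, "DM_B")
  bal3 <- validate_mass_charge_balance(m3)
  expect_false(bal3$balanced[bal3$reaction == "R"])
  # the demand (boundary) reaction is exempt
  expect_false(bal3$checked[bal3$reaction == "DM_B"])
})

test_that("reaction equation parser handles arrows, coefficients and merging", {
  pe <- parse_reaction_equation("2 h_c + 2 o2s_c -> o2_c + h2o2_c")
  expect_false(pe$reversible)
  expect_equal(pe$stoichiometry,
               c(h_c = -2, o2s_c = -2, o2_c = 1, h2o2_c = 1))
  expect_true(parse_reaction_equation("A_c <=> B_c")$reversible)
  expect_equal(parse_reaction_equation("lac-L_e ->")$stoichiometry,
               c(`lac-L_e` = -1))
  expect_equal(parse_reaction_equation("A_c -> 2 A_c")$stoichiometry,
               c(A_c = 1))
})
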