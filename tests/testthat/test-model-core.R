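test_that("model construction validates ids, compartments and bounds", {
  m <- make_chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_length(m$reactions, 3)
  expect_equal(nrow(m$metabolites), 2)

  bad_met <- data.frame(id = c("A", "A"), name = "A", compartment = "c",
                        stringsAsFactors = FALSE)
  expect_error(
    new_model("dup", c(c = "c"), bad_met,
              list(new_reaction("r", c(A = 1))), objective = "r"),
    "duplicate metabolite")
  expect_error(
    new_model("badref", c(c = "c"),
              data.frame(id = "A", name = "A", compartment = "c"),
              list(new_reaction("r", c(A = -1, missing_met = 1))),
              objective = "r"),
    "unknown metabolite.*missing_met")
  expect_error(new_reaction("r", c(A = -1), lb = 5, ub = 1), "lb <= ub")
})

test_that("JSON round trip reproduces the model exactly", {
  m <- make_toy_network("glucose")
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f, "json")
  m2 <- load_model(f, "json")
  expect_equal(m2$reactions, m$reactions, tolerance = 1e-12)
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$enzymes, m$enzymes)
  expect_equal(m2$objective, m$objective)
  # second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(m2, f2, "json")
  expect_identical(readLines(f)[-(1:3)], readLines(f2)[-(1:3)])
  # forced error: stoich referencing a missing metabolite
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc$reactions[[10]]$stoich[["ghost_met"]] <- 1
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f3, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f3, "json"), "ghost_met")
})

test_that("SBML export agrees with JSON export on the S matrix", {
  m <- make_toy_network("xylose")
  fx <- withr::local_tempfile(fileext = ".xml")
  fj <- withr::local_tempfile(fileext = ".json")
  write_model(m, fx, "sbml")
  write_model(m, fj, "json")
  ms <- load_model(fx, "sbml")
  mj <- load_model(fj, "json")
  S <- stoich_matrix(m)
  expect_equal(stoich_matrix(ms)[rownames(S), colnames(S)], S)
  expect_equal(stoich_matrix(mj)[rownames(S), colnames(S)], S)
  # bounds and gene rules survive SBML
  expect_equal(ms$reactions$EX_xyl$lb, m$reactions$EX_xyl$lb)
  expect_equal(ms$reactions$PDH$gene_rule, m$reactions$PDH$gene_rule)
})

test_that("FBA solves the forced-yield chain and reports infeasibility", {
  m <- make_chain_model(uptake = 10, yield = 0.5)
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5.0, tolerance = 1e-9)
  expect_steady_state(m, sol$flux)

  # biomass requiring a metabolite with no producer
  mets <- data.frame(id = c("A", "X"), name = c("A", "X"),
                     compartment = "c", stringsAsFactors = FALSE)
  m2 <- new_model("orphan", c(c = "c"), mets, list(
    new_reaction("EX_A", c(A = -1), lb = -10, ub = 0),
    new_reaction("GROW", c(A = -1, X = -1), lb = 1)), objective = "GROW")
  expect_equal(fba(m2)$status, "infeasible")
})

test_that("FBA matches the vertex-enumeration reference on random models", {
  n_checked <- 0
  for (seed in 1:25) {
    m <- make_random_toy_model(seed, n_mets = 4, n_rxns = 10)
    sol <- fba(m)
    ref <- fba_enumerate(m)
    expect_equal(sol$status, ref$status, info = paste("seed", seed))
    if (sol$status == "optimal") {
      expect_equal(sol$objective_value, ref$objective_value,
                   tolerance = 1e-6, info = paste("seed", seed))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("optimal fluxes satisfy steady state and bounds", {
  for (v in c("glucose", "xylose", "acetate")) {
    m <- make_toy_network(v)
    sol <- fba(m)
    expect_equal(sol$status, "optimal")
    expect_gt(sol$objective_value, 0)
    expect_steady_state(m, sol$flux)
    lb <- vapply(m$reactions, `[[`, 0, "lb")
    ub <- vapply(m$reactions, `[[`, 0, "ub")
    expect_true(all(sol$flux >= lb - 1e-9 & sol$flux <= ub + 1e-9))
  }
})

test_that("add_pathway extends a model and can only relax the optimum", {
  m <- make_toy_network("xylose", include_dad_bypass = FALSE)
  m$reactions$XK$ub <- 0  # no xylulokinase: no growth without the bypass
  expect_equal(fba(m)$objective_value, 0, tolerance = 1e-9)
  before <- fba(make_toy_network("xylose",
                                 include_dad_bypass = FALSE))$objective_value
  new_mets <- data.frame(id = c("abt_c", "rbl_c"),
                         name = c("D-arabinitol", "D-ribulose"),
                         compartment = "c", stringsAsFactors = FALSE)
  new_rxns <- list(
    new_reaction("DAD4", c(xlu_c = -1, nadh_c = -1, abt_c = 1, nad_c = 1),
                 lb = 0),
    new_reaction("DAD2", c(abt_c = -1, nadp_c = -1, rbl_c = 1, nadph_c = 1),
                 lb = 0),
    new_reaction("RK", c(rbl_c = -1, atp_c = -1, ru5p_c = 1, adp_c = 1),
                 lb = 0))
  m2 <- add_pathway(m, new_mets, new_rxns)
  expect_equal(nrow(m2$metabolites), nrow(m$metabolites) + 2)
  expect_length(m2$reactions, length(m$reactions) + 3)
  expect_gt(fba(m2)$objective_value, 0)   # bypass rescues growth
  # LP monotonicity: adding options cannot reduce the optimum
  m3 <- add_pathway(make_toy_network("xylose", include_dad_bypass = FALSE),
                    new_mets, new_rxns)
  expect_gte(fba(m3)$objective_value, before - 1e-9)
  # collisions are refused
  expect_error(add_pathway(m2, new_rxns = list(new_reaction(
    "DAD4", c(xlu_c = -1, abt_c = 1), lb = 0))), "already present")
})

test_that("unbalanced reactions are flagged when formulas are available", {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c",
                     formula = c("C6H12O6", "C3H6O3"),
                     charge = NA_real_, stringsAsFactors = FALSE)
  m <- new_model("bal", c(c = "c"), mets,
                 list(new_reaction("EX_A", c(A = -1), lb = -10, ub = 0)),
                 objective = "EX_A")
  expect_warning(add_pathway(m, new_rxns = list(
    new_reaction("r2", c(A = -1, B = 1), lb = 0))), "unbalanced")
  expect_silent(add_pathway(m, new_rxns = list(
    new_reaction("r3", c(A = -1, B = 2), lb = 0))))
})

test_that("scenario toggles edit the expected reactions", {
  m <- make_toy_network("glucose")
  expect_identical(apply_scenario(m, "none"), m)

  mb <- apply_scenario(m, "block_xpk")
  expect_equal(mb$reactions$XPK$lb, 0)
  expect_equal(mb$reactions$XPK$ub, 0)
  expect_gt(fba(mb)$objective_value, 0)  # alternative routes carry flux

  ms <- apply_scenario(m, "swap_pta_to_ack")
  expect_null(ms$reactions$PTA)
  expect_false(is.null(ms$reactions$ACK))
  expect_gt(fba(ms)$objective_value, 0)

  mx <- make_toy_network("xylose")
  md <- apply_scenario(mx, "dad2_nad_cofactor")
  st <- md$reactions$DAD2$stoich
  expect_false("nadph_c" %in% names(st))
  expect_equal(st[["nadh_c"]], mx$reactions$DAD2$stoich[["nadph_c"]])
  expect_equal(st[["nad_c"]], mx$reactions$DAD2$stoich[["nadp_c"]])
  expect_gt(fba(md)$objective_value, 0)

  expect_error(apply_scenario(make_chain_model(), "block_xpk"),
               "not in model")
})

test_that("formula parsing and medium C/N arithmetic are exact", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("N2H8SO4"), c(H = 8, N = 2, O = 4, S = 1))
  expect_equal(formula_mass("C5H10O5"), 150.13, tolerance = 1e-4)
  expect_error(parse_formula("not a formula"), "cannot parse")
  expect_error(medium_cn_ratio(c(10), "C6H12O6"), "no nitrogen")
})
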