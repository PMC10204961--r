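test_that("all toy variants support growth with sound structure", {
  for (v in c("glucose", "xylose", "acetate")) {
    m <- make_toy_network(v)
    expect_gte(length(m$reactions), 40)
    expect_lte(length(m$reactions), 70)
    sol <- fba(m)
    expect_equal(sol$status, "optimal")
    expect_gt(sol$objective_value, 0)
    # every internal metabolite has at least one producer and one consumer
    S <- stoich_matrix(m)
    internal <- setdiff(rownames(S),
                        unlist(lapply(m$reactions[is_exchange(m)],
                                      function(r) names(r$stoich))))
    for (met in internal) {
      row <- S[met, ]
      has_rev <- vapply(m$reactions[names(row)[row != 0]],
                        function(r) r$lb < 0, NA)
      expect_true(any(row > 0) || any(row < 0 & has_rev),
                  info = paste(v, met, "producer"))
      expect_true(any(row < 0) || any(row > 0 & has_rev),
                  info = paste(v, met, "consumer"))
    }
  }
})

test_that("the xylose bypass rescues growth when xylulokinase is blocked", {
  mx <- make_toy_network("xylose")
  mx$reactions$XK$lb <- 0
  mx$reactions$XK$ub <- 0
  expect_gt(fba(mx)$objective_value, 0)
  m0 <- make_toy_network("xylose", include_dad_bypass = FALSE)
  m0$reactions$XK$lb <- 0
  m0$reactions$XK$ub <- 0
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-9)
})

test_that("zero-CV condition simulation reproduces the ground truth rates", {
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", rate_cv = 0, seed = 14)
  expect_equal(sim$physiology$mu, sim$truth$mu, tolerance = 1e-12)
  expect_equal(sim$physiology$uptake[["EX_glc"]], sim$truth$rates$uptake,
               tolerance = 1e-12)
  expect_equal(sim$physiology$co2, sim$truth$rates$co2, tolerance = 1e-12)
  # truth fluxes satisfy steady state on the EC model
  expect_steady_state(sim$truth$ec_model, sim$truth$flux)
  # truth enzyme usages satisfy the capacity constraint with the true kcats
  asg <- sim$truth$ec_model$kcat_assignment
  for (rid in unique(asg$reaction)) {
    rows <- asg[asg$reaction == rid, ]
    cap <- sum(rows$kcat * 3600 *
                 vapply(rows$enzyme, function(e)
                   sim$truth$flux[[paste0("draw_", e)]], 0))
    expect_lte(sim$truth$flux[[rid]], cap + 1e-6)
  }
})

test_that("nitrogen limitation lowers protein and raises lipid in the plant", {
  m <- make_toy_network("glucose")
  exp_sim <- simulate_condition(m, "exp", seed = 1)
  nlim <- simulate_condition(m, "Nlim", seed = 1)
  expect_lt(nlim$truth$composition$protein, exp_sim$truth$composition$protein)
  expect_gt(nlim$truth$composition$lipid, exp_sim$truth$composition$lipid)
  expect_lt(nlim$truth$mu, exp_sim$truth$mu)
})

test_that("carbon bookkeeping of emitted rates closes", {
  # carbon in (glucose, 6 C) vs carbon out (CO2 + biomass components);
  # biomass carbon is bounded by its composition, so check the C balance
  # through the exchange fluxes plus the biomass carbon estimate
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", rate_cv = 0, seed = 2)
  net <- sim$truth$net_flux
  c_in <- 6 * abs(net[["EX_glc"]])
  c_co2 <- net[["EX_co2"]]
  mu <- sim$truth$mu
  # biomass carbon content: protein ~ glutamate-derived (5 C per 110 g/mol
  # residue -> 45.5 mmol C/g), carb glucan (37 mmol C/g), lipid ~ 72 mmol C/g
  comp <- sim$truth$composition
  c_bio <- mu * (comp$protein * 9.09 * 5 + (1 - comp$protein - comp$lipid) *
                   6.17 * 6 + comp$lipid * 72 * 0.9)
  other <- net[["EX_ac"]] * 2
  expect_equal((c_co2 + c_bio + other) / c_in, 1, tolerance = 0.15)
})

test_that("proteomics simulation recovers concentrations within noise", {
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", seed = 17)
  pr <- simulate_proteomics(sim$truth, cv = 0.1, n_replicates = 2,
                            seed = 17)
  s <- tpa_quantify(pr$records, Ptot = sim$truth$composition$protein)
  truth <- pr$true_conc[s$conc$protein_id]
  rel <- abs(s$conc$conc_ug_per_g - truth) / truth
  # 2 replicates at CV 0.1: nearly all proteins within 3 CV of truth
  expect_gte(mean(rel < 0.3), 0.99)
  # identical seed gives an identical record stream
  pr2 <- simulate_proteomics(sim$truth, cv = 0.1, n_replicates = 2,
                             seed = 17)
  expect_identical(pr$records, pr2$records)
  # planted f-factor is recovered from the quantification
  expect_equal(compute_f_factor(s, m), pr$f_true, tolerance = 0.05)
})

test_that("bundles round-trip through the filesystem", {
  out <- withr::local_tempdir()
  paths <- simulate_bundle(out, "glucose", "exp", seed = 3)
  expect_true(all(file.exists(unlist(paths))))
  m <- load_model(paths$model, "json")
  expect_equal(fba(m)$status, "optimal")
  phys <- read_physiology(paths$physiology)
  expect_gt(phys$mu, 0)
  db <- read_kcat_db(paths$kcats)
  expect_true(all(db$kcat_per_s > 0))
  rec <- read_ms_records(paths$proteomics)
  expect_gt(nrow(rec), 0)
})

test_that("the synthetic kcat database exercises every relaxation level", {
  m <- make_toy_network("xylose")
  db <- make_toy_kcat_db(m, seed = 1)
  irr <- expand_isozymes(split_reversible(m))
  kc <- suppressMessages(match_kcats(irr, db, TOY_ORGANISM))
  lv <- kc$assignment$level
  expect_true(all(c(1, 2, 3, 4) %in% lv))
  # matched kcats at the strictest level are at least the planted truth
  # (enzymes sharing an EC number aggregate by the within-level maximum)
  truth <- ecfluxr:::toy_true_kcats()
  lvl1 <- kc$assignment[kc$assignment$level == 1, ]
  expect_true(all(lvl1$kcat >= unname(truth[lvl1$enzyme]) - 1e-12))
  ec_tab <- table(m$enzymes$ec)
  unique_ec <- m$enzymes$id[m$enzymes$ec %in% names(ec_tab)[ec_tab == 1]]
  sel <- lvl1$enzyme %in% unique_ec
  expect_equal(lvl1$kcat[sel], unname(truth[lvl1$enzyme[sel]]),
               tolerance = 1e-12)
})
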