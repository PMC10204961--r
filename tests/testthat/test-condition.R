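make_constrained_toy <- function(seed = 11, cv = 0) {
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", seed = seed)
  pr <- simulate_proteomics(sim$truth, cv = cv, seed = seed)
  s <- tpa_quantify(pr$records, Ptot = sim$truth$composition$protein)
  list(model = m, sim = sim, pr = pr, sample = s)
}

test_that("f-factor is the model-enzyme mass share, before filtering", {
  x <- make_constrained_toy()
  f <- compute_f_factor(x$sample, x$model)
  expect_equal(f, x$pr$f_true, tolerance = 1e-9)
  # all-enzyme proteome gives f = 1
  rec <- make_ms_records(c(E_HXK = 6e5, E_PGI = 4e5))
  expect_equal(compute_f_factor(tpa_quantify(rec), x$model), 1)
  # a 25% enzyme mass share gives f = 0.25
  rec2 <- make_ms_records(c(E_HXK = 2.5e5, OTH1 = 7.5e5))
  expect_equal(compute_f_factor(tpa_quantify(rec2), x$model), 0.25)
  # f is computed before any SD-based record filtering: adding a noisy
  # enzyme duplicate changes nothing about the mean-based mass share
  noisy <- make_ms_records(c(E_HXK = 2.5e5, OTH1 = 7.5e5), replicates = 2,
                           noise = list(c(0.02, 1.327), c(1.98, 0.673)))
  f3 <- compute_f_factor(tpa_quantify(noisy), x$model)
  expect_equal(f3, 0.25, tolerance = 0.05)
})

test_that("constrain_enzymes enforces the direct-subtraction mass identity", {
  x <- make_constrained_toy()
  sigma <- 0.35
  f <- compute_f_factor(x$sample, x$model)
  irr <- expand_isozymes(split_reversible(x$model))
  kc <- suppressMessages(match_kcats(irr, make_toy_kcat_db(x$model, 1),
                                     TOY_ORGANISM))
  Ptot <- x$sim$truth$composition$protein
  ec <- build_ec_model(irr, kc, sigma = sigma, f = f, Ptot = Ptot)
  molar <- to_molar(x$sample)
  # keep a small measured subset so the budget is respected
  mw <- setNames(ec$enzymes$mw, ec$enzymes$id)
  cand <- intersect(names(molar), ec$annotations$ec$enzymes)
  mass <- molar[cand] * mw[cand]
  keep <- cand[order(mass)][seq_len(10)]
  ec2 <- constrain_enzymes(ec, molar[keep], Ptot = Ptot, Ptot_sd = 0,
                           sigma = sigma, f = f)
  enzyme_conc <- sigma * f * Ptot
  measured <- ec2$annotations$ec$measured
  p_meas <- sum(vapply(measured, function(e)
    ec2$reactions[[paste0("draw_", e)]]$ub * mw[[e]], 0))
  expect_equal(p_meas + pool_upper_bound(ec2), enzyme_conc,
               tolerance = 1e-12)
  # measured usage reactions no longer draw from the pool
  for (e in measured) {
    expect_false("prot_pool" %in%
                   names(ec2$reactions[[paste0("draw_", e)]]$stoich))
  }
  # spec example: enzymeConc 0.20, Pmeasured 0.05 -> pool 0.15
  molar_one <- setNames(0.05 / mw[["E_HXK"]], "E_HXK")
  ec3 <- constrain_enzymes(ec, molar_one, Ptot = 0.20 / (sigma * f),
                           sigma = sigma, f = f)
  expect_equal(pool_upper_bound(ec3), 0.15, tolerance = 1e-9)
  # measured mass beyond the enzyme budget is refused with guidance
  molar_huge <- setNames(10 / mw[["E_HXK"]], "E_HXK")
  expect_error(constrain_enzymes(ec, molar_huge, Ptot = Ptot,
                                 sigma = sigma, f = f),
               "rescale Ptot or increase sigma")
  # no measured enzymes reduces to the plain pool model
  ec4 <- constrain_enzymes(ec, setNames(numeric(0), character(0)),
                           Ptot = Ptot, sigma = sigma, f = f)
  expect_equal(pool_upper_bound(ec4), enzyme_conc, tolerance = 1e-12)
})

test_that("Ptot rescaling adds the assay SD before the budget is computed", {
  x <- make_constrained_toy()
  f <- 0.3
  irr <- expand_isozymes(split_reversible(x$model))
  kc <- suppressMessages(match_kcats(irr, make_toy_kcat_db(x$model, 1),
                                     TOY_ORGANISM))
  ec <- build_ec_model(irr, kc, sigma = 0.35, f = f, Ptot = 0.4)
  ec2 <- constrain_enzymes(ec, setNames(numeric(0), character(0)),
                           Ptot = 0.4, Ptot_sd = 0.05, sigma = 0.35, f = f)
  expect_equal(pool_upper_bound(ec2), 0.35 * f * 0.45, tolerance = 1e-12)
})

test_that("flexibilization relaxes exactly the planted limiting enzyme", {
  ec <- make_one_enzyme_ec(kcat = 10, E = 1e-5)  # vmax 0.36
  # register E1 as a measured enzyme with an SD that lifts vmax to 0.54
  ec$annotations$ec$measured <- "E1"
  ec$annotations$ec$measured_conc <- c(E1 = 1e-5)
  ec$annotations$ec$measured_sd <- c(E1 = 5e-6)
  res <- flexibilize(ec, target_mu = 0.5)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$enzyme, "E1")
  expect_equal(res$records$action, "raise_to_sd")
  expect_equal(res$achieved, 0.54, tolerance = 1e-9)
  # minimal-greedy: undoing the relaxation makes the target infeasible
  ec_undo <- res$model
  ec_undo$reactions$draw_E1$ub <- res$records$old_bound
  expect_lt(fba(ec_undo)$objective_value, 0.5)
  # an already-feasible target returns no records
  res2 <- flexibilize(ec, target_mu = 0.3)
  expect_equal(nrow(res2$records), 0)
  # an unreachable target reports the gap after releasing everything
  res3 <- flexibilize(ec, target_mu = 1e6)
  expect_gt(res3$gap, 0)
})

test_that("released enzymes return their mass to the pool", {
  ec <- make_one_enzyme_ec(kcat = 10, E = 1e-5, mw = 50)
  ec$annotations$ec$measured <- "E1"
  ec$annotations$ec$measured_conc <- c(E1 = 1e-5)
  ec$annotations$ec$measured_sd <- c(E1 = 0)
  pool0 <- pool_upper_bound(ec)
  res <- flexibilize(ec, target_mu = 1)  # forces full release
  rel <- res$records[res$records$action == "release_to_pool", ]
  expect_equal(nrow(rel), 1)
  expect_equal(pool_upper_bound(res$model), pool0 + 1e-5 * 50,
               tolerance = 1e-12)
  expect_length(res$model$annotations$ec$measured, 0)
})

test_that("exchange windows apply the per-quantity tolerances", {
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", seed = 4)
  ec <- sim$truth$ec_model
  phys <- sim$physiology
  ec2 <- set_exchange_windows(ec, phys)
  u <- phys$uptake[["EX_glc"]]
  expect_equal(ec2$reactions$EX_glc_REV$lb, u * 0.99, tolerance = 1e-12)
  expect_equal(ec2$reactions$EX_glc_REV$ub, u * 1.01, tolerance = 1e-12)
  expect_equal(ec2$reactions$BIOMASS$lb, phys$mu * 0.99, tolerance = 1e-12)
  expect_equal(ec2$reactions$EX_co2$ub, phys$co2 * 1.10, tolerance = 1e-12)
  expect_equal(ec2$reactions$EX_o2_REV$lb, phys$o2 * 0.90,
               tolerance = 1e-12)
  expect_equal(ec2$reactions$NGAM$lb, phys$ngam * 0.99, tolerance = 1e-12)
  pool <- pool_upper_bound(ec)
  expect_equal(ec2$reactions$prot_pool_exchange$lb, pool * 0.9,
               tolerance = 1e-12)
  expect_equal(ec2$reactions$prot_pool_exchange$ub, pool * 1.1,
               tolerance = 1e-12)
  # windows never cross zero for strictly positive rates
  expect_gte(ec2$reactions$EX_glc_REV$lb, 0)
  # the windowed model stays solvable
  expect_equal(fba(ec2)$status, "optimal")
  # missing required exchange errors
  phys_bad <- phys
  phys_bad$byproducts <- c(EX_ghost = 1)
  expect_error(set_exchange_windows(ec, phys_bad), "EX_ghost")
})

test_that("unmeasured gas rates are filled from simulated values", {
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", seed = 4)
  phys <- sim$physiology
  phys$co2 <- NULL
  phys$o2 <- NULL
  ec2 <- set_exchange_windows(sim$truth$ec_model, phys)
  expect_gt(ec2$reactions$EX_co2$ub, 0)
  expect_gt(ec2$reactions$EX_o2_REV$ub, 0)
  expect_equal(fba(ec2)$status, "optimal")
})
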