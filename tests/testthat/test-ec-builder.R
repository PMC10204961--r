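test_that("split_reversible produces forward/reverse pairs with kept map", {
  m <- make_toy_network("glucose")
  n_rev <- sum(vapply(m$reactions, function(r) r$lb < 0 & r$ub > 0, NA))
  irr <- split_reversible(m)
  expect_true(all(vapply(irr$reactions, `[[`, 0, "lb") >= 0))
  expect_length(irr$reactions, length(m$reactions) + n_rev)
  # a reversible interior reaction gets bounds (0, ub) on both copies
  expect_equal(irr$reactions$PGI$lb, 0)
  expect_equal(irr$reactions$PGI_REV$ub, -m$reactions$PGI$lb)
  expect_equal(irr$reactions$PGI_REV$stoich, -m$reactions$PGI$stoich)
  # an already-irreversible model passes through unchanged in count
  irr2 <- split_reversible(irr)
  expect_length(irr2$reactions, length(irr$reactions))
  # FBA optimum is invariant under splitting
  expect_equal(fba(irr)$objective_value, fba(m)$objective_value,
               tolerance = 1e-8)
})

test_that("expand_isozymes adds arm reactions whose flux equals the copies", {
  m <- split_reversible(make_toy_network("glucose"))
  n_multi <- sum(vapply(m$reactions, function(r) length(r$gene_rule) >= 2,
                        NA))
  expect_gt(n_multi, 0)
  ex <- expand_isozymes(m)
  expect_true("arm_NONOX" %in% names(ex$reactions))
  expect_true(all(c("NONOX_iso1", "NONOX_iso2") %in% names(ex$reactions)))
  expect_false("NONOX" %in% names(ex$reactions))
  expect_true("armm_NONOX" %in% ex$metabolites$id)
  # single-isozyme reactions untouched
  expect_equal(ex$reactions$HXK, m$reactions$HXK)
  # arm flux equals sum of the copies in an optimal solution
  sol <- fba(ex)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$flux[["arm_NONOX"]],
               sol$flux[["NONOX_iso1"]] + sol$flux[["NONOX_iso2"]],
               tolerance = 1e-8)
  expect_error(expand_isozymes(make_toy_network("glucose")),
               "irreversible")
})

test_that("kcat matching honours the relaxation-level ordering", {
  db <- data.frame(
    ec_number = c("1.1.1.1", "1.1.1.1", "1.1.1.1", "1.1.1.1", "2.2.2.2"),
    substrate = c("substrate a", "substrate a", "other", "other", "x"),
    organism = c("My organism", "Other organism", "My organism", "Third",
                 "My organism"),
    kcat_per_s = c(50, 500, 70, 900, 1),
    source = "test", stringsAsFactors = FALSE)
  m <- make_one_enzyme_ec()  # enzyme E1, EC 1.1.1.1, substrate "substrate a"
  # exact hit (level 1) wins over larger cross-organism values
  res <- match_kcats(m, db, organism = "My organism")
  expect_equal(res$assignment$kcat, 50)
  expect_equal(res$assignment$level, 1L)
  # drop the exact record: cross-organism same-substrate (level 2), max rule
  res2 <- match_kcats(m, db[-1, ], organism = "My organism")
  expect_equal(res2$assignment$level, 2L)
  expect_equal(res2$assignment$kcat, 500)
  # only same-organism other-substrate left: level 3
  res3 <- match_kcats(m, db[3:5, ], organism = "My organism")
  expect_equal(res3$assignment$level, 3L)
  expect_equal(res3$assignment$kcat, 70)
  # any organism, any substrate: level 4
  res4 <- match_kcats(m, db[4:5, ], organism = "My organism")
  expect_equal(res4$assignment$level, 4L)
  # wildcarded last EC field: level 5
  db5 <- data.frame(ec_number = "1.1.1.99", substrate = "z", organism = "q",
                    kcat_per_s = 3, source = "test",
                    stringsAsFactors = FALSE)
  res5 <- match_kcats(m, db5, organism = "My organism")
  expect_equal(res5$assignment$level, 5L)
  # nothing sharing the first three EC fields: unmatched, logged
  db6 <- data.frame(ec_number = "9.9.9.9", substrate = "z", organism = "q",
                    kcat_per_s = 3, source = "test",
                    stringsAsFactors = FALSE)
  expect_message(res6 <- match_kcats(m, db6, organism = "My organism"),
                 "unconstrained")
  expect_equal(res6$unmatched, "E1")
  expect_equal(nrow(res6$assignment), 0)
  # median aggregation is available
  res7 <- match_kcats(m, db[3:4, ], organism = "none",
                      aggregate = "median")
  expect_equal(res7$assignment$kcat, median(c(70, 900)))
})

test_that("enzyme constraint caps flux at E * kcat * 3600", {
  # E = 1e-5 mmol/gDCW, kcat = 10/s -> vmax = 0.36 mmol/gDCW/h
  ec <- make_one_enzyme_ec(kcat = 10, E = 1e-5)
  sol <- fba(ec)
  expect_equal(sol$objective_value, 0.36, tolerance = 1e-9)
})

test_that("pool bound is sigma * f * Ptot and a large pool recovers the base optimum", {
  m <- make_toy_network("glucose")
  irr <- expand_isozymes(split_reversible(m))
  db <- make_toy_kcat_db(m, seed = 1)
  kc <- suppressMessages(match_kcats(irr, db, TOY_ORGANISM))
  ec <- build_ec_model(irr, kc, sigma = 0.35, f = 0.5, Ptot = 0.4)
  expect_equal(pool_upper_bound(ec), 0.35 * 0.5 * 0.4, tolerance = 1e-12)
  # EC optimum never exceeds the base optimum
  base <- fba(m)$objective_value
  expect_lte(fba(ec)$objective_value, base + 1e-8)
  # pool -> infinity recovers the base optimum
  ec$reactions$prot_pool_exchange$ub <- 1e6
  expect_equal(fba(ec)$objective_value, base, tolerance = 1e-6)
})

test_that("kcat monotonicity: raising kcat or pool never lowers the optimum", {
  m <- make_toy_network("glucose")
  irr <- expand_isozymes(split_reversible(m))
  db <- make_toy_kcat_db(m, seed = 1)
  kc <- suppressMessages(match_kcats(irr, db, TOY_ORGANISM))
  ec <- build_ec_model(irr, kc, sigma = 0.35, f = 0.1, Ptot = 0.4)
  mu0 <- fba(ec)$objective_value
  ec2 <- apply_kcat_curation(ec, data.frame(
    enzyme_id = "E_XPK", new_kcat_per_s = 500, stringsAsFactors = FALSE))
  expect_gte(fba(ec2)$objective_value, mu0 - 1e-9)
  ec3 <- ec
  ec3$reactions$prot_pool_exchange$ub <- ec$reactions$prot_pool_exchange$ub * 2
  expect_gte(fba(ec3)$objective_value, mu0 - 1e-9)
})

test_that("sensitivity analysis finds and relaxes the planted limiting kcat", {
  # glutamate dehydrogenase (sole nitrogen assimilation route) is planted
  # with a crippling 0.002/s kcat; the database maximum for its EC number
  # is 127/s, which restores growth
  m <- make_toy_network("glucose")
  irr <- expand_isozymes(split_reversible(m))
  db <- make_toy_kcat_db(m, seed = 1)
  kc <- suppressMessages(match_kcats(irr, db, TOY_ORGANISM))
  asg <- kc$assignment
  asg$kcat[asg$enzyme == "E_GDH1"] <- 0.002
  db <- rbind(db[db$ec_number != "1.4.1.4", ],
              data.frame(ec_number = "1.4.1.4", substrate = "other",
                         organism = "other", kcat_per_s = 127,
                         source = "lit", stringsAsFactors = FALSE))
  ec <- build_ec_model(irr, asg, sigma = 0.35, f = 0.5, Ptot = 0.4)
  crippled <- fba(ec)$objective_value
  expect_lt(crippled, 0.1)
  res <- sensitivity_top_kcat(ec, target_growth = 0.5, kcat_db = db)
  expect_gte(nrow(res$trace), 1)
  expect_equal(res$trace$enzyme[1], "E_GDH1")
  expect_equal(res$trace$old_kcat[1], 0.002)
  expect_equal(res$trace$new_kcat[1], 127)
  expect_gte(res$achieved, 0.5 * (1 - 1e-6))
  expect_equal(res$gap, 0)
  # a model already meeting the target returns an empty trace
  res2 <- sensitivity_top_kcat(res$model, target_growth = res$achieved / 2,
                               kcat_db = db)
  expect_equal(nrow(res2$trace), 0)
})

test_that("top_used_enzymes ranks mass-wise and flags > 1% of pool", {
  m <- make_toy_network("glucose")
  irr <- expand_isozymes(split_reversible(m))
  kc <- suppressMessages(match_kcats(irr, make_toy_kcat_db(m, 1),
                                     TOY_ORGANISM))
  ec <- build_ec_model(irr, kc, sigma = 0.35, f = 0.5, Ptot = 0.4)
  sol <- fba(ec)
  tab <- top_used_enzymes(ec, sol, n = 10)
  expect_lte(nrow(tab), 10)
  expect_true(all(diff(tab$mass_g) <= 1e-12))
  expect_equal(tab$flagged, tab$pct_pool > 1)
  mw <- setNames(ec$enzymes$mw, ec$enzymes$id)
  expect_equal(tab$mass_g, tab$usage_mmol * mw[tab$enzyme],
               ignore_attr = TRUE)
  # n beyond the enzyme count returns the full table
  tab_all <- top_used_enzymes(ec, sol, n = 1e6)
  expect_equal(nrow(tab_all), length(ec$annotations$ec$enzymes))
})

test_that("kcat curation updates coefficients and commutes with building", {
  m <- make_toy_network("glucose")
  irr <- expand_isozymes(split_reversible(m))
  db <- make_toy_kcat_db(m, seed = 1)
  kc <- suppressMessages(match_kcats(irr, db, TOY_ORGANISM))
  ec <- build_ec_model(irr, kc, sigma = 0.35, f = 0.5, Ptot = 0.4)
  # 0.002 -> 127 shrinks the enzyme coefficient by 63500
  entries <- data.frame(enzyme_id = "E_FBP", new_kcat_per_s = 127,
                        stringsAsFactors = FALSE)
  pre <- apply_kcat_curation(ec, data.frame(
    enzyme_id = "E_FBP", new_kcat_per_s = 0.002, stringsAsFactors = FALSE))
  post <- apply_kcat_curation(pre, entries)
  rid <- pre$kcat_assignment$reaction[pre$kcat_assignment$enzyme == "E_FBP"][1]
  expect_equal(pre$reactions[[rid]]$stoich[["pmet_E_FBP"]] /
                 post$reactions[[rid]]$stoich[["pmet_E_FBP"]],
               63500, tolerance = 1e-9)
  expect_true(all(post$provenance$level[
    post$provenance$enzyme == "E_FBP"] == 0L))
  # empty curation is the identity
  expect_identical(apply_kcat_curation(ec, entries[0, ]), ec)
  # curating the model equals building from a curated assignment
  asg2 <- kc$assignment
  asg2$kcat[asg2$enzyme == "E_FBP"] <- 127
  asg2$level[asg2$enzyme == "E_FBP"] <- 0L
  ec2 <- build_ec_model(irr, asg2, sigma = 0.35, f = 0.5, Ptot = 0.4)
  ec3 <- apply_kcat_curation(ec, data.frame(
    enzyme_id = "E_FBP", new_kcat_per_s = 127, stringsAsFactors = FALSE))
  expect_equal(ec2$reactions, ec3$reactions, tolerance = 1e-12)
})

test_that("Eq-1 feasibility holds in optimal solutions of the EC model", {
  m <- make_toy_network("glucose")
  irr <- expand_isozymes(split_reversible(m))
  kc <- suppressMessages(match_kcats(irr, make_toy_kcat_db(m, 1),
                                     TOY_ORGANISM))
  ec <- build_ec_model(irr, kc, sigma = 0.35, f = 0.5, Ptot = 0.4)
  sol <- fba(ec)
  asg <- ec$kcat_assignment
  for (rid in unique(asg$reaction)) {
    rows <- asg[asg$reaction == rid, ]
    cap <- sum(vapply(seq_len(nrow(rows)), function(i)
      rows$kcat[i] * 3600 * sol$flux[[paste0("draw_", rows$enzyme[i])]], 0))
    expect_lte(sol$flux[[rid]], cap + 1e-6)
  }
})
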