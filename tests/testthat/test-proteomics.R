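test_that("TPA quantification returns normalized shares of 1e6 ug/g", {
  # two proteins with equal normalized intensities -> 5e5 ug/g each
  rec <- make_ms_records(c(p1 = 3, p2 = 3))
  s <- tpa_quantify(rec)
  expect_equal(s$conc$conc_ug_per_g, c(5e5, 5e5))
  expect_equal(sum(s$conc$conc_ug_per_g), 1e6)
  # the recovery factor cancels in the shares
  s2 <- tpa_quantify(rec, recovery = 1.0)
  expect_equal(s2$conc$conc_ug_per_g, s$conc$conc_ug_per_g)
  # global intensity rescaling leaves concentrations unchanged
  rec3 <- make_ms_records(c(p1 = 3, p2 = 3), std = rep(5e9, 2))
  expect_equal(tpa_quantify(rec3)$conc$conc_ug_per_g,
               s$conc$conc_ug_per_g)
  # records with missing ratios are excluded with a message
  rec4 <- rbind(rec, data.frame(protein_id = "p3", condition = "cond",
                                replicate = 1, ibaq_heavy = 10,
                                ratio_hl = NA, mw_g_per_mol = 5e4))
  expect_message(s4 <- tpa_quantify(rec4), "excluding 1")
  expect_false("p3" %in% s4$conc$protein_id)
  expect_error(tpa_quantify(rec[0, ]))
})

test_that("zero-noise synthetic proteomics is recovered exactly", {
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", seed = 3)
  pr <- simulate_proteomics(sim$truth, cv = 0, seed = 3)
  s <- tpa_quantify(pr$records, Ptot = sim$truth$composition$protein)
  expect_equal(sum(s$conc$conc_ug_per_g), 1e6, tolerance = 1e-9)
  truth <- pr$true_conc[s$conc$protein_id]
  expect_lt(max(abs(s$conc$conc_ug_per_g - truth) / truth), 1e-9)
})

test_that("molar conversion follows conc * Ptot / MW", {
  # 1e5 ug/g at Ptot 0.5 and MW 50 kDa -> 1e-3 mmol/gDCW
  rec <- make_ms_records(c(p1 = 1e5, p2 = 9e5), mw = c(5e4, 5e4))
  s <- tpa_quantify(rec, Ptot = 0.5)
  molar <- to_molar(s)
  expect_equal(molar[["p1"]], 1e-3, tolerance = 1e-12)
  # Ptot = 0 -> all zero
  expect_equal(unname(to_molar(s, Ptot = 0)), c(0, 0))
  # mass conservation: sum(E * MW) <= Ptot
  expect_lte(sum(molar * 5e4 / 1000), 0.5 + 1e-12)
  expect_error(to_molar(s, mw = c(p1 = 5e4)), "missing molecular weight")
})

test_that("differential expression flags planted fold changes only", {
  noise_a <- list(rep(1.02, 3), rep(0.98, 3))
  noise_b <- list(rep(0.99, 3), rep(1.01, 3))
  base <- c(p1 = 2e5, p2 = 3e5, p3 = 5e5)
  rec_a <- make_ms_records(base, condition = "a", replicates = 2,
                           noise = noise_a)
  # p1 planted 4-fold up in b
  shifted <- c(p1 = 8e5, p2 = 3e5, p3 = 5e5)
  rec_b <- make_ms_records(shifted, condition = "b", replicates = 2,
                           noise = noise_b)
  a <- tpa_quantify(rec_a)
  b <- tpa_quantify(rec_b)
  de <- differential_expression(a, b)
  p1 <- de[de$protein_id == "p1", ]
  # shares: p1 rises 2e5/1e6 -> 8e5/1.6e6; log2(0.5/0.2) = 1.32
  expect_gt(p1$log2fc, 1)
  expect_true(is.finite(p1$p))
  # identical groups -> log2FC 0, not significant
  de0 <- differential_expression(a, a)
  expect_true(all(abs(de0$log2fc) < 0.1))
  expect_false(any(de0$significant))
  # fewer than 2 replicates is an error
  a1 <- tpa_quantify(make_ms_records(base, condition = "a"))
  expect_error(differential_expression(a1, b), "2 replicates")
})

test_that("noisy proteins (SD > mean) are excluded before testing", {
  # p2's duplicates differ wildly: SD of (10, 990) exceeds the mean
  rec_a <- make_ms_records(c(p1 = 500, p2 = 500), replicates = 2,
                           condition = "a",
                           noise = list(c(1, 0.02), c(1, 1.98)))
  a <- tpa_quantify(rec_a)
  rec_b <- make_ms_records(c(p1 = 480, p2 = 520), replicates = 2,
                           condition = "b",
                           noise = list(c(1, 1), c(1.01, 0.99)))
  b <- tpa_quantify(rec_b)
  de <- differential_expression(a, b)
  expect_false("p2" %in% de$protein_id)
  expect_true("p1" %in% de$protein_id)
})

test_that("GO allocation computes mass shares with overlap allowed", {
  rec <- make_ms_records(c(p1 = 2e5, p2 = 3e5, p3 = 5e5))
  s <- tpa_quantify(rec)
  # one group holding everything -> 100%
  res <- allocate_go(s, list(all = c("p1", "p2", "p3")))
  expect_equal(res$pct_mass, 100)
  # disjoint groups covering half the mass sum to 50%
  res2 <- allocate_go(s, list(g1 = "p1", g2 = "p2"))
  expect_equal(sum(res2$pct_mass), 50)
  # overlapping membership counts in every group
  res3 <- allocate_go(s, data.frame(group = c("x", "y"), protein_id = "p3"))
  expect_equal(res3$pct_mass, c(50, 50))
})

test_that("translation rate follows the closed form and recovers the plant", {
  # mu = 0.1/h, Ptot = 0.5, N_rib = 1.2626e-7 mol/gDCW -> 1.0 aa/s
  # one ribosomal protein at molar abundance N_rib with MW 30 g/mmol:
  # conc = 1.2626e-4 * 30 / 0.5 * 1e6 ug/g
  conc_r <- 1.2626e-4 * 30 / 0.5 * 1e6
  rec <- make_ms_records(c(rib = conc_r, oth = 1e6 - conc_r),
                         mw = c(3e4, 5e4))
  s <- tpa_quantify(rec, Ptot = 0.5)
  tr <- translation_rate(s, "rib", mu = 0.1)
  expect_equal(tr$rate_aa_per_s, 1.0, tolerance = 1e-3)
  expect_equal(tr$n_ribosome_mol_per_gdcw, 1.2626e-7, tolerance = 1e-3)
  # mu = 0 -> 0 aa/s
  expect_equal(translation_rate(s, "rib", mu = 0)$rate_aa_per_s, 0)
  # proportional to mu at fixed proteome (exact linearity)
  r1 <- translation_rate(s, "rib", mu = 0.05)$rate_aa_per_s
  r2 <- translation_rate(s, "rib", mu = 0.25)$rate_aa_per_s
  expect_equal(r2 / r1, 5, tolerance = 1e-9)
  expect_error(translation_rate(s, "absent_protein", mu = 0.1),
               "no ribosomal")
})

test_that("generator-planted translation rate is recovered", {
  m <- make_toy_network("glucose")
  sim <- simulate_condition(m, "exp", seed = 5)
  pr <- simulate_proteomics(sim$truth, cv = 0, seed = 5,
                            translation_aa_per_s = 3.0)
  s <- tpa_quantify(pr$records, Ptot = sim$truth$composition$protein)
  tr <- translation_rate(s, pr$ribosomal_ids, mu = sim$truth$mu)
  expect_equal(tr$rate_aa_per_s, 3.0, tolerance = 1e-6)
  expect_equal(tr$n_subunits_detected, length(pr$ribosomal_ids))
})
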