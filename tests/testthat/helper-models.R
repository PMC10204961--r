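# Fixture builders shared across test files. Everything is constructed in
# code; nothing is read from disk except files the tests themselves write.

# two-metabolite linear chain: uptake -> A -> B -> sink, with a 0.5 yield
# step so the optimum is forced by stoichiometry
make_chain_model <- function(uptake = 10, yield = 0.5, fix_uptake = FALSE) {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", formula = NA_character_,
                     charge = NA_real_, stringsAsFactors = FALSE)
  rxns <- list(
    new_reaction("EX_A", c(A = -1), lb = -uptake,
                 ub = if (fix_uptake) -uptake else 0),
    new_reaction("R1", c(A = -1, B = yield), lb = 0),
    new_reaction("EX_B", c(B = -1), lb = 0))
  new_model("chain", c(c = "cytosol"), mets, rxns, objective = "EX_B")
}

# one enzymatic reaction A -> B catalysed by a single enzyme; used for
# the v <= E * kcat * 3600 arithmetic
make_one_enzyme_ec <- function(kcat = 10, E = 1e-5, mw = 50) {
  mets <- data.frame(id = c("A", "B"), name = c("substrate a", "product b"),
                     compartment = "c", formula = NA_character_,
                     charge = NA_real_, stringsAsFactors = FALSE)
  rxns <- list(
    new_reaction("EX_A", c(A = -1), lb = -1000, ub = 0),
    new_reaction("R1", c(A = -1, B = 1), lb = 0, gene_rule = list("E1")),
    new_reaction("EX_B", c(B = -1), lb = 0))
  enz <- data.frame(id = "E1", genes = "E1", mw = mw, ec = "1.1.1.1",
                    stringsAsFactors = FALSE)
  m <- new_model("one_enzyme", c(c = "cytosol"), mets, rxns, enzymes = enz,
                 objective = "EX_B")
  m <- split_reversible(m)
  asg <- data.frame(reaction = "R1", enzyme = "E1", kcat = kcat, level = 1L,
                    stringsAsFactors = FALSE)
  ec <- build_ec_model(m, asg, sigma = 1, f = 1, Ptot = 1)
  # cap the enzyme at a measured concentration instead of the pool
  ec$reactions$draw_E1$stoich <- c(pmet_E1 = 1)
  ec$reactions$draw_E1$ub <- E
  ec
}

# proteomics records with exact planted concentrations (ug/g shares of 1e6)
make_ms_records <- function(conc, mw = NULL, condition = "cond",
                            replicates = 1, std = NULL, noise = NULL) {
  n <- length(conc)
  if (is.null(mw)) mw <- rep(5e4, n)
  if (is.null(std)) std <- rep(1e7, n)
  out <- list()
  for (r in seq_len(replicates)) {
    light <- conc * (if (is.null(noise)) 1 else noise[[r]])
    out[[r]] <- data.frame(
      protein_id = names(conc), condition = condition, replicate = r,
      ibaq_heavy = std, ratio_hl = std / light, mw_g_per_mol = mw,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

expect_steady_state <- function(model, flux, tol = 1e-6) {
  S <- stoich_matrix(model)
  resid <- max(abs(S %*% flux[colnames(S)]))
  expect_lt(resid, tol)
}
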