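# Integration of per-condition proteomics and physiology into an EC model:
# f-factor, measured-enzyme bounds with direct pool subtraction, automatic
# flexibilization of over-tight measured bounds, and exchange variability
# windows for sampling.

#' Read per-condition physiology data
#'
#' @param path YAML file with fields `mu` (1/h), `uptake` (named map,
#'   substrate exchange id -> positive uptake rate mmol/gDCW/h), `co2`, `o2`
#'   (mmol/gDCW/h, optional), `byproducts` (named map, exchange id ->
#'   positive secretion rate), `Ptot`, `Ptot_sd`, `lipid` (g/gDCW),
#'   `acyl_profile` (named map), `ngam` (mmol/gDCW/h).
#' @return a `physiology_data` list.
#' @export
read_physiology <- function(path) {
  y <- yaml::read_yaml(path)
  physiology_data(mu = y$mu, uptake = unlist(y$uptake), co2 = y$co2,
                  o2 = y$o2, byproducts = unlist(y$byproducts) %||% numeric(),
                  Ptot = y$Ptot, Ptot_sd = y$Ptot_sd %||% 0,
                  lipid = y$lipid, acyl_profile = unlist(y$acyl_profile),
                  ngam = y$ngam %||% 0)
}

#' Physiology data container
#'
#' @param mu specific growth rate, 1/h.
#' @param uptake named positive uptake rates per substrate exchange id.
#' @param co2,o2 gas rates, mmol/gDCW/h (positive magnitudes); `NULL` means
#'   unmeasured (simulated values will be used for the windows).
#' @param byproducts named positive secretion rates per exchange id.
#' @param Ptot total protein content, g/gDCW; `Ptot_sd` its SD.
#' @param lipid lipid content, g/gDCW.
#' @param acyl_profile acyl chain mass fractions.
#' @param ngam non-growth maintenance, mmol ATP/gDCW/h.
#' @return a `physiology_data` list.
#' @export
physiology_data <- function(mu, uptake, co2 = NULL, o2 = NULL,
                            byproducts = numeric(), Ptot = NA_real_,
                            Ptot_sd = 0, lipid = NA_real_,
                            acyl_profile = NULL, ngam = 0) {
  stopifnot(mu >= 0, all(is.finite(uptake)), all(uptake >= 0))
  structure(list(mu = mu, uptake = uptake, co2 = co2, o2 = o2,
                 byproducts = byproducts, Ptot = Ptot, Ptot_sd = Ptot_sd,
                 lipid = lipid, acyl_profile = acyl_profile, ngam = ngam),
            class = "physiology_data")
}

#' Sample-specific f-factor
#'
#' Mass fraction of the quantified proteome that belongs to model enzymes,
#' computed on the unfiltered quantification (before any SD-based record
#' filtering, so coverage is not underestimated).
#'
#' @param proteome a `proteome_sample`.
#' @param model a `metabolic_model` (its enzyme table defines membership via
#'   gene ids).
#' @return f in (0, 1].
#' @export
compute_f_factor <- function(proteome, model) {
  genes <- unique(unlist(strsplit(model$enzymes$genes, ";")))
  conc <- setNames(proteome$conc$conc_ug_per_g, proteome$conc$protein_id)
  f <- sum(conc[intersect(genes, names(conc))]) / 1e6
  if (f <= 0) stop("no model enzyme was quantified; f-factor undefined",
                   call. = FALSE)
  min(f, 1)
}

#' Constrain measured enzymes and shrink the shared pool
#'
#' Measured enzymes get their usage reaction rewired off the pool and capped
#' at the measured concentration; the unmeasured-enzyme pool is obtained by
#' direct subtraction: `pool_ub = enzymeConc - Pmeasured`, where
#' `enzymeConc = sigma * f * Ptot_rescaled` and `Pmeasured` is the summed
#' mass of measured model enzymes. `Ptot` is rescaled upward by one SD of
#' the total-protein assay before use. After this step the mass identity
#' `sum(measured bound * MW) + pool_ub = sigma * f * Ptot_rescaled` holds
#' exactly.
#'
#' @param ec an `ec_model`.
#' @param molar named vector of measured molar abundances, mmol/gDCW (from
#'   [to_molar()]); entries not in the model are ignored.
#' @param sd_molar named vector of abundance SDs, mmol/gDCW (used by
#'   [flexibilize()]); may be empty.
#' @param Ptot total protein content, g/gDCW.
#' @param Ptot_sd SD of the total protein assay (added to Ptot).
#' @param sigma,f saturation factor and enzyme mass fraction.
#' @return the constrained `ec_model`; a coverage report is attached at
#'   `annotations$ec$coverage`.
#' @export
constrain_enzymes <- function(ec, molar, sd_molar = numeric(), Ptot,
                              Ptot_sd = 0, sigma = 0.35, f) {
  ptot_rescaled <- Ptot + Ptot_sd
  enzyme_conc <- sigma * f * ptot_rescaled
  mw <- setNames(ec$enzymes$mw, ec$enzymes$id)
  pool_enzymes <- ec$annotations$ec$enzymes
  measured <- intersect(names(molar), pool_enzymes)
  p_measured <- sum(molar[measured] * mw[measured])
  if (p_measured > enzyme_conc) {
    stop("measured enzyme mass (", signif(p_measured, 4),
         " g/gDCW) exceeds the expected total enzyme concentration (",
         signif(enzyme_conc, 4),
         "); rescale Ptot or increase sigma", call. = FALSE)
  }
  for (e in measured) {
    rid <- paste0(DRAW_PREFIX, e)
    ec$reactions[[rid]]$stoich <- setNames(1, paste0(PROT_PREFIX, e))
    ec$reactions[[rid]]$ub <- molar[[e]]
  }
  ec$reactions[[POOL_RXN]]$ub <- enzyme_conc - p_measured
  ec$annotations$ec$pool_ub <- enzyme_conc - p_measured
  ec$annotations$ec$measured <- measured
  ec$annotations$ec$measured_conc <- molar[measured]
  ec$annotations$ec$measured_sd <-
    setNames(ifelse(measured %in% names(sd_molar) &
                      is.finite(sd_molar[measured]),
                    sd_molar[measured], 0), measured)
  ec$annotations$ec$sigma <- sigma
  ec$annotations$ec$f <- f
  ec$annotations$ec$Ptot_rescaled <- ptot_rescaled
  ec$annotations$ec$coverage <- list(
    n_measured = length(measured),
    n_model_enzymes = length(pool_enzymes),
    mass_measured_g = p_measured,
    enzyme_conc_g = enzyme_conc,
    mass_fraction_measured = p_measured / enzyme_conc)
  validate_model(ec)
  ec
}

#' Automatic flexibilization of measured enzyme bounds
#'
#' While the maximal growth rate is below the target, the most limiting
#' measured enzyme (largest finite-difference growth gain from a +10% bound
#' increase; ties broken by enzyme id) is relaxed: first its bound is raised
#' to measured + SD, then the enzyme is released to draw from the shared
#' pool (its allocated mass returns to the pool). Stops when the target is
#' reached or every measured bound has been released.
#'
#' @param ec a constrained `ec_model` (after [constrain_enzymes()]).
#' @param target_mu growth rate to make feasible, 1/h.
#' @param max_steps safety cap.
#' @return list with `model`, `records` (data.frame enzyme, old_bound,
#'   new_bound, step, action) and `achieved`; if the target stays
#'   unreachable, `gap` holds the shortfall.
#' @export
flexibilize <- function(ec, target_mu, max_steps = 100) {
  records <- list()
  mw <- setNames(ec$enzymes$mw, ec$enzymes$id)
  step <- 0L
  growth <- function(m) {
    sol <- fba(m)
    if (sol$status == "optimal") sol$objective_value else 0
  }
  repeat {
    g <- growth(ec)
    if (g >= target_mu * (1 - 1e-6) || step >= max_steps) break
    meas <- ec$annotations$ec$measured
    if (!length(meas)) break
    sol <- fba(ec)
    gains <- vapply(sort(meas), function(e) {
      m2 <- ec
      rid <- paste0(DRAW_PREFIX, e)
      m2$reactions[[rid]]$ub <- m2$reactions[[rid]]$ub * 1.10
      growth(m2) - g
    }, 0)
    force_release <- FALSE
    if (max(gains) > 1e-12) {
      e <- names(gains)[which.max(gains)]  # first index = smallest id on tie
    } else {
      # no single bound bump helps: either several measured bounds bind at
      # once, or the shared pool itself is the cap. Relax the binding
      # measured enzyme holding the most mass; if the pool binds, release
      # the heaviest measured enzyme outright - its allocation returns to
      # the pool and enlarges it.
      binding <- meas[vapply(meas, function(e) {
        r <- ec$reactions[[paste0(DRAW_PREFIX, e)]]
        sol$status == "optimal" && sol$flux[[r$id]] >= r$ub - 1e-9
      }, NA)]
      pool_binds <- sol$status == "optimal" &&
        sol$flux[[POOL_RXN]] >= ec$reactions[[POOL_RXN]]$ub - 1e-9
      if (!length(binding)) {
        if (!pool_binds) break
        binding <- meas
        force_release <- TRUE
      }
      mass <- vapply(binding, function(e)
        ec$annotations$ec$measured_conc[[e]] * mw[[e]], 0)
      binding <- sort(binding)
      e <- binding[which.max(mass[binding])]
    }
    rid <- paste0(DRAW_PREFIX, e)
    old_bound <- ec$reactions[[rid]]$ub
    conc <- ec$annotations$ec$measured_conc[[e]]
    sdv <- ec$annotations$ec$measured_sd[[e]]
    step <- step + 1L
    if (!force_release && sdv > 0 && old_bound < conc + sdv - 1e-15) {
      ec$reactions[[rid]]$ub <- conc + sdv
      records[[step]] <- data.frame(enzyme = e, old_bound = old_bound,
                                    new_bound = conc + sdv, step = step,
                                    action = "raise_to_sd",
                                    stringsAsFactors = FALSE)
    } else {
      # release to the pool; the enzyme's allocated mass returns to it
      ec$reactions[[rid]]$stoich <- setNames(
        c(-mw[[e]], 1), c(POOL_MET, paste0(PROT_PREFIX, e)))
      ec$reactions[[rid]]$ub <- DEFAULT_BOUND
      new_pool <- ec$reactions[[POOL_RXN]]$ub + conc * mw[[e]]
      ec$reactions[[POOL_RXN]]$ub <- new_pool
      ec$annotations$ec$pool_ub <- new_pool
      ec$annotations$ec$measured <- setdiff(ec$annotations$ec$measured, e)
      records[[step]] <- data.frame(enzyme = e, old_bound = old_bound,
                                    new_bound = Inf, step = step,
                                    action = "release_to_pool",
                                    stringsAsFactors = FALSE)
    }
  }
  achieved <- growth(ec)
  list(model = ec,
       records = if (length(records)) do.call(rbind, records) else
         data.frame(enzyme = character(), old_bound = numeric(),
                    new_bound = numeric(), step = integer(),
                    action = character(), stringsAsFactors = FALSE),
       achieved = achieved,
       gap = max(0, target_mu - achieved))
}

# default variability windows (fractions)
DEFAULT_WINDOWS <- list(growth = 0.01, uptake = 0.01, gas = 0.10,
                        byproduct = 0.10, pool = 0.10, ngam = 0.01)

#' Constrain exchanges to measured-rate variability windows
#'
#' Applies the per-quantity variability windows used before sampling: 1% on
#' growth rate and substrate uptake, 10% on gas exchange, by-product rates
#' and the protein pool, 1% on NGAM. Quantities measured as positive rates
#' are translated to the exchange-flux sign convention (uptake negative).
#' When gas rates are unmeasured, FBA-predicted values are used to
#' constrain gas exchange.
#'
#' @param ec an `ec_model` (or plain model) with a biomass objective.
#' @param phys a `physiology_data`.
#' @param windows tolerance overrides, see `DEFAULT_WINDOWS`.
#' @param gas_rxns named list with `co2` and `o2` exchange ids (defaults
#'   `EX_co2`, `EX_o2`).
#' @param ngam_rxn ATP hydrolysis reaction id (default `"NGAM"`).
#' @return the windowed model.
#' @export
set_exchange_windows <- function(ec, phys, windows = list(),
                                 gas_rxns = list(co2 = "EX_co2",
                                                 o2 = "EX_o2"),
                                 ngam_rxn = "NGAM") {
  w <- utils::modifyList(DEFAULT_WINDOWS, windows)
  rev_id <- function(id) paste0(id, REV_SUFFIX)
  need <- function(id) {
    if (!id %in% names(ec$reactions) &&
        !rev_id(id) %in% names(ec$reactions)) {
      stop("required exchange '", id, "' missing from model", call. = FALSE)
    }
  }
  set_win <- function(m, id, value, tol) {
    # value signed (base-model exchange convention: uptake negative).
    # On a split model the negative direction lives on the _REV copy.
    has_fwd <- id %in% names(m$reactions)
    has_rev <- rev_id(id) %in% names(m$reactions)
    target <- id
    if (value < 0 && has_rev) {
      target <- rev_id(id)
      value <- -value
      if (has_fwd) m$reactions[[id]]$ub <- 0
    } else if (value >= 0 && has_rev && has_fwd) {
      m$reactions[[rev_id(id)]]$ub <- 0
    } else if (!has_fwd && has_rev) {
      target <- rev_id(id)
      value <- -value
    }
    lo <- min(value * (1 - tol), value * (1 + tol))
    hi <- max(value * (1 - tol), value * (1 + tol))
    m$reactions[[target]]$lb <- lo
    m$reactions[[target]]$ub <- hi
    m
  }
  for (s in names(phys$uptake)) {
    need(s)
    ec <- set_win(ec, s, -phys$uptake[[s]], w$uptake)
  }
  # growth window
  bm <- ec$objective
  ec <- set_win(ec, bm, phys$mu, w$growth)
  # gases: use simulated values when unmeasured
  gas_vals <- list(co2 = phys$co2, o2 = phys$o2)
  if (is.null(gas_vals$co2) || is.null(gas_vals$o2)) {
    sol <- fba(ec)
    if (sol$status != "optimal") {
      stop("cannot simulate gas rates: model infeasible under growth/",
           "uptake windows", call. = FALSE)
    }
    net_of <- function(id) {
      fwd <- if (id %in% names(sol$flux)) sol$flux[[id]] else 0
      rev <- if (rev_id(id) %in% names(sol$flux))
        sol$flux[[rev_id(id)]] else 0
      fwd - rev
    }
    if (is.null(gas_vals$co2)) gas_vals$co2 <- abs(net_of(gas_rxns$co2))
    if (is.null(gas_vals$o2)) gas_vals$o2 <- abs(net_of(gas_rxns$o2))
  }
  need(gas_rxns$co2)
  need(gas_rxns$o2)
  ec <- set_win(ec, gas_rxns$co2, abs(gas_vals$co2), w$gas)     # production
  ec <- set_win(ec, gas_rxns$o2, -abs(gas_vals$o2), w$gas)      # consumption
  for (b in names(phys$byproducts)) {
    need(b)
    ec <- set_win(ec, b, phys$byproducts[[b]], w$byproduct)
  }
  if (POOL_RXN %in% names(ec$reactions)) {
    pool <- ec$reactions[[POOL_RXN]]$ub
    ec$reactions[[POOL_RXN]]$lb <- pool * (1 - w$pool)
    ec$reactions[[POOL_RXN]]$ub <- pool * (1 + w$pool)
  }
  if (phys$ngam > 0) {
    need(ngam_rxn)
    ec <- set_win(ec, ngam_rxn, phys$ngam, w$ngam)
  }
  validate_model(ec)
  ec
}
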