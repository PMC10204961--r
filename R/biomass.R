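# Biomass equation handling: rescaling to measured protein/lipid content
# with a SLIME-style acyl-chain split, and fitting growth/non-growth
# associated maintenance energy (GAM/NGAM) to physiology.
#
# Biomass bookkeeping convention: the pseudo-metabolites protein_c, lipid_c
# and carb_c each weigh 1 g/mmol, so biomass-reaction coefficients are mass
# fractions and the biomass "molar mass" must total 1 g/mmol.

# acyl-chain molar masses (free fatty acid, g/mmol)
ACYL_CHAIN_MW <- c("C16:0" = 0.25643, "C18:0" = 0.28448,
                   "C18:1" = 0.28246, "C18:2" = 0.28045)
# mass fraction of lipid assigned to the glycerol backbone (TAG-like)
BACKBONE_MASS_FRACTION <- 0.10

#' Biomass composition container
#'
#' @param protein,lipid protein and lipid content, g/gDCW.
#' @param acyl_profile named mass-fraction vector over acyl chains (must sum
#'   to 1 within 1e-6), names as in `names(ACYL_CHAIN_MW)`.
#' @param carbohydrate residual component, g/gDCW; `NA` lets
#'   [rescale_biomass()] absorb the residual here.
#' @param gam growth-associated maintenance, mmol ATP/gDCW (optional
#'   override).
#' @param ngam non-growth maintenance, mmol ATP/gDCW/h (optional override).
#' @return a `biomass_composition` list.
#' @export
biomass_composition <- function(protein, lipid,
                                acyl_profile = c("C16:0" = 0.30,
                                                 "C18:0" = 0.10,
                                                 "C18:1" = 0.60),
                                carbohydrate = NA_real_,
                                gam = NA_real_, ngam = NA_real_) {
  stopifnot(protein >= 0, protein <= 1, lipid >= 0, lipid <= 1)
  if (abs(sum(acyl_profile) - 1) > 1e-6) {
    stop("acyl profile must sum to 1 (got ", sum(acyl_profile), ")",
         call. = FALSE)
  }
  unknown <- setdiff(names(acyl_profile), names(ACYL_CHAIN_MW))
  if (length(unknown)) {
    stop("no molar mass tabulated for chain(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(protein = protein, lipid = lipid,
                 acyl_profile = acyl_profile, carbohydrate = carbohydrate,
                 gam = gam, ngam = ngam),
            class = "biomass_composition")
}

#' Rescale the biomass equation to a measured composition
#'
#' Sets the protein and lipid pseudo-component coefficients of the biomass
#' reaction to the measured g/gDCW values, rewrites the SLIME merge reaction
#' so acyl-chain coefficients follow the measured mass profile, and lets the
#' carbohydrate component absorb the residual so total biomass mass stays
#' exactly 1 g/mmol. Idempotent for identical composition.
#'
#' @param model a `metabolic_model` whose biomass reaction consumes tagged
#'   pseudo-components.
#' @param comp a [biomass_composition()].
#' @param ids id overrides: `biomass` (default: model objective), `protein`,
#'   `lipid`, `carb` pseudo-metabolites, `lipid_merge` reaction,
#'   `backbone` pseudo-metabolite, and `acyl_met(chain)` naming scheme
#'   `acyl_<chain>` with ":" dropped.
#' @return the rescaled model.
#' @export
rescale_biomass <- function(model, comp, ids = list()) {
  tg <- utils::modifyList(
    list(biomass = model$objective, protein = "protein_c", lipid = "lipid_c",
         carb = "carb_c", lipid_merge = "LIPID_SYN",
         backbone = "backbone_c"),
    ids)
  bm <- model$reactions[[tg$biomass]]
  if (is.null(bm)) stop("biomass reaction '", tg$biomass, "' not found",
                        call. = FALSE)
  for (p in c(tg$protein, tg$lipid, tg$carb)) {
    if (!p %in% names(bm$stoich)) {
      stop("biomass reaction lacks tagged pseudo-component '", p, "'",
           call. = FALSE)
    }
  }
  other <- -sum(bm$stoich[bm$stoich < 0]) +
    bm$stoich[[tg$protein]] + bm$stoich[[tg$lipid]] + bm$stoich[[tg$carb]]
  # `other` counts non-tagged consumed mass only for 1 g/mmol components;
  # ATP/ADP in the biomass reaction carry no biomass mass here
  energy_mets <- grep("^(atp|adp)_", names(bm$stoich), value = TRUE)
  other <- other + sum(bm$stoich[energy_mets][bm$stoich[energy_mets] < 0])
  residual <- if (is.na(comp$carbohydrate)) {
    1 - comp$protein - comp$lipid - (-other)
  } else comp$carbohydrate
  if (residual < -1e-9) {
    stop("measured protein + lipid + fixed components exceed 1 g/gDCW by ",
         signif(-residual, 4), " g", call. = FALSE)
  }
  bm$stoich[[tg$protein]] <- -comp$protein
  bm$stoich[[tg$lipid]] <- -comp$lipid
  bm$stoich[[tg$carb]] <- -residual
  if (!is.na(comp$gam)) {
    atp <- grep("^atp_", names(bm$stoich), value = TRUE)
    adp <- grep("^adp_", names(bm$stoich), value = TRUE)
    if (length(atp)) bm$stoich[[atp]] <- -comp$gam
    if (length(adp)) bm$stoich[[adp]] <- comp$gam
  }
  model$reactions[[tg$biomass]] <- bm
  # SLIME merge: backbone fraction + per-chain acyl mass fractions -> 1 g lipid
  lm <- model$reactions[[tg$lipid_merge]]
  if (!is.null(lm)) {
    prod <- names(lm$stoich)[lm$stoich > 0]
    st <- setNames(-BACKBONE_MASS_FRACTION, tg$backbone)
    for (chain in names(comp$acyl_profile)) {
      w <- comp$acyl_profile[[chain]]
      if (w <= 0) next
      acyl_met <- acyl_met_id(chain)
      if (!acyl_met %in% model$metabolites$id) {
        stop("model lacks acyl pseudo-metabolite '", acyl_met,
             "' required by the measured profile", call. = FALSE)
      }
      st[acyl_met] <- -(1 - BACKBONE_MASS_FRACTION) * w
    }
    st[prod] <- lm$stoich[prod]
    lm$stoich <- st
    model$reactions[[tg$lipid_merge]] <- lm
  }
  validate_model(model)
  model
}

acyl_met_id <- function(chain) paste0("acyl_", gsub(":", "", chain), "_c")

#' Total biomass mass of the biomass equation
#'
#' Sum over consumed 1 g/mmol pseudo-components (protein, lipid,
#' carbohydrate) of coefficient x component mass; must equal 1 g/mmol after
#' any rescaling.
#'
#' @param model a `metabolic_model`.
#' @param ids as in [rescale_biomass()].
#' @return total biomass mass, g/mmol.
#' @export
biomass_mass <- function(model, ids = list()) {
  tg <- utils::modifyList(
    list(biomass = model$objective, protein = "protein_c", lipid = "lipid_c",
         carb = "carb_c"), ids)
  bm <- model$reactions[[tg$biomass]]
  -sum(bm$stoich[c(tg$protein, tg$lipid, tg$carb)])
}

#' Fit growth- and non-growth-associated maintenance energy
#'
#' NGAM is fixed from the physiology (lower bound of the ATP hydrolysis
#' reaction); GAM is found by bisection on the biomass ATP coefficient so
#' that the predicted maximal growth rate at the measured uptake matches the
#' measured rate within 0.1% relative. Predicted growth decreases
#' monotonically in GAM, which the bracket check exploits.
#'
#' @param model a `metabolic_model` with substrate uptake bounds already set
#'   to the measured rate.
#' @param mu measured specific growth rate, 1/h.
#' @param ngam non-growth ATP maintenance, mmol/gDCW/h (default 0).
#' @param ngam_rxn id of the ATP hydrolysis reaction (default `"NGAM"`).
#' @param bracket GAM search bracket, mmol ATP/gDCW (default `c(0, 300)`).
#' @param steps bisection steps (default 40).
#' @param ids biomass tagging overrides as in [rescale_biomass()].
#' @return list with `gam`, `ngam`, `mu_predicted`, and the refitted
#'   `model`.
#' @export
fit_gam_ngam <- function(model, mu, ngam = 0, ngam_rxn = "NGAM",
                         bracket = c(0, 300), steps = 40, ids = list()) {
  tg <- utils::modifyList(list(biomass = model$objective), ids)
  if (!is.null(model$reactions[[ngam_rxn]])) {
    model$reactions[[ngam_rxn]]$lb <- ngam
    if (model$reactions[[ngam_rxn]]$ub < ngam) {
      model$reactions[[ngam_rxn]]$ub <- ngam
    }
  }
  set_gam <- function(m, gam) {
    bm <- m$reactions[[tg$biomass]]
    atp <- grep("^atp_", names(bm$stoich), value = TRUE)
    adp <- grep("^adp_", names(bm$stoich), value = TRUE)
    stopifnot(length(atp) == 1)
    bm$stoich[[atp]] <- -gam
    if (length(adp) == 1) bm$stoich[[adp]] <- gam
    m$reactions[[tg$biomass]] <- bm
    m
  }
  mu_at <- function(gam) {
    sol <- fba(set_gam(model, gam))
    if (sol$status != "optimal") 0 else sol$objective_value
  }
  lo <- bracket[1]
  hi <- bracket[2]
  mu_lo <- mu_at(lo)
  mu_hi <- mu_at(hi)
  if (mu_lo < mu * (1 - 1e-3)) {
    stop("measured growth rate ", mu, " 1/h unattainable even at GAM = ",
         lo, " (predicted ", signif(mu_lo, 4), ")", call. = FALSE)
  }
  if (mu_hi > mu * (1 + 1e-3)) {
    stop("GAM bracketing failure: predicted growth ", signif(mu_hi, 4),
         " still above measured ", mu, " at GAM = ", hi, call. = FALSE)
  }
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    if (mu_at(mid) >= mu) lo <- mid else hi <- mid
  }
  gam <- (lo + hi) / 2
  list(gam = gam, ngam = ngam, mu_predicted = mu_at(gam),
       model = set_gam(model, gam))
}
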