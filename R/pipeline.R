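# End-to-end per-condition workflow: load inputs, build the EC model,
# integrate proteomics and physiology, sample, and write report tables plus
# a run manifest.

#' Run the full per-condition analysis pipeline
#'
#' Executes: load model -> optional scenario -> split reversible / expand
#' isozymes -> kcat matching -> EC construction -> biomass rescaling ->
#' GAM/NGAM fitting -> TPA quantification -> molar conversion -> f-factor ->
#' enzyme constraints -> flexibilization -> exchange windows -> flux
#' sampling -> statistics -> base-model mapping -> normalized fluxes, kapp,
#' cofactor turnover. All randomness flows from `seed`; identical configs
#' produce identical reports.
#'
#' @param config list (or path to a YAML file) with elements: `model_path`,
#'   `kcat_path`, `proteomics_path`, `physiology_path`, `condition`,
#'   `out_dir`; optional `sigma` (0.35), `n_iter` (2000), `seed` (1),
#'   `scenario` ("none"), `windows` (list), `organism`, `gam_bracket`.
#' @return invisibly, a list with the final model, sample statistics, and
#'   the manifest; report TSVs and `manifest.json` are written to
#'   `out_dir`.
#' @export
run_condition <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("model_path", "kcat_path", "proteomics_path",
                "physiology_path", "condition", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sigma <- config$sigma %||% 0.35
  n_iter <- config$n_iter %||% 2000
  seed <- config$seed %||% 1
  scenario <- config$scenario %||% "none"
  organism <- config$organism %||% TOY_ORGANISM
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  model <- stage("load_model", load_model(config$model_path, "json"))
  model <- stage("scenario", apply_scenario(model, scenario))
  phys <- stage("physiology", read_physiology(config$physiology_path))
  comp <- stage("composition", biomass_composition(
    protein = phys$Ptot, lipid = phys$lipid,
    acyl_profile = phys$acyl_profile))
  model <- stage("rescale_biomass", rescale_biomass(model, comp))
  # substrate uptake bound for the maintenance fit
  for (s in names(phys$uptake)) {
    model$reactions[[s]]$lb <- -phys$uptake[[s]]
  }
  fit <- stage("fit_gam_ngam",
               fit_gam_ngam(model, mu = phys$mu, ngam = phys$ngam,
                            bracket = config$gam_bracket %||% c(0, 300)))
  model <- fit$model

  irr <- stage("split_expand", expand_isozymes(split_reversible(model)))
  kdb <- stage("kcat_db", read_kcat_db(config$kcat_path))
  kc <- stage("match_kcats", match_kcats(irr, kdb, organism))

  records <- stage("proteomics", read_ms_records(config$proteomics_path))
  records <- records[records$condition == config$condition, ]
  if (!nrow(records)) {
    stop("pipeline stage 'proteomics' failed: no records for condition '",
         config$condition, "'", call. = FALSE)
  }
  prot <- stage("tpa_quantify",
                tpa_quantify(records, Ptot = phys$Ptot))
  f <- stage("f_factor", compute_f_factor(prot, model))
  ec <- stage("build_ec_model",
              build_ec_model(irr, kc, sigma = sigma, f = f,
                             Ptot = phys$Ptot))
  molar <- stage("to_molar", to_molar(prot))
  sd_molar <- stage("sd_molar", {
    sd_conc <- setNames(prot$conc$sd_ug_per_g, prot$conc$protein_id)
    sd_conc[is.na(sd_conc)] <- 0
    sd_conc / 1e6 * phys$Ptot / (prot$mw[names(sd_conc)] / 1000)
  })
  # reliability filter (duplicates whose SD exceeds the mean are not used as
  # individual constraints) and measured-mass budget: individually
  # constrained enzymes may claim at most half of the sigma-discounted
  # enzyme budget; the heaviest entries beyond that are left on the pool,
  # the same release operation flexibilization performs for growth limits
  budget <- config$measured_budget %||% 0.5
  n_budget_released <- 0L
  molar_meas <- stage("measured_set", {
    mw <- setNames(ec$enzymes$mw, ec$enzymes$id)
    cand <- intersect(names(molar), ec$annotations$ec$enzymes)
    reliable <- cand[sd_molar[cand] <= molar[cand]]
    mass <- molar[reliable] * mw[reliable]
    ord <- order(mass)  # keep small first, release heaviest
    enzyme_conc <- sigma * f * (phys$Ptot + phys$Ptot_sd)
    keep <- reliable[ord][cumsum(mass[ord]) <= budget * enzyme_conc]
    n_budget_released <<- length(reliable) - length(keep)
    molar[keep]
  })
  ec <- stage("constrain_enzymes",
              constrain_enzymes(ec, molar_meas, sd_molar, Ptot = phys$Ptot,
                                Ptot_sd = phys$Ptot_sd, sigma = sigma,
                                f = f))
  flex <- stage("flexibilize", flexibilize(ec, target_mu = phys$mu))
  ec <- flex$model
  ec <- stage("windows", set_exchange_windows(ec, phys,
                                              windows = config$windows %||%
                                                list()))
  smp <- stage("sampling", sample_fluxes(ec, n_iter = n_iter, seed = seed))
  stats <- stage("statistics", flux_statistics(smp))
  net <- stage("map_to_base", map_to_base(smp, ec))
  net_stats <- flux_statistics(net)
  med <- setNames(net_stats$median, net_stats$reaction)
  uptake <- phys$uptake[[1]]
  norm <- normalize_by_uptake(med, uptake)
  pairs <- unique(merge(
    ec$kcat_assignment,
    data.frame(reaction = names(ec$annotations$rev_map),
               base = vapply(ec$annotations$rev_map, `[[`, "", "base")),
    by.x = "reaction", by.y = "reaction")[, c("base", "enzyme", "kcat")])
  names(pairs)[1] <- "reaction"
  kapp <- compute_kapp(med, molar, pairs)
  # kapp <= kcat is guaranteed only where the measured bound was enforced;
  # released/flexibilized enzymes may run above their measured level
  kapp$table$constrained <- kapp$table$enzyme %in%
    setdiff(ec$annotations$ec$measured, flex$records$enzyme)
  turnovers <- lapply(c(ATP = "atp", NADH = "nadh", NADPH = "nadph"),
                      function(m) cofactor_turnover(med, model, m, uptake))

  # reports
  out <- config$out_dir
  write_tsv(stats, file.path(out, "flux_sample_stats.tsv"))
  write_tsv(net_stats, file.path(out, "net_flux_stats.tsv"))
  write_tsv(data.frame(reaction = names(norm), pct_of_uptake = unname(norm)),
            file.path(out, "normalized_flux.tsv"))
  write_tsv(kapp$table, file.path(out, "kapp.tsv"))
  for (m in names(turnovers)) {
    tr <- turnovers[[m]]
    write_tsv(rbind(
      cbind(side = "production", tr$production),
      cbind(side = "consumption", tr$consumption)),
      file.path(out, paste0("turnover_", m, ".tsv")))
  }
  write_tsv(flex$records, file.path(out, "flexibilization.tsv"))
  manifest <- list(
    condition = config$condition, seed = seed, n_iter = n_iter,
    sigma = sigma, f = f, scenario = scenario,
    gam = fit$gam, ngam = fit$ngam,
    pool_ub = ec$annotations$ec$pool_ub,
    n_enzymes_constrained = length(ec$annotations$ec$enzymes),
    n_measured = length(ec$annotations$ec$measured),
    n_budget_released = n_budget_released,
    n_flexibilized = nrow(flex$records),
    n_reactions_ec = length(ec$reactions),
    skipped_iterations = length(smp$skipped),
    windows = utils::modifyList(DEFAULT_WINDOWS, config$windows %||% list()))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = ec, sample = smp, stats = stats,
                 net_stats = net_stats, normalized = norm, kapp = kapp,
                 turnovers = turnovers, flexibilization = flex,
                 manifest = manifest, proteome = prot, physiology = phys))
}
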