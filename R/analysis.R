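# Derived flux quantities: uptake-normalized fluxes, apparent catalytic
# activities (kapp = v / E), cofactor turnover and yield, and the NADPH
# allocation trade-off table.

#' Normalize net fluxes by the substrate uptake rate
#'
#' @param flux named numeric vector of net base-model fluxes, mmol/gDCW/h.
#' @param uptake specific substrate uptake rate, mmol/gDCW/h (> 0).
#' @return named vector of percentages (100 * v / uptake).
#' @export
normalize_by_uptake <- function(flux, uptake) {
  stopifnot(is.numeric(uptake), length(uptake) == 1, uptake > 0)
  100 * flux / uptake
}

#' Apparent catalytic activities
#'
#' `kapp = v / (E * 3600)` in 1/s, per enzyme-reaction pair: net flux in
#' mmol/gDCW/h divided by protein abundance in mmol/gDCW. Pairs with zero
#' or unmeasured abundance are excluded with a reason.
#'
#' @param flux named vector of net base-model fluxes, mmol/gDCW/h (typically
#'   sampling medians).
#' @param abundance named vector of enzyme abundances, mmol/gDCW.
#' @param pairs data.frame with columns `reaction`, `enzyme` mapping which
#'   enzyme catalyses which base reaction; optional column `kcat` (1/s) is
#'   carried through for comparison.
#' @return list with `table` (reaction, enzyme, flux, abundance, kapp,
#'   and kcat if supplied) and `excluded` (reaction, enzyme, reason).
#' @export
compute_kapp <- function(flux, abundance, pairs) {
  keep <- list()
  excl <- list()
  for (i in seq_len(nrow(pairs))) {
    rid <- pairs$reaction[i]
    e <- pairs$enzyme[i]
    v <- if (rid %in% names(flux)) flux[[rid]] else NA_real_
    E <- if (e %in% names(abundance)) abundance[[e]] else NA_real_
    if (is.na(E)) {
      excl[[length(excl) + 1L]] <- data.frame(
        reaction = rid, enzyme = e, reason = "unmeasured abundance",
        stringsAsFactors = FALSE)
      next
    }
    if (E <= 0) {
      excl[[length(excl) + 1L]] <- data.frame(
        reaction = rid, enzyme = e, reason = "zero abundance",
        stringsAsFactors = FALSE)
      next
    }
    row <- data.frame(reaction = rid, enzyme = e, flux = v, abundance = E,
                      kapp = abs(v) / (E * HOUR_PER_SEC),
                      stringsAsFactors = FALSE)
    if ("kcat" %in% names(pairs)) row$kcat <- pairs$kcat[i]
    keep[[length(keep) + 1L]] <- row
  }
  list(table = do.call(rbind, keep) %||%
         data.frame(reaction = character(), enzyme = character(),
                    flux = numeric(), abundance = numeric(),
                    kapp = numeric(), stringsAsFactors = FALSE),
       excluded = do.call(rbind, excl) %||%
         data.frame(reaction = character(), enzyme = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Cofactor turnover, per-reaction shares and yield
#'
#' Turnover of a cofactor is the production half-sum over all reactions and
#' all compartment instances of the metabolite:
#' `sum_r max(0, s_mr * v_r)`, which equals total consumption at steady
#' state (the "sum of fluxes involving" the cofactor without double
#' counting). Shares are per-reaction percentages of the turnover on the
#' production and consumption sides; yield is turnover divided by substrate
#' uptake.
#'
#' @param flux named vector of net base-model fluxes, mmol/gDCW/h.
#' @param model the base `metabolic_model`.
#' @param metabolite cofactor name, one of `"ATP"`, `"NADH"`, `"NADPH"`, or
#'   any metabolite id prefix; all compartment instances whose id starts
#'   with the lower-cased name + `"_"` are pooled (per-compartment analysis
#'   is available via `compartments`).
#' @param uptake substrate uptake rate for the yield, mmol/gDCW/h.
#' @param compartments optional compartment filter (e.g. `"c"`).
#' @return a `turnover_report`: list with `metabolite`, `turnover`,
#'   `yield`, `production` and `consumption` data.frames (reaction, flux
#'   contribution, share_pct).
#' @export
cofactor_turnover <- function(flux, model, metabolite, uptake = NA_real_,
                              compartments = NULL) {
  prefix <- paste0(tolower(metabolite), "_")
  ids <- model$metabolites$id[startsWith(model$metabolites$id, prefix)]
  if (!is.null(compartments)) {
    ids <- ids[model$metabolites$compartment[
      match(ids, model$metabolites$id)] %in% compartments]
  }
  if (!length(ids)) {
    stop("no metabolite instance matches '", metabolite, "'", call. = FALSE)
  }
  prod <- list()
  cons <- list()
  for (r in model$reactions) {
    touched <- intersect(names(r$stoich), ids)
    if (!length(touched)) next
    if (!r$id %in% names(flux)) next
    v <- flux[[r$id]]
    if (is.na(v)) next
    rate <- sum(r$stoich[touched]) * v  # mmol cofactor /gDCW/h, signed
    if (rate > 1e-12) {
      prod[[length(prod) + 1L]] <- data.frame(reaction = r$id, rate = rate,
                                              stringsAsFactors = FALSE)
    } else if (rate < -1e-12) {
      cons[[length(cons) + 1L]] <- data.frame(reaction = r$id, rate = -rate,
                                              stringsAsFactors = FALSE)
    }
  }
  ptab <- do.call(rbind, prod) %||%
    data.frame(reaction = character(), rate = numeric())
  ctab <- do.call(rbind, cons) %||%
    data.frame(reaction = character(), rate = numeric())
  turnover <- sum(ptab$rate)
  ptab$share_pct <- if (turnover > 0) 100 * ptab$rate / turnover else
    numeric(nrow(ptab))
  ctab$share_pct <- if (turnover > 0) 100 * ctab$rate / turnover else
    numeric(nrow(ctab))
  structure(list(metabolite = metabolite, turnover = turnover,
                 production = ptab[order(-ptab$rate), , drop = FALSE],
                 consumption = ctab[order(-ctab$rate), , drop = FALSE],
                 yield = if (is.finite(uptake) && uptake > 0)
                   turnover / uptake else NA_real_),
            class = "turnover_report")
}

#' NADPH (or other cofactor) allocation trade-off table
#'
#' Extracts the consumption shares of named reactions from one or more
#' turnover reports (e.g. glutamate dehydrogenase vs fatty acid synthase
#' across growth phases) and flags a reversal of the dominant consumer
#' between the first and last condition.
#'
#' @param reports named list of `turnover_report`s (one per condition).
#' @param reactions character vector of reaction ids of interest.
#' @return list with `table` (data.frame condition x reaction share %) and
#'   `dominant_switch` (logical).
#' @export
tradeoff_report <- function(reports, reactions) {
  if (inherits(reports, "turnover_report")) {
    reports <- list(condition = reports)
  }
  rows <- lapply(names(reports), function(cnd) {
    rep <- reports[[cnd]]
    shares <- vapply(reactions, function(rid) {
      hit <- rep$consumption$share_pct[rep$consumption$reaction == rid]
      if (length(hit)) hit else 0
    }, 0)
    cbind(data.frame(condition = cnd, stringsAsFactors = FALSE),
          as.data.frame(as.list(shares), check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  dom <- apply(tab[, reactions, drop = FALSE], 1, function(x)
    reactions[which.max(x)])
  list(table = tab,
       dominant_switch = length(dom) >= 2 && dom[1] != dom[length(dom)])
}
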