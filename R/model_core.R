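# Core data model for constraint-based metabolic networks: constructors,
# validation, JSON round-trip, the stoichiometric matrix, flux balance
# analysis (LP), model editing and scenario toggles.
#
# Conventions:
#   * fluxes in mmol/gDCW/h; uptake is a negative flux on an exchange reaction
#   * "unbounded" reactions carry the conventional default bounds +-1000
#   * exchange reactions touch exactly one metabolite

MODEL_FORMAT <- "ecflux-model v1"
DEFAULT_BOUND <- 1000

#' Create a reaction
#'
#' @param id unique reaction identifier.
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = substrate).
#' @param lb,ub flux bounds, mmol/gDCW/h.
#' @param name human-readable name.
#' @param gene_rule list of isozymes; each isozyme is a character vector of
#'   enzyme ids that are all required (AND within an isozyme, OR across).
#' @param subsystem pathway label.
#' @return a `reaction` list.
#' @export
new_reaction <- function(id, stoich, lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND,
                         name = id, gene_rule = list(), subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.numeric(stoich), length(stoich) >= 1L,
            !is.null(names(stoich)), all(nzchar(names(stoich))))
  if (!is.finite(lb) || !is.finite(ub) || lb > ub) {
    stop("reaction '", id, "': bounds must be finite with lb <= ub",
         call. = FALSE)
  }
  structure(list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
                 gene_rule = gene_rule, subsystem = subsystem),
            class = "reaction")
}

#' Create a metabolic model
#'
#' @param id model identifier.
#' @param compartments named character vector, compartment id -> name.
#' @param metabolites data.frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`, `charge`.
#' @param reactions list of [new_reaction()] objects.
#' @param enzymes optional data.frame with columns `id`, `genes`
#'   (";"-separated), `mw` (g/mmol) and `ec` (";"-separated EC numbers).
#' @param objective reaction id optimized by default.
#' @param annotations free-form list preserved opaquely through I/O.
#' @return validated object of class `metabolic_model`.
#' @export
new_model <- function(id, compartments, metabolites, reactions,
                      enzymes = NULL, objective, annotations = list()) {
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_real_
  if (is.null(enzymes)) {
    enzymes <- data.frame(id = character(), genes = character(),
                          mw = numeric(), ec = character(),
                          stringsAsFactors = FALSE)
  }
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  model <- structure(list(id = id, format = MODEL_FORMAT,
                          compartments = compartments,
                          metabolites = metabolites, reactions = reactions,
                          enzymes = enzymes, objective = objective,
                          annotations = annotations),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, stoichiometry keys that
#' resolve to metabolites, compartments drawn from the declared set, finite
#' ordered bounds, exchange reactions touching exactly one metabolite, and a
#' resolvable objective.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with the offending ids otherwise.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  errs <- character()
  if (anyDuplicated(mets$id)) {
    errs <- c(errs, paste0("duplicate metabolite ids: ",
                           paste(unique(mets$id[duplicated(mets$id)]),
                                 collapse = ", ")))
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    errs <- c(errs, paste0("duplicate reaction ids: ",
                           paste(unique(rids[duplicated(rids)]),
                                 collapse = ", ")))
  }
  bad_comp <- setdiff(mets$compartment, names(model$compartments))
  if (length(bad_comp)) {
    errs <- c(errs, paste0("undeclared compartment(s): ",
                           paste(bad_comp, collapse = ", ")))
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), mets$id)
    if (length(missing)) {
      errs <- c(errs, paste0("reaction '", r$id,
                             "' references unknown metabolite(s): ",
                             paste(missing, collapse = ", ")))
    }
    if (r$lb > r$ub) errs <- c(errs, paste0("reaction '", r$id, "': lb > ub"))
  }
  if (!model$objective %in% rids) {
    errs <- c(errs, paste0("objective '", model$objective,
                           "' is not a reaction id"))
  }
  if (length(errs)) {
    stop("model validation failed:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoich_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"))
}

#' Is a reaction an exchange reaction?
#'
#' Exchange reactions touch exactly one metabolite.
#' @param model a `metabolic_model`.
#' @return named logical vector over reactions.
#' @export
is_exchange <- function(model) {
  vapply(model$reactions, function(r) length(r$stoich) == 1L, NA)
}

#' Flux balance analysis
#'
#' Solves `optimize c'v  s.t.  S v = 0, lb <= v <= ub` with the package's
#' bounded-variable simplex. Infeasibility and unboundedness are reported in
#' the `status` field, never as silent zeros.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id (default: the model objective).
#' @param sense `"max"` or `"min"`.
#' @return a `flux_distribution`: list with `flux` (named vector),
#'   `objective_value`, `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `dual` (metabolite shadow prices) and `reduced_cost`.
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- objective %||% model$objective
  if (!objective %in% names(model$reactions)) {
    stop("objective reaction '", objective, "' not in model", call. = FALSE)
  }
  S <- stoich_matrix(model)
  bnd <- reaction_bounds(model)
  cc <- as.numeric(names(model$reactions) == objective)
  res <- .simplex_bounded(S, rep(0, nrow(S)), cc, bnd$lb, bnd$ub,
                          sense == "max")
  if (res$status %in% c("maxit", "numerical_failure")) {
    stop("LP solver failed (", res$status, ") on model '", model$id, "'",
         call. = FALSE)
  }
  flux <- setNames(as.numeric(res$x), names(model$reactions))
  structure(list(flux = flux,
                 objective_value = if (res$status == "optimal")
                   res$objective else NA_real_,
                 status = res$status,
                 dual = setNames(as.numeric(res$dual), rownames(S)),
                 reduced_cost = setNames(as.numeric(res$reduced_cost),
                                         names(model$reactions))),
            class = "flux_distribution")
}

# Linear-objective LP over the flux space of `model`; weights is a named
# numeric vector on reaction ids. Optionally adds one extra linear row
# (extra_row, named coefficients) constrained to [extra_lb, extra_ub] via a
# slack column. Used by the sampler's parsimonious step.
optimize_flux <- function(model, weights, maximize = TRUE,
                          extra_row = NULL, extra_lb = NULL, extra_ub = NULL) {
  S <- stoich_matrix(model)
  bnd <- reaction_bounds(model)
  cc <- setNames(rep(0, ncol(S)), colnames(S))
  cc[names(weights)] <- weights
  lb <- bnd$lb
  ub <- bnd$ub
  if (!is.null(extra_row)) {
    row <- setNames(rep(0, ncol(S)), colnames(S))
    row[names(extra_row)] <- extra_row
    S <- rbind(S, row)
    S <- cbind(S, slack = c(rep(0, nrow(S) - 1), -1))
    lb <- c(lb, extra_lb)
    ub <- c(ub, extra_ub)
    cc <- c(cc, 0)
  }
  res <- .simplex_bounded(S, rep(0, nrow(S)), as.numeric(cc), lb, ub, maximize)
  res$x <- setNames(as.numeric(res$x)[seq_along(model$reactions)],
                    names(model$reactions))
  res
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under the model's current bounds.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids (default: all).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = names(model$reactions)) {
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    w <- setNames(1, reactions[i])
    lo <- optimize_flux(model, w, maximize = FALSE)
    hi <- optimize_flux(model, w, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA: model not solvable for reaction ", reactions[i],
           call. = FALSE)
    }
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  out
}

#' Exhaustive vertex-enumeration reference optimum
#'
#' Enumerates every basic feasible solution of `S v = 0, lb <= v <= ub`
#' (all choices of basis columns crossed with all lower/upper assignments of
#' the nonbasic variables) and returns the best objective value. Exponential
#' in model size; intended as an exact reference on models with at most about
#' a dozen reactions.
#'
#' @param model a `metabolic_model` (small).
#' @param objective reaction id.
#' @param sense `"max"` or `"min"`.
#' @return list with `objective_value` (NA if infeasible) and `status`.
#' @export
fba_enumerate <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- objective %||% model$objective
  S <- stoich_matrix(model)
  bnd <- reaction_bounds(model)
  n <- ncol(S)
  if (n > 14) stop("fba_enumerate is restricted to small models", call. = FALSE)
  # drop linearly dependent / all-zero rows to get a full-rank system
  qrS <- qr(t(S))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  S <- S[keep, , drop = FALSE]
  m <- nrow(S)
  cc <- as.numeric(colnames(S) == objective)
  best <- NA_real_
  better <- if (sense == "max") function(a, b) a > b else function(a, b) a < b
  combs <- if (m > 0) utils::combn(n, m) else matrix(integer(), 0, 1)
  for (k in seq_len(ncol(combs))) {
    Bi <- combs[, k]
    B <- S[, Bi, drop = FALSE]
    if (m > 0 && abs(det(B)) < 1e-10) next
    Ni <- setdiff(seq_len(n), Bi)
    for (mask in 0:(2^length(Ni) - 1)) {
      xN <- bnd$lb[Ni]
      if (length(Ni)) {
        sel <- bitwAnd(mask, 2^(seq_along(Ni) - 1)) > 0
        xN[sel] <- bnd$ub[Ni][sel]
      }
      rhs <- -if (length(Ni)) S[, Ni, drop = FALSE] %*% xN else rep(0, m)
      xB <- if (m > 0) solve(B, rhs) else numeric(0)
      if (any(xB < bnd$lb[Bi] - 1e-9) || any(xB > bnd$ub[Bi] + 1e-9)) next
      x <- numeric(n)
      x[Bi] <- xB
      x[Ni] <- xN
      obj <- sum(cc * x)
      if (is.na(best) || better(obj, best)) best <- obj
    }
  }
  list(objective_value = best,
       status = if (is.na(best)) "infeasible" else "optimal")
}

#' Add metabolites and reactions to a model
#'
#' Used e.g. to graft an alternative assimilation pathway onto an existing
#' network. New ids must not collide with existing ones. When elemental
#' formulas are available for all participants of a new reaction, an element
#' imbalance triggers a warning naming the unbalanced elements.
#'
#' @param model a `metabolic_model`.
#' @param new_mets data.frame like `model$metabolites` (may be NULL).
#' @param new_rxns list of [new_reaction()] objects.
#' @return the extended, validated model.
#' @export
add_pathway <- function(model, new_mets = NULL, new_rxns = list()) {
  if (!is.null(new_mets) && nrow(new_mets)) {
    clash <- intersect(new_mets$id, model$metabolites$id)
    if (length(clash)) {
      stop("metabolite id(s) already present: ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
    if (is.null(new_mets$formula)) new_mets$formula <- NA_character_
    if (is.null(new_mets$charge)) new_mets$charge <- NA_real_
    model$metabolites <- rbind(
      model$metabolites,
      new_mets[, c("id", "name", "compartment", "formula", "charge")])
  }
  for (r in new_rxns) {
    if (r$id %in% names(model$reactions)) {
      stop("reaction id already present: ", r$id, call. = FALSE)
    }
    model$reactions[[r$id]] <- r
    imb <- element_imbalance(model, r)
    if (!is.null(imb)) {
      warning("reaction '", r$id, "' is elementally unbalanced: ",
              paste(names(imb), round(imb, 6), sep = "=", collapse = ", "),
              call. = FALSE)
    }
  }
  validate_model(model)
  model
}

# Returns NULL when balanced or when any participant lacks a formula;
# otherwise a named vector of net element excess (product side).
element_imbalance <- function(model, rxn) {
  mets <- model$metabolites
  idx <- match(names(rxn$stoich), mets$id)
  fml <- mets$formula[idx]
  if (any(is.na(fml))) return(NULL)
  tot <- numeric()
  for (i in seq_along(fml)) {
    cnt <- parse_formula(fml[i]) * rxn$stoich[i]
    for (e in names(cnt)) tot[e] <- (if (e %in% names(tot)) tot[e] else 0) + cnt[e]
  }
  tot <- tot[abs(tot) > 1e-6]
  if (length(tot)) tot else NULL
}

#' Apply a predefined scenario toggle
#'
#' Scenario edits used in the flux-comparison analyses:
#' * `"block_xpk"` - set both bounds of the phosphoketolase reaction to 0;
#' * `"swap_pta_to_ack"` - remove the phosphotransacetylase route and add an
#'   acetate-kinase reaction (acetyl phosphate + ADP -> acetate + ATP);
#' * `"dad2_nad_cofactor"` - replace NADP/NADPH by NAD/NADH in the
#'   D-arabinitol 2-dehydrogenase (LXR) reaction;
#' * `"none"` - identity.
#'
#' @param model a `metabolic_model`.
#' @param scenario one of the scenario names above.
#' @param targets named list of reaction/metabolite ids the scenarios act on;
#'   the defaults match the ids produced by [make_toy_network()].
#' @return the edited model.
#' @export
apply_scenario <- function(model,
                           scenario = c("none", "block_xpk",
                                        "swap_pta_to_ack",
                                        "dad2_nad_cofactor"),
                           targets = list()) {
  scenario <- match.arg(scenario)
  tg <- utils::modifyList(
    list(xpk = "XPK", pta = "PTA", ack = "ACK", dad2 = "DAD2",
         acp = "acp_c", adp = "adp_c", atp = "atp_c", ac = "ac_c",
         nadp = "nadp_c", nadph = "nadph_c", nad = "nad_c", nadh = "nadh_c"),
    targets)
  need <- function(id) {
    if (!id %in% names(model$reactions)) {
      stop("scenario '", scenario, "': reaction '", id, "' not in model",
           call. = FALSE)
    }
  }
  if (scenario == "none") return(model)
  if (scenario == "block_xpk") {
    need(tg$xpk)
    model$reactions[[tg$xpk]]$lb <- 0
    model$reactions[[tg$xpk]]$ub <- 0
    return(model)
  }
  if (scenario == "swap_pta_to_ack") {
    need(tg$pta)
    model$reactions[[tg$pta]] <- NULL
    ack <- new_reaction(tg$ack, setNames(c(-1, -1, 1, 1),
                                         c(tg$acp, tg$adp, tg$ac, tg$atp)),
                        lb = 0, ub = DEFAULT_BOUND,
                        name = "acetate kinase",
                        gene_rule = list("E_ACK"), subsystem = "XPK pathway")
    model <- add_pathway(model, new_rxns = list(ack))
    if (!"E_ACK" %in% model$enzymes$id) {
      model$enzymes <- rbind(model$enzymes,
                             data.frame(id = "E_ACK", genes = "E_ACK",
                                        mw = 44, ec = "2.7.2.1",
                                        stringsAsFactors = FALSE))
    }
    return(model)
  }
  # dad2_nad_cofactor
  need(tg$dad2)
  st <- model$reactions[[tg$dad2]]$stoich
  for (swap in list(c(tg$nadp, tg$nad), c(tg$nadph, tg$nadh))) {
    if (swap[1] %in% names(st)) {
      coef <- st[[swap[1]]]
      st <- st[names(st) != swap[1]]
      st[swap[2]] <- (if (swap[2] %in% names(st)) st[[swap[2]]] else 0) + coef
    }
  }
  model$reactions[[tg$dad2]]$stoich <- st
  validate_model(model)
  model
}
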