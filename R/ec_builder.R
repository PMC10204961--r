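# GECKO-style enzyme-constrained model construction.
#
# The enzyme constraint v <= E * kcat (E in mmol/gDCW, kcat in 1/s) is encoded
# by giving every catalysed reaction a coefficient -1/(kcat*3600) on its
# enzyme's pseudo-metabolite (3600 converts 1/s to 1/h), balanced by a usage
# ("draw") reaction whose flux equals the enzyme concentration. Unmeasured
# enzymes draw from a shared protein pool (g/gDCW) weighted by molecular
# weight; the pool exchange is capped at sigma * f * Ptot.

PROT_PREFIX <- "pmet_"     # enzyme pseudo-metabolite ids
DRAW_PREFIX <- "draw_"     # enzyme usage reaction ids
ARM_PREFIX <- "arm_"       # arm reactions for isozyme splits
ARM_MET_PREFIX <- "armm_"  # arm intermediate pseudo-metabolites
POOL_MET <- "prot_pool"
POOL_RXN <- "prot_pool_exchange"
REV_SUFFIX <- "_REV"
HOUR_PER_SEC <- 3600

#' Split reversible reactions into forward/reverse pairs
#'
#' Every reaction with `lb < 0` becomes a forward copy (bounds `[0, ub]`,
#' original id) and a reverse copy with negated stoichiometry (bounds
#' `[0, -lb]`, id suffixed `_REV`). Reactions with `ub <= 0` keep only the
#' reverse copy. The forward/reverse mapping is retained in
#' `model$annotations$rev_map` for [map_to_base()].
#'
#' @param model a `metabolic_model`.
#' @return an irreversible model (all `lb >= 0`).
#' @export
split_reversible <- function(model) {
  out <- list()
  rev_map <- list()
  for (r in model$reactions) {
    if (r$lb >= 0) {
      out[[r$id]] <- r
      rev_map[[r$id]] <- list(base = r$id, dir = 1)
      next
    }
    if (r$ub > 0) {
      fwd <- r
      fwd$lb <- 0
      out[[fwd$id]] <- fwd
      rev_map[[fwd$id]] <- list(base = r$id, dir = 1)
    }
    rev <- r
    rev$id <- paste0(r$id, REV_SUFFIX)
    rev$stoich <- -r$stoich
    rev$lb <- max(0, -r$ub)  # ub < 0 forces the reverse direction
    rev$ub <- -r$lb
    out[[rev$id]] <- rev
    rev_map[[rev$id]] <- list(base = r$id, dir = -1)
  }
  model$reactions <- out
  model$annotations$rev_map <- rev_map
  validate_model(model)
  model
}

#' Expand multi-isozyme reactions into enzyme-specific copies
#'
#' Each reaction catalysed by `N >= 2` alternative isozymes becomes `N`
#' copies plus one arm reaction: the arm converts the substrates into an
#' intermediate pseudo-metabolite, and each copy converts the intermediate
#' into the products, so copy fluxes sum exactly to the arm flux.
#' Single-isozyme reactions are left untouched.
#'
#' @param model an irreversible `metabolic_model`.
#' @return the expanded model; the copy/parent mapping is kept in
#'   `model$annotations$iso_map`.
#' @export
expand_isozymes <- function(model) {
  bnd <- reaction_bounds(model)
  if (any(bnd$lb < 0)) {
    stop("expand_isozymes requires an irreversible model; run ",
         "split_reversible() first", call. = FALSE)
  }
  out <- list()
  iso_map <- list()
  new_mets <- list()
  for (r in model$reactions) {
    if (length(r$gene_rule) < 2) {
      out[[r$id]] <- r
      iso_map[[r$id]] <- list(parent = r$id, kind = "plain")
      next
    }
    arm_met <- paste0(ARM_MET_PREFIX, r$id)
    new_mets[[arm_met]] <- data.frame(
      id = arm_met, name = paste0("arm intermediate of ", r$id),
      compartment = "pseudo", formula = NA_character_, charge = NA_real_,
      stringsAsFactors = FALSE)
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    arm <- new_reaction(paste0(ARM_PREFIX, r$id),
                        c(subs, setNames(1, arm_met)),
                        lb = 0, ub = r$ub,
                        name = paste0("arm of ", r$name),
                        subsystem = r$subsystem)
    out[[arm$id]] <- arm
    iso_map[[arm$id]] <- list(parent = r$id, kind = "arm")
    for (k in seq_along(r$gene_rule)) {
      cp <- new_reaction(paste0(r$id, "_iso", k),
                         c(setNames(-1, arm_met), prods),
                         lb = 0, ub = r$ub,
                         name = paste0(r$name, " (isozyme ", k, ")"),
                         gene_rule = r$gene_rule[k],
                         subsystem = r$subsystem)
      out[[cp$id]] <- cp
      iso_map[[cp$id]] <- list(parent = r$id, kind = "copy")
    }
  }
  if (length(new_mets)) {
    model$metabolites <- rbind(model$metabolites, do.call(rbind, new_mets))
    if (!"pseudo" %in% names(model$compartments)) {
      model$compartments <- c(model$compartments, pseudo = "pseudo")
    }
  }
  model$reactions <- out
  model$annotations$iso_map <- iso_map
  validate_model(model)
  model
}

#' Read a kcat database table
#'
#' @param path TSV with columns `ec_number`, `substrate`, `organism`,
#'   `kcat_per_s` and optionally `source`.
#' @return data.frame of kcat records (kcat > 0 enforced).
#' @export
read_kcat_db <- function(path) {
  db <- read_tsv_checked(path, c("ec_number", "substrate", "organism",
                                 "kcat_per_s"))
  if (any(db$kcat_per_s <= 0)) {
    stop("kcat database contains non-positive kcat values", call. = FALSE)
  }
  db
}

ec_matches <- function(query, target) {
  # query may carry wildcards ('-' or '*') in any field
  qf <- strsplit(query, ".", fixed = TRUE)[[1]]
  tf <- strsplit(target, ".", fixed = TRUE)[[1]]
  if (length(qf) != 4 || length(tf) != 4) return(FALSE)
  all(qf %in% c("-", "*") | qf == tf)
}

#' Match kcat values to enzymatic reactions with stepwise relaxation
#'
#' For every reaction with a gene rule, queries the kcat table in strictly
#' ordered relaxation levels: (1) EC + substrate + organism; (2) EC +
#' substrate, any organism; (3) EC + organism, any substrate; (4) EC only;
#' (5) EC with the last field wildcarded. Within a level the maximum kcat is
#' taken (GECKO convention; `aggregate = "median"` is available). Substrates
#' are compared case-insensitively against the names of the reaction's
#' consumed metabolites.
#'
#' @param model an irreversible, isozyme-expanded `metabolic_model`.
#' @param kcat_db data.frame from [read_kcat_db()].
#' @param organism organism name for levels 1 and 3.
#' @param aggregate within-level aggregation, `"max"` (default) or
#'   `"median"`.
#' @return list with `assignment` (data.frame: reaction, enzyme, kcat,
#'   level) and `unmatched` (enzyme ids excluded from constraints).
#' @export
match_kcats <- function(model, kcat_db, organism,
                        aggregate = c("max", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "max") max else median
  enz <- model$enzymes
  met_names <- setNames(tolower(model$metabolites$name),
                        model$metabolites$id)
  rows <- list()
  unmatched <- character()
  for (r in model$reactions) {
    if (!length(r$gene_rule)) next
    subs <- names(r$stoich)[r$stoich < 0]
    sub_names <- unname(met_names[subs])
    for (iso in r$gene_rule) {
      for (e in iso) {
        ei <- match(e, enz$id)
        if (is.na(ei)) {
          stop("reaction '", r$id, "' references enzyme '", e,
               "' absent from the enzyme table", call. = FALSE)
        }
        ecs <- strsplit(enz$ec[ei], ";")[[1]]
        hit <- match_one_kcat(ecs, sub_names, organism, kcat_db, agg)
        if (is.null(hit)) {
          unmatched <- c(unmatched, e)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            reaction = r$id, enzyme = e, kcat = hit$kcat, level = hit$level,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  assignment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction = character(), enzyme = character(),
               kcat = numeric(), level = integer(), stringsAsFactors = FALSE)
  unmatched <- sort(unique(unmatched))
  if (length(unmatched)) {
    message("match_kcats: no kcat found for ", length(unmatched),
            " enzyme(s): ", paste(unmatched, collapse = ", "),
            "; they remain unconstrained")
  }
  list(assignment = assignment, unmatched = unmatched)
}

match_one_kcat <- function(ecs, sub_names, organism, db, agg) {
  db_sub <- tolower(db$substrate)
  db_org <- tolower(db$organism)
  org <- tolower(organism)
  for (level in 1:5) {
    vals <- numeric()
    for (ec in ecs) {
      ecq <- ec
      if (level == 5) {
        f <- strsplit(ec, ".", fixed = TRUE)[[1]]
        if (length(f) == 4) ecq <- paste(c(f[1:3], "-"), collapse = ".")
      }
      ec_ok <- vapply(db$ec_number, function(t) ec_matches(ecq, t), NA)
      sub_ok <- db_sub %in% sub_names
      org_ok <- db_org == org
      keep <- switch(level,
                     ec_ok & sub_ok & org_ok,  # 1
                     ec_ok & sub_ok,           # 2
                     ec_ok & org_ok,           # 3
                     ec_ok,                    # 4
                     ec_ok)                    # 5 (wildcarded EC)
      vals <- c(vals, db$kcat_per_s[keep])
    }
    if (length(vals)) return(list(kcat = agg(vals), level = level))
  }
  NULL
}

#' Build an enzyme-constrained model
#'
#' Adds one pseudo-metabolite and one usage reaction per constrained enzyme,
#' writes `-1/(kcat*3600)` coefficients into the catalysed reactions, and a
#' shared protein pool with exchange capped at `sigma * f * Ptot` (g/gDCW)
#' from which usage reactions draw weighted by molecular weight. For enzyme
#' complexes (AND within an isozyme) every subunit receives its own balance
#' with the same kcat.
#'
#' @param model an irreversible, isozyme-expanded `metabolic_model`.
#' @param kcats result of [match_kcats()], or a compatible `assignment`
#'   data.frame.
#' @param sigma average enzyme saturation factor in (0, 1].
#' @param f mass fraction of the proteome covered by model enzymes in (0, 1].
#' @param Ptot total protein content, g protein/gDCW.
#' @return an `ec_model` (subclass of `metabolic_model`) with fields
#'   `kcat_assignment`, `provenance`, and pool bookkeeping in
#'   `annotations$ec`.
#' @export
build_ec_model <- function(model, kcats, sigma = 0.35, f = 0.5, Ptot = 0.5) {
  stopifnot(sigma > 0, sigma <= 1, f > 0, f <= 1, Ptot > 0)
  if (is.list(kcats) && !is.data.frame(kcats)) kcats <- kcats$assignment
  if (any(kcats$kcat <= 0)) stop("kcat <= 0 in assignment", call. = FALSE)
  bnd <- reaction_bounds(model)
  if (any(bnd$lb < 0)) {
    stop("build_ec_model requires an irreversible model", call. = FALSE)
  }
  enz <- model$enzymes
  used <- sort(unique(kcats$enzyme))
  mw <- setNames(enz$mw, enz$id)[used]
  if (any(is.na(mw))) {
    stop("missing molecular weight for enzyme(s): ",
         paste(used[is.na(mw)], collapse = ", "), call. = FALSE)
  }
  # enzyme pseudo-metabolites + pool metabolite
  pseudo <- data.frame(
    id = c(paste0(PROT_PREFIX, used), POOL_MET),
    name = c(paste0("enzyme ", used), "protein pool"),
    compartment = "pseudo", formula = NA_character_, charge = NA_real_,
    stringsAsFactors = FALSE)
  model$metabolites <- rbind(model$metabolites, pseudo)
  if (!"pseudo" %in% names(model$compartments)) {
    model$compartments <- c(model$compartments, pseudo = "pseudo")
  }
  # kcat coefficients on catalysed reactions
  for (i in seq_len(nrow(kcats))) {
    rid <- kcats$reaction[i]
    e <- kcats$enzyme[i]
    coef <- -1 / (kcats$kcat[i] * HOUR_PER_SEC)
    model$reactions[[rid]]$stoich[paste0(PROT_PREFIX, e)] <- coef
  }
  # usage reactions: pool (g) -> enzyme pseudo-metabolite (mmol), MW-weighted
  pool_ub <- sigma * f * Ptot
  for (e in used) {
    dr <- new_reaction(paste0(DRAW_PREFIX, e),
                       setNames(c(-mw[[e]], 1),
                                c(POOL_MET, paste0(PROT_PREFIX, e))),
                       lb = 0, ub = DEFAULT_BOUND,
                       name = paste0("usage of enzyme ", e),
                       subsystem = "enzyme usage")
    model$reactions[[dr$id]] <- dr
  }
  pool <- new_reaction(POOL_RXN, setNames(1, POOL_MET), lb = 0, ub = pool_ub,
                       name = "protein pool exchange",
                       subsystem = "enzyme usage")
  model$reactions[[POOL_RXN]] <- pool
  model$kcat_assignment <- kcats
  model$provenance <- kcats[, c("reaction", "enzyme", "level")]
  model$annotations$ec <- list(sigma = sigma, f = f, Ptot = Ptot,
                               pool_ub = pool_ub, enzymes = used,
                               measured = character(0))
  class(model) <- c("ec_model", class(model))
  validate_model(model)
  model
}

#' Pool upper bound of an EC model
#' @param ec an `ec_model`.
#' @return pool exchange upper bound, g/gDCW.
#' @export
pool_upper_bound <- function(ec) ec$reactions[[POOL_RXN]]$ub

#' Identify and relax growth-limiting kcat values
#'
#' Iteratively solves for maximal growth, ranks constrained enzymes by the
#' finite-difference growth gain from scaling their kcat up by 10% (ties
#' broken lexicographically by enzyme id), and replaces the top-ranked kcat
#' with the database maximum for that enzyme's EC numbers. Stops when the
#' target growth is reached, no candidate improves, or `max_steps` is hit.
#' Finite differences are used instead of the enzyme-balance shadow price
#' because the pool-coupled LP is routinely dual-degenerate at its optimum,
#' which makes shadow prices ambiguous.
#'
#' @param ec an `ec_model`.
#' @param target_growth target objective value (1/h).
#' @param kcat_db kcat record data.frame used for replacement maxima.
#' @param max_steps safety cap on replacements.
#' @return list with `model` (possibly updated), `trace` (data.frame of
#'   replacements: enzyme, reaction, old_kcat, new_kcat, growth_after) and
#'   `achieved` (final growth). If the target is unreachable the trace is
#'   returned with the final gap in `gap`.
#' @export
sensitivity_top_kcat <- function(ec, target_growth, kcat_db,
                                 max_steps = 25) {
  trace <- list()
  enz <- ec$enzymes
  db_max_for <- function(e) {
    ecs <- strsplit(enz$ec[match(e, enz$id)], ";")[[1]]
    hits <- vapply(kcat_db$ec_number, function(t)
      any(vapply(ecs, function(q) ec_matches(q, t) || ec_matches(t, q), NA)),
      NA)
    if (!any(hits)) return(NA_real_)
    max(kcat_db$kcat_per_s[hits])
  }
  scale_kcat <- function(m, e, factor = NULL, value = NULL) {
    asg <- m$kcat_assignment
    rows <- which(asg$enzyme == e)
    for (i in rows) {
      asg$kcat[i] <- if (is.null(value)) asg$kcat[i] * factor else value
      m$reactions[[asg$reaction[i]]]$stoich[paste0(PROT_PREFIX, e)] <-
        -1 / (asg$kcat[i] * HOUR_PER_SEC)
    }
    m$kcat_assignment <- asg
    m
  }
  repeat {
    sol <- fba(ec)
    growth <- if (sol$status == "optimal") sol$objective_value else 0
    if (growth >= target_growth * (1 - 1e-6)) break
    if (length(trace) >= max_steps) break
    # finite-difference sensitivity: growth gain from a +10% kcat bump
    asg <- ec$kcat_assignment
    cand <- sort(unique(asg$enzyme))
    gains <- vapply(cand, function(e) {
      s <- fba(scale_kcat(ec, e, factor = 1.1))
      (if (s$status == "optimal") s$objective_value else 0) - growth
    }, 0)
    picked <- NA_character_
    for (idx in order(-gains, cand)) {
      e <- cand[idx]
      if (gains[idx] <= 1e-12) break
      newk <- db_max_for(e)
      oldk <- max(asg$kcat[asg$enzyme == e])
      if (!is.na(newk) && newk > oldk * (1 + 1e-9)) {
        picked <- e
        break
      }
    }
    if (is.na(picked)) break
    rows <- which(asg$enzyme == picked)
    newk <- db_max_for(picked)
    old_kcat <- max(asg$kcat[rows])
    for (i in rows) {
      asg$kcat[i] <- newk
      rid <- asg$reaction[i]
      ec$reactions[[rid]]$stoich[paste0(PROT_PREFIX, picked)] <-
        -1 / (newk * HOUR_PER_SEC)
    }
    ec$kcat_assignment <- asg
    sol2 <- fba(ec)
    trace[[length(trace) + 1L]] <- data.frame(
      enzyme = picked, reaction = asg$reaction[rows[1]],
      old_kcat = old_kcat, new_kcat = newk,
      growth_after = if (sol2$status == "optimal")
        sol2$objective_value else 0,
      stringsAsFactors = FALSE)
  }
  sol <- fba(ec)
  achieved <- if (sol$status == "optimal") sol$objective_value else 0
  list(model = ec,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(enzyme = character(), reaction = character(),
                    old_kcat = numeric(), new_kcat = numeric(),
                    growth_after = numeric(), stringsAsFactors = FALSE),
       achieved = achieved,
       gap = max(0, target_growth - achieved))
}

#' Mass-wise top used enzymes of a solution
#'
#' Usage mass of enzyme e is `usage_e * MW_e` (g/gDCW). Entries above 1% of
#' the protein pool are flagged, following the curation rule of iterating
#' until no single enzyme holds more than 1% of the pool.
#'
#' @param ec an `ec_model`.
#' @param solution a `flux_distribution` for `ec`.
#' @param n number of rows to return (clipped to the enzyme count).
#' @return data.frame: enzyme, usage_mmol, mass_g, pct_pool, flagged;
#'   sorted by descending mass.
#' @export
top_used_enzymes <- function(ec, solution, n = 10) {
  used <- ec$annotations$ec$enzymes
  mw <- setNames(ec$enzymes$mw, ec$enzymes$id)
  usage <- vapply(used, function(e)
    solution$flux[[paste0(DRAW_PREFIX, e)]], 0)
  mass <- usage * mw[used]
  pool <- ec$annotations$ec$pool_ub
  df <- data.frame(enzyme = used, usage_mmol = unname(usage),
                   mass_g = unname(mass),
                   pct_pool = unname(100 * mass / pool),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$mass_g, df$enzyme), ]
  df$flagged <- df$pct_pool > 1
  head(df, min(n, nrow(df)))
}

#' Apply manual kcat curation entries
#'
#' @param ec an `ec_model`.
#' @param entries data.frame with columns `enzyme_id`, `new_kcat_per_s` and
#'   optionally `reaction_id` (default: all reactions of that enzyme) and
#'   `rationale`.
#' @return the updated `ec_model`; provenance level of curated entries is
#'   set to the marker value 0 ("curated").
#' @export
apply_kcat_curation <- function(ec, entries) {
  if (!nrow(entries)) return(ec)
  if (any(entries$new_kcat_per_s <= 0)) {
    stop("curated kcat must be positive", call. = FALSE)
  }
  asg <- ec$kcat_assignment
  for (i in seq_len(nrow(entries))) {
    e <- entries$enzyme_id[i]
    rid <- if (!is.null(entries$reaction_id) &&
               !is.na(entries$reaction_id[i]) &&
               nzchar(entries$reaction_id[i])) entries$reaction_id[i] else NA
    rows <- which(asg$enzyme == e & (is.na(rid) | asg$reaction == rid))
    if (!length(rows)) {
      stop("curation entry targets unknown enzyme/reaction: ", e,
           if (!is.na(rid)) paste0("/", rid), call. = FALSE)
    }
    for (j in rows) {
      asg$kcat[j] <- entries$new_kcat_per_s[i]
      asg$level[j] <- 0L
      ec$reactions[[asg$reaction[j]]]$stoich[paste0(PROT_PREFIX, e)] <-
        -1 / (entries$new_kcat_per_s[i] * HOUR_PER_SEC)
    }
  }
  ec$kcat_assignment <- asg
  ec$provenance <- asg[, c("reaction", "enzyme", "level")]
  ec
}
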