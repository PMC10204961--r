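# Random sampling of the constrained flux solution space: per iteration a
# random set of three interior reactions receives random weights, their
# weighted sum is maximized, and the solution is made parsimonious by
# minimizing total flux while holding the achieved objective. Summary
# statistics (median, SD, variability %) and mapping back to the base-model
# formalism.

#' Sample the flux solution space with random parsimonious objectives
#'
#' Per iteration: draw 3 distinct eligible reactions uniformly (interior
#' reactions only - exchanges, enzyme usage reactions and the pool drain are
#' excluded), draw i.i.d. weights uniform on (0, 1], maximize the weighted
#' flux sum, then minimize total flux subject to keeping that objective
#' within 1e-6 relative (parsimonious step). Fully reproducible given
#' `seed`; a failed iteration is retried once, then skipped with a warning.
#'
#' @param ec an irreversible (EC) model, feasible under its current bounds.
#' @param n_iter number of sampling iterations (2000 for production runs).
#' @param seed integer master seed.
#' @param eligible optional character vector overriding the eligible
#'   reaction set.
#' @return a `flux_sample`: list with `matrix` (n_iter x reactions),
#'   `seed`, `n_iter`, `skipped`.
#' @export
sample_fluxes <- function(ec, n_iter = 2000, seed = 1, eligible = NULL) {
  bnd <- reaction_bounds(ec)
  if (any(bnd$lb < 0)) {
    stop("sample_fluxes expects an irreversible model", call. = FALSE)
  }
  base_sol <- fba(ec)
  if (base_sol$status != "optimal") {
    stop("model infeasible under current constraint windows; cannot sample",
         call. = FALSE)
  }
  rids <- names(ec$reactions)
  if (is.null(eligible)) {
    excl <- is_exchange(ec) | startsWith(rids, DRAW_PREFIX) |
      rids == POOL_RXN
    eligible <- rids[!excl]
  }
  if (!length(eligible)) {
    stop("no eligible reactions for random objectives", call. = FALSE)
  }
  n_pick <- min(3L, length(eligible))
  set.seed(seed)
  mat <- matrix(NA_real_, n_iter, length(rids),
                dimnames = list(NULL, rids))
  skipped <- integer()
  all_ones <- setNames(rep(1, length(rids)), rids)
  # solution polishing: enzyme usage reactions are recomputed exactly from
  # their balance rows (zeroing the LP residual on the capacity identity),
  # then the pool drain is rebalanced; deviations are at solver-residual
  # scale and stay within the bound tolerance
  S <- stoich_matrix(ec)
  pmet_rows <- grep(paste0("^", PROT_PREFIX), rownames(S), value = TRUE)
  polish <- function(v) {
    for (pm in pmet_rows) {
      e <- sub(paste0("^", PROT_PREFIX), "", pm)
      dr <- paste0(DRAW_PREFIX, e)
      if (!dr %in% rids) next
      row <- S[pm, ]
      v[dr] <- -(sum(row * v) - row[[dr]] * v[[dr]]) / row[[dr]]
    }
    if (POOL_MET %in% rownames(S) && POOL_RXN %in% rids) {
      row <- S[POOL_MET, ]
      v[POOL_RXN] <- -(sum(row * v) - row[[POOL_RXN]] * v[[POOL_RXN]]) /
        row[[POOL_RXN]]
    }
    v
  }
  for (it in seq_len(n_iter)) {
    ok <- FALSE
    for (attempt in 1:2) {
      # the retry draws a fresh random objective from the seeded stream
      picks <- sample(eligible, n_pick)
      wts <- setNames(1 - runif(n_pick), picks)  # uniform on (0, 1]
      r1 <- optimize_flux(ec, wts, maximize = TRUE)
      if (r1$status != "optimal") next
      obj <- r1$objective
      lo <- obj - max(abs(obj) * 1e-6, 1e-9)
      r2 <- optimize_flux(ec, all_ones, maximize = FALSE,
                          extra_row = wts, extra_lb = lo,
                          extra_ub = DEFAULT_BOUND * length(wts) * 10)
      if (r2$status != "optimal") next
      mat[it, ] <- polish(r2$x)
      ok <- TRUE
      break
    }
    if (!ok) skipped <- c(skipped, it)
  }
  if (length(skipped)) {
    warning("sample_fluxes: ", length(skipped),
            " iteration(s) failed twice and were skipped", call. = FALSE)
    mat <- mat[-skipped, , drop = FALSE]
  }
  structure(list(matrix = mat, seed = seed, n_iter = n_iter,
                 skipped = skipped),
            class = "flux_sample")
}

#' Per-reaction summary statistics of a flux sample
#'
#' Flux value = median over iterations; variability % = 100 * SD / |median|,
#' reported as `NA` (undefined) when |median| < 1e-9 rather than infinity.
#'
#' @param sample a `flux_sample` or a plain numeric matrix (iterations x
#'   reactions).
#' @return data.frame: reaction, median, sd, variability_pct.
#' @export
flux_statistics <- function(sample) {
  mat <- if (inherits(sample, "flux_sample")) sample$matrix else sample
  if (nrow(mat) < 2) stop("need >= 2 iterations for statistics",
                          call. = FALSE)
  med <- apply(mat, 2, median)
  sdv <- apply(mat, 2, sd)
  data.frame(reaction = colnames(mat), median = unname(med),
             sd = unname(sdv),
             variability_pct = ifelse(abs(med) < 1e-9, NA_real_,
                                      100 * sdv / abs(med)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map EC-formalism fluxes back to base-model reactions
#'
#' Net flux = forward - reverse; isozyme copies are summed into the parent
#' reaction; arm, usage and pool reactions are dropped.
#'
#' @param x a `flux_sample`, numeric matrix, or named flux vector in the
#'   EC model's reaction space.
#' @param ec the `ec_model` carrying `rev_map`/`iso_map` provenance.
#' @return object of the same shape with base reaction ids.
#' @export
map_to_base <- function(x, ec) {
  if (inherits(x, "flux_sample")) x <- x$matrix
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  rev_map <- ec$annotations$rev_map
  iso_map <- ec$annotations$iso_map %||% list()
  base_of <- function(rid) {
    # EC reaction id -> (base id, sign); NA base drops the column
    if (startsWith(rid, DRAW_PREFIX) || rid == POOL_RXN ||
        startsWith(rid, ARM_PREFIX)) {
      return(list(base = NA_character_, dir = 0))
    }
    ir <- iso_map[[rid]]
    key <- if (!is.null(ir) && ir$kind == "copy") ir$parent else rid
    rv <- rev_map[[key]]
    if (is.null(rv)) list(base = key, dir = 1) else rv
  }
  maps <- lapply(colnames(x), base_of)
  bases <- vapply(maps, function(m) m$base, "")
  dirs <- vapply(maps, function(m) as.numeric(m$dir), 0)
  keep <- !is.na(bases)
  base_ids <- unique(bases[keep])
  out <- matrix(0, nrow(x), length(base_ids),
                dimnames = list(NULL, base_ids))
  for (j in which(keep)) {
    out[, bases[j]] <- out[, bases[j]] + dirs[j] * x[, j]
  }
  if (vec_in) out[1, ] else out
}
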