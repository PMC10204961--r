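# Absolute proteome quantification by the total protein approach (TPA) with
# a heavy-labelled internal standard, differential expression, GO-group mass
# allocation and ribosome translation-rate estimation.

#' Read a mass-spectrometry proteomics table
#'
#' @param path TSV with columns `protein_id`, `condition`, `replicate`,
#'   `ibaq_heavy`, `ratio_hl`, `mw_g_per_mol`.
#' @return data.frame of MS records.
#' @export
read_ms_records <- function(path) {
  read_tsv_checked(path, c("protein_id", "condition", "replicate",
                           "ibaq_heavy", "ratio_hl", "mw_g_per_mol"))
}

#' Absolute quantification by the total protein approach
#'
#' Light-channel intensities are recovered from the heavy internal standard
#' and the heavy/light ratio (`I_i = ibaq_heavy_i / ratio_hl_i`), normalized
#' by the mean internal-standard abundance, adjusted for the injection
#' recovery, and converted to concentration shares of 1e6 ug per g total
#' protein. Records with missing or non-positive ratios are excluded with a
#' message. The recovery factor cancels in the shares and is retained for
#' intensity-level reporting only.
#'
#' @param records data.frame of MS records for one condition (replicates
#'   allowed; quantified per replicate, then averaged).
#' @param recovery fraction of the injected sample recovered (default 0.80).
#' @param Ptot total protein content of the biomass, g protein/gDCW
#'   (carried through for molar conversion).
#' @return a `proteome_sample`: list with `condition`, `conc` (data.frame
#'   protein_id, mean ug/g, sd, per-replicate columns), `Ptot`, `mw`
#'   (g/mol).
#' @export
tpa_quantify <- function(records, recovery = 0.80, Ptot = NA_real_) {
  stopifnot(nrow(records) > 0)
  cond <- unique(records$condition)
  if (length(cond) != 1) {
    stop("tpa_quantify expects records from a single condition; got: ",
         paste(cond, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(records$ratio_hl) | records$ratio_hl <= 0
  if (any(bad)) {
    message("tpa_quantify: excluding ", sum(bad),
            " record(s) with missing/non-positive heavy:light ratio")
    records <- records[!bad, ]
  }
  reps <- sort(unique(records$replicate))
  prot <- sort(unique(records$protein_id))
  conc_mat <- matrix(NA_real_, length(prot), length(reps),
                     dimnames = list(prot, paste0("rep", reps)))
  for (k in seq_along(reps)) {
    rr <- records[records$replicate == reps[k], ]
    light <- rr$ibaq_heavy / rr$ratio_hl
    std <- mean(rr$ibaq_heavy)
    if (std <= 0) stop("zero internal-standard intensity", call. = FALSE)
    inten <- light / std / recovery
    tot <- sum(inten)
    if (tot <= 0) stop("zero total intensity in replicate ", reps[k],
                       call. = FALSE)
    conc_mat[rr$protein_id, k] <- inten / tot * 1e6
  }
  mean_conc <- apply(conc_mat, 1, function(x) mean(x, na.rm = TRUE))
  sd_conc <- apply(conc_mat, 1, function(x)
    if (sum(!is.na(x)) >= 2) sd(x, na.rm = TRUE) else NA_real_)
  mw <- setNames(records$mw_g_per_mol[match(prot, records$protein_id)], prot)
  conc <- data.frame(protein_id = prot, conc_ug_per_g = unname(mean_conc),
                     sd_ug_per_g = unname(sd_conc), conc_mat,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(condition = cond, conc = conc, Ptot = Ptot, mw = mw,
                 recovery = recovery, n_replicates = length(reps)),
            class = "proteome_sample")
}

#' Convert proteome shares to molar abundances
#'
#' `E_i = conc_i (g/g protein) * Ptot (g/gDCW) / MW_i (g/mmol)`.
#'
#' @param sample a `proteome_sample`.
#' @param mw optional named vector of molecular weights in g/mol overriding
#'   the sample's own.
#' @param Ptot optional total protein content override, g/gDCW.
#' @return named numeric vector, mmol/gDCW per protein.
#' @export
to_molar <- function(sample, mw = NULL, Ptot = NULL) {
  Ptot <- Ptot %||% sample$Ptot
  if (!is.finite(Ptot)) stop("Ptot is required for molar conversion",
                             call. = FALSE)
  mw <- mw %||% sample$mw
  ids <- sample$conc$protein_id
  missing <- ids[!ids %in% names(mw) | !is.finite(mw[ids])]
  if (length(missing)) {
    stop("missing molecular weight for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g_per_g <- sample$conc$conc_ug_per_g / 1e6
  # mw in g/mol; g/mmol = mw/1000
  setNames(g_per_g * Ptot / (mw[ids] / 1000), ids)
}

#' Differential protein expression between two conditions
#'
#' Welch two-sample t-test on log2 concentrations per protein, with
#' Benjamini-Hochberg adjustment over all tested proteins. Proteins whose
#' replicate standard deviation exceeds the replicate mean in either
#' condition are excluded before testing, as are proteins missing from
#' either condition.
#'
#' @param a,b `proteome_sample` objects with >= 2 replicates each.
#' @param fc_cut significance cut-off on |log2 fold change| (default 1).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return data.frame: protein_id, log2fc (b over a), p, p_adj, significant.
#' @export
differential_expression <- function(a, b, fc_cut = 1.0, alpha = 0.05) {
  rep_cols <- function(s) grep("^rep", names(s$conc), value = TRUE)
  if (length(rep_cols(a)) < 2 || length(rep_cols(b)) < 2) {
    stop("differential expression requires >= 2 replicates per condition",
         call. = FALSE)
  }
  shared <- intersect(a$conc$protein_id, b$conc$protein_id)
  keep <- character()
  for (p in shared) {
    ra <- as.numeric(a$conc[a$conc$protein_id == p, rep_cols(a)])
    rb <- as.numeric(b$conc[b$conc$protein_id == p, rep_cols(b)])
    if (any(is.na(ra)) || any(is.na(rb))) next
    if (sd(ra) > mean(ra) || sd(rb) > mean(rb)) next  # noisy duplicates out
    if (any(ra <= 0) || any(rb <= 0)) next
    keep <- c(keep, p)
  }
  res <- lapply(keep, function(p) {
    ra <- log2(as.numeric(a$conc[a$conc$protein_id == p, rep_cols(a)]))
    rb <- log2(as.numeric(b$conc[b$conc$protein_id == p, rep_cols(b)]))
    lfc <- mean(rb) - mean(ra)
    pv <- if (sd(ra) == 0 && sd(rb) == 0) {
      if (isTRUE(all.equal(mean(ra), mean(rb)))) 1 else 0
    } else {
      tryCatch(t.test(rb, ra)$p.value, error = function(e) NA_real_)
    }
    data.frame(protein_id = p, log2fc = lfc, p = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res) %||%
    data.frame(protein_id = character(), log2fc = numeric(), p = numeric())
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- abs(out$log2fc) > fc_cut & out$p_adj < alpha &
    !is.na(out$p_adj)
  out
}

#' Allocate proteome mass to GO-style groups
#'
#' Group share = sum of member concentrations / 1e6 * 100 (% of proteome
#' mass). Overlapping groups are allowed: each protein counts in every group
#' it belongs to, so shares need not sum to 100%.
#'
#' @param sample a `proteome_sample`.
#' @param go_map named list, group -> character vector of protein ids, or a
#'   data.frame with columns `group` and `protein_id`.
#' @return data.frame: group, pct_mass.
#' @export
allocate_go <- function(sample, go_map) {
  if (is.data.frame(go_map)) {
    go_map <- split(go_map$protein_id, go_map$group)
  }
  conc <- setNames(sample$conc$conc_ug_per_g, sample$conc$protein_id)
  data.frame(
    group = names(go_map),
    pct_mass = vapply(go_map, function(ids)
      sum(conc[intersect(ids, names(conc))]) / 1e6 * 100, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Protein synthesis rate per ribosome
#'
#' Ribosome abundance is estimated from the molar abundances of detected
#' ribosomal proteins (median by default; robust against missing subunits),
#' and the translation rate follows from the protein synthesis demand:
#' `rate = (mu * Ptot / mean_aa_mass) / N_rib / 3600` in amino acids per
#' second.
#'
#' @param sample a `proteome_sample`.
#' @param ribosomal_ids protein ids of ribosomal subunits.
#' @param mu specific growth rate, 1/h.
#' @param Ptot total protein content, g/gDCW (default: the sample's).
#' @param mean_aa_mass mean amino-acid residue mass, g/mol (default 110).
#' @param estimator `"median"`, `"mean"` or `"min"` over detected subunit
#'   molar abundances.
#' @return list with `rate_aa_per_s`, `n_ribosome_mol_per_gdcw`,
#'   `n_subunits_detected`.
#' @export
translation_rate <- function(sample, ribosomal_ids, mu, Ptot = NULL,
                             mean_aa_mass = 110,
                             estimator = c("median", "mean", "min")) {
  estimator <- match.arg(estimator)
  Ptot <- Ptot %||% sample$Ptot
  molar <- to_molar(sample, Ptot = Ptot)  # mmol/gDCW
  det <- intersect(ribosomal_ids, names(molar))
  if (!length(det)) stop("no ribosomal proteins detected in sample",
                         call. = FALSE)
  est <- switch(estimator, median = median, mean = mean, min = min)
  n_rib <- est(molar[det]) / 1000  # mol/gDCW
  rate <- (mu * Ptot / mean_aa_mass) / n_rib / 3600
  list(rate_aa_per_s = rate, n_ribosome_mol_per_gdcw = n_rib,
       n_subunits_detected = length(det))
}
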