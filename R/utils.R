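# Small shared helpers: chemical formula arithmetic, medium C/N bookkeeping,
# TSV conventions.

# Monoisotopic-free average atomic masses (g/mol) for the elements that occur
# in the formulas this package handles.
ATOMIC_MASS <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974, S = 32.06,
  K = 39.098, Mg = 24.305, Fe = 55.845, Na = 22.990, Cl = 35.45
)

#' Parse an elemental formula into atom counts
#'
#' Accepts Hill-style formulas such as `"C6H12O6"` or `"N2H8SO4"`. Returns a
#' named numeric vector of element counts.
#'
#' @param formula character scalar, e.g. `"C5H10O5"`.
#' @return named numeric vector of atom counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", toks)
  nn <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  nn[is.na(nn)] <- 1
  out <- tapply(nn, el, sum)
  setNames(as.numeric(out), names(out))
}

#' Molar mass of an elemental formula
#'
#' @param formula character scalar formula.
#' @return molar mass in g/mol.
#' @export
formula_mass <- function(formula) {
  cnt <- parse_formula(formula)
  unknown <- setdiff(names(cnt), names(ATOMIC_MASS))
  if (length(unknown)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(cnt * ATOMIC_MASS[names(cnt)])
}

#' Molar carbon-to-nitrogen ratio of a medium
#'
#' Computes the molar C/N ratio of a growth medium from component
#' concentrations (g/L) and elemental formulas, e.g. for a seed medium of
#' 20 g/L xylose with 5 g/L ammonium sulfate.
#'
#' @param grams_per_l named numeric vector of concentrations in g/L; names are
#'   only labels.
#' @param formulas character vector of elemental formulas, same length/order.
#' @return molar C/N ratio (dimensionless).
#' @examples
#' medium_cn_ratio(c(xylose = 20, ammonium_sulfate = 5),
#'                 c("C5H10O5", "N2H8SO4"))
#' @export
medium_cn_ratio <- function(grams_per_l, formulas) {
  stopifnot(length(grams_per_l) == length(formulas), all(grams_per_l >= 0))
  mol_c <- 0
  mol_n <- 0
  for (i in seq_along(formulas)) {
    cnt <- parse_formula(formulas[i])
    mol <- grams_per_l[i] / formula_mass(formulas[i])
    mol_c <- mol_c + mol * ifelse("C" %in% names(cnt), cnt[["C"]], 0)
    mol_n <- mol_n + mol * ifelse("N" %in% names(cnt), cnt[["N"]], 0)
  }
  if (mol_n <= 0) stop("medium contains no nitrogen", call. = FALSE)
  unname(mol_c / mol_n)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("TSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
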