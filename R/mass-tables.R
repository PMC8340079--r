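#' Mass tables
#'
#' Residue and modification masses are computed from elemental compositions:
#' monoisotopic masses use the principal-isotope masses, average masses the
#' IUPAC 2013 conventional standard atomic weights. The tables ship as
#' delimited text under `inst/extdata/mass_tables/` so alternative mass
#' scales can be swapped in without touching code.
#'
#' Residue masses are dehydrated (per-residue in a chain); add one water per
#' chain. All masses are in Da.
#'
#' @param mode `"monoisotopic"` or `"average"`.
#' @return A tibble; `gf_monosaccharides()` and `gf_modifications()` carry
#'   one column per mass mode.
#' @name mass-tables
NULL

gf_mass_dir <- function() {
  dir <- Sys.getenv("GLYCOFORMR_MASS_TABLES", unset = "")
  if (nzchar(dir)) return(dir)
  system.file("extdata", "mass_tables", package = "glycoformr", mustWork = TRUE)
}

read_mass_csv <- function(name) {
  readr::read_csv(file.path(gf_mass_dir(), name), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname mass-tables
#' @export
gf_elements <- function() {
  if (is.null(.gf_cache$elements)) .gf_cache$elements <- read_mass_csv("elements.csv")
  .gf_cache$elements
}

# parse "C6H10O5" / "H-2" / "Na1H-1" into a named count vector (signed)
parse_formula <- function(formula) {
  m <- stringr::str_match_all(formula, "([A-Z][a-z]?)(-?\\d+)")[[1]]
  if (nrow(m) == 0 || paste0(m[, 1], collapse = "") != formula) {
    abort(paste0("cannot parse elemental formula: '", formula, "'"))
  }
  setNames(as.numeric(m[, 3]), m[, 2])
}

formula_mass <- function(formula, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  el <- gf_elements()
  w <- setNames(el[[mode]], el$element)
  vapply(formula, function(f) {
    cnt <- parse_formula(f)
    bad <- setdiff(names(cnt), names(w))
    if (length(bad)) abort(paste0("unknown element(s): ", paste(bad, collapse = ", ")))
    sum(cnt * w[names(cnt)])
  }, numeric(1), USE.NAMES = FALSE)
}

with_both_modes <- function(df) {
  df$monoisotopic <- formula_mass(df$formula, "monoisotopic")
  df$average <- formula_mass(df$formula, "average")
  df
}

#' @rdname mass-tables
#' @export
gf_monosaccharides <- function() {
  if (is.null(.gf_cache$monosaccharides)) {
    .gf_cache$monosaccharides <- with_both_modes(read_mass_csv("monosaccharides.csv"))
  }
  .gf_cache$monosaccharides
}

#' @rdname mass-tables
#' @export
gf_amino_acids <- function() {
  if (is.null(.gf_cache$amino_acids)) {
    .gf_cache$amino_acids <- with_both_modes(read_mass_csv("amino_acids.csv"))
  }
  .gf_cache$amino_acids
}

#' @rdname mass-tables
#' @export
gf_modifications <- function() {
  if (is.null(.gf_cache$modifications)) {
    .gf_cache$modifications <- with_both_modes(read_mass_csv("modifications.csv"))
  }
  .gf_cache$modifications
}

check_mode <- function(mode) {
  if (length(mode) != 1 || !mode %in% c("monoisotopic", "average")) {
    abort("`mode` must be \"monoisotopic\" or \"average\"")
  }
  mode
}

# scalar lookup helpers -------------------------------------------------------

monosaccharide_masses <- function(mode) {
  mode <- check_mode(mode)
  tab <- gf_monosaccharides()
  setNames(tab[[mode]], tab$unit)
}

modification_mass <- function(name, mode) {
  mode <- check_mode(mode)
  tab <- gf_modifications()
  i <- match(name, tab$modification)
  if (anyNA(i)) abort(paste0("unknown modification: ", name[is.na(i)][1]))
  tab[[mode]][i]
}

#' Signed mass error in parts per million
#'
#' @param observed Observed neutral mass(es) in Da.
#' @param theoretical Theoretical mass(es) in Da; must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`, vectorized.
#' @examples
#' ppm_error(1000.02, 1000) # +20 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    abort("`theoretical` must be positive and finite")
  }
  1e6 * (observed - theoretical) / theoretical
}
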