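#' Read and write neutral-mass peak lists
#'
#' Peak lists are tab- or comma-separated text with a header; columns
#' `mass` (or `mass_da`) in Da and `intensity` (or `rel_intensity`).
#' Deconvoluted neutral masses, not m/z, are the interchange unit.
#'
#' @param path File path.
#' @return Tibble with `mass`, `intensity`.
#' @export
read_peak_list <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                          trim_ws = TRUE)
  standardize_peaks(df)[c("mass", "intensity")]
}

#' @rdname read_peak_list
#' @param peaks Tibble with `mass` and `intensity`.
#' @export
write_peak_list <- function(peaks, path) {
  readr::write_tsv(standardize_peaks(peaks)[c("mass", "intensity")], path)
  invisible(path)
}

#' Write an annotation report
#'
#' Tab-separated, one row per (peak, rank), with the stable column set from
#' [tidy.glyco_annotation()].
#'
#' @param ann A `glyco_annotation`.
#' @param path Output path.
#' @export
write_annotation_report <- function(ann, path) {
  readr::write_tsv(tidy(ann), path)
  invisible(path)
}

#' Write a glycoform library (whole-subunit entries)
#'
#' @param entries Glycoform entries (e.g. [build_subunit_library()]).
#' @param path Output path.
#' @export
write_glycoform_library <- function(entries, path) {
  df <- as_tibble(entries)
  df$composition <- purrr::pmap_chr(df[glycan_units()], function(hex, hexnac,
                                                                 fuc, neu5ac) {
    composition_label(list(hex = hex, hexnac = hexnac, fuc = fuc,
                           neu5ac = neu5ac))
  })
  cols <- c("glycoform", "composition", "fractional_abundance",
            "hex", "hexnac", "fuc", "neu5ac", "antennae", "n_cores",
            "n_n_glycans", "core_fucose_count", "deamidation")
  readr::write_tsv(select(df, dplyr::any_of(cols)), path)
  invisible(path)
}

#' @rdname write_glycoform_library
#' @param path File written by `write_glycoform_library()`.
#' @export
read_glycoform_library <- function(path) {
  readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                    trim_ws = TRUE)
}

#' Write a machine-readable provenance block
#'
#' Every pipeline run records its configuration, seed and the mass-table
#' provenance so a run can be reproduced bit-for-bit for deterministic
#' stages.
#'
#' @param path Output JSON path.
#' @param config Named list echoed verbatim.
#' @param seed Seed used (or NULL).
#' @return The path, invisibly.
#' @export
write_provenance <- function(path, config = list(), seed = NULL) {
  block <- list(
    package = "glycoformr",
    version = as.character(packageVersion("glycoformr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    mass_tables = gf_mass_dir(),
    config = config
  )
  jsonlite::write_json(block, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
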