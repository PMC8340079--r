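#' Site-specific quantitative glycan library
#'
#' A `glyco_library` is a tibble with one row per (site, glycan species):
#' columns `site`, `glycan`, `abundance`, plus the parsed species columns
#' from [parse_glycan_name()]. Abundances are normalized to sum to 1 within
#' each site; duplicate (site, glycan) rows are summed before normalizing.
#' The reserved species `"unmodified"` encodes sub-100% occupancy, so
#' macroheterogeneity and microheterogeneity fall out of the same
#' combinatorics.
#'
#' @param df Data frame with columns `site`, `glycan`, `abundance`.
#' @param level Provenance tag, e.g. `"glycopeptide"` or `"subunit"`.
#' @return A `glyco_library` tibble (sites keep their input order).
#' @examples
#' glyco_library(data.frame(
#'   site = "N52", glycan = c("A2S2", "A2G2"), abundance = c(3, 1)
#' ))
#' @export
glyco_library <- function(df, level = "glycopeptide") {
  need <- c("site", "glycan", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (any(!is.finite(df$abundance)) || any(df$abundance < 0)) {
    abort("abundances must be finite and non-negative")
  }
  df <- as_tibble(df[need])
  site_order <- unique(df$site)
  parsed <- parse_glycan_name(df$glycan)
  df <- bind_cols(df[c("site", "abundance")], parsed)
  df <- df |>
    group_by(.data$site, .data$glycan) |>
    summarise(abundance = sum(.data$abundance),
              across(c("glycan_class", "antennae", "n_cores", "core_fucose",
                       "deamidation", "hex", "hexnac", "fuc", "neu5ac"), first),
              .groups = "drop") |>
    group_by(.data$site) |>
    mutate(abundance = .data$abundance / sum(.data$abundance)) |>
    ungroup() |>
    arrange(match(.data$site, site_order), desc(.data$abundance), .data$glycan) |>
    relocate("site", "glycan", "abundance")
  new_glyco_library(df, level = level)
}

new_glyco_library <- function(df, level = "glycopeptide") {
  structure(df, level = level,
            class = c("glyco_library", class(tibble())))
}

assert_library <- function(lib) {
  if (!inherits(lib, "glyco_library")) abort("expected a `glyco_library`")
  invisible(lib)
}

#' @export
print.glyco_library <- function(x, ...) {
  cat("<glyco_library> ", dplyr::n_distinct(x$site), " site(s), ",
      nrow(x), " species entries (level: ", attr(x, "level") %||% "?", ")\n",
      sep = "")
  NextMethod()
}

#' Read a site-specific glycan library from delimited text
#'
#' Expects a header with columns `site`, `glycan`, `abundance`
#' (tab- or comma-separated). Rows are normalized per site on load.
#'
#' @param path File path.
#' @param level Provenance tag stored on the library.
#' @return A [glyco_library()].
#' @export
read_site_library <- function(path, level = "glycopeptide") {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                          trim_ws = TRUE)
  glyco_library(df, level = level)
}

#' Write a site library back to tab-separated text
#'
#' @param lib A [glyco_library()].
#' @param path Output path.
#' @export
write_site_library <- function(lib, path) {
  assert_library(lib)
  readr::write_tsv(as_tibble(lib)[c("site", "glycan", "abundance")], path)
  invisible(path)
}

# in-silico enzymatic transforms ----------------------------------------------

#' In-silico exoglycosidase and endoglycosidase library transforms
#'
#' `desialylate_library()` mimics sialidase treatment: every species loses
#' its Neu5Ac residues (complex-type names are rewritten with S-antennae
#' turned into G-antennae; O-glycan sialic suffixes dropped), and species
#' made identical by the transform are merged with summed abundances.
#'
#' `de_n_glycosylate_library()` mimics PNGase F: every N-class species is
#' replaced by the species `"deamidated"` (empty glycan composition plus one
#' Asn-to-Asp deamidation, +0.984 Da, at the formerly occupied site);
#' `"unmodified"` entries stay unmodified because an unoccupied Asn was
#' never glycosylated and is not deamidated. O-sites are untouched.
#'
#' Both transforms preserve per-site normalization and are idempotent.
#'
#' @param lib A [glyco_library()].
#' @return A transformed `glyco_library`.
#' @export
desialylate_library <- function(lib) {
  assert_library(lib)
  df <- as_tibble(lib)
  df$glycan <- desialylate_name(df$glycan)
  glyco_library(df[c("site", "glycan", "abundance")],
                level = attr(lib, "level") %||% "glycopeptide")
}

#' @rdname desialylate_library
#' @export
de_n_glycosylate_library <- function(lib) {
  assert_library(lib)
  df <- as_tibble(lib)
  df$glycan <- ifelse(df$glycan_class == "N", "deamidated", df$glycan)
  glyco_library(df[c("site", "glycan", "abundance")],
                level = attr(lib, "level") %||% "glycopeptide")
}

# glycoform-level bookkeeping -------------------------------------------------

#' Truncate a glycoform library by fractional abundance
#'
#' Retains entries with `fractional_abundance >= cutoff`. Abundances are NOT
#' renormalized: coverage is reported relative to the full pre-truncation
#' total, which is also how retained counts should be read.
#'
#' @param entries Tibble of glycoform entries with a `fractional_abundance`
#'   column (e.g. from [fractional_abundances()]).
#' @param cutoff Fraction in \[0, 1\].
#' @return The retained entries, with attributes `retained` (count) and
#'   `coverage` (retained share of the total abundance); also exposed via
#'   [glance.glyco_glycoforms()].
#' @examples
#' e <- tibble::tibble(glycoform = letters[1:4],
#'                     fractional_abundance = c(0.5, 0.3, 0.15, 0.05))
#' truncate_by_cutoff(e, 0.1)
#' @export
truncate_by_cutoff <- function(entries, cutoff) {
  if (length(cutoff) != 1 || !is.finite(cutoff) || cutoff < 0 || cutoff > 1) {
    abort("`cutoff` must be a single value in [0, 1]")
  }
  if (!"fractional_abundance" %in% names(entries)) {
    abort("`entries` must have a `fractional_abundance` column")
  }
  total <- sum(entries$fractional_abundance)
  kept <- filter(entries, .data$fractional_abundance >= cutoff)
  structure(kept,
            retained = nrow(kept),
            coverage = if (total > 0) sum(kept$fractional_abundance) / total else 0,
            cutoff = cutoff,
            class = unique(c("glyco_glycoforms", class(kept))))
}

#' Size of the unconstrained combinatorial glycoform space
#'
#' Product over sites of the per-site species counts -- the number of
#' distinct site-species tuples before any mass filtering. Returned as a
#' double so paper-scale libraries (1e6--1e8 combinations) do not overflow.
#'
#' @param lib A [glyco_library()], or any tibble with a `site` column.
#' @return A double.
#' @export
count_candidate_glycoforms <- function(lib) {
  if (nrow(lib) == 0) return(0)
  counts <- dplyr::count(as_tibble(lib), .data$site)
  prod(as.numeric(counts$n))
}
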