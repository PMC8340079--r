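#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an annotated spectrum
#'
#' Returns the assignment rows (one per peak and rank) as a plain tibble
#' with the stable report columns; `flags` condenses the per-row boolean
#' flags into a comma-separated string for delimited-text export.
#'
#' @param x A `glyco_annotation`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy glyco_annotation
#' @export
tidy.glyco_annotation <- function(x, ...) {
  df <- as_tibble(x)
  df$flags <- purrr::pmap_chr(
    list(df$unannotated, df$is_adduct_satellite, df$inherited,
         df$artifact_candidate),
    function(u, s, i, a) {
      f <- c(if (isTRUE(u)) "unannotated", if (isTRUE(s)) "sodium_adduct",
             if (isTRUE(i)) "inherited", if (isTRUE(a)) "minus1Da_artifact")
      paste(f, collapse = ",")
    }
  )
  cols <- c("peak_id", "peak_mass", "intensity", "rank", "glycoform",
            "chain_a_glycoform", "chain_b_glycoform",
            "hex", "hexnac", "fuc", "neu5ac",
            "theoretical_mass", "error", "hit_score", "flags",
            "near_miss", "near_miss_error")
  select(df, dplyr::any_of(cols))
}

#' Summarize an annotated spectrum
#'
#' @param x A `glyco_annotation`.
#' @param ... Unused.
#' @return One-row tibble: peak counts, annotated fraction (by count and by
#'   intensity), assignment count, tolerance and mass mode.
#' @method glance glyco_annotation
#' @export
glance.glyco_annotation <- function(x, ...) {
  peaks <- distinct(as_tibble(x), .data$peak_id, .data$intensity,
                    .data$unannotated)
  ok <- !peaks$unannotated
  tibble(
    n_peaks = nrow(peaks),
    n_annotated = sum(ok),
    n_assignments = sum(!is.na(x$glycoform)),
    annotated_fraction = mean(ok),
    annotated_intensity_fraction =
      sum(peaks$intensity[ok]) / sum(peaks$intensity),
    tol = attr(x, "tol"), tol_unit = attr(x, "tol_unit"),
    mode = attr(x, "mode")
  )
}

#' Summarize a truncated glycoform library
#'
#' @param x Output of [truncate_by_cutoff()] / [build_subunit_library()].
#' @param ... Unused.
#' @return One-row tibble with `retained`, `coverage`, `cutoff`.
#' @method glance glyco_glycoforms
#' @export
glance.glyco_glycoforms <- function(x, ...) {
  tibble(retained = attr(x, "retained") %||% nrow(x),
         coverage = attr(x, "coverage") %||% NA_real_,
         cutoff = attr(x, "cutoff") %||% NA_real_)
}
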