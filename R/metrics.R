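# species tables from parse_glycan_name() lack the per-glycoform aggregate
# columns; derive them so single-species rows can be scored directly
ensure_aggregates <- function(entries) {
  if (!"glycoform" %in% names(entries) && "glycan" %in% names(entries)) {
    entries$glycoform <- entries$glycan
  }
  if (!"n_n_glycans" %in% names(entries) && "glycan_class" %in% names(entries)) {
    entries$n_n_glycans <- as.integer(entries$glycan_class == "N")
  }
  if (!"core_fucose_count" %in% names(entries) && "core_fucose" %in% names(entries)) {
    entries$core_fucose_count <- as.integer(entries$core_fucose)
  }
  for (col in c("antennae", "n_cores", "neu5ac", "n_n_glycans",
                "core_fucose_count")) {
    if (!col %in% names(entries)) {
      abort(paste0("entries lack required column `", col, "`"))
    }
  }
  entries
}

#' Abundance-weighted degree of sialylation
#'
#' For each glycoform the observed Neu5Ac count is divided by the maximum
#' number of sialic acids the glycoform could carry: one per N-glycan
#' antenna plus two per O-glycan core-1 unit. The per-glycoform ratios are
#' then averaged with the glycoform weights. Glycoforms with a zero maximum
#' (e.g. pure high-mannose or fully unoccupied species) are excluded from
#' the weighted mean; unoccupied (`"unmodified"`) sites contribute nothing
#' to either numerator or maximum.
#'
#' @param entries Glycoform entries carrying `neu5ac`, `antennae`,
#'   `n_cores` and a weight column.
#' @param weight Name of the weight column (default
#'   `"fractional_abundance"`).
#' @return A fraction in \[0, 1\]; `NA` (with a warning) when every entry
#'   has a zero sialylation maximum.
#' @examples
#' e <- parse_glycan_name(c("A2S2", "A2G2"))
#' e$fractional_abundance <- c(0.75, 0.25)
#' degree_of_sialylation(e) # 0.75
#' @export
degree_of_sialylation <- function(entries, weight = "fractional_abundance") {
  entries <- ensure_aggregates(entries)
  w <- entries[[weight]]
  if (is.null(w)) abort(paste0("no weight column `", weight, "`"))
  max_s <- entries$antennae + 2 * entries$n_cores
  use <- max_s > 0 & w > 0
  if (!any(use)) {
    warn("all glycoforms have a zero sialylation maximum; degree undefined")
    return(NA_real_)
  }
  sum(w[use] * entries$neu5ac[use] / max_s[use]) / sum(w[use])
}

#' Abundance-weighted degree of core fucosylation
#'
#' Counts at most one core fucose per N-glycan: per glycoform the number of
#' core-fucosylated N-glycans is divided by the number of N-glycans, and the
#' ratios are abundance-weighted over glycoforms carrying at least one
#' N-glycan. O-glycans are not considered.
#'
#' @inheritParams degree_of_sialylation
#' @return A fraction in \[0, 1\]; `NA` (with a warning) when no entry
#'   carries an N-glycan.
#' @export
degree_of_core_fucosylation <- function(entries,
                                        weight = "fractional_abundance") {
  entries <- ensure_aggregates(entries)
  w <- entries[[weight]]
  if (is.null(w)) abort(paste0("no weight column `", weight, "`"))
  use <- entries$n_n_glycans > 0 & w > 0
  if (!any(use)) {
    warn("no glycoform carries an N-glycan; degree undefined")
    return(NA_real_)
  }
  sum(w[use] * entries$core_fucose_count[use] / entries$n_n_glycans[use]) /
    sum(w[use])
}

#' Glycosylation quality attributes of a glycoform population
#'
#' @param entries Glycoform entries (see [fractional_abundances()]).
#' @param level Structural level label (`"glycopeptide"`, `"subunit"`,
#'   `"dimer"`).
#' @param target Target identifier (e.g. chain or product name).
#' @param weight Weight column name.
#' @return One-row tibble: `level`, `target`, `sialylation`,
#'   `core_fucosylation`, `total_weight`.
#' @export
glyco_cqa <- function(entries, level = "subunit", target = "protein",
                      weight = "fractional_abundance") {
  tibble(
    level = level, target = target,
    sialylation = degree_of_sialylation(entries, weight),
    core_fucosylation = degree_of_core_fucosylation(entries, weight),
    total_weight = sum(entries[[weight]])
  )
}

#' Compare quality attributes between two batches
#'
#' Joins two CQA tables on (level, target) and reports absolute and relative
#' differences per attribute. Keys present in only one batch produce a
#' warning and rows with missing values.
#'
#' @param results_a,results_b Tibbles from [glyco_cqa()] (rows may be bound
#'   over levels/targets).
#' @param labels Length-2 batch labels used for column suffixes.
#' @return A tibble with per-key attribute values, `delta_abs` and
#'   `delta_rel` columns for each attribute.
#' @export
compare_batches <- function(results_a, results_b,
                            labels = c("batch_a", "batch_b")) {
  key <- c("level", "target")
  only_a <- anti_join(results_a, results_b, by = key)
  only_b <- anti_join(results_b, results_a, by = key)
  if (nrow(only_a) || nrow(only_b)) {
    warn(paste0("unmatched (level, target) keys: ",
                paste(c(paste(only_a$level, only_a$target),
                        paste(only_b$level, only_b$target)), collapse = "; ")))
  }
  joined <- full_join(results_a, results_b, by = key,
                      suffix = paste0("_", labels))
  for (attr_col in c("sialylation", "core_fucosylation")) {
    va <- joined[[paste0(attr_col, "_", labels[1])]]
    vb <- joined[[paste0(attr_col, "_", labels[2])]]
    joined[[paste0(attr_col, "_delta_abs")]] <- vb - va
    joined[[paste0(attr_col, "_delta_rel")]] <-
      ifelse(va != 0, (vb - va) / va, NA_real_)
  }
  joined
}
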