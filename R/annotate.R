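#' Default per-unit bounds for composition search
#'
#' Generous caps for a heavily glycosylated subunit (roughly a 12 kDa glycan
#' load): the stage-1 lattice search never needs more than these counts.
#'
#' @return Named integer vector over the composition columns.
#' @export
composition_bounds <- function() {
  c(hex = 40L, hexnac = 40L, fuc = 8L, neu5ac = 16L)
}

#' Stage 1: decompose a residual mass into monosaccharide compositions
#'
#' Enumerates every composition within the per-unit bounds whose mass lies
#' within `tol_da` of the residual mass (observed mass minus backbone mass).
#' The depth-first search over the four-unit lattice prunes on the residual
#' left at each level, and is complete with respect to exhaustive
#' enumeration.
#'
#' @param residual Residual mass in Da (may be negative: result is empty
#'   unless ~0).
#' @param tol_da Symmetric tolerance in Da.
#' @param bounds Named vector of per-unit maximum counts
#'   (default [composition_bounds()]).
#' @param mode Mass mode.
#' @return Tibble with composition columns, `theoretical` (composition
#'   mass) and signed `error` (= residual - theoretical), sorted by
#'   `abs(error)`.
#' @examples
#' decompose_mass(291.26, tol_da = 3, mode = "average") # Neu5Ac1 and Fuc2
#' @export
decompose_mass <- function(residual, tol_da, bounds = composition_bounds(),
                           mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (length(residual) != 1 || !is.finite(residual)) {
    abort("`residual` must be a single finite number")
  }
  if (tol_da <= 0) abort("`tol_da` must be positive")
  b <- composition_bounds()
  b[names(bounds)] <- bounds
  masses <- monosaccharide_masses(mode)
  # search heaviest-first for effective pruning
  m_neu <- masses[["Neu5Ac"]]; m_hn <- masses[["HexNAc"]]
  m_hex <- masses[["Hex"]]; m_fuc <- masses[["Fuc"]]

  hex_v <- hexnac_v <- fuc_v <- neu_v <- integer(0)
  err_v <- numeric(0)
  max_n <- min(b[["neu5ac"]], max(0L, floor((residual + tol_da) / m_neu)))
  for (n in 0:max_n) {
    r1 <- residual - n * m_neu
    if (r1 < -tol_da) break
    max_hn <- min(b[["hexnac"]], max(0L, floor((r1 + tol_da) / m_hn)))
    for (hn in 0:max_hn) {
      r2 <- r1 - hn * m_hn
      if (r2 < -tol_da) break
      max_h <- min(b[["hex"]], max(0L, floor((r2 + tol_da) / m_hex)))
      for (h in 0:max_h) {
        r3 <- r2 - h * m_hex
        if (r3 < -tol_da) break
        # last unit: directly solve the count window
        f_lo <- max(0L, ceiling((r3 - tol_da) / m_fuc))
        f_hi <- min(b[["fuc"]], floor((r3 + tol_da) / m_fuc))
        if (f_hi < f_lo) next
        f_vals <- seq.int(f_lo, f_hi)
        f_err <- r3 - f_vals * m_fuc
        keep <- abs(f_err) <= tol_da
        if (any(keep)) {
          k <- sum(keep)
          hex_v <- c(hex_v, rep.int(h, k))
          hexnac_v <- c(hexnac_v, rep.int(hn, k))
          fuc_v <- c(fuc_v, as.integer(f_vals[keep]))
          neu_v <- c(neu_v, rep.int(n, k))
          err_v <- c(err_v, f_err[keep])
        }
      }
    }
  }
  out <- tibble::new_tibble(list(
    hex = hex_v, hexnac = hexnac_v, fuc = fuc_v, neu5ac = neu_v,
    theoretical = residual - err_v, error = err_v
  ), nrow = length(err_v))
  out[order(abs(out$error)), ]
}

#' Stage 2: library-constrained site assignment
#'
#' Enumerates all per-site species tuples whose summed composition equals
#' the target composition exactly. The raw score of a tuple is the product
#' over sites of the species' relative library abundances; hit scores
#' normalize raw scores to percent so that the assignments of one
#' composition (or one peak) sum to 100.
#'
#' @param target One-row data frame (or named list) with the composition
#'   columns `hex`, `hexnac`, `fuc`, `neu5ac`.
#' @param lib A [glyco_library()].
#' @param sep Separator used to join per-site species names into the
#'   glycoform label.
#' @return Tibble with `glycoform`, a `species` list-column (per-site
#'   names), composition columns, glycan aggregates (`antennae`, `n_cores`,
#'   `n_n_glycans`, `core_fucose_count`, `deamidation`), `raw_score` and
#'   `hit_score`. Empty when no tuple matches.
#' @export
assign_sites <- function(target, lib, sep = "/") {
  assert_library(lib)
  assign_sites_impl(target, site_index(lib), sep = sep)
}

# precomputed per-site matrices for the stage-2 search; built once per
# spectrum, not once per peak
site_index <- function(lib) {
  sites <- split(as_tibble(lib), factor(lib$site, levels = unique(lib$site)))
  k <- length(sites)
  unit_mat <- lapply(sites, function(s) {
    m <- as.matrix(s[, glycan_units()])
    storage.mode(m) <- "integer"
    m
  })
  suffix_max <- matrix(0L, nrow = k + 1L, ncol = 4L)
  for (i in k:1) suffix_max[i, ] <- suffix_max[i + 1L, ] + apply(unit_mat[[i]], 2, max)
  list(
    k = k,
    unit_mat = unit_mat,
    suffix_max = suffix_max,
    abundance = lapply(sites, function(s) s$abundance),
    name = lapply(sites, function(s) s$glycan),
    antennae = lapply(sites, function(s) s$antennae),
    n_cores = lapply(sites, function(s) s$n_cores),
    is_n = lapply(sites, function(s) as.integer(s$glycan_class == "N")),
    core_fucose = lapply(sites, function(s) as.integer(s$core_fucose)),
    deamidation = lapply(sites, function(s) s$deamidation)
  )
}

assign_sites_impl <- function(target, idx, sep = "/") {
  tgt <- vapply(glycan_units(), function(u) as.integer(target[[u]]), integer(1))
  k <- idx$k
  res <- .dfs_assign(idx$unit_mat, idx$abundance, tgt, idx$suffix_max)
  mat <- res$picks
  n_acc <- nrow(mat)
  if (n_acc == 0L) return(empty_assignments())
  sum_over_sites <- function(field) {
    out <- numeric(n_acc)
    for (s in seq_len(k)) out <- out + idx[[field]][[s]][mat[, s]]
    out
  }
  name_cols <- lapply(seq_len(k), function(s) idx$name[[s]][mat[, s]])
  name_mat <- matrix(unlist(name_cols), nrow = n_acc)
  raw <- res$raw
  hit <- 100 * raw / sum(raw)
  rows <- tibble::new_tibble(list(
    glycoform = do.call(paste, c(name_cols, sep = sep)),
    species = lapply(asplit(name_mat, 1), unname),
    hex = sum_over_sites_unit(idx, mat, 1L),
    hexnac = sum_over_sites_unit(idx, mat, 2L),
    fuc = sum_over_sites_unit(idx, mat, 3L),
    neu5ac = sum_over_sites_unit(idx, mat, 4L),
    antennae = sum_over_sites("antennae"),
    n_cores = sum_over_sites("n_cores"),
    n_n_glycans = sum_over_sites("is_n"),
    core_fucose_count = sum_over_sites("core_fucose"),
    deamidation = sum_over_sites("deamidation"),
    raw_score = raw,
    hit_score = hit
  ), nrow = n_acc)
  rows[order(-hit, rows$glycoform), ]
}

sum_over_sites_unit <- function(idx, mat, col) {
  out <- numeric(nrow(mat))
  for (s in seq_len(idx$k)) out <- out + idx$unit_mat[[s]][mat[, s], col]
  out
}

empty_assignments <- function() {
  tibble(glycoform = character(), species = list(),
         hex = numeric(), hexnac = numeric(), fuc = numeric(),
         neu5ac = numeric(), antennae = numeric(), n_cores = numeric(),
         n_n_glycans = numeric(), core_fucose_count = numeric(),
         deamidation = numeric(), raw_score = numeric(),
         hit_score = numeric())
}

# mass of the -1 Da deconvolution artifact (one isotope spacing)
ARTIFACT_SHIFT <- 1.00235

#' Annotate a deconvoluted spectrum with ranked glycoform assignments
#'
#' For each neutral-mass peak the residual mass over the backbone (including
#' variable-oxidation and deamidation alternatives) is decomposed into
#' monosaccharide compositions (stage 1), each composition is expanded into
#' library-constrained site assignments (stage 2), assignments are merged
#' across backbone-modification alternatives, hit-scored, and ranked by
#' descending hit score (ties: ascending absolute mass error, then
#' lexicographic label).
#'
#' Peaks without assignments are never dropped: they are flagged
#' `unannotated` and reported with their best near-miss composition. Peaks
#' sitting +21.982 Da above an annotated peak are flagged as sodium-adduct
#' satellites and, when otherwise unannotated, inherit the parent's
#' assignments (flagged `inherited`; satellite intensity is not added to the
#' parent). Optionally, unannotated peaks are re-searched at
#' `mass + 1.00235` Da to rescue -1 Da deconvolution artifacts.
#'
#' @param peaks Data frame with columns `mass` (neutral Da) and
#'   `intensity` (columns `mass_da`/`rel_intensity` are also accepted).
#' @param backbone A [protein_backbone()] or list of them (masses are
#'   summed, e.g. the two chains of a noncovalent dimer).
#' @param lib A [glyco_library()]; for dimer annotation, chain pseudo-sites.
#' @param tol Tolerance value (default 20).
#' @param tol_unit `"ppm"` or `"Da"`.
#' @param mode Mass mode; must be consistent with how the library masses
#'   will be interpreted.
#' @param bounds Stage-1 per-unit bounds; by default derived from the
#'   library itself (sum over sites of the per-site maximum counts), which
#'   is exact because stage 2 can never exceed the library's maxima.
#' @param detect_adducts Flag sodium-adduct satellites?
#' @param rescue_artifacts Re-search unannotated peaks at +1.00235 Da?
#' @param sep Glycoform label separator (per-site species names).
#' @return A `glyco_annotation` tibble: one row per (peak, rank), plus one
#'   flagged row per unannotated peak. See package vignette for the column
#'   contract.
#' @export
annotate_spectrum <- function(peaks, backbone, lib, tol = 20,
                              tol_unit = c("ppm", "Da"),
                              mode = c("monoisotopic", "average"),
                              bounds = NULL,
                              detect_adducts = TRUE,
                              rescue_artifacts = TRUE,
                              sep = "/") {
  tol_unit <- match.arg(tol_unit)
  mode <- match.arg(mode)
  if (tol <= 0) abort("`tol` must be positive")
  peaks <- standardize_peaks(peaks)
  assert_library(lib)
  backbones <- if (inherits(backbone, "glyco_backbone")) list(backbone) else backbone
  if (!all(vapply(backbones, inherits, logical(1), "glyco_backbone"))) {
    abort("`backbone` must be a glyco_backbone or a list of them")
  }
  base_mass <- sum(vapply(backbones, backbone_mass, numeric(1), mode = mode))
  max_ox <- sum(vapply(backbones, function(b) b$max_oxidation, integer(1)))
  ox_mass <- modification_mass("oxidation", mode)
  deam_mass <- modification_mass("deamidation", mode)
  na_mass <- modification_mass("sodium_adduct", mode)
  # per-site deamidation capacity determines the variant range
  max_deam <- sum(vapply(split(lib$deamidation, lib$site), max, numeric(1)))
  idx <- site_index(lib)
  if (is.null(bounds)) {
    bounds <- setNames(as.integer(idx$suffix_max[1, ]), glycan_units())
  }

  per_peak <- purrr::map(seq_len(nrow(peaks)), function(i) {
    annotate_one_peak(peaks$mass[i], base_mass, idx, tol, tol_unit, mode,
                      bounds, max_ox, ox_mass, max_deam, deam_mass, sep)
  })

  ann <- assemble_annotation(peaks, per_peak)

  # -1 Da deconvolution artifact rescue
  if (rescue_artifacts) {
    for (i in which(!peaks$id %in% ann$peak_id[!is.na(ann$glycoform)])) {
      res <- annotate_one_peak(peaks$mass[i] + ARTIFACT_SHIFT, base_mass, idx,
                               tol, tol_unit, mode, bounds, max_ox, ox_mass,
                               max_deam, deam_mass, sep)
      if (nrow(res)) {
        res$artifact_candidate <- TRUE
        per_peak[[i]] <- res
      }
    }
    ann <- assemble_annotation(peaks, per_peak)
  }

  # sodium-adduct satellites
  ann <- flag_sodium_adducts(ann, peaks, na_mass, tol, tol_unit,
                             enabled = detect_adducts)

  # near-miss diagnostics for peaks that stayed unannotated
  miss <- is.na(ann$glycoform)
  ann$near_miss <- NA_character_
  ann$near_miss_error <- NA_real_
  for (r in which(miss)) {
    nm <- decompose_mass(ann$peak_mass[r] - base_mass, tol_da = 2,
                         bounds = bounds, mode = mode)
    if (nrow(nm)) {
      ann$near_miss[r] <- composition_label(nm[1, ])
      ann$near_miss_error[r] <- nm$error[1]
    }
  }

  structure(ann,
            class = c("glyco_annotation", class(tibble())),
            tol = tol, tol_unit = tol_unit, mode = mode,
            base_mass = base_mass,
            backbone_ids = vapply(backbones, function(b) b$id, character(1)),
            n_peaks = nrow(peaks))
}

isTRUE_vec <- function(x) !is.na(x) & x

# satellite detection: a peak sitting +21.982 Da (within tolerance) above an
# annotated peak is a sodium-adduct candidate. A peak explained by its own
# glycoforms keeps them (only `adduct_parent` is recorded); an otherwise
# unannotated satellite inherits the parent's assignments, flagged, and its
# intensity is never added to the parent.
flag_sodium_adducts <- function(ann, peaks, na_mass, tol, tol_unit,
                                enabled = TRUE) {
  ann$adduct_parent <- NA_integer_
  if (!enabled || nrow(peaks) < 2) return(ann)
  annotated_ids <- unique(ann$peak_id[!is.na(ann$glycoform) &
                                        !isTRUE_vec(ann$artifact_candidate)])
  if (!length(annotated_ids)) return(ann)
  pm <- peaks$mass
  n <- nrow(peaks)
  parent_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tol_da_i <- if (tol_unit == "ppm") tol * 1e-6 * pm[i] else tol
    cand <- annotated_ids[abs(pm[annotated_ids] - (pm[i] - na_mass)) <= tol_da_i]
    cand <- setdiff(cand, i)
    if (length(cand)) parent_of[i] <- cand[which.max(peaks$intensity[cand])]
  }
  ann$adduct_parent <- parent_of[ann$peak_id]
  # pure satellites: unannotated peaks with a parent inherit its assignments
  sat_ids <- intersect(unique(ann$peak_id[ann$unannotated]),
                       which(!is.na(parent_of)))
  if (length(sat_ids)) {
    inherited <- purrr::map_dfr(sat_ids, function(i) {
      rows <- filter(ann, .data$peak_id == parent_of[i], !is.na(.data$glycoform))
      rows$peak_id <- i
      rows$peak_mass <- pm[i]
      rows$intensity <- peaks$intensity[i]
      rows$inherited <- TRUE
      rows$is_adduct_satellite <- TRUE
      rows$adduct_parent <- parent_of[i]
      rows
    })
    ann$is_adduct_satellite[ann$peak_id %in% sat_ids] <- TRUE
    ann <- bind_rows(filter(ann, !(.data$peak_id %in% sat_ids &
                                     is.na(.data$glycoform))),
                     inherited)
  }
  arrange(ann, .data$peak_id, .data$rank)
}

standardize_peaks <- function(peaks) {
  peaks <- as_tibble(peaks)
  if (!"mass" %in% names(peaks) && "mass_da" %in% names(peaks)) {
    peaks <- rename(peaks, mass = "mass_da")
  }
  if (!"intensity" %in% names(peaks) && "rel_intensity" %in% names(peaks)) {
    peaks <- rename(peaks, intensity = "rel_intensity")
  }
  if (!all(c("mass", "intensity") %in% names(peaks))) {
    abort("`peaks` needs columns `mass` (or `mass_da`) and `intensity`")
  }
  if (any(peaks$mass <= 0)) abort("peak masses must be positive")
  if (any(peaks$intensity < 0)) abort("peak intensities must be >= 0")
  peaks$id <- seq_len(nrow(peaks))
  peaks
}

composition_label <- function(comp) {
  parts <- c(Hex = comp$hex, HexNAc = comp$hexnac, Fuc = comp$fuc,
             Neu5Ac = comp$neu5ac)
  parts <- parts[parts > 0]
  if (!length(parts)) return("empty")
  paste0(names(parts), parts, collapse = " ")
}

annotate_one_peak <- function(mass, base_mass, idx, tol, tol_unit, mode,
                              bounds, max_ox, ox_mass, max_deam, deam_mass,
                              sep) {
  tol_da <- if (tol_unit == "ppm") tol * 1e-6 * mass else tol
  out <- list()
  for (ox in 0:max_ox) {
    for (d in 0:max_deam) {
      shift <- base_mass + ox * ox_mass + d * deam_mass
      residual <- mass - shift
      hits <- decompose_mass(residual, tol_da, bounds, mode)
      if (!nrow(hits)) next
      for (h in seq_len(nrow(hits))) {
        asg <- assign_sites_impl(hits[h, ], idx, sep = sep)
        if (!nrow(asg)) next
        asg <- filter(asg, .data$deamidation == d)
        if (!nrow(asg)) next
        asg$oxidation <- ox
        asg$theoretical_mass <- shift + hits$theoretical[h]
        asg$error <- if (tol_unit == "ppm") {
          ppm_error(mass, asg$theoretical_mass)
        } else {
          mass - asg$theoretical_mass
        }
        out[[length(out) + 1L]] <- asg
      }
    }
  }
  if (!length(out)) return(empty_peak_result())
  res <- bind_rows(out)
  res <- res[abs(res$error) <= tol, ]
  if (!nrow(res)) return(empty_peak_result())
  # merge oxidation alternatives of the same glycoform (they are not
  # distinct proteoforms for abundance purposes)
  if (anyDuplicated(res$glycoform)) {
    res <- res |>
      arrange(abs(.data$error)) |>
      group_by(.data$glycoform) |>
      summarise(species = .data$species[1],
                across(c("hex", "hexnac", "fuc", "neu5ac", "antennae",
                         "n_cores", "n_n_glycans", "core_fucose_count",
                         "deamidation", "oxidation", "theoretical_mass",
                         "error"), first),
                raw_score = sum(.data$raw_score), .groups = "drop")
  }
  res$hit_score <- 100 * res$raw_score / sum(res$raw_score)
  res$artifact_candidate <- FALSE
  res[order(-res$hit_score, abs(res$error), res$glycoform), ]
}

empty_peak_result <- function() {
  out <- empty_assignments()
  out$oxidation <- integer()
  out$theoretical_mass <- numeric()
  out$error <- numeric()
  out$artifact_candidate <- logical()
  out
}

assemble_annotation <- function(peaks, per_peak) {
  rows <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    res <- per_peak[[i]]
    if (nrow(res) == 0) {
      return(tibble(peak_id = peaks$id[i], peak_mass = peaks$mass[i],
                    intensity = peaks$intensity[i], rank = NA_integer_,
                    glycoform = NA_character_, unannotated = TRUE))
    }
    res$peak_id <- peaks$id[i]
    res$peak_mass <- peaks$mass[i]
    res$intensity <- peaks$intensity[i]
    res$rank <- seq_len(nrow(res))
    res$unannotated <- FALSE
    res
  })
  rows$is_adduct_satellite <- FALSE
  rows$inherited <- FALSE
  for (col in c("hit_score", "theoretical_mass", "error")) {
    if (!col %in% names(rows)) rows[[col]] <- NA_real_
  }
  if (!"artifact_candidate" %in% names(rows)) rows$artifact_candidate <- FALSE
  rows$artifact_candidate[is.na(rows$artifact_candidate)] <- FALSE
  relocate(rows, "peak_id", "peak_mass", "intensity", "rank", "glycoform",
           "hit_score", "theoretical_mass", "error")
}

#' @export
print.glyco_annotation <- function(x, ...) {
  if (all(c("peak_id", "glycoform", "unannotated") %in% names(x))) {
    n_peaks <- attr(x, "n_peaks") %||% dplyr::n_distinct(x$peak_id)
    n_un <- dplyr::n_distinct(x$peak_id[x$unannotated])
    cat("<glyco_annotation> ", n_peaks, " peak(s), ",
        sum(!is.na(x$glycoform)), " assignment row(s), ",
        n_un, " unannotated peak(s) [", attr(x, "tol"), " ",
        attr(x, "tol_unit"), ", ", attr(x, "mode"), "]\n", sep = "")
  }
  NextMethod()
}

#' Fractional glycoform abundances from an annotated spectrum
#'
#' The fractional abundance of glycoform *g* is the sum over peaks of
#' (relative peak intensity) x (hit score / 100). Sodium-adduct satellite
#' peaks are excluded from both numerator and denominator (their intensity
#' duplicates the parent peak's glycoforms); unannotated peaks contribute
#' intensity to the denominator only, so the abundances sum to 1 exactly
#' when every non-satellite peak has at least one assignment.
#'
#' @param ann A `glyco_annotation` from [annotate_spectrum()].
#' @return A tibble of glycoform library entries: `glycoform`, composition
#'   columns, glycan aggregates and `fractional_abundance`, sorted
#'   descending.
#' @export
fractional_abundances <- function(ann) {
  if (!inherits(ann, "glyco_annotation")) abort("expected a `glyco_annotation`")
  use <- filter(ann, !.data$is_adduct_satellite)
  peaks <- distinct(use, .data$peak_id, .data$intensity)
  total <- sum(peaks$intensity)
  if (total <= 0) abort("total peak intensity is zero")
  asg <- filter(use, !is.na(.data$glycoform), !.data$inherited)
  if (nrow(asg) == 0) abort("no assignments to aggregate")
  asg |>
    mutate(weight = .data$intensity / total * .data$hit_score / 100) |>
    group_by(.data$glycoform) |>
    summarise(species = .data$species[1],
              across(c("hex", "hexnac", "fuc", "neu5ac",
                       "antennae", "n_cores", "n_n_glycans",
                       "core_fucose_count", "deamidation"), first),
              fractional_abundance = sum(.data$weight), .groups = "drop") |>
    arrange(desc(.data$fractional_abundance), .data$glycoform)
}

#' Count and coverage of glycoforms above an abundance threshold
#'
#' @param entries Glycoform entries with `fractional_abundance`.
#' @param threshold Strict lower bound on fractional abundance.
#' @return One-row tibble with `count` and `coverage` (summed share of the
#'   total abundance).
#' @export
abundance_coverage <- function(entries, threshold) {
  total <- sum(entries$fractional_abundance)
  kept <- entries$fractional_abundance[entries$fractional_abundance > threshold]
  tibble(count = length(kept),
         coverage = if (total > 0) sum(kept) / total else 0)
}
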