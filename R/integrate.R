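#' Build a whole-subunit glycoform library from an annotated spectrum
#'
#' Fractional abundances are computed from peak intensities and hit scores
#' (oxidation variants are already merged during annotation), then truncated
#' at the given fractional-abundance cutoff. The retained count and the
#' abundance coverage relative to the pre-truncation total are attached as
#' attributes.
#'
#' @param ann A `glyco_annotation` of a subunit spectrum.
#' @param cutoff Fractional-abundance cutoff (default 0.003, i.e. 0.3%).
#' @return Glycoform entries (as [fractional_abundances()]) with attributes
#'   `retained`, `coverage` and `cutoff`.
#' @export
build_subunit_library <- function(ann, cutoff = 0.003) {
  entries <- fractional_abundances(ann)
  out <- truncate_by_cutoff(entries, cutoff)
  if (nrow(out) == 0) {
    abort(paste0("cutoff ", cutoff, " removes every glycoform (max abundance ",
                 signif(max(entries$fractional_abundance), 3), ")"))
  }
  out
}

#' Assemble a dimer library from two chain glycoform libraries
#'
#' The two chains become ordered pseudo-sites. Chain abundances are
#' renormalized to 1 within each chain for scoring (coverage statistics
#' belong to the truncation step, not to scoring). Backbones must be in
#' native chemistry: a carbamidomethylated backbone cannot occur in a
#' noncovalent complex measured under native conditions.
#'
#' @param entries_a,entries_b Glycoform entries for each chain (e.g. from
#'   [build_subunit_library()]).
#' @param backbone_a,backbone_b Native-chemistry [protein_backbone()]s.
#' @param max_entries Warn when a chain exceeds this many entries (the
#'   combinatorial space grows as the product of chain sizes; annotation
#'   engines built on glycan-list expansion traditionally cap near 120).
#' @return A `glyco_dimer_library` list.
#' @export
dimer_library <- function(entries_a, entries_b, backbone_a, backbone_b,
                          max_entries = 120L) {
  for (bb in list(backbone_a, backbone_b)) {
    if (!inherits(bb, "glyco_backbone")) abort("backbones must be glyco_backbone objects")
    if (bb$carbamidomethyl) {
      abort(paste0("backbone '", bb$id, "' is carbamidomethylated; convert to ",
                   "native chemistry with convert_backbone_context() first"))
    }
  }
  for (e in list(entries_a, entries_b)) {
    if (!"fractional_abundance" %in% names(e) ||
        !any(c("glycoform", "glycan") %in% names(e)) || nrow(e) == 0) {
      abort("chain entries must be non-empty glycoform tables")
    }
  }
  if (nrow(entries_a) > max_entries || nrow(entries_b) > max_entries) {
    warn(paste0("chain library exceeds ", max_entries, " entries (",
                nrow(entries_a), " x ", nrow(entries_b),
                "); the combination space may be large"))
  }
  norm <- function(e) {
    e <- ensure_aggregates(as_tibble(e))
    mutate(e, abundance = .data$fractional_abundance /
             sum(.data$fractional_abundance))
  }
  structure(list(chain_a = norm(as_tibble(entries_a)),
                 chain_b = norm(as_tibble(entries_b)),
                 backbone_a = backbone_a, backbone_b = backbone_b),
            class = "glyco_dimer_library")
}

#' @export
print.glyco_dimer_library <- function(x, ...) {
  cat("<glyco_dimer_library> ", x$backbone_a$id, ": ", nrow(x$chain_a),
      " glycoform(s) x ", x$backbone_b$id, ": ", nrow(x$chain_b),
      " glycoform(s)\n", sep = "")
  invisible(x)
}

#' Annotate a native dimer spectrum as combinations of subunit glycoforms
#'
#' Every ordered chain pair is a candidate: its theoretical mass is the sum
#' of the two chain backbone masses plus both glycan loads (noncovalent
#' association adds no mass), its raw score the product of the chain
#' glycoform abundances. Pairs within the tolerance of a peak are hit-scored
#' and ranked exactly as in [annotate_spectrum()]. Native complexes are
#' conventionally annotated with average masses and a Da tolerance because
#' their spectra are not isotopically resolved.
#'
#' @param peaks Peak table (`mass`, `intensity`).
#' @param dlib A [dimer_library()].
#' @param tol Tolerance (default 3).
#' @param tol_unit `"Da"` (default) or `"ppm"`.
#' @param mode Mass mode (default `"average"`).
#' @param detect_adducts Flag +21.982 Da satellites.
#' @param sep Separator between the two chain glycoform labels.
#' @return A `glyco_annotation` with extra columns `chain_a_glycoform`,
#'   `chain_b_glycoform`.
#' @export
annotate_dimer <- function(peaks, dlib, tol = 3, tol_unit = c("Da", "ppm"),
                           mode = c("average", "monoisotopic"),
                           detect_adducts = TRUE, sep = " | ") {
  tol_unit <- match.arg(tol_unit)
  mode <- match.arg(mode)
  if (!inherits(dlib, "glyco_dimer_library")) abort("expected a `glyco_dimer_library`")
  peaks <- standardize_peaks(peaks)

  bb_a <- backbone_mass(dlib$backbone_a, mode)
  bb_b <- backbone_mass(dlib$backbone_b, mode)
  na_mass <- modification_mass("sodium_adduct", mode)
  deam_mass <- modification_mass("deamidation", mode)

  chain_mass <- function(e, bb) {
    bb + composition_mass(e, mode) + e$deamidation * deam_mass
  }
  a <- mutate(dlib$chain_a, .mass = chain_mass(dlib$chain_a, bb_a))
  b <- mutate(dlib$chain_b, .mass = chain_mass(dlib$chain_b, bb_b))

  pairs <- tidyr::crossing(ai = seq_len(nrow(a)), bi = seq_len(nrow(b)))
  pairs <- mutate(pairs,
                  theoretical_mass = a$.mass[.data$ai] + b$.mass[.data$bi],
                  raw_score = a$abundance[.data$ai] * b$abundance[.data$bi])

  per_peak <- purrr::map(seq_len(nrow(peaks)), function(i) {
    m <- peaks$mass[i]
    tol_da <- if (tol_unit == "ppm") tol * 1e-6 * m else tol
    hit <- filter(pairs, abs(m - .data$theoretical_mass) <= tol_da)
    if (nrow(hit) == 0) return(empty_peak_result())
    res <- tibble(
      chain_a_glycoform = a$glycoform[hit$ai],
      chain_b_glycoform = b$glycoform[hit$bi],
      glycoform = paste(a$glycoform[hit$ai], b$glycoform[hit$bi], sep = sep),
      species = purrr::map2(a$glycoform[hit$ai], b$glycoform[hit$bi], c),
      hex = a$hex[hit$ai] + b$hex[hit$bi],
      hexnac = a$hexnac[hit$ai] + b$hexnac[hit$bi],
      fuc = a$fuc[hit$ai] + b$fuc[hit$bi],
      neu5ac = a$neu5ac[hit$ai] + b$neu5ac[hit$bi],
      antennae = a$antennae[hit$ai] + b$antennae[hit$bi],
      n_cores = a$n_cores[hit$ai] + b$n_cores[hit$bi],
      n_n_glycans = a$n_n_glycans[hit$ai] + b$n_n_glycans[hit$bi],
      core_fucose_count = a$core_fucose_count[hit$ai] + b$core_fucose_count[hit$bi],
      deamidation = a$deamidation[hit$ai] + b$deamidation[hit$bi],
      raw_score = hit$raw_score,
      oxidation = 0L,
      theoretical_mass = hit$theoretical_mass,
      error = if (tol_unit == "ppm") ppm_error(m, hit$theoretical_mass) else
        m - hit$theoretical_mass,
      artifact_candidate = FALSE
    )
    res$hit_score <- 100 * res$raw_score / sum(res$raw_score)
    arrange(res, desc(.data$hit_score), abs(.data$error), .data$glycoform)
  })

  ann <- assemble_annotation(peaks, per_peak)

  ann <- flag_sodium_adducts(ann, peaks, na_mass, tol, tol_unit,
                             enabled = detect_adducts)

  ann$near_miss <- NA_character_
  ann$near_miss_error <- NA_real_

  structure(ann,
            class = c("glyco_annotation", class(tibble())),
            tol = tol, tol_unit = tol_unit, mode = mode,
            base_mass = bb_a + bb_b,
            backbone_ids = c(dlib$backbone_a$id, dlib$backbone_b$id),
            n_peaks = nrow(peaks))
}
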