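#' Bundled example data
#'
#' `hcg_sequences_path()` points at the bundled FASTA of the mature human
#' chorionic gonadotropin chains (92-residue alpha, 145-residue beta).
#' `hcg_backbones()` returns them as backbones: natively the alpha chain
#' carries 5 and the beta chain 6 intrachain disulfide bonds; with
#' `carbamidomethyl = TRUE` the reduced/alkylated forms used for subunit
#' HPLC-MS are returned instead.
#'
#' @param carbamidomethyl Reduced + alkylated chemistry?
#' @param max_oxidation Variable oxidations allowed during annotation.
#' @return A named list of two [protein_backbone()]s.
#' @export
hcg_backbones <- function(carbamidomethyl = FALSE, max_oxidation = 0L) {
  bbs <- read_backbones(hcg_sequences_path(),
                        carbamidomethyl = carbamidomethyl,
                        max_oxidation = max_oxidation)
  if (!carbamidomethyl) {
    bbs[["hCGalpha"]] <- convert_backbone_context(bbs[["hCGalpha"]], FALSE, 5L)
    bbs[["hCGbeta"]] <- convert_backbone_context(bbs[["hCGbeta"]], FALSE, 6L)
  }
  bbs
}

#' @rdname hcg_backbones
#' @export
hcg_sequences_path <- function() {
  system.file("extdata", "hcg_sequences.fasta", package = "glycoformr",
              mustWork = TRUE)
}

#' Annotate a subunit peak list from files
#'
#' File-level wrapper tying FASTA input, a site-specific glycan library and
#' a deconvoluted peak list into an annotation report. Defaults follow the
#' subunit regime: 20 ppm tolerance, monoisotopic masses.
#'
#' @param fasta FASTA file with the subunit sequence(s).
#' @param backbone_id FASTA record to use (default: first).
#' @param library_file Site library (site, glycan, abundance).
#' @param peaks_file Peak list (mass, intensity).
#' @param out_report Output TSV path (optional).
#' @param tol,tol_unit,mode Annotation settings.
#' @param carbamidomethyl,n_disulfides,max_oxidation Backbone chemistry.
#' @param desialylated Transform the library with [desialylate_library()]
#'   before annotating (for sialidase-treated samples)?
#' @param de_n_glycosylated Transform with [de_n_glycosylate_library()]
#'   (for PNGase F-treated samples)?
#' @param provenance Write a `<out_report>.provenance.json` sidecar?
#' @return The `glyco_annotation`, invisibly when a report is written.
#' @export
run_annotate_subunit <- function(fasta, library_file, peaks_file,
                                 backbone_id = NULL, out_report = NULL,
                                 tol = 20, tol_unit = "ppm",
                                 mode = "monoisotopic",
                                 carbamidomethyl = FALSE, n_disulfides = 0L,
                                 max_oxidation = 0L, desialylated = FALSE,
                                 de_n_glycosylated = FALSE,
                                 provenance = TRUE) {
  bbs <- read_backbones(fasta, carbamidomethyl = carbamidomethyl,
                        n_disulfides = n_disulfides,
                        max_oxidation = max_oxidation)
  bb <- if (is.null(backbone_id)) bbs[[1]] else bbs[[backbone_id]]
  if (is.null(bb)) abort(paste0("no FASTA record '", backbone_id, "'"))
  lib <- read_site_library(library_file)
  if (desialylated) {
    inform("applying in-silico desialylation to the library")
    lib <- desialylate_library(lib)
  }
  if (de_n_glycosylated) {
    inform("applying in-silico de-N-glycosylation to the library")
    lib <- de_n_glycosylate_library(lib)
  }
  peaks <- read_peak_list(peaks_file)
  ann <- annotate_spectrum(peaks, bb, lib, tol = tol, tol_unit = tol_unit,
                           mode = mode)
  g <- glance(ann)
  inform(paste0(g$n_peaks, " peak(s), ", g$n_annotated, " annotated (",
                round(100 * g$annotated_intensity_fraction, 1),
                "% of intensity), ", g$n_assignments, " assignment(s)"))
  if (!is.null(out_report)) {
    write_annotation_report(ann, out_report)
    if (provenance) {
      write_provenance(paste0(out_report, ".provenance.json"),
                       config = list(fasta = fasta, library = library_file,
                                     peaks = peaks_file, tol = tol,
                                     tol_unit = tol_unit, mode = mode,
                                     carbamidomethyl = carbamidomethyl,
                                     n_disulfides = n_disulfides,
                                     max_oxidation = max_oxidation,
                                     desialylated = desialylated,
                                     de_n_glycosylated = de_n_glycosylated))
    }
    return(invisible(ann))
  }
  ann
}

#' Build and write a subunit glycoform library from files
#'
#' Runs [run_annotate_subunit()] and then [build_subunit_library()] at the
#' given fractional-abundance cutoff (default 0.3%).
#'
#' @inheritParams run_annotate_subunit
#' @param cutoff Fractional-abundance cutoff.
#' @param out_library Output TSV path (optional).
#' @return Glycoform entries, invisibly when written.
#' @export
run_build_library <- function(fasta, library_file, peaks_file,
                              backbone_id = NULL, out_library = NULL,
                              cutoff = 0.003, ...) {
  ann <- run_annotate_subunit(fasta, library_file, peaks_file,
                              backbone_id = backbone_id, provenance = FALSE,
                              ...)
  entries <- build_subunit_library(ann, cutoff = cutoff)
  inform(paste0(attr(entries, "retained"), " glycoform(s) retained at cutoff ",
                cutoff, "; coverage ",
                round(100 * attr(entries, "coverage"), 1), "%"))
  if (!is.null(out_library)) {
    write_glycoform_library(entries, out_library)
    write_provenance(paste0(out_library, ".provenance.json"),
                     config = list(fasta = fasta, library = library_file,
                                   peaks = peaks_file, cutoff = cutoff))
    return(invisible(entries))
  }
  entries
}

#' Annotate a native dimer peak list from files
#'
#' Chain glycoform libraries (as written by [write_glycoform_library()])
#' become the two pseudo-sites; the dimer is annotated at +/- 3 Da with
#' average masses by default. Backbones are used in native chemistry with
#' the given disulfide counts.
#'
#' @param fasta FASTA with both chain sequences.
#' @param chain_a_id,chain_b_id FASTA record names.
#' @param library_a,library_b Glycoform library files per chain.
#' @param peaks_file Peak list.
#' @param n_disulfides_a,n_disulfides_b Native disulfide counts.
#' @param out_report Output TSV path (optional).
#' @param tol,tol_unit,mode Annotation settings (defaults 3 Da, average).
#' @return The `glyco_annotation`, invisibly when written.
#' @export
run_annotate_dimer <- function(fasta, chain_a_id, chain_b_id,
                               library_a, library_b, peaks_file,
                               n_disulfides_a = 0L, n_disulfides_b = 0L,
                               out_report = NULL, tol = 3, tol_unit = "Da",
                               mode = "average") {
  bbs <- read_backbones(fasta)
  bb_a <- convert_backbone_context(bbs[[chain_a_id]], FALSE, n_disulfides_a)
  bb_b <- convert_backbone_context(bbs[[chain_b_id]], FALSE, n_disulfides_b)
  ea <- read_glycoform_library(library_a)
  eb <- read_glycoform_library(library_b)
  dlib <- dimer_library(ea, eb, bb_a, bb_b)
  peaks <- read_peak_list(peaks_file)
  ann <- annotate_dimer(peaks, dlib, tol = tol, tol_unit = tol_unit,
                        mode = mode)
  g <- glance(ann)
  inform(paste0(g$n_peaks, " peak(s), ", g$n_annotated, " annotated, ",
                g$n_assignments, " glycoform assignment(s)"))
  if (!is.null(out_report)) {
    write_annotation_report(ann, out_report)
    write_provenance(paste0(out_report, ".provenance.json"),
                     config = list(fasta = fasta, library_a = library_a,
                                   library_b = library_b, peaks = peaks_file,
                                   tol = tol, tol_unit = tol_unit,
                                   mode = mode))
    return(invisible(ann))
  }
  ann
}

#' Compute quality attributes from glycoform library files
#'
#' @param files Named character vector of glycoform library files; names
#'   become target identifiers.
#' @param level Structural level label.
#' @param out Output TSV path (optional).
#' @return CQA tibble (one row per file).
#' @export
run_metrics <- function(files, level = "subunit", out = NULL) {
  res <- purrr::imap_dfr(files, function(f, target) {
    glyco_cqa(read_glycoform_library(f), level = level, target = target)
  })
  if (!is.null(out)) {
    readr::write_tsv(res, out)
    return(invisible(res))
  }
  res
}

#' Simulate a ground-truthed subunit scenario to files
#'
#' Writes the site library, the peak list and a JSON truth sidecar.
#'
#' @param out_prefix Path prefix for `<prefix>_library.tsv`,
#'   `<prefix>_peaks.tsv`, `<prefix>_truth.json`.
#' @param seed RNG seed.
#' @param sites Site table (default: 2 N-sites + 3 O-regions of capacity
#'   2, the layout of a gonadotropin-like subunit pair).
#' @param backbone Backbone to decorate (default: bundled beta chain,
#'   carbamidomethylated).
#' @param n_per_site,concentration,occupancy Passed to
#'   [simulate_site_library()].
#' @param ... Passed to [simulate_spectrum()].
#' @return The `glyco_simulation`, invisibly.
#' @export
run_simulate <- function(out_prefix, seed = 1L,
                         sites = NULL, backbone = NULL,
                         n_per_site = 12L, concentration = 1,
                         occupancy = 0.9, ...) {
  if (is.null(sites)) {
    sites <- bind_rows(
      glycosylation_sites("beta", "N", 13L),
      glycosylation_sites("beta", "N", 30L),
      glycosylation_sites("beta", "O", 115L, 122L, 2L),
      glycosylation_sites("beta", "O", 123L, 133L, 2L),
      glycosylation_sites("beta", "O", 134L, 145L, 2L)
    )
  }
  if (is.null(backbone)) {
    backbone <- hcg_backbones(carbamidomethyl = TRUE)[["hCGbeta"]]
  }
  lib <- simulate_site_library(sites, n_per_site = n_per_site,
                               concentration = concentration,
                               occupancy = occupancy, seed = seed)
  sim <- simulate_spectrum(lib, backbone, ...)
  write_site_library(lib, paste0(out_prefix, "_library.tsv"))
  write_peak_list(sim$peaks, paste0(out_prefix, "_peaks.tsv"))
  jsonlite::write_json(
    list(contributors = sim$truth$contributors,
         cqa = sim$truth$cqa,
         artifact = sim$truth$artifact,
         satellite_of = sim$truth$satellite_of),
    paste0(out_prefix, "_truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  write_provenance(paste0(out_prefix, ".provenance.json"),
                   config = list(out_prefix = out_prefix), seed = seed)
  invisible(sim)
}
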