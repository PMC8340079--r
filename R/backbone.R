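#' Protein backbone description
#'
#' A backbone bundles an amino-acid sequence with its cysteine chemistry
#' (either carbamidomethylated after reduction/alkylation, or native with a
#' given number of disulfide bonds) and the allowed range of variable
#' oxidations. Carbamidomethylation applies to all cysteines, so it is
#' mutually exclusive with disulfide bonds.
#'
#' @param id Identifier (chain name).
#' @param sequence One-letter amino-acid sequence (canonical residues only).
#' @param carbamidomethyl Logical; carbamidomethylate every Cys?
#' @param n_disulfides Number of intrachain disulfide bonds (each removes
#'   two hydrogens).
#' @param max_oxidation Maximum number of variable oxidations (+15.995 Da
#'   each, monoisotopic) considered during annotation.
#' @return An object of class `glyco_backbone`.
#' @examples
#' bb <- protein_backbone("demo", "PEPTIDE")
#' backbone_mass(bb, "monoisotopic")
#' @export
protein_backbone <- function(id, sequence, carbamidomethyl = FALSE,
                             n_disulfides = 0L, max_oxidation = 0L) {
  sequence <- toupper(stringr::str_trim(sequence))
  letters_ok <- gf_amino_acids()$letter
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, letters_ok)
  if (length(bad)) {
    abort(paste0("unknown amino-acid letter(s): ", paste(unique(bad), collapse = ", ")))
  }
  n_cys <- sum(res == "C")
  if (n_disulfides > floor(n_cys / 2)) {
    abort(paste0("n_disulfides (", n_disulfides, ") exceeds floor(#Cys / 2) = ",
                 floor(n_cys / 2)))
  }
  if (carbamidomethyl && n_disulfides > 0) {
    abort("carbamidomethylation and disulfide bonds are mutually exclusive")
  }
  structure(
    list(id = id, sequence = sequence, n_cys = n_cys,
         carbamidomethyl = isTRUE(carbamidomethyl),
         n_disulfides = as.integer(n_disulfides),
         max_oxidation = as.integer(max_oxidation)),
    class = "glyco_backbone"
  )
}

#' @export
print.glyco_backbone <- function(x, ...) {
  cat("<glyco_backbone> ", x$id, ": ", nchar(x$sequence), " aa, ",
      x$n_cys, " Cys (",
      if (x$carbamidomethyl) "carbamidomethylated" else
        paste0(x$n_disulfides, " disulfide bond(s)"),
      "), up to ", x$max_oxidation, " oxidation(s)\n", sep = "")
  invisible(x)
}

#' Backbone mass
#'
#' Residue-mass sum plus one water per chain, plus fixed modifications
#' (carbamidomethyl on every Cys if selected) and the disulfide decrement
#' (-2 H per bond). Variable oxidations are not included; annotation folds
#' them in as alternative backbone masses.
#'
#' @param backbone A [protein_backbone()].
#' @param mode Mass mode.
#' @return Mass in Da.
#' @export
backbone_mass <- function(backbone, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(backbone, "glyco_backbone"))
  aa <- gf_amino_acids()
  w <- setNames(aa[[mode]], aa$letter)
  res <- strsplit(backbone$sequence, "")[[1]]
  m <- sum(w[res]) + modification_mass("water", mode)
  if (backbone$carbamidomethyl) {
    m <- m + backbone$n_cys * modification_mass("carbamidomethyl", mode)
  }
  m + backbone$n_disulfides * modification_mass("disulfide", mode)
}

#' Convert a backbone between cysteine chemistries
#'
#' Recomputes the backbone description for a different analysis context
#' (e.g. from the reduced + carbamidomethylated form used for subunit
#' HPLC-MS to the native disulfide-bonded form of the intact complex).
#' Glycan compositions attached downstream are unaffected; only the
#' backbone mass changes.
#'
#' @param backbone A [protein_backbone()].
#' @param carbamidomethyl Target alkylation state.
#' @param n_disulfides Target number of disulfide bonds.
#' @return A new `glyco_backbone`.
#' @export
convert_backbone_context <- function(backbone, carbamidomethyl,
                                     n_disulfides) {
  stopifnot(inherits(backbone, "glyco_backbone"))
  protein_backbone(backbone$id, backbone$sequence,
                   carbamidomethyl = carbamidomethyl,
                   n_disulfides = n_disulfides,
                   max_oxidation = backbone$max_oxidation)
}

#' Read protein backbones from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @param ... Passed to [protein_backbone()] (chemistry flags applied to
#'   every record).
#' @return A named list of `glyco_backbone` objects.
#' @export
read_backbones <- function(path, ...) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    seq_chr <- as.character(seqs)
  } else {
    lines <- readr::read_lines(path)
    hdr <- grepl("^>", lines)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    grp <- cumsum(hdr)
    seq_chr <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                      collapse = "")
  }
  out <- purrr::map2(ids, seq_chr, function(id, s) protein_backbone(id, s, ...))
  setNames(out, ids)
}
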