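# shared fixtures, built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

hcg_sequences <- function() {
  lines <- readLines(hcg_sequences_path())
  hdr <- grepl("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                 collapse = "")
  stats::setNames(seqs, ids)
}

# two-site toy library with an isobaric swap (A2S2 vs A2G2 differ; the
# glycoform totals A2S2+A2G2 are order-isobaric across sites)
toy_swap_library <- function(p1 = 0.8, p2 = 0.5) {
  glyco_library(data.frame(
    site = c("s1", "s1", "s2", "s2"),
    glycan = c("A2S2", "A2G2", "A2S2", "A2G2"),
    abundance = c(p1, 1 - p1, p2, 1 - p2)
  ))
}

toy_backbone <- function(max_oxidation = 0L) {
  protein_backbone("toy", "PEPTIDE", max_oxidation = max_oxidation)
}

# beta-chain-like site layout: 2 N-sites + 3 O-regions of capacity 2
beta_like_sites <- function() {
  dplyr::bind_rows(
    glycosylation_sites("beta", "N", 13L),
    glycosylation_sites("beta", "N", 30L),
    glycosylation_sites("beta", "O", 115L, 122L, 2L),
    glycosylation_sites("beta", "O", 123L, 133L, 2L),
    glycosylation_sites("beta", "O", 134L, 145L, 2L)
  )
}

# mass of a glycan name on a backbone, for building exact peak lists
species_mass <- function(names, backbone, mode = "monoisotopic") {
  backbone_mass(backbone, mode) +
    sum(composition_mass(parse_glycan_name(names), mode))
}

enumerate_entries_for_test <- function(lib, floor = 1e-4) {
  glycoform_entries(lib, floor = floor)
}

# brute-force stage-1 oracle: full enumeration over bounded compositions
brute_force_decompose <- function(residual, tol_da, bounds, mode) {
  grid <- expand.grid(hex = 0:bounds[["hex"]], hexnac = 0:bounds[["hexnac"]],
                      fuc = 0:bounds[["fuc"]], neu5ac = 0:bounds[["neu5ac"]])
  grid$mass <- composition_mass(grid, mode)
  grid[abs(residual - grid$mass) <= tol_da, c("hex", "hexnac", "fuc", "neu5ac")]
}

comp_key <- function(df) {
  sort(paste(df$hex, df$hexnac, df$fuc, df$neu5ac, sep = "/"))
}
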