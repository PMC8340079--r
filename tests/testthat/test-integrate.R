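test_that("subunit libraries recover simulation truth at cutoff 0", {
  lib <- glyco_library(data.frame(
    site = c("s1", "s1", "s2"),
    glycan = c("A2S2", "A2G2", "core-1"),
    abundance = c(0.7, 0.3, 1)
  ))
  bb <- toy_backbone()
  sim <- simulate_spectrum(lib, bb, seed = 31)
  ann <- annotate_spectrum(sim$peaks, bb, lib)
  entries <- build_subunit_library(ann, cutoff = 0)
  truth <- sim$truth$glycoforms
  merged <- dplyr::left_join(truth, tibble::as_tibble(entries),
                             by = "glycoform")
  expect_equal(merged$fractional_abundance, merged$abundance,
               tolerance = 1e-9)
  expect_error(build_subunit_library(ann, cutoff = 0.99), "removes every")
})

test_that("backbone context conversion applies the alkylation arithmetic", {
  seqs <- hcg_sequences()
  red <- protein_backbone("beta", seqs[["hCGbeta"]], carbamidomethyl = TRUE)
  nat <- convert_backbone_context(red, carbamidomethyl = FALSE,
                                  n_disulfides = 6L)
  delta <- backbone_mass(nat, "average") - backbone_mass(red, "average")
  expect_equal(delta, -12 * 57.052 - 12 * 1.008, tolerance = 1e-2)
  alpha_red <- protein_backbone("alpha", seqs[["hCGalpha"]],
                                carbamidomethyl = TRUE)
  alpha_nat <- convert_backbone_context(alpha_red, FALSE, 5L)
  expect_equal(backbone_mass(alpha_nat, "average") -
                 backbone_mass(alpha_red, "average"),
               -10 * 57.052 - 10 * 1.008, tolerance = 1e-2)
  # identity conversion
  same <- convert_backbone_context(nat, FALSE, 6L)
  expect_equal(backbone_mass(same, "average"), backbone_mass(nat, "average"))
})

test_that("dimer libraries demand native chemistry and warn when oversized", {
  entries <- parse_glycan_name(c("A2S2", "A2G2"))
  entries$fractional_abundance <- c(0.6, 0.4)
  entries$n_n_glycans <- 1L
  entries$core_fucose_count <- 0L
  bb_cam <- protein_backbone("a", "CCPEPTIDE", carbamidomethyl = TRUE)
  bb_nat <- protein_backbone("a", "CCPEPTIDE", n_disulfides = 1L)
  expect_error(dimer_library(entries, entries, bb_cam, bb_nat),
               "carbamidomethylated")
  expect_warning(dimer_library(entries[rep(1:2, 3), ], entries, bb_nat,
                               bb_nat, max_entries = 5),
                 "exceeds")
  dl <- dimer_library(entries, entries, bb_nat, bb_nat)
  expect_equal(sum(dl$chain_a$abundance), 1)
})

test_that("dimer annotation assigns chain pairs with product hit scores", {
  seqs <- hcg_sequences()
  bb_a <- protein_backbone("alpha", seqs[["hCGalpha"]], n_disulfides = 5L)
  bb_b <- protein_backbone("beta", seqs[["hCGbeta"]], n_disulfides = 6L)
  ea <- parse_glycan_name(c("A2S2", "A2G2"))
  ea$fractional_abundance <- c(0.7, 0.3)
  eb <- parse_glycan_name(c("A2S1G1", "A2G2F"))
  eb$fractional_abundance <- c(0.6, 0.4)
  dl <- dimer_library(ea, eb, bb_a, bb_b)
  m <- backbone_mass(bb_a, "average") + backbone_mass(bb_b, "average") +
    composition_mass(parse_glycan_name("A2S2"), "average") +
    composition_mass(parse_glycan_name("A2S1G1"), "average")
  ann <- annotate_dimer(data.frame(mass = m, intensity = 1), dl)
  hit <- dplyr::filter(ann, !is.na(glycoform))
  expect_equal(hit$chain_a_glycoform, "A2S2")
  expect_equal(hit$chain_b_glycoform, "A2S1G1")
  expect_equal(hit$hit_score, 100)
  # mass closure: dimer theoretical mass is the exact chain sum
  expect_equal(hit$theoretical_mass, m, tolerance = 1e-9)
})

test_that("isobaric chain pairs split hit scores by abundance products", {
  # A2S2 + A2G2 vs A2G2 + A2S2 across chains: exactly isobaric
  bb <- protein_backbone("x", "PEPTIDE")
  ea <- parse_glycan_name(c("A2S2", "A2G2"))
  ea$fractional_abundance <- c(0.8, 0.2)
  eb <- parse_glycan_name(c("A2S2", "A2G2"))
  eb$fractional_abundance <- c(0.5, 0.5)
  dl <- dimer_library(ea, eb, bb, bb)
  m <- 2 * backbone_mass(bb, "average") +
    composition_mass(parse_glycan_name("A2S2"), "average") +
    composition_mass(parse_glycan_name("A2G2"), "average")
  ann <- annotate_dimer(data.frame(mass = m, intensity = 1), dl)
  hit <- dplyr::filter(ann, !is.na(glycoform))
  expect_equal(nrow(hit), 2L)
  expect_equal(hit$hit_score[hit$chain_a_glycoform == "A2S2"], 80)
  expect_equal(hit$hit_score[hit$chain_a_glycoform == "A2G2"], 20)
})

test_that("truncated-library dimer annotation is a subset of untruncated", {
  set.seed(33)
  sites <- dplyr::bind_rows(glycosylation_sites("a", "N", 52L),
                            glycosylation_sites("a", "O", 1L, 10L, 2L))
  lib_a <- simulate_site_library(sites, n_per_site = 4, seed = 34)
  lib_b <- simulate_site_library(sites, n_per_site = 4, seed = 35)
  bb <- protein_backbone("x", "PEPTIDE")
  ga <- enumerate_entries_for_test(lib_a)
  gb <- enumerate_entries_for_test(lib_b)
  sim <- simulate_dimer(ga, gb, bb, bb, seed = 36)
  full <- annotate_dimer(sim$peaks, dimer_library(ga, gb, bb, bb))
  ta <- truncate_by_cutoff(ga, 0.05)
  tb <- truncate_by_cutoff(gb, 0.05)
  trunc <- annotate_dimer(sim$peaks, dimer_library(ta, tb, bb, bb))
  expect_true(all(na.omit(trunc$glycoform) %in% full$glycoform))
  expect_lte(sum(!is.na(trunc$glycoform)), sum(!is.na(full$glycoform)))
  # combination-space contraction relative to the joint site-level space
  joint <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(lib_a), site = paste0("A_", site)),
    dplyr::mutate(tibble::as_tibble(lib_b), site = paste0("B_", site))
  )
  expect_lt(nrow(ta) * nrow(tb), count_candidate_glycoforms(joint))
})
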