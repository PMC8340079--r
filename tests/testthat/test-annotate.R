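test_that("stage-1 decomposition handles the trivial and isobaric cases", {
  z <- decompose_mass(0, tol_da = 0.01)
  expect_equal(nrow(z), 1L)
  expect_equal(unlist(z[1, glycan_units()]), c(hex = 0L, hexnac = 0L,
                                               fuc = 0L, neu5ac = 0L))
  # Neu5Ac (291.26) and 2x Fuc (292.28) are isobaric within +/- 3 Da
  iso <- decompose_mass(composition_mass(c(neu5ac = 1), "average"),
                        tol_da = 3, mode = "average")
  expect_true(any(iso$neu5ac == 1 & iso$fuc == 0))
  expect_true(any(iso$neu5ac == 0 & iso$fuc == 2))
  # far-negative residual yields nothing
  expect_equal(nrow(decompose_mass(-50, tol_da = 1)), 0L)
})

test_that("stage-1 search equals brute-force enumeration (completeness)", {
  bounds <- c(hex = 5L, hexnac = 5L, fuc = 5L, neu5ac = 5L)
  set.seed(21)
  residuals <- c(runif(12, 0, 2500), composition_mass(c(hex = 3, hexnac = 2),
                                                      "monoisotopic"))
  for (r in residuals) {
    for (mode in c("monoisotopic", "average")) {
      got <- decompose_mass(r, tol_da = 1.5, bounds = bounds, mode = mode)
      want <- brute_force_decompose(r, 1.5, bounds, mode)
      expect_equal(comp_key(got), comp_key(want), info = paste(mode, r))
    }
  }
})

test_that("enlarging the tolerance never removes a composition hit", {
  set.seed(22)
  bounds <- c(hex = 6L, hexnac = 6L, fuc = 4L, neu5ac = 4L)
  for (r in runif(8, 100, 2000)) {
    narrow <- decompose_mass(r, tol_da = 0.5, bounds = bounds)
    wide <- decompose_mass(r, tol_da = 2.5, bounds = bounds)
    expect_true(all(comp_key(narrow) %in% comp_key(wide)))
  }
})

test_that("site assignment enumerates matching tuples with product scores", {
  # both sites fixed: single assignment at 100%
  lib1 <- glyco_library(data.frame(site = c("s1", "s2"),
                                   glycan = "A2S2", abundance = 1))
  target <- parse_glycan_name("A2S2")[glycan_units()] * 2L
  a1 <- assign_sites(target, lib1)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$hit_score, 100)
  # isobaric swap: hand-computed 80 / 20 split
  a2 <- assign_sites(parse_glycan_name("A2S2")[glycan_units()] +
                       parse_glycan_name("A2G2")[glycan_units()],
                     toy_swap_library(0.8, 0.5))
  expect_equal(nrow(a2), 2L)
  expect_equal(a2$hit_score[a2$glycoform == "A2S2/A2G2"],
               100 * 0.8 * 0.5 / (0.8 * 0.5 + 0.2 * 0.5))
  expect_equal(a2$hit_score[a2$glycoform == "A2G2/A2S2"], 20)
  # unreachable target: empty result
  expect_equal(nrow(assign_sites(c(hex = 1, hexnac = 0, fuc = 0, neu5ac = 0),
                                 lib1)), 0L)
})

test_that("hit scores always sum to 100 per annotated peak", {
  set.seed(23)
  for (i in 1:5) {
    lib <- simulate_site_library(beta_like_sites(), n_per_site = 5,
                                 seed = 100 + i)
    bb <- toy_backbone()
    sim <- simulate_spectrum(lib, bb, seed = 200 + i)
    ann <- annotate_spectrum(head(sim$peaks, 40), bb, lib)
    sums <- tapply(ann$hit_score[!is.na(ann$glycoform) & !ann$inherited],
                   ann$peak_id[!is.na(ann$glycoform) & !ann$inherited], sum)
    expect_true(all(abs(sums - 100) < 1e-6))
    # ranking is by descending hit score
    by_peak <- split(ann$hit_score[!is.na(ann$glycoform)],
                     ann$peak_id[!is.na(ann$glycoform)])
    expect_true(all(vapply(by_peak, function(h) all(diff(h) <= 1e-12),
                           logical(1))))
  }
})

test_that("a clean single-glycoform peak annotates at 100% with zero error", {
  lib <- glyco_library(data.frame(site = "s1", glycan = "A2G2", abundance = 1))
  bb <- toy_backbone()
  m <- species_mass("A2G2", bb)
  ann <- annotate_spectrum(data.frame(mass = m, intensity = 1), bb, lib)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$glycoform, "A2G2")
  expect_equal(ann$hit_score, 100)
  expect_equal(ann$error, 0, tolerance = 1e-6)
  expect_false(ann$unannotated)
})

test_that("unannotated peaks are kept, flagged, and get a near-miss", {
  lib <- glyco_library(data.frame(site = "s1", glycan = "A2G2", abundance = 1))
  bb <- toy_backbone()
  off <- species_mass("A2G2", bb) + 0.8 # ~0.8 Da off: outside 20 ppm
  ann <- annotate_spectrum(data.frame(mass = off, intensity = 1), bb, lib,
                           rescue_artifacts = FALSE, detect_adducts = FALSE)
  expect_true(ann$unannotated)
  expect_true(is.na(ann$glycoform))
  expect_false(is.na(ann$near_miss))
})

test_that("sodium-adduct satellites inherit the parent's assignments", {
  lib <- glyco_library(data.frame(site = "s1", glycan = "A2G2", abundance = 1))
  bb <- toy_backbone()
  m <- species_mass("A2G2", bb)
  peaks <- data.frame(mass = c(m, m + 21.98194), intensity = c(1, 0.3))
  ann <- annotate_spectrum(peaks, bb, lib)
  sat <- dplyr::filter(ann, peak_id == 2)
  expect_true(all(sat$is_adduct_satellite))
  expect_true(all(sat$inherited))
  expect_equal(sat$glycoform, "A2G2")
  expect_equal(sat$adduct_parent, 1L)
  # satellite rows are excluded from fractional abundances
  fa <- fractional_abundances(ann)
  expect_equal(fa$fractional_abundance, 1)
})

test_that("-1 Da deconvolution artifacts are rescued and flagged", {
  lib <- glyco_library(data.frame(site = "s1", glycan = "A2G2", abundance = 1))
  bb <- toy_backbone()
  m <- species_mass("A2G2", bb) - 1.00235
  ann <- annotate_spectrum(data.frame(mass = m, intensity = 1), bb, lib,
                           rescue_artifacts = TRUE)
  expect_equal(ann$glycoform, "A2G2")
  expect_true(ann$artifact_candidate)
  no_rescue <- annotate_spectrum(data.frame(mass = m, intensity = 1), bb, lib,
                                 rescue_artifacts = FALSE)
  expect_true(no_rescue$unannotated)
})

test_that("oxidation variants are searched and merged into one glycoform", {
  lib <- glyco_library(data.frame(site = "s1", glycan = "A2G2", abundance = 1))
  bb <- protein_backbone("toy", "PEPTIDE", max_oxidation = 1L)
  m_ox <- species_mass("A2G2", bb) + 15.99491
  ann <- annotate_spectrum(data.frame(mass = m_ox, intensity = 1), bb, lib,
                           detect_adducts = FALSE)
  expect_equal(ann$glycoform, "A2G2")
  expect_equal(ann$oxidation, 1L)
  expect_equal(ann$hit_score, 100)
})

test_that("fractional abundances follow the intensity x hit-score rule", {
  # weighted-sum oracle: peaks {3: g1 100%} and {1: g1 50%, g2 50%}
  lib <- toy_swap_library(0.5, 0.5)
  bb <- toy_backbone()
  m_mixed <- species_mass(c("A2S2", "A2G2"), bb)
  m_pure <- species_mass(c("A2S2", "A2S2"), bb)
  ann <- annotate_spectrum(data.frame(mass = c(m_pure, m_mixed),
                                      intensity = c(3, 1)), bb, lib,
                           detect_adducts = FALSE)
  fa <- fractional_abundances(ann)
  expect_equal(fa$fractional_abundance[fa$glycoform == "A2S2/A2S2"], 0.75)
  expect_equal(fa$fractional_abundance[fa$glycoform == "A2S2/A2G2"], 0.125)
  expect_equal(fa$fractional_abundance[fa$glycoform == "A2G2/A2S2"], 0.125)
  expect_equal(sum(fa$fractional_abundance), 1)
})

test_that("abundance coverage agrees with a sort-and-sum oracle", {
  expect_equal(abundance_coverage(
    tibble::tibble(fractional_abundance = c(0.6, 0.3, 0.1)), 0.05),
    tibble::tibble(count = 3L, coverage = 1))
  expect_equal(abundance_coverage(
    tibble::tibble(fractional_abundance = c(0.6, 0.3, 0.1)), 0.7)$count, 0L)
  set.seed(24)
  w <- rgamma(1000, 0.5); w <- w / sum(w)
  got <- abundance_coverage(tibble::tibble(fractional_abundance = w), 0.001)
  expect_equal(got$count, sum(w > 0.001))
  expect_equal(got$coverage, sum(w[w > 0.001]))
})
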