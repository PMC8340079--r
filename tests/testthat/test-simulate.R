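test_that("library simulation is deterministic under a seed", {
  s <- beta_like_sites()
  a <- simulate_site_library(s, seed = 51)
  b <- simulate_site_library(s, seed = 51)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_site_library(s, seed = 52)
  expect_false(identical(a$abundance, c$abundance))
})

test_that("occupancy is encoded as the unmodified weight at N-sites", {
  s <- beta_like_sites()
  lib <- simulate_site_library(s, occupancy = 0.626, seed = 53)
  n_sites <- unique(lib$site[lib$glycan_class == "N"])
  for (site in n_sites) {
    un <- lib$abundance[lib$site == site & lib$glycan == "unmodified"]
    expect_equal(un, 1 - 0.626, tolerance = 1e-12)
  }
  # per-site occupancies by name
  lib2 <- simulate_site_library(s, occupancy = c(N13 = 0.626, N30 = 1),
                                seed = 54)
  expect_equal(lib2$abundance[lib2$site == "N13" & lib2$glycan == "unmodified"],
               0.374, tolerance = 1e-12)
  expect_false("unmodified" %in% lib2$glycan[lib2$site == "N30" &
                                               lib2$abundance > 0])
})

test_that("large Dirichlet concentration approaches uniform abundances", {
  s <- glycosylation_sites("x", "N", 1L)
  lib <- simulate_site_library(s, n_per_site = 8, concentration = 5e4,
                               occupancy = 1, seed = 55)
  glyc <- lib$abundance[lib$glycan != "unmodified"]
  expect_true(all(abs(glyc - 1 / length(glyc)) < 0.02))
})

test_that("noiseless spectra expose theoretical masses and true intensities", {
  lib <- glyco_library(data.frame(site = "s1",
                                  glycan = c("A2S2", "A2G2", "M5"),
                                  abundance = c(0.5, 0.3, 0.2)))
  bb <- toy_backbone()
  sim <- simulate_spectrum(lib, bb, seed = 56)
  expect_equal(nrow(sim$peaks), 3L)
  expected <- vapply(c("A2S2", "A2G2", "M5"), function(g) species_mass(g, bb),
                     numeric(1))
  expect_equal(sort(sim$peaks$mass), sort(unname(expected)), tolerance = 1e-9)
  expect_equal(sort(sim$peaks$intensity), c(0.2, 0.3, 0.5))
})

test_that("near-isobars merge into one peak within the resolution window", {
  # one Neu5Ac (291.10) vs two fucoses (292.12) differ by ~1.02 Da:
  # unresolved at a 3 Da window, resolved at 0.1 Da
  lib <- glyco_library(data.frame(site = c("s1", "s1", "s2", "s2"),
                                  glycan = c("A2S1G1", "A2G2F",
                                             "A2G2", "A2G2F"),
                                  abundance = c(0.6, 0.4, 0.5, 0.5)))
  bb <- toy_backbone()
  m_neu <- species_mass(c("A2S1G1", "A2G2"), bb)
  m_2fuc <- species_mass(c("A2G2F", "A2G2F"), bb)
  expect_lt(abs(m_neu - m_2fuc), 3)
  merged <- simulate_spectrum(lib, bb, resolution_window = 3, seed = 57)
  expect_equal(nrow(merged$peaks), 3L)
  counts <- table(merged$truth$contributors$peak_id)
  expect_true(any(counts == 2))
  resolved <- simulate_spectrum(lib, bb, resolution_window = 0.1, seed = 57)
  expect_equal(nrow(resolved$peaks), 4L)
  # per-peak contributions sum to the noiseless intensity
  by_peak <- tapply(merged$truth$contributors$abundance,
                    merged$truth$contributors$peak_id, sum)
  expect_equal(as.numeric(by_peak),
               merged$peaks$intensity[order(merged$peaks$mass)],
               tolerance = 1e-12)
})

test_that("satellite and artifact injection follow their probabilities", {
  lib <- glyco_library(data.frame(site = "s1", glycan = c("A2S2", "M5"),
                                  abundance = c(0.7, 0.3)))
  bb <- toy_backbone()
  sim <- simulate_spectrum(lib, bb, adduct_prob = 1, adduct_ratio = 0.25,
                           seed = 58)
  expect_equal(nrow(sim$peaks), 4L) # 2 true + 2 satellites
  sat <- !is.na(sim$truth$satellite_of)
  expect_equal(sum(sat), 2L)
  parent <- sim$truth$satellite_of[sat]
  expect_equal(sim$peaks$mass[sat] - sim$peaks$mass[parent],
               rep(21.98194, 2), tolerance = 1e-4)
  expect_equal(sim$peaks$intensity[sat], 0.25 * sim$peaks$intensity[parent])
  art <- simulate_spectrum(lib, bb, artifact_prob = 1, seed = 59)
  expect_true(all(art$truth$artifact))
  expect_equal(art$peaks$mass, art$truth$peak_true_mass - 1.00235,
               tolerance = 1e-9)
})

test_that("dimer simulation multiplies independent chain abundances", {
  ea <- parse_glycan_name(c("A2S2", "A2G2"))
  ea$fractional_abundance <- c(0.7, 0.3)
  eb <- parse_glycan_name(c("A2S1G1", "A2G2F"))
  eb$fractional_abundance <- c(0.6, 0.4)
  bb <- toy_backbone()
  sim <- simulate_dimer(ea, eb, bb, bb, seed = 60, resolution_window = 0.5)
  gf <- sim$truth$glycoforms
  expect_equal(nrow(gf), 4L)
  expect_equal(sum(gf$abundance), 1, tolerance = 1e-12)
  # marginals recover the chain abundances
  a_marg <- tapply(gf$abundance, sub(" \\| .*$", "", gf$glycoform), sum)
  expect_equal(as.numeric(a_marg[c("A2S2", "A2G2")]), c(0.7, 0.3),
               tolerance = 1e-12)
  # single-glycoform chains collapse to one peak at the summed mass
  one <- simulate_dimer(ea[1, ], eb[1, ], bb, bb, seed = 61)
  expect_equal(nrow(one$peaks), 1L)
  expect_equal(one$peaks$mass,
               2 * backbone_mass(bb, "average") +
                 composition_mass(parse_glycan_name("A2S2"), "average") +
                 composition_mass(parse_glycan_name("A2S1G1"), "average"),
               tolerance = 1e-9)
})

test_that("sigma=0 spectra are recovered exactly by annotation", {
  lib <- simulate_site_library(beta_like_sites(), n_per_site = 4, seed = 62)
  bb <- toy_backbone()
  sim <- simulate_spectrum(lib, bb, seed = 63)
  ann <- annotate_spectrum(sim$peaks, bb, lib)
  got <- split(ann$glycoform[!is.na(ann$glycoform)],
               ann$peak_id[!is.na(ann$glycoform)])
  want <- split(sim$truth$contributors$glycoform,
                sim$truth$contributors$peak_id)
  # every true contributor is found at its peak
  ok <- vapply(names(want), function(p) all(want[[p]] %in% got[[p]]),
               logical(1))
  expect_true(all(ok))
})
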