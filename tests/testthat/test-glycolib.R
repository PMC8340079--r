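test_that("library loading normalizes per site and sums duplicates", {
  lib <- glyco_library(data.frame(site = "s1", glycan = c("A2S2", "A2G2"),
                                  abundance = c(3, 1)))
  expect_equal(sort(lib$abundance), c(0.25, 0.75))
  dup <- glyco_library(data.frame(site = "s1", glycan = c("A2S2", "A2S2", "A2G2"),
                                  abundance = c(1, 1, 2)))
  expect_equal(nrow(dup), 2L)
  expect_equal(dup$abundance[dup$glycan == "A2S2"], 0.5)
  expect_error(glyco_library(data.frame(site = "s", glycan = "A2", abundance = -1)),
               "non-negative")
})

test_that("sub-100% occupancy is encoded by the unmodified species", {
  lib <- glyco_library(data.frame(
    site = "N13", glycan = c("unmodified", "A2S2F", "A2S2"),
    abundance = c(0.374, 0.4, 0.226)
  ))
  occupancy <- 1 - lib$abundance[lib$glycan == "unmodified"]
  expect_equal(occupancy, 0.626, tolerance = 1e-9)
})

test_that("in-silico desialylation merges species and zeroes Neu5Ac", {
  lib <- glyco_library(data.frame(site = "s1", glycan = c("A2S2", "A2G2"),
                                  abundance = c(0.6, 0.4)))
  ds <- desialylate_library(lib)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$glycan, "A2G2")
  expect_equal(ds$abundance, 1)
  # fully sialylated fucosylated species becomes its Gal-terminated parent
  one <- desialylate_library(glyco_library(
    data.frame(site = "s", glycan = "A2S1G1F", abundance = 1)))
  expect_equal(one$glycan, "A2G2F")
  # O-glycans lose the sialic suffix
  olib <- desialylate_library(glyco_library(
    data.frame(site = "o", glycan = c("2 x Core + 3 x S", "2 x Core"),
               abundance = c(0.7, 0.3))))
  expect_equal(nrow(olib), 1L)
  expect_equal(olib$neu5ac, 0L)
})

test_that("library transforms preserve normalization and are idempotent", {
  lib <- glyco_library(data.frame(
    site = rep(c("N13", "O1"), each = 3),
    glycan = c("A2S2", "A2S1G1F", "unmodified",
               "core-1", "2 x Core + 3 x S", "unmodified"),
    abundance = c(0.5, 0.3, 0.2, 0.4, 0.4, 0.2)
  ))
  for (f in list(desialylate_library, de_n_glycosylate_library)) {
    t1 <- f(lib)
    sums <- tapply(t1$abundance, t1$site, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_equal(as.data.frame(f(t1)), as.data.frame(t1))
  }
  expect_equal(degree_of_sialylation(
    dplyr::mutate(tibble::as_tibble(desialylate_library(lib)),
                  fractional_abundance = abundance)), 0)
})

test_that("de-N-glycosylation deamidates occupied N-sites only", {
  lib <- glyco_library(data.frame(
    site = c("N1", "N1", "O1"),
    glycan = c("A2G2F", "unmodified", "core-1"),
    abundance = c(0.6, 0.4, 1)
  ))
  dn <- de_n_glycosylate_library(lib)
  n1 <- dplyr::filter(tibble::as_tibble(dn), site == "N1")
  expect_setequal(n1$glycan, c("deamidated", "unmodified"))
  expect_equal(n1$abundance[n1$glycan == "deamidated"], 0.6)
  expect_equal(n1$deamidation[n1$glycan == "deamidated"], 1L)
  # O-region untouched
  expect_equal(dplyr::filter(tibble::as_tibble(dn), site == "O1")$glycan, "core-1")
  # fully unoccupied N-site: no deamidation anywhere
  un <- de_n_glycosylate_library(glyco_library(
    data.frame(site = "N1", glycan = "unmodified", abundance = 1)))
  expect_equal(un$glycan, "unmodified")
  expect_equal(sum(un$deamidation), 0L)
})

test_that("glycoform truncation reports coverage and is monotone", {
  e <- tibble::tibble(glycoform = letters[1:4],
                      fractional_abundance = c(0.5, 0.3, 0.15, 0.05))
  t1 <- truncate_by_cutoff(e, 0.1)
  expect_equal(attr(t1, "retained"), 3L)
  expect_equal(attr(t1, "coverage"), 0.95)
  expect_equal(attr(truncate_by_cutoff(e, 0), "coverage"), 1)
  expect_equal(nrow(truncate_by_cutoff(e, 1)), 0L)
  expect_error(truncate_by_cutoff(e, -0.1), "\\[0, 1\\]")
  cuts <- sort(runif(10))
  kept <- vapply(cuts, function(co) nrow(truncate_by_cutoff(e, co)), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("candidate glycoform count is the product of per-site entry counts", {
  lib <- glyco_library(data.frame(
    site = rep(paste0("s", 1:4), each = 5),
    glycan = rep(c("A1", "A2", "A2S1", "A2S2", "unmodified"), 4),
    abundance = rep(0.2, 20)
  ))
  expect_equal(count_candidate_glycoforms(lib), 625)
  # a 2-pseudo-site dimer library with 42 x 58 entries
  dimerish <- tibble::tibble(site = rep(c("a", "b"), c(42, 58)))
  expect_equal(count_candidate_glycoforms(dimerish), 2436)
  one <- glyco_library(data.frame(site = c("s1", "s2", "s2"),
                                  glycan = c("A2", "A2", "A1"),
                                  abundance = c(1, 1, 1)))
  expect_equal(count_candidate_glycoforms(one), 2)
})

test_that("site libraries round-trip through delimited text", {
  lib <- glyco_library(data.frame(
    site = c("N13", "N13", "O1"),
    glycan = c("A2S2", "unmodified", "2 x Core + 3 x S"),
    abundance = c(0.7, 0.3, 1)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_library(lib, path)
  back <- read_site_library(path)
  expect_equal(as.data.frame(back), as.data.frame(lib))
  expect_error(read_site_library(
    withr::local_tempfile(lines = "site\tglycan\tabundance\ns\tNOPE\t1",
                          fileext = ".tsv")), "NOPE")
})
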