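#' Default glycan candidate pools for simulation
#'
#' The N-pool spans the structures dominating recombinant gonadotropin
#' glycosylation: mono- to triantennary complex-type glycans with varying
#' sialylation/galactosylation, with and without core fucose, plus
#' high-mannose M5/M6 and one hybrid. The O-pool for a region of capacity
#' `k` holds all `x` core-1 / `y` Neu5Ac combinations with
#' `x <= k`, `y <= 2x`. Both pools include `"unmodified"` so occupancy is
#' part of the same categorical draw.
#'
#' @param capacity O-region capacity (max core-1 units).
#' @return Character vector of glycan names.
#' @export
default_n_glycan_pool <- function() {
  complex <- purrr::map(1:3, function(a) {
    combos <- tidyr::crossing(s = 0:a, g = 0:a)
    combos <- filter(combos, .data$s + .data$g <= a)
    nm <- paste0("A", a,
                 ifelse(combos$s > 0, paste0("S", combos$s), ""),
                 ifelse(combos$g > 0, paste0("G", combos$g), ""))
    c(nm, paste0(nm, "F"))
  })
  unique(c(unlist(complex), "M5", "M6", "M5-A1G1", "M5-A1G1F"))
}

#' @rdname default_n_glycan_pool
#' @export
default_o_region_pool <- function(capacity = 2L) {
  combos <- tidyr::crossing(x = seq_len(capacity), y = 0:(2L * capacity))
  combos <- filter(combos, .data$y <= 2L * .data$x)
  names <- purrr::map2_chr(combos$x, combos$y, function(x, y) {
    if (y == 0 && x == 1) "core-1" else
      paste0(x, " x Core", if (y > 0) paste0(" + ", y, " x S"))
  })
  unique(names)
}

rdirichlet1 <- function(k, concentration) {
  g <- rgamma(k, shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Simulate a site-specific quantitative glycan library
#'
#' Per-site categorical abundances are drawn from a symmetric Dirichlet
#' prior over a random subset of the glycan pool. At N-sites, occupancy
#' below 1 is encoded by giving `"unmodified"` the weight `1 - occupancy`
#' and scaling glycan weights by `occupancy`.
#'
#' @param sites Site table from [glycosylation_sites()]; a `site` label
#'   column is derived from kind and span.
#' @param n_per_site Number of glycan species drawn per site (capped by the
#'   pool size).
#' @param concentration Dirichlet concentration (large values approach the
#'   uniform distribution).
#' @param occupancy Occupancy per N-site in \[0, 1\]; scalar or named by
#'   site label.
#' @param n_pool,o_pool Candidate name pools; defaults cover the
#'   complex/high-mannose and core-1 repertoires.
#' @param seed Optional RNG seed (reproducibility contract: same seed, same
#'   library).
#' @return A [glyco_library()].
#' @export
simulate_site_library <- function(sites, n_per_site = 12L, concentration = 1,
                                  occupancy = 0.9,
                                  n_pool = default_n_glycan_pool(),
                                  o_pool = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(sites) == 0) abort("`sites` is empty")
  if (length(n_pool) == 0) abort("empty N-glycan pool")
  sites <- mutate(sites, site = site_label(.data$kind, .data$start, .data$end))
  rows <- purrr::pmap_dfr(sites, function(subunit, kind, start, end, capacity,
                                          site, ...) {
    if (kind == "N") {
      pool <- setdiff(n_pool, "unmodified")
      k <- min(n_per_site, length(pool))
      picked <- sample(pool, k)
      ab <- rdirichlet1(k, concentration)
      occ <- if (!is.null(names(occupancy)) && site %in% names(occupancy)) {
        occupancy[[site]]
      } else {
        occupancy[[1]]
      }
      tibble(site = site,
             glycan = c(picked, "unmodified"),
             abundance = c(ab * occ, 1 - occ))
    } else {
      pool <- o_pool %||% default_o_region_pool(capacity)
      pool <- union(pool, "unmodified")
      k <- min(n_per_site, length(pool))
      picked <- unique(c("unmodified", sample(pool, k)))
      ab <- rdirichlet1(length(picked), concentration)
      tibble(site = site, glycan = picked, abundance = ab)
    }
  })
  glyco_library(rows, level = "simulated")
}

site_label <- function(kind, start, end) {
  ifelse(kind == "N", paste0("N", start), paste0("O", start, "-", end))
}

#' Enumerate whole-protein glycoform entries from a site library
#'
#' Expands the per-site categorical libraries into the full cross-site
#' glycoform population: each glycoform's abundance is the product of its
#' per-site species abundances, and enumeration is floored to keep the
#' table desk-scale. This is the unconstrained space that stage-2
#' annotation searches, and the ground-truth population of the simulator.
#'
#' @param lib A [glyco_library()].
#' @param floor Minimum product abundance retained (running prefix products
#'   below the floor are pruned, which is exact because abundances are
#'   <= 1).
#' @param sep Per-site label separator.
#' @return A tibble with `glycoform`, `fractional_abundance`, composition
#'   columns and glycan aggregates.
#' @export
glycoform_entries <- function(lib, floor = 1e-6, sep = "/") {
  gf <- enumerate_glycoforms(lib, floor = floor, sep = sep)
  rename(gf, fractional_abundance = "abundance")
}

# full cross-site enumeration with a running-abundance floor
enumerate_glycoforms <- function(lib, floor = 1e-6, sep = "/") {
  assert_library(lib)
  sites <- split(as_tibble(lib), factor(lib$site, levels = unique(lib$site)))
  acc <- tibble(glycoform = "", abundance = 1,
                hex = 0L, hexnac = 0L, fuc = 0L, neu5ac = 0L,
                antennae = 0L, n_cores = 0L, n_n_glycans = 0L,
                core_fucose_count = 0L, deamidation = 0L)
  for (s in sites) {
    s2 <- tibble(.g = s$glycan, .a = s$abundance,
                 .hex = s$hex, .hexnac = s$hexnac, .fuc = s$fuc,
                 .neu5ac = s$neu5ac, .ant = s$antennae, .nc = s$n_cores,
                 .nn = as.integer(s$glycan_class == "N"),
                 .cf = as.integer(s$core_fucose), .de = s$deamidation)
    acc <- tidyr::crossing(acc, s2) |>
      mutate(glycoform = ifelse(.data$glycoform == "", .data$.g,
                                paste(.data$glycoform, .data$.g, sep = sep)),
             abundance = .data$abundance * .data$.a,
             hex = .data$hex + .data$.hex,
             hexnac = .data$hexnac + .data$.hexnac,
             fuc = .data$fuc + .data$.fuc,
             neu5ac = .data$neu5ac + .data$.neu5ac,
             antennae = .data$antennae + .data$.ant,
             n_cores = .data$n_cores + .data$.nc,
             n_n_glycans = .data$n_n_glycans + .data$.nn,
             core_fucose_count = .data$core_fucose_count + .data$.cf,
             deamidation = .data$deamidation + .data$.de) |>
      select(-dplyr::starts_with(".")) |>
      filter(.data$abundance >= floor)
  }
  arrange(acc, desc(.data$abundance))
}

#' Simulate a deconvoluted spectrum from a site library
#'
#' Glycoforms are enumerated from the library (product abundances, floored
#' at `abundance_floor`), their theoretical masses computed, and masses
#' falling within the resolution window merged into single peaks whose
#' intensity is the summed abundance of the contributors -- the isobaric
#' collapse that makes intact-level annotation ambiguous in the first
#' place. Gaussian mass error, multiplicative log-normal intensity noise,
#' sodium-adduct satellites (+21.982 Da) and the -1 Da deconvolution
#' artifact can be layered on top. The ground truth (contributors per peak,
#' true glycoform table, true quality attributes) is recorded before noise.
#'
#' @param lib A [glyco_library()].
#' @param backbone A [protein_backbone()] (or list summed, for dimers).
#' @param mode Mass mode.
#' @param mass_error_sd Gaussian mass error sigma; ppm if
#'   `mass_error_unit = "ppm"` (default), Da otherwise.
#' @param mass_error_unit `"ppm"` or `"Da"`.
#' @param resolution_window Peaks closer than this (Da) merge (default 0.1
#'   Da, isotopically resolved subunit regime; use ~3 Da for native dimer
#'   spectra).
#' @param adduct_prob Probability that a peak spawns a sodium-adduct
#'   satellite.
#' @param adduct_ratio Satellite/parent intensity ratio.
#' @param artifact_prob Probability that a peak mass is shifted by
#'   -1.00235 Da (deconvolution artifact).
#' @param intensity_noise_sd Sigma of multiplicative log-normal intensity
#'   noise.
#' @param abundance_floor Minimum glycoform abundance enumerated.
#' @param seed Optional RNG seed.
#' @return A list of class `glyco_simulation`: `peaks` (tibble `mass`,
#'   `intensity`), `truth` (list with `contributors`, `glycoforms`,
#'   `library`, `cqa`, per-peak `artifact`/`satellite_of` bookkeeping).
#' @export
simulate_spectrum <- function(lib, backbone,
                              mode = c("monoisotopic", "average"),
                              mass_error_sd = 0,
                              mass_error_unit = c("ppm", "Da"),
                              resolution_window = 0.1,
                              adduct_prob = 0, adduct_ratio = 0.3,
                              artifact_prob = 0, intensity_noise_sd = 0,
                              abundance_floor = 1e-6, seed = NULL) {
  mode <- match.arg(mode)
  mass_error_unit <- match.arg(mass_error_unit)
  if (!is.null(seed)) set.seed(seed)
  if (resolution_window <= 0) abort("`resolution_window` must be positive")
  backbones <- if (inherits(backbone, "glyco_backbone")) list(backbone) else backbone
  base_mass <- sum(vapply(backbones, backbone_mass, numeric(1), mode = mode))
  deam_mass <- modification_mass("deamidation", mode)

  gf <- enumerate_glycoforms(lib, floor = abundance_floor)
  gf$theoretical_mass <- base_mass + composition_mass(gf, mode) +
    gf$deamidation * deam_mass
  build_simulation(gf, mode, mass_error_sd, mass_error_unit,
                   resolution_window, adduct_prob, adduct_ratio,
                   artifact_prob, intensity_noise_sd, lib)
}

build_simulation <- function(gf, mode, mass_error_sd, mass_error_unit,
                             resolution_window, adduct_prob, adduct_ratio,
                             artifact_prob, intensity_noise_sd, lib) {
  gf <- arrange(gf, .data$theoretical_mass)
  # greedy clustering in mass order: a new peak starts when the gap to the
  # previous glycoform exceeds the resolution window, or when the cluster
  # would grow wider than the window (an unresolvable peak cannot span more
  # than the instrument's resolution width)
  masses <- gf$theoretical_mass
  peak_id <- integer(length(masses))
  cur <- 1L; start_mass <- masses[1]
  if (length(masses)) peak_id[1] <- 1L
  for (i in seq_along(masses)[-1]) {
    if (masses[i] - masses[i - 1L] > resolution_window ||
        masses[i] - start_mass > resolution_window) {
      cur <- cur + 1L
      start_mass <- masses[i]
    }
    peak_id[i] <- cur
  }
  gf$peak_id <- peak_id

  peaks <- gf |>
    group_by(.data$peak_id) |>
    summarise(true_mass = sum(.data$theoretical_mass * .data$abundance) /
                sum(.data$abundance),
              intensity = sum(.data$abundance), .groups = "drop")

  n <- nrow(peaks)
  peaks$artifact <- stats::runif(n) < artifact_prob
  err <- if (mass_error_unit == "ppm") {
    rnorm(n, 0, mass_error_sd) * 1e-6 * peaks$true_mass
  } else {
    rnorm(n, 0, mass_error_sd)
  }
  peaks$mass <- peaks$true_mass + err - peaks$artifact * ARTIFACT_SHIFT
  if (intensity_noise_sd > 0) {
    peaks$intensity <- peaks$intensity * exp(rnorm(n, 0, intensity_noise_sd))
  }

  na_mass <- modification_mass("sodium_adduct", mode)
  sat <- filter(peaks, stats::runif(n) < adduct_prob)
  sat_tbl <- NULL
  if (nrow(sat)) {
    sat_tbl <- tibble(mass = sat$mass + na_mass,
                      intensity = sat$intensity * adduct_ratio,
                      satellite_of = sat$peak_id)
  }

  out_peaks <- tibble(mass = peaks$mass, intensity = peaks$intensity)
  satellite_of <- rep(NA_integer_, nrow(out_peaks))
  if (!is.null(sat_tbl)) {
    out_peaks <- bind_rows(out_peaks, sat_tbl[c("mass", "intensity")])
    satellite_of <- c(satellite_of, sat_tbl$satellite_of)
  }

  truth <- list(
    contributors = select(gf, "peak_id", "glycoform", "abundance",
                          "theoretical_mass"),
    glycoforms = select(gf, -"peak_id"),
    library = lib,
    cqa = glyco_cqa(mutate(gf, fractional_abundance = .data$abundance /
                             sum(.data$abundance)),
                    level = "simulation", target = "truth"),
    peak_true_mass = peaks$true_mass,
    artifact = peaks$artifact,
    satellite_of = satellite_of
  )
  structure(list(peaks = out_peaks, truth = truth, mode = mode),
            class = "glyco_simulation")
}

#' @export
print.glyco_simulation <- function(x, ...) {
  cat("<glyco_simulation> ", nrow(x$peaks), " peak(s) from ",
      nrow(x$truth$glycoforms), " true glycoform(s) [", x$mode, "]\n",
      sep = "")
  invisible(x)
}

#' Simulate a native dimer spectrum from two chain glycoform tables
#'
#' Chain-pair abundances are the product of the chain abundances (chains
#' associate independently of their glycans -- an assumption, documented in
#' the vignette); the combined glycoforms then run through the same
#' merge/noise model as [simulate_spectrum()], by default in average-mass
#' mode with a 3 Da resolution window (native spectra are not isotopically
#' resolved).
#'
#' @param entries_a,entries_b Chain glycoform tables (columns as
#'   [fractional_abundances()]; `abundance` or `fractional_abundance`).
#' @param backbone_a,backbone_b Native-chemistry backbones.
#' @inheritParams simulate_spectrum
#' @param sep Chain label separator.
#' @return A `glyco_simulation`.
#' @export
simulate_dimer <- function(entries_a, entries_b, backbone_a, backbone_b,
                           mode = "average", mass_error_sd = 0,
                           mass_error_unit = "Da",
                           resolution_window = 3,
                           adduct_prob = 0, adduct_ratio = 0.3,
                           artifact_prob = 0, intensity_noise_sd = 0,
                           abundance_floor = 1e-6, seed = NULL,
                           sep = " | ") {
  if (!is.null(seed)) set.seed(seed)
  norm_entry <- function(e) {
    e <- ensure_aggregates(as_tibble(e))
    if (!"abundance" %in% names(e)) {
      e$abundance <- e$fractional_abundance / sum(e$fractional_abundance)
    } else {
      e$abundance <- e$abundance / sum(e$abundance)
    }
    e
  }
  a <- norm_entry(as_tibble(entries_a))
  b <- norm_entry(as_tibble(entries_b))
  bb <- backbone_mass(backbone_a, mode) + backbone_mass(backbone_b, mode)
  deam_mass <- modification_mass("deamidation", mode)

  pairs <- tidyr::crossing(ai = seq_len(nrow(a)), bi = seq_len(nrow(b)))
  agg <- function(col) a[[col]][pairs$ai] + b[[col]][pairs$bi]
  gf <- tibble(
    glycoform = paste(a$glycoform[pairs$ai], b$glycoform[pairs$bi], sep = sep),
    abundance = a$abundance[pairs$ai] * b$abundance[pairs$bi],
    hex = agg("hex"), hexnac = agg("hexnac"), fuc = agg("fuc"),
    neu5ac = agg("neu5ac"), antennae = agg("antennae"),
    n_cores = agg("n_cores"), n_n_glycans = agg("n_n_glycans"),
    core_fucose_count = agg("core_fucose_count"),
    deamidation = agg("deamidation")
  )
  gf <- filter(gf, .data$abundance >= abundance_floor)
  gf$theoretical_mass <- bb + composition_mass(gf, mode) +
    gf$deamidation * deam_mass
  build_simulation(gf, mode, mass_error_sd, mass_error_unit,
                   resolution_window, adduct_prob, adduct_ratio,
                   artifact_prob, intensity_noise_sd, lib = NULL)
}
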