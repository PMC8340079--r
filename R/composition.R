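#' Monosaccharide composition columns
#'
#' Glycan compositions are carried as plain integer columns `hex`, `hexnac`,
#' `fuc`, `neu5ac` in tibbles, so composition arithmetic is ordinary
#' column-wise arithmetic and results pipe straight into dplyr verbs.
#'
#' @return Character vector of the composition column names.
#' @export
glycan_units <- function() c("hex", "hexnac", "fuc", "neu5ac")

# map tidy column names -> mass-table unit names
unit_lookup <- c(hex = "Hex", hexnac = "HexNAc", fuc = "Fuc", neu5ac = "Neu5Ac")

as_composition_row <- function(hex = 0, hexnac = 0, fuc = 0, neu5ac = 0) {
  tibble(hex = hex, hexnac = hexnac, fuc = fuc, neu5ac = neu5ac)
}

#' Mass of a monosaccharide composition
#'
#' Sums residue masses over the composition counts; additive by
#' construction, and the empty composition has mass 0. `comp` may be a
#' data frame carrying the [glycan_units()] columns (vectorized over rows)
#' or a named numeric vector.
#'
#' @param comp Data frame with columns `hex`, `hexnac`, `fuc`, `neu5ac`
#'   (missing columns count as 0), or a named numeric vector using those
#'   names.
#' @param mode Mass mode, `"monoisotopic"` or `"average"`.
#' @return Numeric vector of masses in Da.
#' @examples
#' composition_mass(data.frame(neu5ac = 1), mode = "average") # ~291.26
#' @export
composition_mass <- function(comp, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  masses <- monosaccharide_masses(mode)
  if (is.numeric(comp) && !is.null(names(comp))) {
    comp <- as_tibble(as.list(comp))
  }
  if (!is.data.frame(comp)) abort("`comp` must be a data frame or named numeric vector")
  if (any(vapply(glycan_units(), function(u) {
    u %in% names(comp) && any(comp[[u]] < 0, na.rm = TRUE)
  }, logical(1)))) {
    abort("composition counts must be non-negative")
  }
  total <- numeric(max(nrow(comp), 0L))
  for (u in glycan_units()) {
    if (u %in% names(comp)) total <- total + comp[[u]] * masses[[unit_lookup[[u]]]]
  }
  total
}

# glycan nomenclature ---------------------------------------------------------

#' Parse glycan nomenclature into species records
#'
#' The grammar covers the condensed names in common use for complex-type and
#' high-mannose N-glycans and mucin-type core-1 O-glycans:
#'
#' * `"A<a>[S<s>][G<g>][F]"` — complex N-glycan with `a` antennae, `s`
#'   sialylated and `g` galactosylated (non-sialylated) antennae, optional
#'   core fucose; composition HexNAc `2 + a`, Hex `3 + s + g`, Neu5Ac `s`,
#'   Fuc 1 if `F`. Requires `s + g <= a`.
#' * `"M<n>"` — high-mannose, Hex `n`, HexNAc 2, zero antennae.
#' * `"M<n>-A<a>[S<s>][G<g>][F]"` — hybrid: the antenna block adds `a`
#'   HexNAc and `s + g` Hex to the mannose core.
#' * suffix `"+ LacN<k>"` — adds `k` LacNAc repeats (Hex1 HexNAc1) to an
#'   N-glycan without changing the antenna count.
#' * `"core-1"`, `"<x> x Core [+ <y> x S]"` — O-glycans: `x` core-1 units
#'   (HexNAc1 Hex1 each) plus `y` Neu5Ac, `y <= 2x`. `x` and `*` are both
#'   accepted as the multiplication sign; a bare `+ S` means one Neu5Ac.
#' * `"unmodified"` — the reserved identity species (empty composition);
#'   encodes an unoccupied site.
#' * `"deamidated"` — empty glycan composition plus one Asn-to-Asp
#'   deamidation on the backbone; the product of de-N-glycosylation at a
#'   formerly occupied site.
#'
#' @param name Character vector of glycan names.
#' @return A tibble with one row per name: `glycan` (input name),
#'   `glycan_class` (`"N"`, `"O"`, `"none"`), `antennae`, `n_cores`
#'   (core-1 units), `core_fucose`, `deamidation` (0/1), and the
#'   composition columns `hex`, `hexnac`, `fuc`, `neu5ac`.
#' @examples
#' parse_glycan_name(c("A2S2", "A2G2F", "M5", "core-1", "2 x Core + 3 x S"))
#' @export
parse_glycan_name <- function(name) {
  if (!is.character(name) || length(name) == 0) {
    abort("`name` must be a non-empty character vector")
  }
  purrr::map_dfr(name, parse_glycan_name_one)
}

parse_glycan_name_one <- function(name) {
  raw <- name
  s <- stringr::str_trim(name)

  base <- tibble(
    glycan = raw, glycan_class = "none", antennae = 0L, n_cores = 0L,
    core_fucose = FALSE, deamidation = 0L,
    hex = 0L, hexnac = 0L, fuc = 0L, neu5ac = 0L
  )

  if (tolower(s) == "unmodified") return(base)
  if (tolower(s) == "deamidated") {
    base$deamidation <- 1L
    return(base)
  }

  # O-glycans: "core-1", "5 core-1 + 9 S", "2 x Core + 3 x S", "Core + S"
  m <- stringr::str_match(
    s,
    stringr::regex(
      "^(?:(\\d+)\\s*[x×*]?\\s*)?core(?:-1)?(?:\\s*\\+\\s*(?:(\\d+)\\s*)?[x×*]?\\s*S)?$",
      ignore_case = TRUE
    )
  )
  if (!is.na(m[1, 1])) {
    x <- if (is.na(m[1, 2])) 1L else as.integer(m[1, 2])
    has_s <- stringr::str_detect(s, stringr::regex("\\+\\s*(\\d+\\s*)?[x×*]?\\s*S$", ignore_case = TRUE))
    y <- if (!has_s) 0L else if (is.na(m[1, 3])) 1L else as.integer(m[1, 3])
    if (x < 1) abort(paste0("O-glycan must have at least one core-1 unit: '", raw, "'"))
    if (y > 2L * x) {
      abort(paste0("O-glycan '", raw, "' exceeds two sialic acids per core-1 unit"))
    }
    base$glycan_class <- "O"
    base$n_cores <- x
    base$hex <- x
    base$hexnac <- x
    base$neu5ac <- y
    return(base)
  }

  # optional "+ LacN<k>" suffix on N-glycans
  lacn <- 0L
  lm <- stringr::str_match(s, stringr::regex("^(.*?)\\s*\\+\\s*LacN(\\d+)$", ignore_case = TRUE))
  if (!is.na(lm[1, 1])) {
    lacn <- as.integer(lm[1, 3])
    s <- stringr::str_trim(lm[1, 2])
  }

  # high-mannose core, optionally with a hybrid antenna block
  hm <- stringr::str_match(s, "^M(\\d+)(?:-(A\\d+(?:S\\d+)?(?:G\\d+)?F?))?$")
  if (!is.na(hm[1, 1])) {
    n_man <- as.integer(hm[1, 2])
    if (n_man < 3) abort(paste0("high-mannose glycan needs >= 3 Hex: '", raw, "'"))
    base$glycan_class <- "N"
    base$hex <- n_man
    base$hexnac <- 2L
    if (!is.na(hm[1, 3])) {
      ant <- parse_antenna_block(hm[1, 3], raw)
      base$antennae <- ant$a
      base$hex <- base$hex + ant$s + ant$g
      base$hexnac <- base$hexnac + ant$a
      base$neu5ac <- ant$s
      base$fuc <- as.integer(ant$f)
      base$core_fucose <- ant$f
    }
    base$hex <- base$hex + lacn
    base$hexnac <- base$hexnac + lacn
    return(base)
  }

  # complex-type N-glycan
  cm <- stringr::str_match(s, "^A\\d+(?:S\\d+)?(?:G\\d+)?F?$")
  if (!is.na(cm[1, 1])) {
    ant <- parse_antenna_block(s, raw)
    base$glycan_class <- "N"
    base$antennae <- ant$a
    base$hexnac <- 2L + ant$a + lacn
    base$hex <- 3L + ant$s + ant$g + lacn
    base$neu5ac <- ant$s
    base$fuc <- as.integer(ant$f)
    base$core_fucose <- ant$f
    return(base)
  }

  abort(paste0("cannot parse glycan name: '", raw, "'"))
}

parse_antenna_block <- function(s, raw) {
  m <- stringr::str_match(s, "^A(\\d+)(?:S(\\d+))?(?:G(\\d+))?(F)?$")
  if (is.na(m[1, 1])) abort(paste0("cannot parse antenna block in '", raw, "'"))
  a <- as.integer(m[1, 2])
  sia <- if (is.na(m[1, 3])) 0L else as.integer(m[1, 3])
  gal <- if (is.na(m[1, 4])) 0L else as.integer(m[1, 4])
  if (sia + gal > a) {
    abort(paste0("'", raw, "': sialylated + galactosylated antennae exceed antenna count"))
  }
  list(a = a, s = sia, g = gal, f = !is.na(m[1, 5]))
}

#' Canonical glycan name
#'
#' Regenerates a canonical nomenclature string from a parsed species record,
#' so `parse_glycan_name()` followed by `canonical_glycan_name()` round-trips
#' to an equal composition.
#'
#' @param species Tibble as returned by [parse_glycan_name()].
#' @return Character vector of canonical names.
#' @export
canonical_glycan_name <- function(species) {
  purrr::pmap_chr(species, function(glycan, glycan_class, antennae, n_cores,
                                    core_fucose, deamidation, hex, hexnac,
                                    fuc, neu5ac, ...) {
    if (glycan_class == "none") {
      return(if (deamidation > 0) "deamidated" else "unmodified")
    }
    if (glycan_class == "O") {
      if (neu5ac == 0 && n_cores == 1) return("core-1")
      return(paste0(n_cores, " x Core", if (neu5ac > 0) paste0(" + ", neu5ac, " x S")))
    }
    # N-glycans: reconstruct antenna/LacNAc bookkeeping from the counts.
    # The split of hexoses between mannose core and galactoses is not unique
    # for hybrids; galactosylation is assumed maximal, which preserves the
    # composition (the round-trip contract).
    a <- antennae
    s <- neu5ac
    lacn <- hexnac - 2L - a
    core_hex <- hex - s - lacn # mannoses + galactoses
    if (a == 0) {
      nm <- paste0("M", core_hex)
    } else if (core_hex - 3L <= a - s) {
      g <- core_hex - 3L
      nm <- paste0("A", a,
                   if (s > 0) paste0("S", s),
                   if (g > 0) paste0("G", g),
                   if (core_fucose) "F")
    } else {
      gal <- a - s
      man <- core_hex - gal
      nm <- paste0("M", man, "-A", a,
                   if (s > 0) paste0("S", s),
                   if (gal > 0) paste0("G", gal),
                   if (core_fucose) "F")
    }
    if (lacn > 0) nm <- paste0(nm, " + LacN", lacn)
    nm
  })
}

# textual desialylation of a single name: S-antennae become G-antennae,
# O-glycan sialic suffixes are dropped
desialylate_name <- function(name) {
  vapply(name, function(nm) {
    s <- stringr::str_trim(nm)
    low <- tolower(s)
    if (low %in% c("unmodified", "deamidated")) return(nm)
    if (stringr::str_detect(low, "core")) {
      out <- stringr::str_remove(s, stringr::regex("\\s*\\+\\s*(\\d+\\s*)?[x×*]?\\s*S$", ignore_case = TRUE))
      return(out)
    }
    m <- stringr::str_match(s, "^(.*?A)(\\d+)S(\\d+)(?:G(\\d+))?(F?)((?:\\s*\\+\\s*LacN\\d+)?)$")
    if (!is.na(m[1, 1])) {
      a <- m[1, 2]
      sia <- as.integer(m[1, 4])
      gal <- if (is.na(m[1, 5])) 0L else as.integer(m[1, 5])
      return(paste0(a, m[1, 3], "G", sia + gal, m[1, 6], m[1, 7]))
    }
    nm
  }, character(1), USE.NAMES = FALSE)
}
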