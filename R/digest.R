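#' In-silico tryptic digestion
#'
#' Classical trypsin specificity: cleavage C-terminal to K or R, except when
#' the next residue is proline. All peptides with 0 to `max_missed` missed
#' cleavages are emitted; spans are 1-based inclusive.
#'
#' @param sequence Amino-acid sequence (one-letter).
#' @param max_missed Maximum number of missed cleavages (default 1).
#' @return Tibble with columns `start`, `end`, `sequence`,
#'   `missed_cleavages`.
#' @examples
#' tryptic_digest("AKA", max_missed = 0)
#' @export
tryptic_digest <- function(sequence, max_missed = 1L) {
  sequence <- toupper(stringr::str_trim(sequence))
  n <- nchar(sequence)
  if (n == 0) return(tibble(start = integer(), end = integer(),
                            sequence = character(), missed_cleavages = integer()))
  res <- strsplit(sequence, "")[[1]]
  # cut points: after position i when res[i] in K/R and res[i+1] != P
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts == n | res[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts[cuts < n], n) # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  k <- length(starts)
  out <- purrr::map_dfr(0:max_missed, function(m) {
    if (k - m < 1) return(NULL)
    i <- seq_len(k - m)
    tibble(start = starts[i], end = ends[i + m], missed_cleavages = m)
  })
  out$sequence <- stringr::str_sub(sequence, out$start, out$end)
  arrange(select(out, "start", "end", "sequence", "missed_cleavages"),
          .data$start, .data$missed_cleavages)
}

#' Find N-glycosylation sequons
#'
#' Scans for the consensus motif N-X-S/T with X != P.
#'
#' @param sequence Amino-acid sequence.
#' @return Tibble with columns `position` (of the Asn, 1-based) and `motif`.
#' @examples
#' find_sequons("ANVTA") # sequon at position 2
#' @export
find_sequons <- function(sequence) {
  sequence <- toupper(stringr::str_trim(sequence))
  m <- stringr::str_locate_all(sequence, "N(?=[^P][ST])")[[1]]
  tibble(
    position = as.integer(m[, 1]),
    motif = stringr::str_sub(sequence, m[, 1], m[, 1] + 2L)
  )
}

#' Glycosylation site table
#'
#' N-sites are single residues carrying a sequon; O-glycosylation in
#' Ser/Thr-rich stretches cannot be localized to individual residues from
#' intact or glycopeptide data, so O-sites are modeled as regions with a
#' per-region glycan capacity.
#'
#' @param subunit Chain identifier.
#' @param kind `"N"` or `"O"`.
#' @param start,end Residue span (1-based inclusive; `end == start` for
#'   N-sites).
#' @param capacity Maximum number of glycans carried by the site/region
#'   (1 for N-sites).
#' @return Tibble of class contract used by [max_glycans_at_level()].
#' @export
glycosylation_sites <- function(subunit, kind, start, end = start,
                                capacity = 1L) {
  kind <- match.arg(kind, c("N", "O"), several.ok = TRUE)
  if (any(capacity < 1)) abort("site capacity must be >= 1")
  tibble(subunit = subunit, kind = kind, start = as.integer(start),
         end = as.integer(end), capacity = as.integer(capacity))
}

#' Maximum glycan count at the intact level
#'
#' Sum of per-site capacities; caps the combinatorics of whole-protein
#' glycoform enumeration.
#'
#' @param sites Tibble from [glycosylation_sites()] (rows may be bound
#'   together).
#' @return Integer.
#' @examples
#' s <- glycosylation_sites("b", "O", c(115, 123, 134), c(122, 133, 145), 2L)
#' max_glycans_at_level(s) # 6
#' @export
max_glycans_at_level <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0) return(0L)
  sum(sites$capacity)
}
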