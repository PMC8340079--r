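---
title: "Annotating glycoforms of a heterodimeric glycoprotein across structural levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating glycoforms of a heterodimeric glycoprotein across structural levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoformr)
library(dplyr)
```

## The problem

Heavily glycosylated proteins such as human chorionic gonadotropin (hCG) — a
noncovalent heterodimer whose two chains together carry four N-glycosylation
sites and several O-glycosylated Ser/Thr-rich stretches — produce deconvoluted
intact-mass spectra in which each neutral-mass signal hides many coexisting
glycoforms. A mass spectrometer cannot resolve isobaric proteoforms, so an
observed peak's intensity is the sum over every glycoform whose mass falls
within the instrument's resolution. The question this package answers is:
given quantitative, site-specific knowledge of which glycans occur where (from
glycopeptide analysis), which glycoforms explain each intact-level peak, and
with what probability?

## The two-stage annotation model

For a peak of neutral mass $m$ and a protein backbone of mass $B$ (computed
from the sequence with fixed modifications, disulfide decrements and, as
alternatives, variable oxidations), the residual $\Delta = m - B$ is:

1. **Stage 1 — composition decomposition.** Find every monosaccharide
   composition $c = (n_\mathrm{Hex}, n_\mathrm{HexNAc}, n_\mathrm{Fuc},
   n_\mathrm{Neu5Ac})$ with $|\Delta - \mathrm{mass}(c)| \le \tau$. The
   search is a depth-first walk of the bounded four-unit lattice and is
   complete with respect to exhaustive enumeration (a tested property).
2. **Stage 2 — site assignment.** For each composition, enumerate every
   per-site tuple of library species whose summed composition equals it
   exactly. A tuple's *raw score* is the product over sites of the species'
   relative abundances; *hit scores* normalize raw scores to percent per
   peak, so they estimate each isobaric glycoform's contribution to peak
   intensity. Assignments are ranked by descending hit score, ties broken by
   absolute mass error and then label.

Site-specific libraries are categorical distributions per site; the reserved
species `unmodified` carries the unoccupied fraction, so occupancy
(macroheterogeneity) and glycan identity (microheterogeneity) run through
the same combinatorics. The *fractional abundance* of glycoform $g$ over a
spectrum combines peak intensities $I_p$ and hit scores $h_{p,g}$:
$A_g = \sum_p \frac{I_p}{\sum_q I_q} \cdot \frac{h_{p,g}}{100}$.

Two mass regimes mirror practice: isotopically resolved subunit spectra are
annotated with monoisotopic masses at 20 ppm; unresolved native spectra of
the dimer with IUPAC 2013 average masses at ±3 Da. Mass tables live in
`inst/extdata/mass_tables/` as delimited text and are derived from elemental
compositions, so alternative scales can be swapped without code changes.

## Stepwise integration

Glycopeptide-level libraries annotate subunit spectra; the resulting
glycoform tables (oxidation variants merged, truncated at a fractional
abundance cutoff of 0.3% by default) become the per-chain "species" of a
two-pseudo-site library for the dimer. A dimer candidate is an ordered chain
pair; its mass is the sum of the native-chemistry chain masses (noncovalent
association adds no mass) and its prior the product of chain abundances.
Truncation coverage is always reported against the pre-truncation total,
while scoring renormalizes within the truncated library. A warning is issued
above ~120 entries per chain: the combination space grows as the product of
chain sizes, and keeping that constraint visible helps users judge
feasibility, but it is not a hard limit.

Because subunit spectra are usually measured reduced and alkylated while the
native complex is disulfide-bonded, `convert_backbone_context()` moves a
backbone between chemistries (removing carbamidomethyl groups, applying −2 H
per disulfide) without touching glycan compositions.

## Nomenclature grammar

Names follow the condensed style used for released-glycan and glycopeptide
reporting: `A2S1G1` is a biantennary complex N-glycan with one sialylated
and one galactosylated antenna; a trailing `F` marks a core fucose; `M5` is
high-mannose; `M5-A1G1` a hybrid; `+ LacN1` appends a LacNAc repeat;
`core-1` and `2 x Core + 3 x S` are mucin-type O-glycans (at most two
sialic acids per core). `parse_glycan_name()` and
`canonical_glycan_name()` round-trip to equal compositions — for hybrids the
mannose/galactose split of the hexoses is not unique, and regeneration
assumes maximal galactosylation, which preserves the composition.

In-silico glycosidase transforms operate on names: desialylation rewrites
`S` antennae as `G` antennae and strips O-glycan sialic suffixes, then
merges species made identical; PNGase-F de-N-glycosylation replaces N-class
species by the species `deamidated` (empty glycan composition, one
Asn→Asp deamidation of +0.984 Da), while `unmodified` entries stay
unmodified — an unoccupied asparagine was never amidated by a glycan and is
not deamidated. Both transforms are idempotent and preserve per-site
normalization.

## Artifact handling

* **Sodium adducts.** A peak sitting +21.982 Da above an annotated peak is
  an adduct candidate. Only a peak with *no assignments of its own* is
  treated as a pure satellite: it inherits the parent's assignments with an
  `inherited` flag and is excluded from fractional-abundance sums (its
  intensity duplicates the parent's glycoforms and is *not* added to the
  parent). An annotated peak that merely matches the spacing keeps its own
  assignments and records the candidate parent — early versions excluded
  such peaks and visibly biased abundance estimates in dense simulated
  spectra.
* **−1 Da deconvolution artifact.** Sulfur-rich proteins are prone to a
  systematic −1 Da error in zero-charge deconvolution. Unannotated peaks
  are optionally re-searched at +1.00235 Da and flagged
  `minus1Da_artifact` rather than silently widening the tolerance.
* **Unannotated peaks** are never dropped: they carry the nearest
  composition within ±2 Da as a near-miss diagnostic, which is how one
  spots cases like a genuine peak needing >44 ppm (observed 24 583.7 Da
  against a theoretical 24 584.8 Da).

## The synthetic-data generator

`simulate_site_library()` draws per-site categorical abundances from a
symmetric Dirichlet prior over a pool of complex/high-mannose N-glycans and
core-1 O-glycans; N-site occupancy is encoded as the `unmodified` weight.
`simulate_spectrum()` enumerates the glycoform population (product
abundances, floored at $10^{-6}$), merges theoretical masses that fall
within a resolution window into single peaks with summed intensities — the
isobaric collapse the annotation must then undo — and layers on Gaussian
mass error, log-normal intensity noise, sodium-adduct satellites and the
−1 Da artifact. Ground truth (per-peak contributors, the glycoform table,
true quality attributes) is recorded before noise.

Defaults, chosen once as the study conditions: a beta-chain-like layout of
2 N-sites plus 3 O-regions of capacity 2 (at most 6 O-glycans at intact
level), 12 glycans per site, Dirichlet concentration 1 (a broad, weakly
informative spread typical of recombinant-product site profiles), N-site
occupancy 0.9 (with 0.626 as a documented scenario preset for a partially
occupied site), resolution window 0.1 Da for isotopically resolved subunit
spectra and 3 Da for native dimer spectra. Peak merging clusters sorted
masses greedily and starts a new peak when either the gap to the previous
glycoform or the running cluster span exceeds the window: a peak wider than
the resolution width would not deconvolute to a single mass, and capping
the span keeps every true contributor recoverable within the annotation
tolerance — without the cap the generator can state a truth that no search
could return.

The dimer simulator assumes chains associate independently of their glycans
(no glycan-driven pairing preference); nothing in intact-level data
constrains this, and it is the simplest defensible null model.

What the generator does *not* emulate: m/z-domain raw spectra, isotope
envelopes, charge-state ladders, deconvolution errors other than the −1 Da
shift, intensity-dependent detection limits, or correlated site occupancy.
Passing recovery tests therefore demonstrates the combinatorial and scoring
machinery, not robustness to upstream deconvolution pathology.

## Quality attributes

The degree of sialylation of a glycoform is its Neu5Ac count divided by the
maximum it could carry — one per N-glycan antenna plus two per O-glycan
core — and the population degree is the abundance-weighted mean over
glycoforms with a nonzero maximum. Core fucosylation counts at most one
core fucose per N-glycan, weighted over glycoforms carrying at least one
N-glycan. Conventions worth stating: `unmodified` sites contribute to
neither numerator nor maximum (occupancy is a separate statistic);
non-antennary high-mannose species contribute 0 to the sialylation maximum
and drop out of the mean when the maximum is 0 (a hybrid like `M5-A1G1`
contributes its single antenna). Both degrees are scale-invariant in the
weights and bounded in [0, 1]; a desialylated library yields exactly 0.
`compare_batches()` joins two result tables on (level, target) and reports
absolute and relative deltas, warning on unmatched keys.

## Numerical and design choices

* Stage-1 bounds for direct `decompose_mass()` calls default to Hex ≤ 40,
  HexNAc ≤ 40, Fuc ≤ 8, Neu5Ac ≤ 16 — generous for a ~12 kDa glycan load on
  a 26 kDa backbone. During spectrum annotation the bounds are instead
  derived from the library's per-site maxima, which is exact (stage 2 can
  never exceed them) and guarantees the composition search is complete
  relative to the library; a fixed cap below the library's own maximum
  would silently make some glycoforms unsearchable.
* The stage-2 depth-first search is compiled (C++ via Rcpp); the pure-R
  equivalent was two orders of magnitude slower on dense spectra. Pruning
  uses per-unit suffix maxima, so results equal the naive enumeration.
* Distinct site-tuples are counted once; permutations of identical species
  across different sites are distinct tuples, but a tuple is never
  double-counted across backbone-modification alternatives — oxidation
  variants of the same glycoform are merged with summed raw scores.
* The ±3 Da dimer tolerance is symmetric, and ppm tolerances are converted
  at the observed peak mass for stage 1 with a final filter on the exact
  theoretical mass.
* The search tolerance should cover the expected mass accuracy: for data
  with Gaussian mass error of standard deviation $\sigma$, a tolerance of
  about $3\sigma$ retains essentially all true matches, whereas a
  tolerance equal to $\sigma$ excludes roughly a third of them by
  construction. The recovery benchmarks pair 20 ppm simulated error with a
  60 ppm search window for exactly this reason.
* Degenerate inputs: an empty sequence yields one water; an empty
  composition has mass 0; a residual more negative than the tolerance
  decomposes to nothing; a cutoff that removes every glycoform raises an
  explicit error rather than returning an empty library.
* Test and acceptance problem sizes (12 glycans/site over 5 sites, ≈50 000
  enumerated glycoforms, ≈2 000 merged peaks; dimer chains of 60 × 60) were
  chosen as the package's desk-scale reference conditions.

## Known limitations

* Glycan topology and linkage isomers are out of scope: compositions over
  {Hex, HexNAc, Fuc, Neu5Ac} are the unit of arithmetic, and the alphabet,
  while extensible through the bundled tables, defaults to those four
  (no Neu5Gc, sulfation or phosphorylation).
* O-glycans cannot be localized within Ser/Thr-rich regions from the data
  this package consumes; O-sites are modeled as regions with a capacity,
  matching what glycopeptide evidence supports.
* Hit scores are priors-under-isobaricity, not posterior probabilities
  calibrated against fragmentation evidence.
* Deconvolution itself (raw m/z to neutral mass) is upstream and out of
  scope; peak lists are taken at face value apart from the two artifact
  heuristics above.
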