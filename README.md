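# glycoformr

Multi-level glycoform annotation for heavily glycosylated proteins and
noncovalent protein complexes.

Intact-mass and native mass spectrometry of a glycoprotein like human
chorionic gonadotropin (hCG) — an αβ heterodimer carrying four N-glycans
and up to six O-glycans — yields deconvoluted spectra whose ~50–400 neutral
mass signals each hide many isobaric glycoforms. `glycoformr` turns
site-specific quantitative glycan libraries (from glycopeptide analysis)
into ranked, probability-scored glycoform assignments for those signals,
propagates annotations upward (glycopeptide → subunit → dimer), and
computes abundance-weighted glycosylation quality attributes for batch
comparison.

The core is a two-stage search. For a peak of mass $m$ over a backbone of
mass $B$, stage 1 finds every monosaccharide composition
$c = (n_{\mathrm{Hex}}, n_{\mathrm{HexNAc}}, n_{\mathrm{Fuc}},
n_{\mathrm{Neu5Ac}})$ with $|m - B - \mathrm{mass}(c)| \le \tau$
(20 ppm monoisotopic for subunits, ±3 Da average for the native dimer).
Stage 2 enumerates all per-site library species tuples summing exactly to
$c$; a tuple's raw score is the product of its site abundances, and hit
scores normalize raw scores to percent per peak. Fractional glycoform
abundance combines relative peak intensity with hit scores:
$A_g = \sum_p (I_p/\sum_q I_q)\,(h_{p,g}/100)$. Quality attributes weight
per-glycoform ratios by abundance: sialylation relative to one Neu5Ac per
N-glycan antenna plus two per O-glycan core, core fucosylation relative to
one fucose per N-glycan.

A seeded synthetic-data module generates ground-truthed site libraries and
peak lists (isobaric merging, mass error, sodium-adduct satellites, the
−1 Da deconvolution artifact), so the whole pipeline is testable without
any external data.

## Worked example

```r
library(glycoformr)
library(dplyr)

# a two-site library with an isobaric swap: A2S2 and A2G2 trade places
lib <- glyco_library(data.frame(
  site     = c("s1", "s1", "s2", "s2"),
  glycan   = c("A2S2", "A2G2", "A2S2", "A2G2"),
  abundance = c(0.8, 0.2, 0.5, 0.5)
))
bb <- protein_backbone("demo", "PEPTIDE")
m  <- backbone_mass(bb, "monoisotopic") +
  sum(composition_mass(parse_glycan_name(c("A2S2", "A2G2")), "monoisotopic"))

ann <- annotate_spectrum(data.frame(mass = m, intensity = 1), bb, lib)
ann[, c("glycoform", "hit_score", "error", "rank")]
#> # A tibble: 2 × 4
#>   glycoform hit_score    error  rank
#>   <chr>         <dbl>    <dbl> <int>
#> 1 A2S2/A2G2        80 1.97e-10     1
#> 2 A2G2/A2S2        20 1.97e-10     2
```

Both site assignments explain the peak exactly (same total composition);
the hit scores 80/20 are the normalized products of the site abundances —
the probability each isobaric glycoform contributes to the peak. Downstream:

```r
fa <- fractional_abundances(ann)
degree_of_sialylation(fa)        # 0.5: two of four antennae sialylated
tidy(ann); glance(ann); autoplot(ann)
```

File-level wrappers (`run_annotate_subunit()`, `run_build_library()`,
`run_annotate_dimer()`, `run_metrics()`, `run_simulate()`) tie FASTA
sequences, delimited libraries and peak lists into reports with JSON
provenance sidecars; `inst/cli/glycoformr-cli.R` exposes them as shell
subcommands. The bundled mature hCG chain sequences
(`hcg_sequences_path()`, `hcg_backbones()`) reproduce the documented
tryptic glycopeptides, sequon maps and the 25.7 kDa native backbone mass.

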