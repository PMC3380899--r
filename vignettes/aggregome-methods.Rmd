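---
title: "Methods: SILAC quantification of detergent-insoluble aggregome proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SILAC quantification of detergent-insoluble aggregome proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggregome)
```

## The experiment this package models

`aggregome` implements the quantitative analysis of a detergent-insoluble
("aggregome") proteome experiment. Cells overexpressing an aggregation-prone
protein (full-length TDP-43 or its N-terminal splice variant TDP-S6) are lysed
in a stringent detergent buffer; the insoluble pellet is solubilized in 8 M
urea and mixed 1:1 by protein weight with a heavy SILAC-labeled
(Lys8/Arg10) internal-standard fraction. After SDS-PAGE fractionation and
tryptic digestion, LC-MS/MS yields, per peptide, a light (experimental) and a
heavy (internal standard) extracted-ion intensity. Because the heavy peptides
are chemically identical to their light counterparts, the light/heavy ratio is
a within-run normalized abundance, and differences of log2 ratios between
transfection conditions (mock, TDP-43, TDP-S6) measure each protein's movement
into or out of the insoluble fraction.

The pipeline has five analysis stages plus a synthetic-data generator:

1. **Peptide chemistry** — digestion, monoisotopic masses, b/y fragment
   ladders, decoy databases, targeted-method planning.
2. **PSM filtering** — grouped target-decoy filtering to a protein-level FDR.
3. **SILAC quantification** — protein rollup, recentering, significance
   calling, triple-SILAC mapping.
4. **PTM stoichiometry** — normalization of modified-peptide changes
   (ubiquitin GG remnants, methyl/dimethyl RGG sites) to the parent protein.
5. **Targeted MS/MS quantification** — summed-fragment quantification with
   AGC inject-time correction and reference-peptide normalization.

## Mass chemistry

All masses are monoisotopic. Residue masses are the standard table (G
57.021464 ... W 186.079313), water is 18.0105646 Da and the proton
1.00727646 Da; `[M+H]+ = neutral + proton` and `m/z(z) = (neutral +
z*proton)/z`. The modification registry carries full-precision deltas: GG
remnant +114.042927 (identical for the dialkyl pseudo-GG adduct — the premise
of the external-reference strategy for ubiquitination sites), methyl
+14.01565, dimethyl +28.0313, Met oxidation +15.994915, SILAC Lys8 +8.014199
and Arg10 +10.008269.

The bundled reference tables print peptide [M+H]+ values to four decimals.
Recomputing them from any consistent standard residue table leaves a small
systematic residue (up to ~1.6e-4 Da, growing with peptide length), implying
the original search engine's residue table was rounded slightly differently.
Tests therefore require agreement within two units in the last printed digit
(2e-4 Da); most cells agree within one.

**Digestion.** Trypsin cleaves after K/R but not before proline. The proline
exception is the field's standard rule; the bundled reference peptides are
consistent with it. A lysine carrying a GG remnant or a dimethyl group (and
dimethylated arginine likewise) blocks cleavage: the blocked site neither
terminates a peptide nor spends the missed-cleavage budget. This choice is
forced by the reference peptides themselves, which span a modified K that a
cleavage would have separated. Unmodified missed K/R sites do count against
the budget (default two). Semi-tryptic ("partial") enumeration requires one
tryptic terminus.

**Inclusion-list planning.** The printed isolation centers for the targeted
method sit almost exactly 0.50 m/z above the monoisotopic 2+ m/z, so that the
1.7 m/z window covers the isotope envelope instead of sitting on its left
edge. `plan_inclusion_list()` adopts center = mono m/z + 0.50 (2 dp) and
validates against the printed centers at ±0.03 (two of the six printed values
differ from the rule by 0.01-0.02). The printed center list pairs its first
two labels in the opposite order from the peptide list; centers are therefore
validated as a set.

## Target-decoy FDR machinery

The decoy database appends the reversal of every target protein under a
`REV_` prefix (the identifier scheme is ours; the count doubles and
composition is preserved). The FDR estimator is `2*nd/nt`: `nd` decoy matches
among `nt` accepted matches, doubled because false matches are assumed to hit
target and decoy sequences equally often.

Filtering proceeds exactly in the grouped, dynamic style: PSMs are split by
trypticity (full/partial) and charge (2+, 3+, 4+), gated at |mass error| <=
15 ppm, and then per-group minimum Xcorr and deltaCn thresholds are raised
from floors (1.0 and 0.05) on a fixed grid (steps 0.1 and 0.01) until the
**protein-level** FDR is at or below the 1% target. "Protein FDR" is
operationalized as `2 * (decoy protein groups) / (all protein groups)` after
family grouping, because the constraint is stated at protein level while the
estimator is defined on matches. Each greedy step tightens the single
group/axis whose increment removes the most decoy PSMs per target PSM lost
(ties: fewer targets lost, then the canonical group order with Xcorr before
deltaCn), so the search keeps as many target PSMs as it can and is fully
deterministic. An infeasible target (e.g. all-decoy input) yields an empty
acceptance with a diagnostic rather than an error.

Family grouping merges proteins sharing any accepted peptide, transitively
(connected components of the peptide-protein graph, via igraph; the tests
check it against an independent union-find). A group is decoy only if all its
members are decoys. Proteins identified by a single distinct peptide are
flagged (`single_peptide`) — the in-lab equivalent was manual spectrum
inspection, which cannot be automated, so the flag preserves the information.

## SILAC quantification and significance calling

The protein-level log2(light/heavy) ratio is the **median** of peptide-level
log2 ratios across peptides and gel regions (the original pipeline's rollup
rule is unpublished; the median is robust to occasional interference-affected
peptides). Replicates are rolled up separately and averaged; condition
means are differenced to give `d43 = log2(TDP-43) - log2(mock)`,
`dS6 = log2(TDP-S6) - log2(mock)` and `dS6_43 = dS6 - d43` (an exact
identity by construction). Modified peptides are excluded from the rollup so
that protein abundance reflects unmodified peptides only.

Each difference population is recentered by subtracting its mean (the means
are logged for the audit trail). The significance cutoff per comparison is
`1.64 * SD` of the recentered differences — the one-tailed 95% point of a
normal null, read as the SD of the population of differences; back-solving
the printed cutoffs (±0.91, ±0.89, ±0.65) gives population SDs near
0.55/0.54/0.40, which the synthetic generator adopts as its null. Proteins
quantified in only some conditions are excluded from cutoff estimation but
retained with partial calls.

Group calls mirror the reference table's sections: group 1 = beyond the
cutoff versus mock in both models with the same sign; group 2 = only in the
TDP-S6 model; group 3 = only in the TDP-43 model; group 4 ("lost in TDP-S6")
uses the **signed one-tailed** condition `dS6_43 < -cutoff` and attaches in
addition to groups 1-3 (dual marking), standing alone only when no other
group fires. Fold changes are presented as `2^x`, rounded to whole folds when
at least 2.

The triple-SILAC map plots recentered `d43` on x and, by default, recentered
`dS6_43` on y (`dS6` is available as an alternative y axis; the choice is
recorded in the output's attributes, since the original figure's axis
annotation is ambiguous between the two).

## PTM stoichiometry normalization

For a modified peptide with per-condition light/heavy ratios `r_cond`:

- unnormalized percent of control: `100 * r_cond / r_mock`;
- normalized percent of control: `100 * unnorm / unmodified%`, where
  `unmodified% = 100 * 2^(protein difference vs mock)` comes from the SILAC
  rollup over the protein's unmodified peptides (all accepted unmodified
  peptides, replicate-averaged — the reference table does not state which
  subset was used, so this is configurable in principle and this default is
  the natural one).

The normalization separates a stoichiometry change from a protein-abundance
change: a modified peptide that merely tracks its protein normalizes to
100%. Site labels are 1-based protein coordinates (`K145-gg`,
`R291-dimethyl`); a doubly modified peptide yields one record per site
sharing the same PSMs. GG sites are labeled generically ("gg") because
NEDD8/ISG15 leave the same remnant; the ubiquitin interpretation is
metadata, not computation. Reporting uses 3 significant figures; computation
keeps full precision.

## Targeted quantification with AGC correction

Ion-trap MS/MS under automatic gain control fills the trap to a fixed ion
count (5,000) within at most 150 ms, so raw fragment intensity reflects fill
time rather than analyte flux. Quantification therefore: (1) requires
**every** designated fragment of a peptide to be present (closest peak within
±0.5 m/z) and sums the matched intensities — absence of any required fragment
makes the scan non-quantifying, which is a value, not an error; (2) multiplies
the sum by `150 ms / inject time`, which cancels the AGC effect (halving the
flux doubles the fill time below the cap and leaves the corrected intensity
unchanged); (3) divides by each of two constitutive reference peptides
(triosephosphate isomerase) quantified by precursor XIC (not subject to AGC;
summarized by apex intensity within the elution window — area is available);
(4) forms experimental/control ratios per reference and replicate and reports
the mean log2 with a t-based 95% CI over the k = references x replicates
values (`qt(0.975, k-1) * sd / sqrt(k)`). The CI's span is genuinely
ambiguous in the source ("95% confidence interval for two replicates",
formula unstated); a replicates-only variant is provided (`ci = "t_reps"`)
and neither is asserted as the original. Percent change is
`100 * (2^mean - 1)`, which reproduces the printed 62% from a log2 ratio of
0.70.

## The synthetic-data generator

`simulation_config()` defaults encode the study's structure: 585 proteins
quantified in three conditions and two replicates; 41 spiked changers (35 up,
6 down) with |log2 effect| ~ N(1.5, 0.3) truncated at 1.0, assigned to one or
both overexpression conditions; a correlated Gaussian null for (d43, dS6)
whose per-comparison SDs are 0.55/0.54/0.40 (the third SD fixes the
correlation, ~0.73); mock log2(light/heavy) ~ N(0, 0.3); 2 + Poisson(4)
peptides per protein with log2 measurement noise of SD 0.25 and log-normal
heavy-channel intensities; decoy PSMs (5% of targets) and planted false
target PSMs (1%) drawn from a separated low-score distribution; three
modification sites with condition-dependent stoichiometries placed on real
cleavable K/R residues so the modified peptide is the mod-induced
missed-cleavage product; and targeted scans whose inject times follow
`min(150, AGC target / flux)` with per-run loading factors that the reference
normalization must cancel. Every random draw comes from the single mandatory
seed, and a `truth.json` manifest records all ground truth.

Because the spiked changers sit on top of the configured null, the *measured*
population SDs — and hence the estimated cutoffs — come out somewhat above
the configured 0.55/0.54/0.40 (near 1.0/1.0/0.9 at the defaults), as they
would in the real experiment where the printed cutoffs describe the measured
population including changers and measurement noise.

What the generator does **not** emulate: chromatographic peak shape and
retention behavior, isotope envelopes, co-elution interference, ratio
compression, shared peptides between homologous proteins (random sequences
essentially never collide), or intensity-dependent missingness. Green tests
therefore demonstrate that the algorithms are implemented correctly and are
calibrated under clean Gaussian conditions — not that the pipeline is robust
to every pathology of real LC-MS/MS data.

## Numerical and reporting choices

Internal computation keeps full double precision; rounding happens only at
report time (tables at 4 dp, ratios/percents presented at 3 significant
figures, fragment m/z at 2 dp for method planning). Degenerate inputs are
values, not crashes: empty acceptance sets give FDR 0, non-positive
intensities mark records non-quantifiable and are counted, missing references
exclude the affected sample with a log entry, missing comparisons give
partial significance calls. Ties in the threshold search resolve
deterministically as described above. Derived-column comparisons against the
bundled printed tables propagate the rounding of printed inputs: ratios of
two 3-significant-figure intensities are checked at 1.2% relative, percent
columns at 2.2%, and normalized percents (which divide by an already-rounded
printed intermediate) at 3.2% — each with a floor of one (two for normalized)
units in the last printed digit.

The test suite runs the full pipeline at the study scale (585 proteins) once,
and uses reduced populations (40-200 proteins, shorter synthetic proteins)
for repeated-seed property checks; these sizes keep every distributional
check well-powered while keeping the default suite quick.

## Known limitations

- Xcorr/deltaCn are consumed, never computed; no spectra are simulated or
  scored, and vendor RAW/mzML decoding is out of scope (a documented TSV scan
  format stands in).
- The rollup median and the CI span are reasoned defaults for unpublished
  details of the original pipeline, not reproductions of it.
- Site localization is taken from the PSM's modification string at face
  value; no localization scoring is attempted.
- The 585/41 population counts of the original study depend on unreleased raw
  data; the generator emulates their structure, and no test asserts them
  numerically.
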