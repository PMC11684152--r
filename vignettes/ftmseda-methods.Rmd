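---
title: "Methods: exploratory analysis of formula-assigned FT-MS data"
author: "ftmseda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exploratory analysis of formula-assigned FT-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftmseda)
```

# The data model

Ultrahigh-resolution FT-MS of complex organic mixtures yields, per study,
a peak table (rows = peaks identified by a mass identifier, columns =
samples, cells = intensities) and a molecular identification table (per
peak: a molecular formula and/or element counts C, H, N, O, S, P; C and H
are required wherever a formula is recorded).  `FTMSExperiment` binds the
two as a `SummarizedExperiment`: the `"intensity"` assay is the peak
table, `rowData` the molecular table, and three pieces of metadata travel
with the object — the intensity scale (`abundance`, `log2`, `log10`,
`ln`, `presence_absence`), the raw missing-value code, and an append-only
provenance log feeding the HTML report.

A deliberate design choice is that the canonical missing marker is `NA`,
never 0.  Uploaded files typically encode "peak not observed" as an
abundance of 0; `encodeMissing()` rewrites exactly those cells to `NA`
once, after which presence/absence, observed counts, and intensity
summaries cannot conflate "absent" with "measured zero".  Operations that
depend on the distinction (summaries, filters on observation counts,
group comparisons, distances) refuse to run before missingness has been
encoded rather than guessing.

Two ingestion routes exist.  The generalized two-file route reads the
tables as-is, parsing formulas into element counts (Hill-notation
tokenizer restricted to C, H, N, O, S, P; a `strict = FALSE` escape hatch
ignores other elements).  The CoreMS-style route reads long-format
per-sample candidate assignments, profiles a confidence-score cut-off
(`confidenceProfile()` reports peaks retained and mass-error statistics
per threshold), resolves one formula per (sample, m/z) by maximum
confidence score or maximum peak height, and pivots to an
`FTMSExperiment`.  Peak identity across samples after pivoting is the
resolved formula string (isotope-annotated formulas kept distinct):
after calibration the formula is the stable cross-sample key, whereas
m/z binning would introduce a tolerance parameter we cannot validate
from single files.  Ties during resolution are broken by smaller
absolute mass error, then lexicographically smallest formula, so a rerun
is always byte-identical — a requirement for meaningful provenance.
Candidate confidence scores are required to lie in [0, 1]; values
outside are rejected loudly rather than rescaled.

# Calculated chemical properties

All properties are per peak, computed from element counts (and mass),
and are `NA` for every peak without an assigned formula — a property of
a formula, not of an m/z value.

* **Elemental ratios** O:C, H:C, N:C, P:C (dimensionless); N:P only when
  P ≥ 1.  These place peaks in van Krevelen space.
* **Kendrick mass and defect** (Da).  KM = mass × 14 / 14.01565 rescales
  the CH2 repeat unit to exactly 14, so homologous series share their
  defect.  The defect convention here is KMD = ceiling(KM) − KM, giving
  values in [0, 1); the rounding convention (round(KM) − KM) is
  available via `convention = "round"`.  The ceiling form is used by
  default because it keeps all defects non-negative, which makes series
  alignment plots easier to read; the two differ only by an integer
  offset per peak.  A 1e-9 guard protects exact-integer Kendrick masses
  from floating-point noise in the ceiling.
* **NOSC** (dimensionless), the nominal oxidation state of carbon:
  NOSC = 4 − (4C + H − 3N − 2O − 2S + 5P)/C.  It is −4 for methane, +4
  for CO2, 0 for carbohydrate-like CH2O stoichiometry, and is bounded in
  [−4, 4] for valence-plausible formulas.
* **GFE** (kJ per mol C), the standard-state Gibbs free energy of the
  carbon oxidation half reaction, via the linear relation
  GFE = 60.3 − 28.5 × NOSC.  More reduced organic matter (lower NOSC)
  has higher GFE, i.e. more energy available on oxidation.
* **DBE** = 1 + (2C − H + N + P)/2, rings plus double bonds.
* **Aromaticity index** AI = (1 + C − O − S − 0.5H)/(C − O − S − N − P),
  a lower bound on aromatic character.  When the denominator is
  non-positive or the computed value negative the index carries no
  information and is clamped to 0 (the standard convention); set
  `clamp = FALSE` to get `NA` instead.  AImod replaces O with 0.5·O,
  assuming at most half the oxygen is carbonyl-like.
* **Elemental composition**: the symbols with non-zero counts in fixed
  order C, H, N, O, S, P (`"CHO"`, `"CHNOS"`, ...).
* **Compound class**: a lookup of the (O:C, H:C) point against a named
  set of axis-aligned rectangles with a precedence order.  The default
  table shipped in `inst/extdata/compound_class_boundaries.csv` follows
  the van Krevelen regions commonly used for natural organic matter
  (lipid, protein, amino sugar, carbohydrate, lignin, tannin,
  condensed/unsaturated hydrocarbon).  Intervals are min-inclusive and
  max-exclusive so boundary points resolve deterministically; a point in
  several rectangles reports all classes joined by `";"` in precedence
  order, and a point in none reports `"Other"`.  The table is plain CSV
  and fully user-replaceable — groups that standardized on a different
  boundary table should load their own with `readBoundarySet()`.

# Filtering

Four predefined filters (sample name, mass range, minimum number of
non-missing observations — optionally per group — and
formula-assigned-only) plus custom filters on any molecular-table or
calculated column (inclusive numeric ranges or categorical keep-sets)
are applied by `applyFilters()` as an ordered chain.

Each filter's membership is evaluated against the dataset as it entered
the chain, and the chain is a running set intersection.  Consequently
the per-step retention counts — the "effect of each filter applied
sequentially" bar chart — depend on the order, while the final peak set
provably does not, even when a sample-name filter (which changes the
column set) shares a chain with a per-group observation filter.  The
per-group minimum-observed rule keeps a peak when **any** group reaches
the minimum; the alternative (every group) discards peaks that are
unique to one group, which is exactly what downstream comparisons look
for, so ANY is the default and the choice is surfaced here rather than
hidden.  An empty result after any step is an error naming the filter,
not a silent empty dataset.  `resetFilters()` returns the snapshot taken
before the first filter; calculated-property columns added before
filtering survive a reset.

# Group comparisons

Groups are assigned by plain substring matching against sample names
(first pattern wins, case-sensitive; regular expressions behind
`regex = TRUE`).  Matching is case-sensitive because sample names are
instrument-generated identifiers where case is usually meaningful.

Two methods decide whether a peak is unique to one of two groups, both
operating on presence/absence:

* **Threshold method**: a peak is unique to group 1 when its observed
  proportion p1 ≥ `presThreshold` and p2 ≤ `absnThreshold`
  (symmetrically for group 2), observed in both when both proportions
  reach `presThreshold`, and otherwise the evidence is insufficient.
  Defaults are `presThreshold = 0.5`, `absnThreshold = 0`: a peak must
  appear in at least half of one group and never in the other.  These
  defaults are a deliberate, documented choice — strict on the "absent"
  side so that "unique" means unique.
* **G-test**: per peak, the 2×2 table of groups × (observed, missing)
  sample counts is tested for independence with the likelihood-ratio
  statistic G = 2 Σ O ln(O/E), divided by the Williams small-sample
  factor q = 1 + (n/n1 + n/n2 − 1)(n/c1 + n/c2 − 1)/(6n), and referred
  to a chi-square distribution with one degree of freedom.  Groups must
  have at least three samples each.  Zero cells contribute 0 to G (the
  x·ln x → 0 limit); a degenerate margin (peak observed in no or every
  sample) gives G = 0, p = 1 by construction.  A peak is unique to the
  group with the larger observed proportion when p ≤ α and that
  proportion reaches `presThreshold`.  No multiple-testing correction is
  applied by default, matching common practice for this screen;
  `pAdjust = TRUE` switches labeling to Benjamini–Hochberg adjusted
  p-values and emits the adjusted column.

A known property, verified by exact enumeration during development: with
10 samples per group and α = 0.05 the Williams-corrected test is
slightly conservative (exact null rejection rate ≈ 0.043) because the
presence counts are discrete.  This is a property of the published test
at small n, not of this implementation — the implementation matches an
independent cell-by-cell oracle to 1e-9 on every 2×2 table with margins
up to 12.

# Ordination and plot tables

`distanceMatrix()` offers euclidean, manhattan, Bray–Curtis (missing
treated as zero abundance) and Jaccard on presence/absence.
`runPCoA()` performs classical scaling via `stats::cmdscale` (the
eigendecomposition of the double-centered −½D² matrix), returning up to
five axes.  Negative eigenvalues, which arise for non-euclidean
metrics, are dropped from both the coordinates and the R² denominator —
no Lingoes/Cailliez correction is applied, so R² per axis is the
eigenvalue over the sum of positive eigenvalues and the R² sequence is
non-increasing with sum ≤ 1.

Visualization is deliberately split from rendering: every plot builder
returns a plain data.frame (one row per point, axis metadata in
attributes) so that any graphics layer can consume it and tests target
numbers, not pixels.  Van Krevelen tables place peaks at (O:C, H:C),
Kendrick tables at (KM, KMD); both exclude peaks lacking the required
values rather than zero-filling, carry formula and mass as hover fields,
and can attach uniqueness labels from a comparison.  Density tables
evaluate one Gaussian-kernel curve per sample (or per group, pooling
each group's per-sample observations) with Silverman's rule-of-thumb
bandwidth on a shared 512-point grid spanning the pooled range extended
by four bandwidths — shared so curves are directly comparable, extended
so each curve integrates to 1 within 1e-3 on its own grid.  Units with
fewer than two distinct values are omitted with a warning.  None of
these kernel settings is prescribed by upstream practice; they are
stated here so users know exactly what a curve is.

# Database mapping, report and export

Formulas map to compound/reaction/module/pathway entries of KEGG or
MetaCyc through a local CSV lookup table; no live web queries are made,
which keeps runs reproducible and avoids licensing entanglements.  Per
formula and (database, entry type) at most `maxRecords` entries (default
5) are returned, truncated in entry-id order for determinism.  Wide
(semicolon-joined cells) and long (one row per entry) layouts carry
identical information; matching by formula string means isomers share
mappings, which is inherent to formula-level identification.

`generateReport()` renders a dependency-free HTML document from the
provenance log: input dimensions, upload selections, each calculated
property with its plain-text equation, each filter with before/after
counts, comparison settings and label counts, and the full step trail.
Setting `options(ftmseda.timestamp = ...)` pins the timestamp, making
reports byte-identical across identical runs — used by the test suite
and available to any pipeline that wants reproducible artifacts.
`exportBundle()` writes the processed two-file pair (re-importable
losslessly up to CSV numeric formatting), an optional merged sheet,
uniqueness and group-summary CSVs when comparisons exist, plot tables,
and the report.

# The synthetic-data generator

`simulateDataset()` emulates the structure this workflow consumes, with
known ground truth: per-peak formulas drawn with C between 4 and 40, H
rejection-sampled into an H:C window of [0.2, 2.5] (capped at the
2C + 2 + N valence limit), O into O:C of [0, 1.2], N/S/P included with
probabilities 0.3/0.15/0.08; monoisotopic masses computed from the
counts; presence of each peak in each sample Bernoulli per group
(defaults: 0.7 for null peaks, 0.9 vs 0.1 for the 20% of peaks flagged
differential); log-normal intensities (meanlog 18, sdlog 1.5, the
1e7–1e9 range of FTICR peak heights); 10% of peaks without formulas.
CoreMS mode additionally writes per-sample candidate files where the
true formula always has the highest confidence score, so resolution can
be checked exactly against the truth sidecar.

What the generator does **not** emulate: m/z noise, peak shapes or
resolution (no spectrum simulation), intensity-dependent missingness,
correlation between peaks, batch effects, or charge-state/ion-type
structure.  Tests passing on these fixtures therefore validate the
statistical and bookkeeping machinery — not instrument physics, nor the
correctness of upstream formula assignment.

# Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to exercise
every code path while keeping a full run comfortably interactive: the
end-to-end pipeline at 2000 peaks × 20 samples, the null-calibration
check at 5000 peaks × 20 samples, exhaustive G-test verification over
all 2×2 tables with margins up to 12, and PCoA reconstruction at 10
samples.  Key tolerances: G/q/p against the oracle to 1e-9; PCoA
distance reconstruction to 1e-8; KMD homologous-series invariance to
1e-9; density normalization to 1e-3.

# Known limitations

* Peak matching across samples (CoreMS route) requires identical
  resolved formula strings; no m/z-tolerance matching.
* Only two-group comparisons; no abundance-based differential tests —
  comparisons are presence/absence by design.
* One Kendrick base (CH2); no isotope-resolved property variants.
* The G-test is conservative for small groups (see above); with very
  small groups the threshold method may be preferable.
* The default compound-class boundary table is one of several in
  circulation; results are only comparable across studies that use the
  same table.
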