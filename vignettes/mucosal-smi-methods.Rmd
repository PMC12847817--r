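---
title: "Methods: spatial single-cell multiomics analysis of colonic mucosa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell multiomics analysis of colonic mucosa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mucosaSMI` implements an end-to-end analysis of imaging-based spatial
molecular imaging (SMI) data from sigmoid-colon biopsies across three cohorts
— inflammatory bowel disease in endoscopic remission (IBD), Parkinson's
disease (PD) and neurologically healthy controls (NHC). The pipeline covers
per-cell quality control of RNA and protein panels, posterior-gated
supervised cell-type annotation, disease-vs-control composition and
differential-expression statistics, gene-set over-representation,
marker-stratified neighborhood ligand–receptor analysis, and fluid-biomarker
regressions. A synthetic-cohort generator with recorded ground truth makes
every stage testable without access to the deposited slides.

# Quality control

## RNA rules

Cells are flagged (and removed downstream) when any of six rules fires, all
evaluated on raw counts:

1. total gene counts below 20;
2. negative-probe counts at or above 10% of all counts;
3. total counts not exceeding the number of detected genes
   (mean count per detected feature at or below 1 — a signature of diffuse
   background rather than a real cell);
4. fewer than 10 detected features;
5. cell area an outlier under an iterative two-sided Grubbs test at
   p = 0.01, applied within each field of view (FOV);
6. mean raw count per negative probe at or above 0.5.

Two readings were genuinely open and are configurable:
the "<20 counts" total excludes negative probes by default (they estimate
background, not signal; `rna_counts_include_negprobes` switches this), and
"a mean of 0.5 negative counts" is read as the mean raw count per
negative-probe feature (the only reading under which the rule flags noisy
cells). Grubbs is scoped per FOV because segmented cell areas vary by tissue
region; `grubbs_scope = "slide"` is available.

The Grubbs statistic is `G = max|x - mean| / sd`, compared against
`G_crit(n, a) = ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with `t` the upper
`a/(2n)` Student-t quantile on `n-2` degrees of freedom; the extreme value is
removed and the test repeated until no rejection. Samples with fewer than 3
values or zero variance yield no outliers.

## Protein rules

Per-protein percentiles are computed across all cells on the slide before any
removal; negative-probe channels are excluded from both protein counts. A
cell is flagged when fewer than half of the proteins sit at or above their
90th percentile, when fewer than 10 proteins sit at or below their 50th
percentile, when the mean negative-probe intensity falls outside the [2, 15]
window, or when its area is a per-FOV Grubbs outlier.

The "50% of proteins at or above the 90th percentile" keep-rule is stringent
for continuously varying intensities: with an untied distribution at most
~10% of cells can clear a per-protein 90th percentile on any one channel, so
broad passing requires percentile ties. In practice sparse checkpoint-style
channels (expressed in a small subset of cells, zero elsewhere) tie their low
percentiles at zero, which is how the rule behaves sensibly on real
immuno-oncology panels — and how the synthetic protein panel is built
(see below). A per-cell alternative reading is available behind
`prot_high_scope = "per_cell"`; the per-protein reading is the default
because it is the literal one.

## Normalization

RNA counts are scaled per cell to the median library size and
`log(1+x)`-transformed, excluding negative probes. This is a deliberate,
config-visible replacement of regression-based variance stabilization: the
downstream statistics (rank-sum tests, posterior classification on raw
counts, ratio-of-means fold changes) require only a monotone transform, and
the library-size normalization keeps the scale-invariance property
(multiplying a cell's counts by a constant leaves its normalized vector
unchanged) that the tests verify directly.

Protein intensities are scaled by (mean total intensity across cells) /
(cell total intensity), then transformed by `asinh(x / 50)` — the standard
cytometry cofactor-50 arcsinh, linear near zero and logarithmic in the tail.

# Cell-type annotation

Annotation is supervised: per-type reference profiles (pseudocount-smoothed
gene fractions, built from any labeled reference via
`build_reference_profiles()`) score each cell under a Poisson count model
with the cell's library size as exposure:

$$\log L_t = \sum_g x_g \log(n\,p_{t,g}) - n\,p_{t,g}.$$

Because profiles sum to one over genes, the exposure terms cancel across
types and the assigned label is invariant to library size. Posteriors are
prior-weighted normalized likelihoods (uniform prior by default); a cell is
retained only when its best posterior reaches the gate of 0.75. The same
classifier is re-run within each retained primary class (epithelial,
myeloid, plasma, stroma, T cell) against that class's refined profiles
(e.g., colonocytes and goblet cells inside epithelial; CD4 and CD8 inside
T cells), with the same gate.

This classifier is an openly documented simplification of the
expectation-maximization cell-typing tools used with SMI panels: supervised
assignment against fixed reference profiles, with an optional
negative-binomial dispersion (`dispersion > 0`) and optional Gaussian
morphology-marker features (PanCK/CD45/CD3/CD68 means; off by default).
Immunoglobulin genes (IGH/IGK/IGL prefixes) are removed before annotation
because they are highly expressed in all cell types and would swamp the
likelihood.

# Composition statistics

Per cluster and per comparison (IBD vs NHC, PD vs NHC) the package reports:

- a pooled 2×2 chi-squared test of (in-cluster vs not) × (disease vs NHC),
  without Yates correction by default (cell counts are in the thousands);
- a patient-level Wilcoxon rank-sum test on per-patient cluster proportions;
- the pooled-proportion fold change;
- Benjamini–Yekutieli (BY) adjusted chi-squared p-values across all
  cluster × comparison rows;
- a significance code (`*`, `**`, `***` at adjusted p 0.05/0.01/0.001),
  emitted only when FC > 1.5 or FC < 0.66.

The star is driven by the BY-adjusted chi-squared p gated by the FC bounds;
the Wilcoxon p is reported alongside rather than folded into the code, since
no combination rule is defined for the pair of tests. This matters: the
pooled chi-squared treats cells as independent, so under real
patient-to-patient compositional variability it is anti-conservative (the
design effect grows with cells per patient). The patient-level Wilcoxon is
the robust companion readout, which is why both are always reported. The
package's null-calibration test therefore simulates the no-variability null
(identical compositions for every patient), the regime the chi-squared test
is exact for.

Fold changes are computed on pooled proportions, not means of per-patient
fold changes, matching the per-patient count-aggregation description. Note
that a planted k-fold Dirichlet multiplier on a base share `p` renormalizes
to an observed FC of `k/(1+(k-1)p)`, not `k`; recovery bands in the tests
account for this arithmetic.

# Differential expression and volcano classes

Within a cluster, each gene is tested by a cell-level Wilcoxon rank-sum
between a disease arm and NHC on normalized expression (the ecosystem's
default for targeted panels; a patient-pseudobulk alternative is an obvious
extension but is not the default here). Fold change is the ratio of arm
means with a 1e-9 epsilon; p-values are BY-adjusted within the
(cluster, comparison) gene family — BY is used for every adjustment in the
package for consistency. Volcano classes:

- `dark_red`: adjusted p < 0.05 and FC > 1.2;
- `light_red`: raw p < 0.05 and FC > 1.2 (not dark);
- `dark_blue` / `light_blue`: mirrored with FC < 0.83;
- `ns` otherwise.

The light classes carry the same FC bounds as the dark ones; without them
the red and blue halves would be inconsistent.

Because the volcano FC is a ratio of mean log-normalized values, a planted
k-fold change on raw means is compressed, and the compression grows with
expression level (log1p is near-linear only below a few counts). The synthetic
defaults place the marker gene FTH1 at ~5 counts per marker-positive
colonocyte precisely so a true 2× raw effect lands clearly above the 1.2
gate; at 16+ counts the same effect would sit near the gate. This is a
property of the analysis worth knowing when reading real volcano plots.

# Over-representation analysis

For a directional gene list (dark_red or dark_blue genes) against a GMT
collection, each set is scored by the upper-tail hypergeometric probability
of the observed overlap given the tested universe, BY-adjusted across sets;
the top 10 pathways per direction are reported, ranked by adjusted p. No GO
topology is used — the sets are user-supplied.

# Spatial ligand–receptor analysis

Neighborhoods are all unordered cell pairs within a closed 25 µm Euclidean
ball, computed strictly within FOV (coordinates are in µm; a µm/pixel factor
converts pixel input). The source cell type (colonocytes) is stratified by
raw marker detection — FTH1 counts at or above 1 — because positivity in
imaging panels is a detection event; the threshold is configurable.

For each (target type, ligand, receptor), the score is the mean over
directed source→target neighbor pairs of ligand expression in the source
times receptor expression in the target. Significance comes from a
permutation null: cell labels (type and stratum jointly) are re-drawn by
permutation within each FOV, preserving the spatial point pattern and the
expression-cell linkage, and all scores are recomputed N times (N ≥ 100,
default 1000). Empirical p = (1 + #{null ≥ observed})/(N + 1); a row absent
from a permutation (no qualifying edge) contributes a null score of zero.
P-values are BY-adjusted per (group, stratum); significant rows are counted
per group and stratum — the quantity compared across cohorts.

This is explicitly a stand-in for unbalanced optimal-transport coupling
tools: the claims exercised here (more significant marker-positive
interactions in the disease groups) concern neighborhood ligand–receptor
enrichment, which the label permutation tests directly. What the null
detects is the three-way coupling of labels, expression and geometry: a
stratum is significant only when its real cells co-express the pair with
their real neighbors more than random labelings do. Two design consequences:

- a stratum whose cells do not express the ligand cannot become significant
  (its observed score is ~0 and ties with the null), which is what makes the
  marker-negative stratum and the healthy cohort quiet in the planted
  scenario; and
- LR pairs over genes with genuinely type-specific expression are *not* null
  even without any spatial structure — the label–expression coupling is
  real. Calibration checks therefore use LR pairs built from
  housekeeping-like genes with type-uniform rates.

# Fluid biomarkers

The MSD-style module averages assay duplicates (flagging CV > 20%),
optionally normalizes stool analytes to BCA total protein, compares analyte
concentrations between disease arms and NHC by Wilcoxon rank-sum (chosen for
small skewed immunoassay samples; Welch t behind a flag), and fits ordinary
least-squares regressions (slope, intercept, R², two-sided slope t-test) for
the CCL22–ferritin and CCL22–disease-duration relationships. Regressions run
on raw concentrations to mirror how such panels are usually plotted; a log
option is a one-liner for the caller. Note that a log-scale correlation ρ
attenuates on the raw scale for lognormal data
(`r = (exp(ρσ²)-1)/(exp(σ²)-1)`), so an R² near ρ² · 0.93 at σ = 0.5 is the
expected raw-scale recovery, which the tests encode.

# The synthetic cohort

`simulate_cohort()` draws, per patient, a refined-type composition from a
Dirichlet distribution whose mean is the base composition times per-group
multipliers (defaults: colonocytes ×2 in IBD and PD, CD4 T cells ×0.5 in
IBD, CD8 T cells ×2 in PD — the compositional phenotype of the study
conditions), with concentration 100 (patient-to-patient CV of roughly 10%
for mid-size clusters). Cohort sizes default to 13 IBD / 12 PD / 8 NHC
participants with two 0.5 mm FOVs each; cells per FOV defaults to 1200,
a working choice consistent with the study's total of ~75k cells over 66
FOVs (the per-FOV number is not stated anywhere).

Gene counts are negative binomial, `variance = mean + mean²·dispersion`
(dispersion 0.3), with mean = lognormal size factor × per-type profile ×
planted fold changes. The built-in panel couples marker blocks per refined
type, shared housekeeping genes, the iron axis (FTH1 high in colonocytes
with a ferroportin partner SLC40A1), a chemokine axis (CCL20→CCR6),
immunoglobulins (to exercise the Ig exclusion) and low-rate spike genes.
Planted effects default to FTH1 ×2 in IBD colonocytes and ×0.5 in PD, and
SLC40A1 ×0.5 in both — the iron-mishandling phenotype. Negative probes are
Poisson at 0.02 counts/cell; areas are lognormal (median 120 µm², sdlog
0.35) with an optional fraction multiplied by 10 and recorded as planted
outliers.

Marker positivity is a mixture truth: a configurable fraction (0.5) of
colonocytes draws FTH1 from the high component (base rate × 4), the rest
from a near-zero component; membership is recorded explicitly so downstream
thresholds cannot redefine the truth. In the disease groups, marker-positive
colonocytes additionally induce CCL20 (×12 over a near-silent baseline —
CCL20 is an inflammation-inducible chemokine, so healthy colonocytes carry
essentially none) and attract plasma cells: each target-type cell is, with
probability `strength`, re-placed uniformly within 25 µm of a random
marker-positive source in its FOV (a parent–offspring process). Together
these two mechanisms — disease-specific ligand induction plus spatial
attraction — are what make the marker-positive stratum of the disease
groups, and only it, carry significant ligand–receptor interactions under
the permutation null.

Protein intensities are lognormal: a handful of broad channels in every
cell, several sparse per-primary-type channels expressed in ~30% of their
type (zero elsewhere — creating the percentile ties the protein QC rules
need, see above), two negative-probe channels centered in the [2, 15]
acceptance window, all scaled by a per-cell factor. The fluid panel draws
analytes per participant from group-shifted lognormals, with CCL22 and
ferritin bivariate-lognormal (log-scale ρ defaults: 0.77 IBD, 0.71 PD, 0
NHC), a 2× CCL22 depletion in PD plasma, and a planted negative
CCL22–duration relationship in PD calibrated to a target R² of 0.32.

What the generator does **not** emulate: segmentation errors and doublets,
crypt/tissue morphology, spatial expression gradients within types,
batch/slide effects, probe-specific background structure, and the full
variance structure that regression-based normalization targets. Passing
tests therefore demonstrate correctness of the statistical machinery under a
clean generative model, not robustness to those artifacts.

# Numerical choices and degenerate inputs

- Profiles carry a 1e-6 pseudocount; DE fold changes an 1e-9 epsilon.
- Posterior computation uses log-sum-exp stabilization; ties in the argmax
  resolve to the first type (deterministic given column order).
- The rank-sum normal approximation applies tie and continuity corrections
  and matches `wilcox.test(exact = FALSE, correct = TRUE)` per gene; the
  exact test is used for combined samples of at most 20 without ties.
- Closed-ball convention: a pair exactly at 25 µm is a neighbor.
- Grubbs on fewer than 3 values or zero variance: no outliers, no error.
- Empty p-value vectors adjust to empty vectors; clusters absent from the
  NHC arm yield an NA fold change with a warning rather than an error.
- Density curves are renormalized by the trapezoid rule on their grid so
  each integrates to 1.

# Problem sizes used by the test suite

The suite runs cohorts of roughly 1–20 thousand cells: annotation recovery
uses ~20,700 cells at ≥200 counts/cell; composition calibration uses 100
null replicates of ~1,350 cells; DE calibration uses 100 label permutations
of a ~6,800-cell cohort; the spatial analysis uses 199–500 permutations on
cohorts of ~1,800–3,600 cells. These sizes were chosen so each statistical
property is tested well inside its asymptotic regime while the whole suite
stays fast enough to run routinely.

# Known limitations

- The pooled chi-squared composition test is anti-conservative under
  patient-level overdispersion (see above); treat its stars together with
  the Wilcoxon column.
- The Poisson classifier ignores within-type expression heterogeneity
  beyond library size; heavily admixed or intermediate cells fail the 0.75
  gate rather than being modeled.
- The permutation null conditions on geometry and expression; it cannot
  separate "attraction of cells" from "induced expression near neighbors" —
  both manifest as label–expression–geometry coupling.
- Protein QC under the literal per-protein percentile reading depends
  critically on percentile ties; on fully continuous data it removes almost
  everything, which is flagged rather than silently patched.
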