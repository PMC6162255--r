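---
title: "AMT-tag label-free differential proteomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AMT-tag label-free differential proteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoamt)
```

## The problem

A label-free LC-MS experiment detects tens of thousands of peptide
features (unique mass classes, UMCs) per run, but data-dependent MS/MS
acquisition identifies only a small fraction of them — in deep
tissue-proteome studies roughly one in ten. Comparing two subject groups
(say, diabetic and non-diabetic skeletal-muscle mitochondria) on only the
identified features wastes most of the signal and biases coverage toward
abundant peptides. The accurate mass and time (AMT) tag strategy
addresses this: identifications accumulated across all runs define, for
each peptide, a consensus accurate mass and a consensus normalized
elution time (NET), and unidentified features are then matched to this
database by proximity in (mass, NET) space.

`mitoamt` implements the complete analysis: AMT database construction,
peptide assignment, cross-run alignment and normalization, a composite
permutation test for differential expression with protein rollup, and
enrichment plus interaction-network assembly over the resulting DEPs. A
synthetic-cohort generator with planted ground truth makes every stage
testable.

## NET computation and calibration

Within one run, NET is the min–max rescaling of the elution axis to
$[0,1]$; it is strictly monotone in elution and independent of the units
(scan number or minutes). A run whose elution values are all identical
is degenerate and rejected.

Min–max scaling removes per-run affine drift only up to the sampling of
the elution extremes, so runs are additionally calibrated against the
database: for each run, ordinary least squares fits
$\mathrm{net}_{\mathrm{ref}} = a + b\,\mathrm{net}_{\mathrm{run}}$ on
the anchor peptides the run shares with the reference (its identified
features), one pass of outlier rejection removes anchors with
$|r_i| > 3\hat\sigma_r$, the line is refitted, and the map is applied to
*all* of the run's features, clipping into $[0,1]$. The calibration
model is deliberately affine with two parameters: it is the minimal
model that inverts the drift the generator plants and it is identifiable
from a handful of anchors. Runs with fewer than three anchors cannot be
calibrated; they raise a classed warning and are flagged
(`calibrated = FALSE`) rather than aborting a multi-run build, so the
caller decides whether to keep them.

Database construction is two-pass: NETs are normalized per run, a
first-pass database supplies reference median NETs, every run is
calibrated against it, and the database is recompiled once from the
calibrated NETs (`build_calibrated_amt_db()`). Two passes are bounded,
deterministic, and sufficient at the scales this package targets;
iterating to convergence was rejected as it adds nondeterminism in
stopping without measurable benefit on the planted-drift recovery tests.

Per peptide the database records the arithmetic **mean** of observed
masses and the **median** of observed calibrated NETs; the even-count
median is the midpoint of the central pair (the conventional choice).
The median is used for NET because elution is the noisier, occasionally
multimodal axis.

## Matching tolerances and tie policy

A feature matches an entry when both
$|10^6 (m_{\mathrm{obs}} - \bar m)/\bar m| \le 10\ \mathrm{ppm}$ and
$|\mathrm{net}_{\mathrm{obs}} - \widetilde{\mathrm{net}}| \le 0.025$.
The ppm deviation is computed relative to the database entry's average
mass: the database is the reference object, and at these tolerances the
choice of denominator changes the window by under $10^{-4}$ relative.
Among candidates the winner minimizes the tolerance-scaled Euclidean
distance $\sqrt{(\Delta\mathrm{ppm}/10)^2 + (\Delta\mathrm{net}/0.025)^2}$,
which weights both axes by their allowed slack; exact distance ties are
broken by peptide id so results are deterministic. Multi-candidate
matches are assigned to the nearest entry but flagged `ambiguous`, and a
strict mode (`drop_ambiguous = TRUE`) discards them instead — both
policies are defensible and the flag preserves the information either
way. Features identified by database search are never reassigned.

The production matcher windows a mass-sorted index by binary search;
its correctness criterion is exact agreement with exhaustive pairwise
search, which the test suite enforces on random 200 × 200 instances.

## Alignment, normalization, replicate collapsing

The alignment table holds one row per peptide and one column per run;
a cell is the **sum** of the intensities of all UMCs carrying that
peptide in that run (UMC intensity is itself a sum over mass-spectral
components, so summation extends the existing contract). Absence is
`NA`, never zero — zeros would corrupt the log2 scale and the detection
filter.

Quantile normalization acts on run-level log2 intensities, *before*
replicate collapsing, because the systematic variation it corrects
(loading, ionization efficiency) is a per-run effect. The algorithm is
the standard one with missingness support: each column's observed
quantiles are interpolated onto a common grid, the reference
distribution is the across-column mean, ties receive the mean of the
quantile values they span, and missing cells remain missing
(`limma::normalizeQuantiles`, `ties = TRUE`). On complete data this
reduces to replacing every column's order statistics by their
across-column means and is idempotent.

Replicates are collapsed to the subject mean of observed log2 values —
a subject's cell is missing only when all replicates are missing.
Subjects, not runs, are the statistical units: a 9 vs 9 design has 16
degrees of freedom, and treating 27 correlated replicate columns per
group as independent would overstate them threefold.

## The composite test

Peptides enter testing only if detected in strictly more than 50% of
subjects in **each** group (with $n = 9$ that means $\ge 5$), and only
if their protein retains at least two distinct sibling peptides after
the detection filter (membership recomputed until stable). The
two-sibling threshold (rather than three) matches the dataset-level
protein accounting this pipeline reproduces; a single-peptide protein
call is not considered reliable.

Per peptide, two statistics are computed on subject-level log2 values:

* the pooled-variance Student $t$ (the classical equal-variance form —
  the design is balanced, which is exactly where pooling is defensible);
* the log2-median ratio, $\mathrm{median}(x) - \mathrm{median}(y)$,
  robust to single-subject outliers.

Positive values mean higher in the case group.

**Permutation null.** Group labels are permuted over balanced
relabelings: distinct subject partitions into groups of the original
sizes, with complementary labelings deduplicated when the sizes are
equal (they give identical two-sided statistics) and the identity
partition excluded. When the number of distinct relabelings does not
exceed the request (default 1000) they are enumerated exhaustively;
otherwise they are sampled without replacement under the configured
seed. Null statistics are **pooled across peptides and permutations**,
and the two-sided adjusted p-value is

$$p_i = \frac{1 + \#\{|T^{\mathrm{null}}| \ge |T_i|\}}{1 + N_{\mathrm{null}}}.$$

Pooling gives p-value resolution far below $1/B$ per peptide (with
$m$ peptides the granularity is $\approx 1/(mB)$), at the price of
assuming peptides share a common null scale — reasonable after quantile
normalization. The $+1$ correction keeps p-values in
$(0,1]$ and valid under the null. Infinite $t$ values (zero pooled
variance with unequal means) are retained and compared on the absolute
scale, so they take the smallest attainable p rather than corrupting the
pool.

**Stouffer combination.** The two adjusted p-values are combined
preserving direction:
$z_i = \mathrm{sign}_i\,\Phi^{-1}(1 - p_i/2)$,
$z_c = (z_t + z_{\mathrm{ratio}})/\sqrt2$,
$p_c = 2(1 - \Phi(|z_c|))$, clamped into $(0,1]$. Signed combination
with two-sided reconstruction means concordant evidence reinforces and
a peptide whose two statistics disagree in direction is penalized —
equal evidence with opposite signs cancels to $p_c = 1$ exactly. Input
zeros (impossible from the permutation construction, possible from user
input) are clamped to the smallest positive double with a classed
warning.

**Storey q-values.** $\hat\pi_0 = \min\!\big(1, \#\{p > \lambda\} /
((1-\lambda)m)\big)$ with $\lambda = 0.5$ (the conventional midpoint;
with pooled-null p-value granularity there is no need for the spline
extrapolation over a $\lambda$ grid), then the step-down rule
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. Output is clamped
into $(0,1]$ and is monotone nondecreasing in $p$.

**Calls and rollup.** A peptide is significant iff $q \le 0.1$ **and**
$|\log_2 \text{ratio}| \ge \log_2 1.5$; the fold criterion is two-sided
because both up- and downregulation are of interest. A protein is a DEP
iff at least one sibling peptide is significant; its fold change is the
median over significant siblings (all siblings when none are), and its
direction is `up`/`down` by sign or `mixed` when significant siblings
disagree — mixed calls are surfaced, not silently resolved.

## Enrichment and network assembly

Enrichment of the up- and downregulated DEP sets uses the one-sided
hypergeometric upper tail $P(X \ge k)$ (Fisher's exact enrichment
test); `mode = "ease"` subtracts one from the overlap (floored at zero)
before the tail, the conservative EASE-score variant popularized by
DAVID. The **universe is the measured proteome** — the proteins passing
the peptide filters — not the genome: detectability is a strong
confounder in proteomics and a genome background would inflate every
test. Following the $P \le 0.05$ convention for this analysis style, no
multiple-testing correction is applied to the significance call; a
Storey q-value column is emitted for information.

The network model seeds on DEPs annotated to at least one enriched
term; an interactor is retained only if it is itself a DEP or annotated
to a selected term; edges induced among retained nodes are
deduplicated (undirected, provenance tags merged) and self-loops
dropped. Nodes are the endpoints of the induced edges — the model is an
interaction network, so DEPs without a single qualifying interaction do
not appear as isolates. Node attributes carry the protein log2 fold
change and the enriched-term group labels (`"unassigned"` when none).

## What the generator emulates — and what it does not

Defaults describe a 9 vs 9 cohort with triplicate runs (54 run tables):

| parameter | default | meaning |
|---|---|---|
| `mass_error_ppm_sd` | 3 ppm | relative mass error of an FT-class instrument |
| `net_noise_sd` | 0.005 NET | per-feature elution jitter |
| `net_drift_slope_sd` / `intercept_sd` | 0.1 / 0.02 | run-specific affine drift (lognormal slope, NET-unit intercept) |
| `log2_intensity_sd` | 0.5 | per-run intensity noise (log2) |
| `id_rate` | 0.104 | MS/MS identification probability per feature |
| `dropout_midpoint`, `dropout_steepness` | 19, 0.8 | logistic detection curve on true log2 intensity |
| base abundance | $\mathcal N(23, 2^2)$ log2 | typical LC-MS summed-intensity scale |
| masses, NETs | $U(800, 3500)$ Da, $U(0,1)$ | tryptic-peptide range |

The identification rate is anchored to the ~10.4% per-run value typical
of deep label-free tissue studies; mass and NET noise magnitudes are
platform-style defaults chosen once (no published values exist for this
combination), sized so that the ±10 ppm / ±0.025 NET windows sit at
>3σ of the respective errors. Elution is emitted in arbitrary scan
units through the run's affine map, so NET computation and calibration
are genuinely exercised downstream; elution jitter is applied on the
NET scale inside the map, keeping `net_noise_sd`'s meaning independent
of the drift. Dropout is logistic in true log2 abundance, making
missingness intensity-dependent so the 50% detection filter has real
work to do (`dropout_steepness = 0` disables it). Unidentified features
keep their true identity only in the hidden manifest, enabling matcher
accuracy scoring; `simulate_cohort()` strips it from the analyst-facing
tables.

Planted DE proteins receive a signed log2 fold change shared by all
their sibling peptides, with magnitude at least $\log_2 1.5$.

The generator does **not** emulate: correlated peptide behavior within
a protein beyond the shared fold change, per-subject biological random
effects beyond replicate noise, chimeric/incorrect identifications in
the search results, charge-state or isotopic-envelope structure,
nonlinear retention drift, or shared (non-unique) peptides. Passing
tests therefore demonstrate correctness of the algorithms under a clean
generative model, not robustness to every pathology of real LC-MS data;
in particular, matcher accuracy on real data depends on peptide density
in (mass, NET) space, which here is uniform.

## Numerical and degenerate-input choices

* Seeds: one integer seed drives everything; per-run and per-stage
  streams derive from it by a deterministic label hash kept below
  $2^{31}$ (`derive_seed()`), so any stage can be re-run in isolation.
* Degenerate runs (constant elution), empty feature sets, empty
  identified sets, columns with fewer than two observations, and
  unmapped runs raise classed errors (`mitoamt_*`) rather than
  propagating `NaN`s.
* Zero pooled variance: $t = 0$ for equal means, signed infinity
  otherwise (handled in the null pool as described).
* `filter_peptides` returning nothing is a classed warning, not an
  error — an empty result is a legitimate outcome of strict filters.
* All file formats are plain TSV with `NA` for missing; GMT and SIF
  follow their usual layouts.

## Validation scales

The test suite validates each operation against independent oracles
(exhaustive matching, enumerated permutations, brute-force step-down
q-values, combinatorial hypergeometric tails) at small sizes, and the
dataset-scale properties on synthetic cohorts of 400 proteins
(~2,200 peptides) under the default 9 vs 9 × 3 design: pure-null
q ≤ 0.1 call rates over 20 seeded cohorts, and planted-signal recovery
with fold changes in $[1.5, 2.0]$. These sizes were chosen as the
smallest at which the cohort-level behavior (filter occupancy,
pooled-null granularity, rollup) is representative of a full study.
`scripts/acceptance.R` re-runs the same computations from scratch and
emits the headline numbers as JSON.

## Known limitations

* No decoy-based FDR for AMT assignments (decoy-NET methods); the
  matcher reports accuracy only against synthetic ground truth.
* No imputation; missingness is handled by exclusion and the detection
  filter.
* No moderated-variance (empirical-Bayes) statistics — the composite
  permutation test is the implemented contract; `limma` remains the
  natural alternative when few subjects are available.
* Peptides shared between proteins are not resolved; the peptide map is
  assumed unique.
* Enrichment p-values are uncorrected by design (the q-value column is
  informational).
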