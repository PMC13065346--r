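---
title: "Methods: EV-miRNA landscape analysis with miRland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EV-miRNA landscape analysis with miRland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRland)
```

# Scope and data model

`miRland` analyzes miRNA-level count matrices from extracellular-vesicle
(EV) small-RNA sequencing across several parent-cell subtypes. The default
design mirrors a four-subtype cardiac EV study — CM, CF, HCMVEC and Mac
EVs with 3, 3, 3 and 4 biological replicates — but every stage works for
any number of groups with at least two replicates each. The substrate is
an `ev_counts` object: an integer feature-by-sample matrix plus a group
factor. Feature IDs follow miRBase conventions; the species prefix is
lower-cased at ingest, the remainder is case-sensitive.

# Harmonizing two pipeline dialects

Counts produced by different vendor pipelines disagree in two ways this
package models: features present in one file and absent in the other, and
features reported without their `-3p`/`-5p` arm suffix. `harmonize_counts()`
applies two rules:

* **Zero-filling.** A feature missing from one file is added with zero
  counts for that file's samples, symmetrically, so downstream stages see
  one rectangular matrix. Zero-filling is recorded per file in the log.
* **Arm resolution.** An arm-less feature `X` is renamed to `X-5p` or
  `X-3p` iff exactly one of the arms has non-zero total counts in the
  reference file *and* the chromosome annotations of `X` and that arm
  agree when both are available. Any other evidence pattern — both arms
  expressed, neither expressed, conflicting chromosomes, or a rename that
  would collide with a feature already present — excludes the feature from
  the merged matrix and logs it as unresolved.

Exclusion of unresolved features is this package's choice (the rule's
published description is silent): keeping an arm-less row alongside a
resolved arm would double-count reads against it, and the log preserves
auditability. Harmonization never alters a numeric count — it renames,
unions and zero-fills only — so the count mass of every retained feature is
conserved and harmonizing an already-harmonized pair is a no-op (both are
tested properties).

A caveat worth stating: the sole-expressed-arm rule can be *consistently
wrong* when the true arm happens to be silent in the reference samples
while its sibling arm is expressed there and missing from the primary
file. The round-trip test therefore asserts exact recovery only on
features whose rename provably lands on the true arm; the failure mode is
inherent to the rule, not to its implementation.

# Normalization and PCA

Two abundance scales are kept deliberately distinct:

* **CPM** (`cpm()`): count / sample total × 10⁶, no pseudocount. Used for
  top-*k* abundance ranking, matching how per-subtype abundance is usually
  presented (mean ± SD of CPM).
* **Median-of-ratios** (`size_factors()`): a pseudo-reference is the
  per-feature geometric mean over samples, restricted to features non-zero
  everywhere (a geometric mean with zeros is degenerate); each sample's
  size factor is the median count-to-reference ratio, rescaled so the
  size factors have geometric mean exactly 1. Normalized counts
  (count / size factor) feed differential expression and τ. If no feature
  is non-zero everywhere the procedure fails with a message suggesting
  CPM — deliberately, rather than silently switching scales.

The variance-stabilizing transform is `log2(normalized + 1)`. Shrinkage
transforms (regularized log) are implementation details of particular
packages; the transparent substitute keeps zeros at zero via the
pseudocount of 1, at the cost that PCA variance percentages are not
comparable to shrinkage-based ones — they are treated as approximate
references only throughout. `mir_pca()` treats samples as observations,
centers features and does not unit-scale them (scaling would erase the
abundance structure the log transform already stabilized), drops constant
features, and returns scores plus variance-explained fractions that are
non-negative, non-increasing and sum to 1.

# Detection partition and abundance ranking

`detect_partition()` assigns each feature to the exact subset of groups in
which a detection rule holds — the cells of the multi-group Venn diagram.
The default rule, *any replicate non-zero*, is the most permissive reading
of "detected in sequencing"; because published Venn counts depend on the
(usually unstated) rule applied by the original authors, the rule is a
parameter and `detection_benchmark()` reports agreement with reference
counts under every built-in rule rather than asserting one. Stricter
rules can only shrink per-group totals (a tested monotonicity property).

`rank_abundance()` ranks by mean CPM within each group, with ties broken
lexicographically by feature ID so rankings are reproducible, and flags
features in the top *k* of all groups (`common_abundant`) or of exactly
one (`uniquely_abundant`).

# Differential expression

All groups enter one analysis: size factors and dispersions are estimated
once on the full matrix, then every unordered pair of groups is tested per
feature. The model is the negative binomial with variance μ + αμ².

**Dispersion.** Three steps share information across features:

1. Method-of-moments start values from pooled within-group means and
   variances of normalized counts.
2. A mean-dispersion trend: a gamma GLM of the moment estimates on log
   mean, refitted once after trimming gross outliers. The gamma family
   targets the conditional *mean* of the dispersion. This matters:
   median-targeting or log-scale-centered fits systematically sit below
   the mean dispersion, and an underestimated α inflates every Wald
   statistic.
3. A per-feature maximum a posteriori estimate: the Cox–Reid-adjusted NB
   profile log-likelihood (group means profiled out by ratio-of-sums)
   plus a normal prior on log α centered at the trend, maximized on a
   log-α grid with quadratic refinement. The prior variance is the spread
   of log moment estimates around the trend in excess of their expected
   chi-square sampling noise, floored at 0.25.

The likelihood/prior asymmetry is what controls the far tail of the null
distribution: with three replicates, a feature's observed scatter can
collapse by chance, but such data carry almost no likelihood evidence
*against* a larger α, so the prior pulls the estimate back to the trend
instead of letting a spuriously tiny α manufacture a p-value of 10⁻⁶.
A symmetric 50/50 average of moment and trend values (the design first
implemented) lacks this asymmetry and measurably inflates the extreme
tail; the package's test suite quantifies the difference on null
simulations.

**Wald test.** log2FC = log2((m_A + ε)/(m_B + ε)) with ε = 0.5 normalized
counts guarding zero means; SE = sqrt(1/I_A + 1/I_B)/ln 2 with
I_g = Σ_j s_j m/(1 + α s_j m), the NB observed information for a log-mean
parameter; two-sided p-values from the standard normal. Features with zero
counts in both groups of a pair report log2FC = 0 and p = 1. There is no
outlier replacement, no independent filtering and no fold-change
shrinkage — the fold-change-based enrichment criterion downstream reads
these unshrunken estimates. Benjamini–Hochberg adjustment (`adjust_fdr()`,
an explicit step-up implementation tested against an independent oracle)
is applied within each pairwise table, the per-contrast convention.

**What calibration can and cannot achieve.** With ~9 residual degrees of
freedom of dispersion information and realistic trend-free dispersion
heterogeneity, a plug-in normal Wald test holds its size well at
conventional thresholds (the test suite checks the p < 0.05 fraction
against 99% binomial bounds on null simulations) but no small-sample NB
procedure keeps the p ≈ 10⁻⁵ tail exact; on fully null matrices the
family-wise chance of at least one BH discovery therefore exceeds its
nominal level, for this implementation and for the field-standard engines
alike. Consumers should read single isolated discoveries on tiny designs
accordingly.

# Tissue-specificity index and the key-miRNA filter

τ = Σᵢ (1 − xᵢ/x_max)/(N − 1) over per-group mean *normalized* counts
(not CPM): 0 for uniform profiles, 1 for single-group expression,
undefined (NA) for all-zero profiles, which are never called enriched. τ
is scale-invariant and non-decreasing as mass moves toward the maximal
group (both tested numerically).

`classify_key()` evaluates, per (feature, subtype):

* **abundant** — in the subtype's top-*k* (default 20) by mean CPM;
* **upregulated** — FDR < α (default 0.05) with log2FC favoring the
  subtype in ≥ 1 pairwise comparison;
* **enriched** — τ > 0.7, or linear fold change > 5 in the subtype's favor
  in ≥ 2 pairwise comparisons.

A *key* miRNA satisfies all three; *consensus-upregulated* miRNAs pass the
upregulation test against every other subtype. Two interpretation choices
were genuinely open and are resolved as follows:

* Whether the fold-change arm of enrichment requires FDR significance in
  those comparisons is unstated in the procedure this mirrors. Default:
  significance required (`require_significance = TRUE`) — a fold change
  computed between two near-zero means is noise, and the significance
  gate removes exactly those; the permissive reading is available behind
  the flag.
* The τ arm is applied direction-free (τ > 0.7 marks a feature enriched
  for any subtype under evaluation, per the criterion's literal form);
  since key status also requires subtype-specific abundance and
  upregulation, a feature enriched toward a *different* subtype cannot
  become key through this arm in practice.

# Assumption-routed group statistics

`assess_assumptions()` computes per-group Shapiro–Wilk p-values on the raw
and (for positive data) log scale, plus a spread test — Brown–Forsythe
(median-centered Levene) for ≥ 3 groups, the F test for 2 — and derives
predicates at α = 0.05. Normality is assessed per group, all groups must
pass (the convention of the desktop statistics software this mirrors);
groups with < 3 observations make Shapiro–Wilk inapplicable and fail
normality explicitly. `select_route()` is a total, deterministic mapping,
exhaustively unit-tested over all predicate combinations:

| design | predicates | route |
|---|---|---|
| multi-group | normal, equal SD | ANOVA + Tukey |
| multi-group | normal, unequal SD | Brown–Forsythe & Welch ANOVA + Dunnett T3 |
| multi-group | not normal | Kruskal–Wallis + Dunn |
| two-group (multiplicative) | lognormal, equal SD | lognormal t |
| two-group (multiplicative) | lognormal, unequal SD | lognormal Welch t |
| two-group (multiplicative) | not lognormal | Mann–Whitney |
| two-group (index) | normal, equal SD | unpaired t |
| two-group (index) | normal, unequal SD | Welch t |
| two-group (index) | not normal | Mann–Whitney |

Dimensionless indices (e.g. lacunarity of a vessel network) are routed on
the raw scale via `scale_hint = "dimensionless_index"`; multiplicative
vessel metrics via `"lognormal_candidate"`. Numerical notes: the
Brown–Forsythe *ANOVA* (adjusted-df F\*) is distinct from the
Brown–Forsythe *spread* test and both are implemented; Dunnett T3
comparisons use Welch t statistics with a Sidak adjustment — the
independence form of the studentized-maximum-modulus adjustment, adopted
because no SMM distribution is available in the supported dependency set;
Dunn's comparisons use tie-corrected rank sums with Bonferroni
adjustment. Parametric routes refuse zero-variance groups; log routes
refuse non-positive values, naming the offending observation.

# The synthetic generator: what it emulates, and what not

`simulate_counts()` draws NB counts with feature-specific baselines
(log-uniform means, default 5–5000 expected counts), feature-specific
dispersions, per-sample library-size factors (uniform 0.5–1.5), optional
single-group signed log2 fold-change effects, and structural zeros that
silence a feature in a random strict subset of groups so detection sets
differ between subtypes. Defaults reflect the modeled study where it
states them (group names, sizes 3/3/3/4, |log2FC| = 2 for effect-recovery
checks) and plausible values for what it does not (no depth or
library-size figures are published; dispersions α ∈ U(0.05, 0.6),
independent of the mean, represent realistic trend-free biological
heterogeneity for small-RNA counts). These were fixed before any
calibration measurements and not revisited.

Deliberate simplifications: one effect group per feature (keeps
consensus-upregulation and τ ground truth unambiguous), structural zeros
drawn from non-effect features (keeps effect truth unambiguous), no isomiR
structure, no UMI or read-level error model, no correlation between
features. Consequently a green test establishes correctness of the
*pipeline mechanics and statistical calibration under the NB model* — not
robustness to adapter/ligation biases, isomiR collapsing choices or
cross-feature correlation, all of which real EV small-RNA data contain.

`emit_dialects()` splits a simulated matrix into the two pipeline
dialects: the primary file carries all groups but the last and suffers arm
stripping (at most one arm per hairpin, so IDs stay parseable) and feature
drop-out; the reference file carries the last group with full IDs — the
arrangement that makes the sole-expressed-arm rule exercise both its
success and failure modes.

# Reproducibility and interfaces

Every stochastic step flows through a single configured seed; identical
configuration and seed reproduce fixtures and reports bit for bit (tested).
Stage outputs are tab-separated tables plus JSON for the detection
partition, harmonization log, consensus sets and the final report; the
report contains only numbers re-derivable from the emitted tables plus a
provenance block. Configuration serializes to JSON (no YAML parser exists
in the supported dependency set). The CLI (`inst/exec/mirland`) maps error
classes to exit codes: 2 configuration, 3 data/format, 4 statistical
degeneracy.

# Known limitations

* PCA variance percentages are not comparable to shrinkage-transform
  results; treat published values as qualitative references.
* Published detection-Venn and DE counts are engine- and rule-sensitive;
  `detection_benchmark()` reports agreement per rule instead of asserting
  a single number.
* The far-tail family-wise behavior of small-sample NB Wald testing is
  inherently inexact (see the differential-expression section).
* Group labels containing `-` would confuse post-hoc pair parsing in the
  group-statistics report tables.
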