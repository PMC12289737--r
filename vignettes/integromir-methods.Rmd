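---
title: "Methods: joint miRNA/mRNA differential expression and integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint miRNA/mRNA differential expression and integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(integromir)
```

# Scope

`integromir` implements a complete analysis chain for two-group studies
that profile miRNAs on qPCR Ct arrays and mRNAs on microarrays from the
same samples: per-platform differential expression, gene-set
over-representation against an expressed-gene background, integration of
the two layers through predicted miRNA targets and a directed regulatory
graph, and qPCR validation. A synthetic-data generator with known ground
truth makes every stage testable end to end. This vignette records the
statistical model behind each stage, the parameters that matter, the
numerical choices, and the known limitations.

# The Ct-array model

A Ct value is the PCR cycle at which fluorescence crosses the detection
threshold; each additional template doubling saves one cycle, so **lower
Ct means higher abundance**. The package enforces one convention
throughout: a negative case-minus-control Ct difference is upregulation.

Processing order in `run_mirna_pipeline()`:

1. censor Ct > 35 to the ceiling 40 ("Undetermined");
2. remove miRNAs Undetermined in 4 or more of the samples (counted over
   all samples of both groups, per the two-pass filter convention);
3. quantile-normalize the full matrix, **ceiling values included**;
4. re-censor Ct > 30 to 40 and re-apply the 4-or-more filter;
5. per-miRNA equal-variance Student's t-test on the normalized Ct
   values, Benjamini–Hochberg adjustment;
6. relative quantification RQ = 2^−ΔΔCt with
   ΔΔCt = mean Ct(case) − mean Ct(control), so log2(RQ) = −ΔΔCt exactly;
7. a miRNA is called when adjusted p ≤ 0.05 and RQ > 2 **or** RQ < 1/2.

Design choices worth making explicit:

* Censored values participate in normalization and testing: the stated
  order of operations (normalize, then re-censor) implies the censored
  matrix is normalized as-is. An alternative — excluding censored cells —
  would require a missing-data-aware normalization that the two-pass
  design does not call for.
* The t-test is the equal-variance two-sample form. With three samples
  per group a Welch correction is too unstable to be useful.
* The fold-change rule is two-sided: a single threshold of 2 captures
  both up- (RQ > 2) and downregulated (RQ < 0.5) miRNAs.
* ΔΔCt is computed from globally normalized Ct values with no endogenous
  control gene, since quantile normalization already aligns the sample
  distributions; endogenous controls are used only in the qPCR
  validation module, where no global normalization exists.
* Features whose pooled variance is exactly zero (typically all-censored
  rows) receive an `NA` p-value and are never callable.

# Quantile normalization and ties

`quantile_normalize()` replaces each value by the reference value at its
within-column rank, the reference being the across-column mean of sorted
columns. Tied values receive the **mean of the reference values spanned
by their tied ranks**, which treats tied cells symmetrically. The cost
of this rule is that exact idempotence and exact distribution equality
hold only up to tie blocks: columns with different numbers of ceiling
values (different tie-block sizes) change slightly under a second pass.
On tie-free matrices the operation is idempotent to machine precision,
and in the pipeline the affected top ranks are immediately re-censored
to 40, so downstream results do not depend on this choice.

# The microarray model

`fit_moderated_t()` follows the standard empirical-Bayes variance-
shrinkage construction. After the detection-flag filter (present or
marginal in at least one sample), the coefficient-of-variation filter
(CV = sd/mean of *linear-scale* intensities < 50% in both conditions —
CV of log values is not a meaningful quantity), and quantile
normalization:

* per gene g: log2FC_g = mean(case) − mean(ctrl) and pooled variance
  s²_g on d = n₁ + n₂ − 2 degrees of freedom;
* the prior (d₀, s₀²) is estimated by closed-form moment matching on
  z_g = log s²_g: under a scaled-F model E[z] and Var[z] are digamma/
  trigamma expressions in (d₀, s₀²), solved with a Newton inversion of
  the trigamma function;
* the posterior variance is the degrees-of-freedom-weighted average
  s̃²_g = (d₀ s₀² + d s²_g)/(d₀ + d), so each moderated variance lies
  between the gene's own variance and the prior;
* t̃_g = log2FC_g / (s̃_g √(1/n₁ + 1/n₂)) is referred to a t
  distribution with d₀ + d degrees of freedom.

`d0_override = 0` recovers the ordinary pooled t-test; `d0_override =
Inf` pools all genes to the common prior variance. If the moment
estimator fails (e.g. all variances equal), the fit falls back to
d₀ = 0 with a warning. The test suite cross-checks the hyperparameters
and p-values against the independent `limma` implementation to 1e-8.

A gene is called when adjusted p < 0.05 and the linear fold change
2^|log2FC| ≥ 1.5 (inclusive threshold). The expressed-gene background
for enrichment (`build_background()`) keeps genes whose mean normalized
expression is at or above the 10th percentile; ties at the cutoff are
retained, so a constant matrix keeps every gene.

# Over-representation

`hypergeom_overrep()` computes the upper-tail hypergeometric probability
of observing at least k query genes inside a set of size K in a
background of N genes with a query of size n, i.e.
p = Σ_{i≥k} C(K,i) C(N−K, n−i) / C(N,n). Query and set are intersected
with the background before counting — the test is only meaningful over
the universe of genes that could have been detected. Odds ratios are the
cross-product ratio of the 2×2 overlap table, with the Haldane–Anscombe
0.5 correction added to every cell when any cell is zero. Only
over-representation is tested (one-sided); BH adjustment is applied
within each collection, mirroring per-resource reporting.

# Integration

`inverse_overlap()` operationalizes the repression model: targets of
upregulated miRNAs are intersected with downregulated genes and vice
versa, each overlap tested hypergeometrically against the expressed-gene
background.

`find_relations()` searches a typed directed graph (miRNA, gene,
regulator nodes). "Shortest path" mode accepts only a direct
miRNA → gene edge; "shortest path plus one node" mode accepts the pair's
shortest directed path when its length is at most 2 (one intervening
node). Semantics fixed here, where several readings were possible:

* relations are unique per (miRNA, gene) pair — parallel routes collapse
  to one record, with the lexicographically smallest intermediate kept;
* edge direction is always respected; a regulator → miRNA edge is never
  traversed outward from the miRNA;
* output is sorted by miRNA then gene id, so results are independent of
  node insertion order.

`direction_table()` cross-tabulates relations by direction pair, and
`chi_square_2x2()` tests independence with 1 df. The Yates continuity
correction is on by default — appropriate for the 2×2 table — using
c = min(0.5, |O − E|) per cell so the corrected statistic cannot go
negative (all four |O − E| are equal in a 2×2 table, so this matches
the textbook formula whenever |O − E| ≥ 0.5). The uncorrected statistic
equals the closed form (ad − bc)²N/(r₁r₂c₁c₂), which the tests verify on
random tables.

# qPCR validation

`delta_delta_ct()` computes per-replicate ΔCt = Ct(target) −
Ct(reference), subtracts the mean control ΔCt, and reports RQ = 2^−ΔΔCt
per replicate with group means ± SEM. The group comparison is a
two-sided equal-variance t-test **on the ΔCt values**, not on RQ: ΔCt is
the log-scale, approximately variance-stabilized quantity, while RQ is
log-normal. Technical replicates of pooled RNA are the testing unit;
with pooled samples no biological-replicate inference is possible, which
is a stated limitation, not a software choice. Reference genes are
user-specified (e.g. L41 for mRNA, RNU19 for miRNA); no automatic
selection is attempted. `platform_concordance()` reports the Pearson
correlation of paired log2 fold changes with the usual t-transform
p-value, plus the sign-agreement fraction.

# The synthetic-data generator

`sim_config()` fixes the simulated study: a 3-vs-3 two-group design
profiled on both platforms. Defaults, chosen once as a realistic small
rodent-brain study:

| parameter | default | rationale |
|---|---|---|
| `n_mirnas`, `n_genes` | 300, 2000 | small Ct array; desk-scale gene panel |
| `n_per_group` | 3 | the study design being emulated |
| `baseline_ct_range` | 18–30 Ct | range of reliably detected assays; the >30 re-censor rule implies informative miRNAs sit below 30 |
| `noise_sd_ct` | 0.3 cycles | typical qPCR replicate scatter |
| `effect_ct` | −2 cycles | a fourfold planted change |
| `baseline_log2_range` | 6–14 | typical microarray log2 intensity span |
| `noise_sd_log2` | 0.25 | within-group array noise |
| `effect_log2fc` | 1 | a twofold planted change |
| `detect_limit_ct` | 35 | values above are Undetermined (stored as 40) |
| `flag_absent_quantile` | 0.1 | bottom decile flagged absent |
| `target_map_density` | 0.02 | background miRNA–target rate |
| `p_target_true` | 0.9 | planted inverse-targeting rate |
| `n_intermediates` | 20 | regulator nodes enabling length-2 paths |

Half of each planted set moves in each direction, so both up- and
downregulated features exist under one effect magnitude. One seed
governs the whole study; each simulator derives a fixed per-component
sub-stream from it, so any component can be regenerated independently
and reproducibly.

What the generator does **not** emulate: probe-level array artifacts,
pre-amplification chemistry, batch effects, inter-plate calibration,
correlated co-expression structure, or missing-at-random dropouts
(the Undetermined mechanism is a deterministic detection limit applied
to the noisy Ct, mirroring qPCR chemistry). Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to every artifact of real arrays.

# Statistical power at the recovery design

A useful calibration point for the generator's default effect sizes:
with a two-cycle shift, 0.3 cycles of noise and 3 samples per group, the
per-miRNA noncentrality is 2/(0.3·√(2/3)) ≈ 8.2 on 4 degrees of
freedom. Because the 4-df t distribution has heavy tails, the pooled-sd
estimate fluctuates strongly, and the self-consistent BH fixed point for
20 planted of 300 features at q = 0.05 sits near 78% sensitivity — an
intrinsic ceiling of the design, not of the implementation (a direct
simulation of the bare t-test without any censoring or normalization
reproduces it). The acceptance checks report the measured recovery;
readers should expect values near this ceiling rather than near 100%.

# Problem sizes and determinism in the checks

The shipped tests and the acceptance script use desk-scale sizes chosen
as representative while keeping full runs fast: 300–500 features and 20
seeds for calibration and recovery averages, 2000-gene studies for
integration, 50 seeds of 16 genes for concordance, exhaustive oracle
sweeps up to N = 30 for the hypergeometric tail and n = 8 for
clustering. All randomness flows from explicit seeds; identical seeds
reproduce every table byte-identically.

# Known limitations

* Probe→gene collapsing is out of scope; features are treated as genes.
* The CV filter needs positive linear means; features violating this are
  removed and logged rather than imputed.
* The knowledge-graph search is exact only for paths of length ≤ 2 by
  design; longer regulatory cascades are not enumerated.
* With ceiling-value ties, quantile normalization is idempotent only up
  to tie blocks (see above).
* Enrichment p-values are discrete; at small set sizes the achievable
  levels step below the nominal threshold, making the test conservative.
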