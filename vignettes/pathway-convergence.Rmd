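---
title: "Cross-omics pathway convergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-omics pathway convergence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathconverge)
```

## The question the pipeline answers

Genome-wide association studies implicate loci, not mechanisms. A
complementary line of evidence is the transcriptome of the disease-relevant
cell type: if the pathways that are differentially regulated in, say,
macrophages from unstable atherosclerotic plaques are the same pathways whose
member genes harbour risk variants, that convergence points at a cellular
process through which the variants could act. `pathconverge` implements that
convergence analysis as a tested, seedable pipeline with three arms:

1. an **expression arm**: gene-set enrichment analysis (GSEA) of a
   two-class comparison (e.g. symptomatic vs asymptomatic plaques) or of a
   continuous covariate (e.g. %plaque-lipid from MRI T2 mapping), with
   permutation significance and leading-edge extraction;
2. a **genetic arm**: MAGENTA-style gene-set enrichment of GWAS summary
   statistics — windowed SNP-to-gene assignment, best-SNP gene scores,
   confounder regression, percentile-cutoff enrichment;
3. a **cross-interrogation**: each arm's top significantly enriched pathways
   become a custom "superset" evaluated in the *other* arm (GvsM and MvsG
   directions), and the genes driving both directions are intersected and
   annotated with GWAS-SNP presence.

Because the study data behind such analyses are rarely redistributable, the
package ships a first-class synthetic-data module that generates every input
with planted, recorded ground truth, so the whole pipeline is testable
offline.

## Expression arm

### Ranking metrics

For a two-class phenotype each gene is scored with the signal-to-noise
ratio

$$ s2n = \frac{\mu_1 - \mu_2}{\sigma_1 + \sigma_2}, \qquad
   \sigma_k \leftarrow \max(\sigma_k,\; 0.2\,|\mu_k|,\; 0.2), $$

the classic GSEA metric with its variance floor; the floor keeps
near-constant genes from dominating the ranking through a vanishing
denominator. The floor constants (20% of the mean, absolute minimum 0.2)
follow the metric's established convention and are not configurable — a gene
that needs them is by definition carrying almost no usable signal. For a
continuous phenotype the metric is the Pearson correlation of each gene with
the covariate. Ranked lists are sorted non-increasing with ties broken by
gene identifier, so a ranking is a pure function of its inputs.

### The running-sum enrichment score

Walking down the ranked list of $N$ genes, a member ("hit") of a set $S$
(with $s = |S|$) increments the running sum by $|r_i|^\alpha / \sum_{j \in S}
|r_j|^\alpha$ and a non-member decrements it by $1/(N-s)$. The enrichment
score (ES) is the signed deviation of maximal absolute value; $\alpha = 1$
(the default) is weighted GSEA, $\alpha = 0$ the classic Kolmogorov–Smirnov
statistic. Two numerical conventions are fixed here:

* a tie between equal positive and negative extremes resolves to the
  **positive** score, and the comparison carries a $10^{-12}$ tolerance —
  the positive and negative branches accumulate rounding differently, and
  without the tolerance a mathematically exact tie can flip sign depending
  on summation order (we hit this in exhaustive small-case enumeration);
* if all hit weights are zero (possible for $\alpha > 0$ on a degenerate
  metric), hits fall back to uniform weight $1/s$, i.e. the unweighted
  statistic.

The engine evaluates the running sum only at hit positions (its extrema can
occur nowhere else), in a small C++ kernel; `enrichment_score()` additionally
returns the full running-sum vector for plotting. The test suite checks the
kernel against an independent, literal element-by-element walk over every
ranked list of length ≤ 12 and every member subset of size ≤ 4, across 100
random metric draws, and against `fgsea::calcGseaStat()` on random fixtures.

### Permutations, NES, FDR

Significance comes from a permutation null. Two modes exist:

* **phenotype** permutation (default for binary designs with ≥ 7 samples
  per class): class labels are reassigned at random and the *entire* ranking
  is recomputed, which preserves inter-gene correlation;
* **gene-set** permutation (default for continuous phenotypes and small
  classes): random member sets of equal size are scored against the observed
  ranking.

Per set, the nominal p-value is the same-sign tail fraction of null scores
with an add-one correction (so $p \in (0,1]$ and 1000 permutations can never
report $p = 0$), and the normalized enrichment score (NES) divides the
observed ES by the mean |null ES| of the same sign. The FDR q-value follows
the GSEA procedure — the pooled, per-set-normalized null compared against
the observed NES distribution, computed separately for each sign — and is
made monotone non-increasing in |NES| within each sign by a running maximum,
preventing q-value inversions. A set is called *significant* at the
conventional regime p < 0.05 and FDR < 0.25, *highly significant* at
p < 0.01 and FDR < 0.25.

The leading edge of a positively enriched set is its members at ranks up to
the running-sum peak; for negative scores, the members at or beyond the
peak. For negative scores the minimum is attained just before a hit, and the
reported peak rank is that hit's rank, so the trailing block of members is
exactly "ranks ≥ peak". `leading_edge_matrix()` assembles the binary
gene-by-pathway occurrence matrix over significant sets, ordered by
average-linkage clustering on Jaccard distance — the standard heat-map view
of a leading-edge analysis.

## Genetic arm

Each gene's assignment region extends 110 kb upstream and 40 kb downstream
of its span (flipped on the minus strand), the cited method's defaults;
containment is evaluated on 0-based half-open intervals via
`GenomicRanges::findOverlaps()`, and a SNP inside several overlapping
regions counts for every one of them. A gene with at least one assigned SNP
scores $-\log_{10}(\min p)$; genes without SNPs are absent rather than
imputed, matching best-SNP semantics. Raw scores are regressed (OLS with
intercept) on gene span, SNP count and SNP density, and the residual is the
corrected score; constant or collinear confounders are dropped with a
warning, and residual orthogonality to every retained confounder is a tested
invariant (tolerance $10^{-8}$). The original method's LD-derived
confounders (independent SNP count, recombination hotspots) are *omitted*:
summary-statistic input carries no LD information. This is a documented
limitation, not an approximation we can bound.

Enrichment of a set is the count of members strictly above the 75th
percentile of all corrected scores, compared against the count distribution
of equal-size random gene sets drawn without replacement from the scored
genes (add-one corrected). Because above-cutoff membership is binary, that
null is hypergeometric, and the exact tail is computed alongside as a
permanent cross-check; the sampling route is kept as the primary statistic
so the machinery generalizes to score-dependent statistics. The 75th
percentile is the method's polygenic default; 95 is available via
`magenta_params()` and is considerably more powerful when few, strong
signals concentrate in small sets (see Limitations). Benjamini–Hochberg
FDR is applied across sets.

## Cross-interrogation

The GvsM direction takes the top `top_k_gsea` (default 200, the study
configuration) *significantly* enriched, positively scoring expression
pathways as a custom collection and evaluates it in the genetic arm; MvsG
takes the top `top_k_magenta` (default 30) GWAS-enriched pathways — gated on
nominal enrichment p < 0.05, the genetic method's native significance label
— and evaluates them in the expression arm. Both directions then apply the
p < 0.05 AND FDR < 0.25 regime *within the superset* to flag cross-enriched
pathways; conditioning the FDR on the superset matches the phrasing "k of
these pathways cross-enriched". An arm with no significant pathway yields an
empty superset and a skipped direction, so fully null inputs produce an
empty report rather than an error.

The overlap genes are the intersection of two pooled unions: the leading
edges of cross-enriched MvsG pathways, and — because the genetic method has
no native leading-edge concept — the members of cross-enriched GvsM pathways
with corrected score strictly above the enrichment cutoff, the direct
analogue of "genes driving the signal". Pooling across pathways (rather than
per-pathway-pair intersection) is the reading consistent with reported
overlap counts; it is an interpretation, and the report flags each gene's
per-direction memberships so a per-pair view can be reconstructed. Each
overlap gene is annotated with differential-expression $-\log_{10}(p)$, both
direction flags and a GWAS-SNP presence flag (same windows as the genetic
arm; genes without coordinates serialize as "." — distinct from FALSE).
Report rows order deterministically: SNP-bearing genes first, then by
descending DE signal, ties by gene id.

## The synthetic-data generator

`sim_config()` declares the study conditions; the defaults are the
conditions the pipeline is tested under, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_samples_per_class` | 12 | the study scale (12 vs 12 plaques) |
| `n_genes`, `n_sets` | 2000, 200 | desk-scale collection with realistic set-size overlap |
| `set_size_range` | 20–100 | typical curated-pathway sizes, inside the 15/500 GSEA filter |
| planted sets | 3 expression, 2 GWAS, 1 convergent | the minimal convergence topology |
| `expression_effect` | 1.0 (× noise sd) | a coordinated one-sd module shift, detectable but not trivial at n = 12 vs 12 |
| `continuous_covariate_coupling` | 0.8 | a strong but noisy module–covariate link |
| `n_snps` | 5000 | genome-wide-like null density: about one SNP per default window |
| `gwas_signal_fraction`, p scale | 0.3, 1e-6 | roughly a third of a risk pathway's genes carry a typed low-p variant |
| `gene_length_kb`, gap | 5–50, 400 | variable spans (non-degenerate confounders); adjacent default windows stay disjoint |

Expression is generated on a log-like additive scale (Gaussian noise around
a baseline); genes of planted sets are shifted by `expression_effect ×
noise_sd` in class 1 only, once per gene even when sets overlap. The
continuous covariate couples to the standardized mean of one designated
planted module. GWAS data are n null SNPs placed uniformly with p ~ U(0,1),
plus one signal SNP with p ~ U(0, scale) inside the gene body of each
planted-set gene selected with probability `gwas_signal_fraction`; the genes
actually given a signal are recorded in the ground truth, which is
audit-consistent with the generated records by construction (and by test).

What the generator deliberately does **not** emulate: bead-level microarray
intensity physics (the analysis consumes normalized values; the
preprocessing floor/clip path is still exercised via the baseline offset),
LD structure and allele frequencies (summary p-values only), probe-level
redundancy beyond the explicit `collapse_probes()` path, and biological
correlation structure beyond the planted modules. Passing tests therefore
demonstrate the *statistical machinery* — calibration under the null, power
against planted coordinated signal, determinism — not performance on real
chips or real LD patterns.

## Numerical choices

* Quantile normalization maps every column onto the row-means of the
  column-sorted matrix via `order()`; exact multiset equality and
  idempotence are tested, and agreement with `limma::normalizeQuantiles()`
  is checked on tie-free fixtures.
* Welch's unequal-variance t-test is used for differential expression (the
  robust default at n = 12 vs 12); fold change is computed on the linear
  scale with class means floored at 1.0 to avoid division blow-ups, and the
  selection rule (fold change > 1.5 in either direction AND p < 0.05) is
  strict at both boundaries. No multiple-testing correction is applied to
  the per-gene list — error control happens at the gene-set level.
* Preprocessing defaults (floor 20, ceiling 20 000, min fold 3, min delta
  100) are the referenced preprocessing module's documented defaults; all
  overridable.
* Permutation p-values carry an add-one correction; FDR q-values are
  clamped to [0, 1] and monotonized within sign.
* All randomness flows through R's RNG under explicit seeds (the C++
  samplers use `unif_rand()`), so every pipeline output is a pure function
  of (inputs, seed); CLI reruns are byte-identical, which the suite checks
  by digest.

## Problem sizes used by the test suite

The suite exercises: exhaustive ES enumeration (lists ≤ 12, subsets ≤ 4,
100 metric draws); null calibration on a 5000-gene, 12 vs 12, 500-set study
at 1000 permutations; power on 20 replicates of 50-set studies with three
planted sets; the N = 100 / K = 25 / n = 8 hypergeometric fixture at 50 000
null draws; and 20 + 20 end-to-end convergence runs (planted and fully
null) at the default configuration. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that stays
pleasant to run.

## Known limitations

* **Per-seed overlap sensitivity.** The leading edge of a truly enriched
  set captures on average ~85% of its planted genes — members whose noisy
  metric falls below the running-sum peak are excluded by definition. A
  per-seed demand of ≥ 80% planted-gene recovery in the overlap list
  therefore fails in a minority of seeds even though aggregate sensitivity
  exceeds 80%; this is intrinsic to peak-truncated leading edges, not a
  defect of the implementation.
* **75th-percentile power.** For small sets whose signal is a handful of
  very strong genes, the 75th-percentile cutoff dilutes the count statistic
  with the 25% base rate of null members; such sets can reach nominal
  p ≈ 0.02 yet fail a within-superset FDR gate. The 95th-percentile cutoff
  (config) is the right tool for that regime.
* **Label-swap p-invariance is approximate.** Swapping class labels negates
  every s2n value and every ES exactly (tested), but the same-sign
  permutation p-value is exactly invariant only under a sign-symmetric
  null; with a finite permutation sample the p-values agree approximately.
* **No LD, no genotypes.** The genetic arm treats every SNP as independent
  evidence; with real summary statistics, clustered SNPs inflate per-gene
  evidence in ways the confounder regression can only partially absorb.
* Gene identifiers are matched as exact case-sensitive strings throughout;
  no aliasing or annotation services are provided.
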