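---
title: "Modelling non-additive transcriptional responses to paired perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-additive transcriptional responses to paired perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyseq)
```

## The question the package answers

When a cell receives two perturbations at once — here, canonically, siRNA
knockdown of the melanocytic master regulator MITF (driving
dedifferentiation) together with IFN&gamma; stimulation — a gene's combined
response need not be the sum of its responses to each perturbation alone.
Genes whose combined log2 fold-change exceeds the additive expectation show
*positive synergism*; genes falling short show *antagonism*. PD-L1 (CD274)
induction is the motivating example: dedifferentiated melanoma cells can
show disproportionately strong IFN&gamma;-driven induction of
immune-regulatory genes.

`synergyseq` implements the full quantitative path from a replicated 2×2
factorial count matrix to directional non-additive calls, and from a paired
±cytokine expression cohort to marker-based strata, with a synthetic-data
generator providing ground truth for every stage.

## The interaction model

For gene $g$ and sample $j$ with size factor $s_j$, counts are modelled as
negative binomial:

$$K_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\ \alpha_g\right),
\qquad
\log_2 \mu_{gj} = \beta_0 + \beta_A x_A + \beta_B x_B
 + \beta_{AB}\, x_A x_B + \log_2 s_j,$$

with variance $\mu + \alpha \mu^2$. $x_A$ indicates the knockdown, $x_B$
the cytokine. Because the design is a saturated 2×2, the full model's MLE
reduces to four independent condition-mean problems, each solved by Newton
iteration on the NB score equation; the reduced model (no $\beta_{AB}$) is
fitted by IRLS (at most 100 iterations, tolerance $10^{-8}$ on the
coefficient change; non-convergence is flagged, never fatal). The
interaction is tested by the likelihood ratio
$\Lambda = 2(\ell_{\text{full}} - \ell_{\text{reduced}})$.

Three contrasts are reported on log2 scale: the single-factor fold-changes
`lfc_A` $=\beta_A$ and `lfc_B` $=\beta_B$, and the combined `lfc_AB`
$=\beta_A + \beta_B + \beta_{AB}$ — an exact decomposition, so the
non-additive effect
$\delta = \mathrm{lfc}_{AB} - (\mathrm{lfc}_A + \mathrm{lfc}_B)$ equals
$\beta_{AB}$ by construction.

### Dispersion and the reference distribution

Per-gene dispersion is estimated by maximizing the Cox–Reid adjusted
profile likelihood of the saturated model (a method-of-moments estimate
seeds the search interval). The adjustment subtracts
$\tfrac12 \log\det(X^\top W X)$ and compensates the downward bias of plain
ML when four means are estimated from three replicates each; without it the
interaction test is markedly anticonservative.

Even with unbiased dispersions, the asymptotic $\chi^2_1$ reference ignores
the uncertainty of $\hat\alpha_g$ at small $n$. The package therefore
refers $\Lambda$ to $F(1,\ n - 4)$ by default, the usual small-sample
correction when a scale-like parameter is estimated from $n - 4$ residual
degrees of freedom. With three replicates per condition this puts the
empirical type-I error near the nominal 0.05 (the acceptance suite measures
it on 2,000 simulated additive genes), where the $\chi^2$ reference sits
slightly above 0.07. `lrt_ref = "chisq"` restores the asymptotic reference;
designs with a single replicate per condition fall back to it automatically
because $F$ with zero denominator degrees of freedom is undefined.

This transparent engine is deliberately simpler than production DE tools:
no dispersion-trend shrinkage, no outlier replacement, no independent
filtering. Results on real data will therefore differ gene-by-gene from
those tools; what is preserved — and tested — is the closed-form behaviour
of the estimates and the calibration of the interaction test.

## From fits to non-additive calls

The classifier applies the joint rule

* interaction significance: BH-adjusted LRT $p < 0.05$ (strict), and
* substantial effect: $|\delta| > 1$ log2 unit (strict, so a gene at
  exactly 1.0 is excluded),

then assigns each non-additive gene an *emergence category* from its
single-factor responder status (BH-adjusted contrast $p < 0.05$):
`from_neither`, `from_A_only`, `from_B_only`, `from_both`. The categories
are disjoint and partition the non-additive set, so their counts always sum
to the total. Direction is the sign of $\delta$: `positive_synergism`
above the additive expectation, `antagonism` below. Finer sub-taxonomies
(e.g. antagonism relative to each single effect) can be layered on the
exported (expected, observed) pairs from `expected_vs_observed()`; the
package itself implements only the sign rule it needs.

Upstream of the classifier, `response_gene_filter()` keeps significant
genes with max expression ≥ 2 TPM in at least one sample and at least one
contrast with $|\mathrm{lfc}| \ge 1$. Classification is restricted to this
retained set by default (`classify_all(fits, retained)`); passing
`retained = NULL` classifies every fitted gene.

## Enrichment

`rank_genes()` scores genes by signal-to-noise
$(\mu_1 - \mu_2)/(\sigma_1 + \sigma_2)$ with each group SD floored at
$\max(\sigma,\ 0.2|\mu|,\ 0.2)$; ties are broken lexicographically by gene
id so rankings are deterministic. `enrichment_score()` walks the ranked
list with weight exponent 1 (hit increments $\propto |s|$, miss decrements
$1/(N - N_{hit})$) and returns the signed maximal deviation.
`gsea_permutation()` builds the null from random gene sets of equal size
(*gene-set* permutation, not phenotype permutation), uses +1-smoothed
one-sided p-values within the sign stratum, normalizes ES by the mean
same-sign null magnitude, and reports a sign-stratified ratio FDR
(null tail fraction over observed tail fraction at each $|NES|$, clamped to
$[0,1]$) — a documented, deterministic simplification of the historical
procedure. Leading edges are the pre-peak (or post-peak, for negative ES)
members; `core_genes()` collects genes present in ≥ 3 leading edges by
default.

Annotation-style overlap enrichment (`overlap_enrichment()`) uses the upper
hypergeometric tail with BH adjustment across the collection. The hosted
annotation tools this emulates describe their p-values only loosely; the
hypergeometric form is this package's documented choice, not a claim about
any external tool's internals.

## Cohort stratification

The cohort path mirrors a standard public-data re-analysis: exclude
engineered or off-treatment lines (`filter_wildtype()`), convert FPKM to
TPM per sample ($TPM_i = FPKM_i / \sum_j FPKM_j \times 10^6$), drop genes
below 3 TPM in every line, transform to $\log_2(TPM+1)$, and z-score genes
(sample SD, divisor $n-1$ — the convention of the statistical environments
these analyses are usually run in; constant genes become zero rows and are
flagged). Z-scores are recomputed after every subsetting step rather than
inherited.

Per-line response scores are means of $\log_2(TPM+1)$ over a signature set.
`rank_and_split()` fixes two conventions the printed group sizes force:
halves assign the median line to the *lower* group for odd $n$ (45 lines →
22 upper / 23 lower), and quartile groups take $\lceil n/4 \rceil$ lines
(45 → 12 per extreme). The PD-L1 high/low cut within the marker-low
quartile has no published rule; the default cuts at the largest adjacent
gap in the sorted induction values, with explicit `threshold` and `median`
overrides, and the realized cut is always returned.

Associations use average-rank Spearman correlation (two-sided, asymptotic
t approximation under ties), simple linear regression, Mann–Whitney U,
Kruskal–Wallis with hand-rolled Dunn post-hoc z tests (BH-adjusted — the
adjustment method for post-hoc p-values is this package's documented
choice), and paired Wilcoxon. Correlation matrices order columns by
average-linkage clustering on $1 - r$ and adjust the $k(k-1)/2$ distinct
pairs by Bonferroni or BH. PCA centres (but does not rescale) the top
2,000 genes by mean expression and fixes component signs by making the
first nonzero loading positive.

## The synthetic generator

`simulate_factorial()` draws counts from the same NB parameterization the
fitter assumes, with per-gene baselines log-uniform on a configurable
interval, size factors log-uniform on $[0.7, 1.4]$ (all-equal factors would
leave normalization untested), and genes partitioned into eight
ground-truth classes (null; single main effects; both effects additive;
four non-additive classes by accompanying main effects). Effect magnitudes
are fixed at the configured sizes with Bernoulli(1/2) signs recorded in the
truth table — the classifier must handle both directions. Defaults are 3
replicates per condition, main and interaction effects of 2 log2 units,
dispersion 0.05, and a 60% null fraction; the study's own data provide no
dispersion estimates, so defaults are chosen for testability rather than
fitted realism.

`simulate_cohort()` generates a 58-line panel on TPM scale (columns
renormalized to $10^6$ so the unit invariant is testable end-to-end): 45
wild-type cytokine-treated lines plus 9 engineered and 4 off-treatment
lines to exercise the filter. Each line's latent dedifferentiation
$u \in [0,1]$ suppresses a MITF-like marker (up to 6 log2 units at full
coupling), amplifies induction of a 20-gene ISG panel, and increases
induced PD-L1-like expression (up to 3 log2 units), all with Gaussian
log2-scale noise (SD 0.2 by default).

What the generator does *not* emulate: gene–gene correlation, count-level
sampling noise in the cohort (abundances are drawn directly on TPM scale),
library-preparation artefacts, batch structure, and single-cell
heterogeneity. Passing tests demonstrate that the algorithms are correct
under their stated models — not that the models capture every property of
real sequencing data.

## Problem sizes and determinism

The test and acceptance suites run at desk scale: 2,000 null genes for
type-I calibration, 2,400 genes across eight planted classes for recovery,
up to 1,000 Monte-Carlo replicates per condition for moment checks, 99–100
permutations per enrichment calibration toy, and 58-line cohorts. Every
stochastic stage takes an explicit integer seed and restores the caller's
RNG state; identical seeds give byte-identical outputs, which the pipeline
manifests (config, seeds, input and output checksums) make checkable.

## Known limitations

* The engine targets balanced or mildly unbalanced 2×2 designs only; no
  continuous covariates, batch terms, or >2 factors.
* Per-gene dispersion without information sharing is noisy below ~3
  replicates; the F reference compensates for the test's size but not for
  the fold-change estimates' variance (no shrinkage estimator is provided).
* Fold-changes for conditions with all-zero counts are reported missing
  (no pseudocounts are injected into the likelihood).
* The FDR of the permutation test is a simplified ratio estimate; for few
  sets it is coarse and can be conservative.
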