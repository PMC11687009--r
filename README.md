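# synergyseq

Quantitative analysis of **non-additive transcriptional responses to paired
perturbations** in bulk RNA-seq, built around the canonical melanoma
setting: siRNA knockdown of the differentiation master regulator **MITF**
crossed with **IFNγ** stimulation in a replicated 2×2 factorial design, and
the downstream question of how dedifferentiation conditions
cytokine-induced expression of immune-regulatory genes such as PD-L1
(*CD274*).

The package is for computational biologists who have (or want to simulate)
a gene-by-sample count matrix from a two-factor experiment and need to
know, per gene, whether the combined response differs from the sum of the
single-factor responses — and, for cohort data, how marker-defined strata
(e.g. MITF-high vs MITF-low cell lines) differ in their induced responses.

## The model

Counts follow a negative-binomial GLM with a log2 link and size-factor
offset:

```
K_gj ~ NB(mu_gj, alpha_g),   log2 mu_gj = b0 + bA·xA + bB·xB + bAB·xA·xB + log2 s_j
```

with variance `mu + alpha·mu^2`. The interaction coefficient `bAB` is
tested by a likelihood-ratio test of the full versus no-interaction model
(per-gene Cox–Reid adjusted profile-likelihood dispersions; `F(1, n-4)`
reference by default for small-sample calibration). Because the combined
contrast decomposes exactly as `lfc_AB = bA + bB + bAB`, the non-additive
effect `delta = lfc_AB − (lfc_A + lfc_B)` equals `bAB`. A gene is called
**non-additive** when its BH-adjusted interaction p < 0.05 and |delta| > 1
log2 unit; it is then assigned an emergence category (`from_neither`,
`from_A_only`, `from_B_only`, `from_both`, by single-factor responder
status) and a direction (`positive_synergism` if delta > 0, `antagonism`
otherwise).

Around this core: median-of-ratios size factors, FPKM→TPM conversion and
expression filters, weighted running-sum gene-set enrichment with a
gene-set permutation null and leading-edge core-gene extraction, and
marker-based cohort stratification (22/23 halves and 12-line quartiles for
a 45-line panel) with rank-based association statistics. A synthetic-data
generator with recorded ground truth backs every stage.

## Worked example

Simulate a factorial experiment with planted effect classes, fit the
interaction model and classify:

```r
library(synergyseq)

cfg  <- sim_factorial_config(n_genes = 500, seed = 7)
sim  <- simulate_factorial(cfg)          # counts + design + truth table
sf   <- estimate_size_factors(sim$counts)
disp <- estimate_dispersion(sim$counts, sim$design, sf)
fits <- fit_interaction(sim$counts, sim$design, sf, disp)

tpm <- sweep(sim$counts, 2, colSums(sim$counts), "/") * 1e6
attr(tpm, "unit") <- "TPM"
retained <- response_gene_filter(fits, tpm)   # >=2 TPM and >=1 log2 FC
res <- classify_all(fits, retained)
res$summary
#> from_neither  from_A_only  from_B_only    from_both        total
#>           14           10           11           14           49
```

49 genes are called non-additive; the four emergence categories partition
them (14 + 10 + 11 + 14 = 49). Per-gene calls carry the effect size and
direction:

```r
head(subset(res$calls, is_nonadditive), 3)
#>      gene responder_A responder_B delta padj_interaction     category          direction
#> 8  G00016        TRUE        TRUE  1.98          0.00609    from_both positive_synergism
#> 9  G00020       FALSE       FALSE -2.00          0.01429 from_neither         antagonism
#> 20 G00053       FALSE       FALSE -1.94          0.03996 from_neither         antagonism
```

`G00016` responds to both single factors but its combined response sits
~2 log2 units above the additive expectation — positive synergism emerging
from dual responders. The truth table (`sim$truth`) lets you score the
calls; `run_factorial_pipeline()` and `run_cohort_pipeline()` chain all
stages and write TSV/JSON artifacts with a reproducibility manifest, and
`inst/cli/synergyseq.R` exposes both drivers from the shell.

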