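# myoaging

Statistical framework for single-cell / single-nucleus analysis of
skeletal muscle aging, implemented as a tested R package plus a numbered
analysis workflow — and exercised entirely on synthetic data with known
ground truth.

Aging atlases of human muscle ask a recurring set of statistical
questions: *does a cell type's abundance change with age?* (a
hierarchical Poisson mixed model over cell counts per 10x library),
*which genes change with age in each cell type?* (per-gene Bayesian
negative binomial mixed models with donor random effects), *what fiber
type is each myonucleus?* (MYH7/MYH2/MYH1 thresholding), *do human and
mouse aging signatures agree?* (homolog mapping, Jaccard,
over-representation, pathway co-enrichment), plus the supporting
quality-control and ligand–receptor relevance filters. `myoaging`
implements each of these as a package function with its published
decision rules (LTSR > 0.9 significance, > 5% expressed-proportion
filters, the 70%/90% neighborhood labeling rules, strict 0.5 MYH
threshold, > 75%-unclassified donor exclusion), and ships a generator
that simulates the whole cohort structure so every method can be
validated against planted truth.

## The models in brief

**Composition.** Counts `N_cs` of cell type *c* in library *s* follow a
Poisson log-link GLMM:

    N_cs ~ Age + (1|Celltype) + (1|Sample) + (1|Chemistry) + (1|Modality)
         + (Age-1|Celltype) + (Chemistry:Celltype) + (Modality:Celltype)
         + (Sample:Celltype)     [all non-Age terms as random effects]

with age standardized over libraries. Per-cell-type effects are
grand-mean-adjusted log fold changes; significance is the local true
sign rate LTSR = Φ(|μ|/σ), the posterior probability that the sign of
the effect is correct, thresholded at 0.9.

**Differential expression.** Per gene, `y ~ NB(μ, θ)` with
`log μ = β₀ + β_a·age + covariates + log(libsize) + b_donor`,
`b_donor ~ N(0, σ²)`, fitted by an in-package Laplace engine
(`nbglmm_laplace`, millisecond-scale per gene; matches glmmTMB to four
decimals). Evidence for the age term is a Bayes factor against a
N(0,1) slab, and the reported LTSR is the Bayes-factor-moderated sign
probability, so "LTSR > 0.9 and expressed in > 5% of aged cells" works
as a genome-wide rule without further correction.

## Worked example

The `analysis/` scripts run the whole workflow file-to-file
(`Rscript analysis/01_simulate.R` … `07_interactions.R`). The same thing
programmatically:

```r
library(myoaging)

# a 20-donor, 40-library cohort; cell type CT1 gains abundance with age
truth <- composition_truth(age_logfc = c(1, rep(0, 7)))
sim <- simulate_composition(truth, seed = 42)
fit <- fit_composition_glmm(sim$composition, sim$samples)
celltype_age_effects(fit)
#>   cell_type covariate   logfc  log2fc    sd  ltsr significant
#> 1       CT1       age  0.9176  1.3238 0.129 1.000        TRUE
#> 2       CT2       age -0.0767 -0.1107 0.129 0.724       FALSE
#> ...                                  (only the planted type is called)
```

The planted natural-log effect of 1.0 is recovered as 0.92 ± 0.13 with
LTSR 1.0; the seven null cell types sit at LTSR 0.6–0.73, below the 0.9
cutoff. Running `analysis/03_composition.R` and `analysis/04_deg.R` on
the seed-1 cohort prints the planted composition effect recovered as
1.018 ± 0.128 (LTSR 1.000, the only significant type) and the
expression panel recovering 10/10 genes spiked at log2FC 1.5 with 0/190
false calls — e.g. `gene0001: log2FC 1.32, LTSR 1.000, BF 1.0e29`.

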