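# ploidysig

Cross-species extraction of evolutionarily conserved polyploidy-associated
transcriptional signatures.

Somatic polyploidy (endopolyploid hepatocytes, cardiomyocytes, decidua
cells) shifts gene expression only weakly, and any single polyploid-vs-
diploid comparison confounds that shift with much larger tissue and
species effects. `ploidysig` implements the reciprocal cross-species
strategy that separates them: human heart (polyploid) is contrasted with
mouse heart (diploid) and mouse liver (polyploid) with human liver
(diploid), and only genes moving in the same direction in **both**
contrasts are kept, which cancels tissue- and species-specific signal. An
intra-species 4n-vs-2n contrast (sorted decidua-like cells) provides a
third line of evidence.

The package is aimed at computational biologists who want each stage of
this procedure as a tested, reusable function, together with a
synthetic-data generator (planted ground truth included) for validating
the whole chain.

## Methods at a glance

* **Moderated differential expression** — quantile normalization, then a
  two-group empirical-Bayes t-test per contrast:
  `t_g = Δ_g / (s̃_g √(1/n₁+1/n₂))` with posterior variance
  `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀+d_g)`, the prior `(d₀, s₀²)` fitted by
  moment matching of log variances. Genes pass with linear fold change
  ≥ 1.15 (or ≤ 1/1.15) and p < 0.01, and are intersected into three
  direction-concordant tiers (A: heart+liver+decidua, B: heart+liver,
  C: decidua).
* **Ploidy component (PCA)** — full-rank PCA of the conditions'
  correlation matrix; loadings are variable–component correlations, so
  per-component mean squared loading = variance fraction. Components are
  labelled shared / tissue / species / ploidy from loading sign patterns;
  gene scores are standardized, and genes beyond ±2 SD on the ploidy
  component are the induced/suppressed selections.
* **Enrichment** — exact one-sided binomial upper tail
  `P(X ≥ k) = Σ C(n,j)p₀ʲ(1−p₀)ⁿ⁻ʲ` (log-space) for interactome
  over-representation; hypergeometric over-representation of gene modules
  gated at p < 0.01 **and** Storey q < 0.15 simultaneously against two
  backgrounds (all orthologs, all interactants).
* **Network** — interaction graph at stringency > 0.9 over the
  significant genes, clustered with a deterministic MCL implementation
  (expansion 2, inflation 2).

## Worked example

```r
library(ploidysig)

# simulate the reference study conditions and run the whole pipeline
bundle <- run_pipeline(default_pipeline_config(seed = 1))
```

```
[ploidysig] inputs: 5000 genes x 16 samples
[ploidysig] tiers: A 106/105, B 106/105, C 147/146
[ploidysig] network: 10 nodes, 20 edges, 2 cluster(s)
```

5000 ortholog groups were simulated with 125 planted ploidy-induced and
125 ploidy-suppressed genes (log2 effect 1). Tier B recovers 211 genes —
sensitivity 0.84 against the planted truth with no false discoveries.
The PCA stage confirms the design structure:

```r
bundle$pca$cross_species$labels
#>       PC1       PC2       PC3       PC4
#>  "shared"  "tissue" "species"  "ploidy"
round(100 * bundle$pca$cross_species$var_fraction, 1)
#>  PC1  PC2  PC3  PC4
#> 44.7 31.7 14.7  8.8
```

PC4's kurtosis is 12.7 (Gaussian reference: 3), flagging a genuine sparse
signal, and all 125 genes beyond −2 SD are planted up-regulated genes
(precision 1.00). The planted interactome is strongly over-represented in
the tier-B up list:

```r
bundle$enrichment$binomial$tier_B_up
#> 54 of 106 genes are interactants (0.51 vs background 0.22),
#> exact binomial p = 8.2e-11
```

The same stages can be run one at a time with narrated output:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_differential_expression.R
Rscript analysis/03_ploidy_pca.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_network.R
```

writing their tables under `results/`. The methods vignette
(`vignettes/polyploidy-signatures.Rmd`) documents the model, the
parameter calibration and the numerical choices.

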