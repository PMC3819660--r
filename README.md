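# orgflow

Organ-specific transcriptome comparison for replicate-free, de novo
assembled RNA-seq designs: length- and depth-scaled scaffold abundances,
an n-sample trimmed-mean (TMM-style) normalization against a synthetic
reference profile, subcellular partitioning of scaffolds from BLAST hit
tables, common-set correlation and clustering statistics, and fold-class
annotation of metabolic-pathway topologies for substance-flow reading.
It is aimed at plant transcriptomics workflows that compare organs
(petal stages, sepal, leaf) sampled once each on a single plant, where
every organ expresses a private minority of transcripts and classic
pairwise normalizations do not apply directly.

## The method in brief

Counts below 2 are zeroed as fortuitous; the abundance of scaffold *g*
in sample *k* is `Y_gk = c_gk / (L_g * T_k)` (count over length times
cleaned sample total).  The genes expressed in **all** n samples form
the common set G; their mean abundances constitute a virtual reference
sample `Y_g` with total `N`.  For each real sample,

```
M_g = log2( (Y_gk / N_k) / (Y_g / N) )
A_g = 0.5 * log2( (Y_gk / N_k) * (Y_g / N) )
w_g = 1/Y_gk + 1/Y_g
```

M and A are min–max normalized, genes strictly inside the windows
(0.3, 0.7) for M and (0.2, 0.8) for A form the trimmed set G\*, and

```
log2 TMM_k = sum_{g in G*} w_g M_g / sum_{g in G*} w_g ,   R_k = 2^log2TMM_k
```

Normalized expression is `(Y_gk / N_k) / R_k * 1e6`.  Downstream:
chloroplast calls need e-value ≤ 1e-5, identity ≥ 95%, coverage ≥ 80%
(mitochondrion: 80% / 50%), with scaffolds ≤ 200 nt nuclear by
exclusion; pathway nodes get arrow tiers by strict fold thresholds
(>2 ↑, >10 ↑↑, >100 ↑↑↑, otherwise ≈).

## Worked example

All inputs can be simulated with known ground truth:

```r
library(orgflow)
sim <- simulateOrganData(simulationSpec(nGenes = 1000, nSamples = 6,
                                        seed = 42))
ab  <- estimateAbundance(cleanCounts(sim$counts))
res <- normalizeTMM(ab)
normFactors(res)
#>   sample  nG nGstar     logTMM         R
#> 1      A 744    583 -0.6038656 0.6579886
#> 2      B 744    486 -0.4727122 0.7206086
#> 3      C 744    451 -0.5532408 0.6814875
#> 4      D 744    400 -0.5535652 0.6813343
#> 5      E 744    454 -0.6036670 0.6580791
#> 6      F 744    458 -0.4472856 0.7334215
```

`nG` is the size of the common gene set, `nGstar` the genes kept after
trimming, and `R` the factor dividing each sample's relative abundance.
Sample A carries the planted up-regulation (5% of genes, 8-fold), which
shifts its factor below the others; the remaining spread reflects the
count noise that the estimator's inverse-abundance weights amplify (see
the methods vignette).

```r
part <- classifyScaffolds(sim$hitsCp, sim$hitsMt,
                          scaffoldLengths(sim$counts))
part
#> PartitionResult: chloroplast=50, mitochondrion=30, nucleus=920

ann <- annotatePathway(sim$pathway, normalizedExpression(res),
                       targetSamples = c("A", "C", "D", "E"),
                       refSamples = c("B", "F"))
ann[, c("node_id", "label", "fold", "direction", "tier", "max_sample")]
#>   node_id      label     fold direction tier max_sample
#> 1     n01 EC 1.1.1.1 1.251938    approx    0          D
#> 2     n02 EC 1.1.1.2 2.370668 target_up    1          A
#> 3     n03 EC 1.1.1.3 1.296337    approx    0          A
#> 4     n04 EC 1.1.1.4 3.995194 target_up    1          A
#> 5     n05 EC 1.1.1.5 1.072639    approx    0          F
```

The planted organelle scaffolds are recovered exactly (50 chloroplast,
30 mitochondrial of 1000), and the pathway nodes mapped to up-regulated
scaffolds (n02, n04) carry single up-arrows toward the petal-like
target group with sample A as the highest expressor.

A thin command-line wrapper ships in `inst/scripts/orgflow`
(`orgflow normalize|classify|flow|simulate ...`).

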