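# baymir

Scores the strength of **endogenous miRNA-mediated repression** for
sequence-predicted miRNA-mRNA candidate pairs using only mRNA expression
profiles — no miRNA expression data required. It is aimed at
transcriptomics researchers who have (a) a genes × samples expression
compendium and (b) a candidate target network (e.g. conserved seed-match
pairs in TargetScan-style tables), and who want to know which candidate
interactions actually leave a footprint on expression.

## The method

For each miRNA family *k* (miRNAs sharing a seed), an **activity vector**
is inferred from the family's candidate targets: when the family is
active, its targets sit below their average expression, so

```
w_k = -(1/N_k) Σ_{i ∈ targets(k)} z(y_i),     w_k ← w_k / ||w_k||
```

with `z(·)` the per-gene z-score. Each gene's **down-regulation profile**
`d = ȳ − y` (positive where the gene is below its own mean, on log2
scale) is then regressed on the activity vectors of its candidate
regulators with a non-negativity-constrained elastic net:

```
ĥ = argmin_{h ≥ 0}  ½‖d − W h‖² + λ₁ Σ h_k + ½ λ₂ Σ h_k²
```

solved by cyclic coordinate descent with the one-sided soft-threshold
update `h_j ← (ρ_j − λ₁)₊ / (‖w_j‖² + λ₂)`. The coefficients `ĥ` are the
repression scores: positive means the family's activity explains part of
the gene's down-regulation in the presence of its other candidate
regulators; an exact zero means no expression evidence for the pair. A
per-gene **gene-variation index** (variance across samples) is provided
as a companion predictor. Penalties default to one global pair chosen by
cross-validation over samples.

The package also ships the benchmark statistics used to evaluate such
scores (score-bin response curves, median-split repression metrics,
hypergeometric/Fisher enrichment with BH-FDR, rank-sum site-position
comparisons) and a synthetic-data generator with planted ground truth, so
the entire pipeline is testable end to end without any downloads. See the
methods vignette (`vignettes/baymir-methods.Rmd`) for the model,
numerical choices and known limitations.

## Worked example

```r
library(baymir)

# synthetic inputs with planted truth: 300 genes, 10 families, 80 samples
b   <- simulateBundle(nGenes = 300, nFamilies = 10, nSamples = 80, seed = 42)
res <- runBaymir(b$expr, b$net)   # preprocess -> activities -> scores

res$activity
#> MirActivity: 80 samples x 10 miRNA families

head(res$scores[order(-res$scores$score),
                c("gene_id", "family_id", "score", "converged", "n_iter")])
#>  gene_id family_id    score converged n_iter
#>    G0127  miR-F006 8.416320      TRUE      2
#>    G0053  miR-F010 7.634190      TRUE      2
#>    G0252  miR-F001 7.288325      TRUE      2
#>    G0214  miR-F001 7.081176      TRUE      2
#>    G0240  miR-F001 5.005845      TRUE      2
#>    G0297  miR-F006 4.818922      TRUE      4
```

Each row is one candidate pair; `score` is the non-negative repression
coefficient (log2-scale down-regulation attributed to the family at unit
activity). Evaluating against a simulated over-expression assay, higher
score bins show stronger repression (more negative mean log-fold change),
and the median-split metric (negative mean response of above-median
pairs, per family) is well above zero:

```r
responses <- simulateOverexpression(b$truth, effectScale = 1,
                                    noiseSd = 0.1, seed = 7)
scoreBinResponse(res$scores, responses)[, c("bin", "n", "mean_response")]
#>   bin  n mean_response
#> 1   1 62   -0.07500312
#> 2   2 61   -0.09279907
#> 3   3 61   -0.18461111
#> 4   4 61   -0.93151456
#> 5   5 61   -3.60623217

medianSplitMetric(res$scores, responses)$metric
#> [1] 1.866008
```

Against the planted truth, recovered scores rank the planted coefficients
with Spearman correlation 0.94 over functional edges in this example.

A thin command-line front end is included:

```sh
Rscript inst/scripts/baymir simulate --genes 300 --families 10 \
    --samples 80 --seed 42 --out-dir bundle/
Rscript inst/scripts/baymir score --expression bundle/expression.tsv \
    --targets bundle/sites.tsv --sites --log-scale --out scores.tsv
Rscript inst/scripts/baymir evaluate --scores scores.tsv \
    --sites bundle/sites.tsv --out-prefix eval
```

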