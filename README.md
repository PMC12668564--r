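# d3impute

Dropout-aware imputation of single-cell RNA-seq expression matrices.

Single-cell RNA-seq count matrices are dominated by zeros, and the zeros come
in two kinds: *biological* zeros (the gene is genuinely silent in that cell)
and *non-biological* zeros or "dropouts" (the transcript was expressed but not
captured). Imputing all zeros over-smooths the data and erases real biology;
imputing none of them leaves technical noise that degrades clustering,
trajectory inference and differential expression. `d3impute` addresses this
for analysts working with cell × gene count matrices, optionally paired with
a bulk RNA-seq reference over the same gene namespace.

The workflow has three stages:

1. **Distribution-aware preprocessing.** After standard quality control
   (≥ 200 detected genes per cell, genes detected in ≥ 3 cells, top 2000
   highly variable genes by variance-stabilized scoring), seven candidate
   transformations (value-to-rank, unit-vector, library-size log
   normalization, log2/log10/loge of x+1, per-gene Box–Cox) are scored by the
   silhouette coefficient of the transformed matrix under the cell labels,
   and the argmax

   To\* = argmax over To in Γ of SC(To(X_QC))

   is applied to the single-cell matrix and to the bulk (or pseudo-bulk)
   reference.

2. **Dropout-aware discriminator.** The binary indicator I₀ (1 = observed
   non-zero) is factorized as I₀ ≈ UᵀV with non-negative latent matrices
   U (p × n cells) and V (p × m genes), minimizing

   ‖I₀ − UᵀV‖²_F + β(‖U‖²_F + ‖V‖²_F) + λc·Tr(U L_c Uᵀ) + λg·Tr(V L_g Vᵀ)

   by multiplicative updates, where L_c and L_g are graph Laplacians of
   kNN-sparsified Pearson similarity networks: a cell–cell network from the
   single-cell matrix and a gene co-expression network from the bulk
   reference (mutual neighbors weight 1, one-sided 0.5). Zeros whose
   reconstruction I\* = UᵀV exceeds a threshold (by default half the mean
   reconstruction of observed entries) are flagged as recoverable dropouts
   in the imputation index I₁; all other zeros are preserved as biological.

3. **Density-guided imputation.** Each cell with flagged positions is
   projected along the direction to the centroid F of its refined
   neighborhood E — its k nearest neighbors re-ranked by shared-nearest-
   neighbor overlap — choosing the grid point c_t = c_i + t(F − c_i) that
   maximizes the local density ρ(c_t) = 1/(Σ_{c_j∈E} ‖c_t − c_j‖² + ε).
   The final matrix is Y = Y₁ ⊙ I₁ + X: observed entries are untouched,
   biological zeros stay exactly zero.

The package also ships the full evaluation suite (skewness, silhouette, NMI,
ARI, pseudo-temporal ordering score, Kendall concordance, ROC/AUC, PCC,
RMSE), a splat-style negative-binomial simulator with seeded dropout masking
for benchmarking against known ground truth, and a three-stage grid search
over (β, λ), k and p.

## Worked example

```r
library(d3impute)

# simulate 300 cells x 1000 genes in 3 groups, then hide 50% of the non-zeros
sim <- simulate_counts(sim_params(n_cells = 300, n_genes = 1000, seed = 11))
msk <- apply_dropout_mask(sim$counts, rate = 0.5, seed = 44)

cfg <- default_config(
  io        = list(sc = msk$masked),
  qc        = list(min_genes = 1, min_cells_per_gene = 1, n_hvgs = 1000),
  transform = list(candidates = "log10"),
  disc      = list(k_cells = 15),
  verbose   = FALSE
)
res <- run_pipeline(cfg)

truth <- apply_transform(msk$truth, res$transform$spec)
score_masking_run(msk, res$imputed, res$I1, truth = truth$values)[
  c("pcc_masked", "rmse_masked", "dropout_recall", "false_flag_rate")]
#> $pcc_masked
#> [1] 0.6283632
#> $rmse_masked
#> [1] 0.6877464
#> $dropout_recall
#> [1] 0.8937989
#> $false_flag_rate
#> [1] 0.32399
res$metrics[1:2, ]
#>       metric     value
#> 1 ari_before 0.2331366
#> 2  ari_after 0.8268297
```

At the masked positions the imputed values correlate with the hidden truth at
r ≈ 0.63 (the zero-filled baseline has no correlation by construction), 89%
of the artificially hidden values are recognized as dropouts, and k-means
clustering recovers the three groups far better after imputation (ARI 0.83)
than before (0.23). The `false_flag_rate` is the price paid: ~32% of true
biological zeros are also filled at this masking intensity.

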