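# graphmarkers

Geometry-aware graph attention classification and explanation of
single-cell count matrices.

## What problem this solves

Single-cell experiments (scRNA-seq gene expression, scATAC-seq peaks or
genomic windows) deliver a cells × features count matrix together with
cell-type or cell-state labels. Standard practice finds the features that
characterise each population by differential analysis — ranking features by
how *different* they are between groups — which says nothing about whether
a feature is actually *used* by a predictive model of cell identity, and is
biased towards highly expressed, highly covered features.

`graphmarkers` takes the model-based route. It is aimed at computational
biologists who want, for each cell type, a ranked list of the features that
drive a classifier's decisions rather than a list of fold-changes:

1. embed the cells with a **geometry-regularised autoencoder** whose latent
   space is pulled towards a diffusion-based manifold embedding,
   minimising

   L = MSE(X, f⁻¹(f(X))) + λ · (1/N) Σᵢ ‖ξᵢ − f(xᵢ)‖²,

   with hidden width ⌈√F⌉ and latent width p = ⌈F^⅓⌉;
2. build the **k-NN cell–cell graph** (k = 15) from pairwise Euclidean
   distances in that latent space;
3. classify cells with a two-layer **graph attention network**
   (αᵢⱼ = softmax over N(i)∪{i} of aᵀ LeakyReLU(Θₛxᵢ + Θₜxⱼ);
   x′ᵢ = Σⱼ αᵢⱼ Θₜxⱼ), with a GCN baseline;
4. **explain** the frozen classifier with learned feature/edge masks that
   maximise the mutual information between prediction and masked input,
   average the masks per cell type, and report the top-50 features —
   compared against one-vs-rest Wilcoxon differential analysis.

The package also ships the full evaluation battery (corruption recovery
with MSE / top-coverage MSE / NB likelihood / Spearman, graph homogeneity,
explanation specificity and stability, technical-bias overlaps,
signal-to-noise) and a seeded synthetic-count simulator with planted cell
types, markers, negative-binomial noise and dropout, so everything is
testable offline.

## Worked example

```r
library(graphmarkers)

# a seeded matrix with 4 planted cell types, 20 markers each (features
# feat_1..feat_20 belong to type_1, feat_21..feat_40 to type_2, ...)
sim <- generate_counts(synthetic_spec(n_cells = 600, n_features = 500,
                                      n_types = 4, markers_per_type = 20,
                                      effect_log2fc = 2, seed = 7))
m <- log_transform(normalize_library_size(sim$matrix))

xi  <- phate_embed(m, seed = 1)                    # manifold target (p = 8)
gr  <- train_grae(m, xi, train_config(seed = 1))   # geometry-regularised AE
g   <- knn_graph(gr, k = 15)                       # cell-cell graph
cls <- train_classifier(g, m, gat_config(seed = 1), "GAT")
cls$report

ex <- explain_class(cls$model, g, m, m$labels, explainer_config(seed = 1),
                    n_top = 50, max_nodes_per_class = 5)
ex$type_1
head(top_features(ex$type_1), 8)
specificity(ex)
```

```
<classification_report> acc 0.892 | macro P 0.901 R 0.892 F1 0.893
<class_explanation> type_1: 5 nodes explained (subsampled), fidelity 1.00
  top: feat_18, feat_6, feat_3, feat_9, feat_15, feat_11, feat_4, feat_5 ...
[1] "feat_18" "feat_6"  "feat_3"  "feat_9"  "feat_15" "feat_11" "feat_4"
[8] "feat_5"
[1] 0.96
```

The test macro-F1 of 0.893 says the attention network recovers the planted
types from the graph; every one of the eight top-ranked features for
`type_1` is one of its twenty planted markers (`feat_1`–`feat_20`), and a
specificity of 0.96 means different types receive almost disjoint top-50
explanations.
`wilcoxon_da(m)` produces the differential baseline and
`xai_da_similarity()` compares the two feature lists.

`run_all(pipeline_config(...))` chains every stage and writes the processed
matrix, embedding, latent space, edge list, classification report,
per-class explanation tables and a metrics JSON into an output directory;
`run_ablation()` reruns the corruption-recovery and homogeneity comparisons
over embedders (GRAE / AE / VAE / PCA) and classifiers (GAT / GCN). A thin
command-line wrapper with the same stages lives in
`inst/cli/graphmarkers-cli.R`.

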