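# omixcl

Cross-modality graph contrastive learning for paired single-cell
multi-omics integration, in base R.

## The problem

Paired assays (10x Multiome, SNARE-seq and kin) measure the same cell twice:
scRNA-seq captures transcript abundance, scATAC-seq chromatin accessibility.
The two matrices live in different feature spaces with different noise, yet
describe one cellular state. Analysts want a single embedding in which the
two views of each cell coincide, cell types cluster, and labels annotated on
the RNA side transfer to the ATAC side. omixcl is for method developers and
analysts who want that pipeline as inspectable, dependency-light R code with
every stage exposed and tested.

## The method

Each modality is preprocessed (library-size normalisation, log1p, highly
variable genes, scaling, 30-component PCA) and summarised as a directed
k-nearest-neighbour cell graph (k = 20, Euclidean), from which a random
fraction of *unidirectional* edges — the likeliest type-crossing ones — is
removed. A **shared** three-layer graph convolutional encoder with a
two-layer projection head maps both modalities into a common space:

    H1 = ReLU(Â X W0)      H2 = ReLU(Â H1 W1)      H3 = Â H2 W2
    Z  = ReLU(H3 Wp1) Wp2,          Â = D^(-1/2) A D^(-1/2)

trained full-batch with Adam on the InfoNCE objective

    L = -(1/N) Σ_i log[ exp(sim(z_i^R, z_i^A)/τ) / Σ_j exp(sim(z_i^R, z_j^A)/τ) ]

where `sim` is cosine similarity and τ = 0.1: each modality's graph acts as
a natural augmentation of the other, the two views of a cell are the
positive pair, all other cells are negatives. Labels transfer RNA→ATAC by
k-NN plurality vote in the joint embedding, and the integration is scored
with ARI, NMI, F1 (and their sum), batch entropy, silhouette and
marker-signal loss. An MLP encoder and a squared-error loss are built in as
ablations, and a negative binomial shared-latent simulator generates paired
datasets with known types for end-to-end validation.

## Worked example

```r
library(omixcl)

ds <- simulate_paired(sim_config(n_cells = 200, n_genes = 100, seed = 42))
fit <- omixcl(ds$rna, ds$atac, ds$labels,
              preproc = preproc_config(n_hvg = 100, n_pca = 15),
              graph   = graph_config(k = 10),
              model   = model_config(hidden_dim = 100, out_dim = 32),
              train   = train_config(epochs = 200))
summary(fit)
```

```
Cross-modality graph contrastive integration fit

Cells: 200   Encoder: GCN (34700 parameters)   Loss: contrastive
Training: 200 epochs, loss 6.0162 -> 1.3720, pair cosine 0.601 -> 0.709

Integration metrics (RNA -> ATAC label transfer):
  ARI 0.883  NMI 0.847  F1 0.960  SUM 2.690
  batch entropy 0.867  silhouette 0.073  accuracy 0.960

Per-class transfer accuracy:
type_1 type_2 type_3
 0.985  0.985  0.909
```

Reading this: the contrastive loss fell from its ln(N)-ish start to 1.37 and
the mean cosine between the two views of the same cell rose to 0.71, so the
modalities are aligning. 96% of ATAC cells received their true type from the
RNA reference; ARI/NMI score the induced partition against the truth, batch
entropy 0.87 says RNA and ATAC cells are well mixed in each neighbourhood
(1 = perfect mixing), and the modest silhouette reflects compact but
adjacent type clusters in the 32-dimensional embedding. `predict(fit)`
returns the transferred labels, `predict(fit, type = "embedding")` the joint
embedding, `plot(fit)` a 2-D view, `coef(fit)` the five weight matrices.

At the package's study scale (600 cells, defaults, 300 epochs) the same
pipeline reaches transfer accuracy ≈ 0.99 and batch entropy ≈ 0.96; the
graph-free MLP ablation loses more than a full SUM point — the empirical
case for encoding the cell graphs at all.

File-based workflows use `run_pipeline(config, rna, atac, labels)` with a
YAML config (see `validate_config()`), or the CLI at
`inst/cli/omixcl.R` (`simulate`, `preprocess`, `build-graph`, `train`,
`embed`, `transfer-labels`, `evaluate`, `run`).

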