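# pgsubtype

Unsupervised subtyping of patient cohorts from structural-MRI gray-matter
volumes and clinical scales, using a population graph and a graph attention
autoencoder, with individualized differential structural covariance
networks (IDSCNs) for network-level characterization.

## Who this is for

Neuroimaging groups who have, per subject, a table of regional gray-matter
volumes (e.g., 166 atlas regions), clinical scale scores (PSQI, SAS, SDS),
and nuisance covariates (age, sex, total intracranial volume), and who want
to ask: *does this patient group contain distinct, biologically meaningful
subgroups?* The package also ships a synthetic cohort generator with
planted subtypes, so the entire pipeline can be exercised and validated
without access to clinical data.

## The model

**Population graph.** Each patient is a node with feature vector
`x_i ∈ R^F` (regional volumes). Imaging similarity is the sum of two
cross-subject Pearson correlations (ROI channel + skeletonized channel),
`S_I ∈ [-2, 2]^{N×N}`. Clinical similarity `C_d` is a binary gate: for each
measure, two subjects are similar when their absolute score difference is
below the 25th percentile of all pairwise differences; measures are
combined (OR by default). The fused weights `A = S_I ⊙ C_d` (Hadamard
product) are sparsified by keeping the top 20% strongest pairs, binarized
into `A0`, with a connectivity floor so no node is left isolated.

**Graph attention autoencoder.** A four-layer multi-head graph attention
encoder (per-head widths 256/128/64/32, heads 4/4/1/1, LeakyReLU attention
logits `e_ij = LeakyReLU(aᵀ[Wh_i ‖ Wh_j])` softmax-normalized over the
inclusive neighborhood, layer-norm + ELU after each layer) maps subjects to
16-dimensional embeddings `z_i = W_μ h_i^(L) + b_μ`. An MLP decoder
reconstructs features; an inner-product decoder `Â = σ(ZZᵀ)` reconstructs
the adjacency. The loss is

    L = (1/N) Σ_i ‖x̂_i − x_i‖² + λ · BCE(Â, A0)

optimized full-graph with Adam (lr 0.001). The backward pass is hand-derived
matrix calculus, verified against finite differences in the test suite.

**Subtyping, selection, stability.** K-means clusters the embeddings; the
structure weight λ ∈ {0, …, 1} and cluster count C ∈ {2, …, 5} are chosen
by the silhouette coefficient. Stability is quantified by retraining on
random 80% subsamples (30 runs) and scoring all 435 run pairs with the
adjusted Rand index on overlapping subjects.

**IDSCN.** A reference network `PCC_n` (partial correlations over controls,
adjusting for age, sex, TIV) is perturbed by adding one patient; each
edge's change is scored as `Z = ΔPCC_n / ((1 − PCC_n²)/(n − 1))`, with
two-sided normal p-values, per-subject multiple-comparison correction,
retention of edges altered in ≥ 33 patients (top 20 by count), and an
alternative K-means clustering on the retained edges' Z-scores.

## Worked example

```r
library(pgsubtype)

cohort <- generate_cohort(cohort_spec(seed = 1))   # 140 ID + 57 HC, 166 ROIs
graph  <- build_population_graph(cohort)           # ID-only, 1946 edges
fit    <- train_gaae(graph, cfg = train_config(epochs = 200,
                                               lambda_struct = 0.3, seed = 1))
labels <- cluster_latent(fit$z, c = 2, seed = 1)

table(labels)
#> labels
#>  1  2
#> 87 53
adjusted_rand_index(labels, graph$pheno$true_subtype)
#> [1] 0.9151868
compute_silhouette(fit$z, labels)
#> [1] 0.7415514
```

The generator plants two subtypes of 90 and 50 patients with correlated
gray-matter reductions and clinical elevation; the pipeline recovers the
planting from the embeddings with ARI 0.92 (90/50 recovered as 87/53), and
the two-cluster solution scores silhouette 0.74. Downstream, the recovered
subtypes differ on every clinical scale in the planted direction, and the
shared gray-matter perturbation of the larger subtype surfaces as commonly
altered covariance edges:

```r
stats <- group_stats_table(graph$pheno, labels, c("psqi", "sas", "sds"))
stats[, c("variable", "mean1", "mean2", "p_adjusted")]
#>   variable    mean1    mean2   p_adjusted
#> 1     psqi 13.70115 12.60377 1.377908e-02
#> 2      sas 53.45020 44.66757 1.684019e-05
#> 3      sds 55.15079 44.93488 1.598444e-06

nets <- idscn_all(cohort)                     # 140 leave-one-in networks
summary <- top_altered_edges(nets, min_subjects = 33, top_k = 20)
nrow(summary$edges)
#> [1] 20
```

The command-line interface (`inst/cli/pgsubtype`) exposes `simulate`,
`build-graph`, `train`, `subtype`, `stability`, `idscn` and `run-all`
subcommands over the same functions; `run_pipeline()` orchestrates all
stages and writes a manifest with content hashes of every output.

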