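# lrcmc — Laplacian Rank Constrained Multiview Clustering

`lrcmc` clusters samples that have been measured in several feature spaces at
once — typically multi-omics cohorts where the same patients carry mRNA
expression, DNA methylation and miRNA profiles — without a separate
clustering step. It is aimed at bioinformaticians doing cancer subtype
discovery or any multiview integration task where the sample size n is small
relative to the feature dimension, so graph-based methods are preferable to
feature-space ones.

## The method

Given m views X¹,…,Xᵐ (each d_v × n, samples in columns) and a target
cluster count c, the method jointly learns:

- **Per-view affinity graphs S¹,…,Sᵐ** — each column s_jᵛ is a k-sparse
  similarity distribution over the other samples (adaptive neighbors):
  the minimizer of Σᵢ ‖xᵢ−xⱼ‖² s_ij + α‖s_j‖² on the probability simplex,
  with the per-column α set implicitly so exactly k entries are nonzero.
- **Per-view spectral embeddings Fᵛ** — the c bottom eigenvectors of the
  graph Laplacian Lᵛ = Dᵛ − (Sᵛ+Sᵛᵀ)/2, which by the Ky Fan theorem minimize
  Tr(FᵀLᵛF) over orthonormal F.
- **A weighted consensus graph Z** with self-tuned view weights
  w_v = 1/(2‖Z−Sᵛ‖_F), so views that agree with the consensus count more and
  noisy views are down-weighted automatically.
- **A rank constraint on the consensus Laplacian** L_Z: since the
  multiplicity of L_Z's zero eigenvalue equals the number of connected
  components of Z, penalizing 2β·Tr(Uᵀ L_Z U) (U = bottom c eigenvectors of
  L_Z) and adapting β (doubled when Z has fewer than c components, halved
  when more) drives Z to have *exactly* c components.

The joint objective

```
min  Σ_v [ 2 Tr(FᵛᵀLᵛFᵛ) + α‖Sᵛ‖²_F + w_v‖Z−Sᵛ‖²_F ] + 2β Tr(Uᵀ L_Z U)
s.t. FᵛᵀFᵛ = I, UᵀU = I, columns of each Sᵛ and Z on the simplex, zero diagonal
```

is solved by alternating closed-form updates (every affinity/consensus
column is a simplex-projected quadratic with an exact solution).  At
convergence the clusters are simply the connected components of Z — no
k-means or other post-clustering is needed, and the whole pipeline is
deterministic.  Only β needs tuning, and it tunes itself.

## Worked example

```r
library(lrcmc)

# 3 clusters of 30 samples, seen in 3 five-dimensional views
sim <- make_multiview_blobs(n_per_cluster = 30, c = 3, m = 3, dims = 5,
                            separation = 10, noise_sd = 1, seed = 42)
fit <- lrcmc_fit(sim$views, lrcmc_config(c = 3, k = 10))
print(fit)
#> Laplacian rank constrained multiview clustering fit
#>   samples: 90   views: 3   clusters: 3
#>   converged: TRUE after 2 iterations (consensus components: 3)
#>   final beta: 1
#>   view weights: 5e+11, 5e+11, 5e+11
#>   cluster sizes: 30, 30, 30

clustering_metrics(sim$labels, fit$labels)
#> clustering metrics (n = 90): ACC 1.0000  NMI 1.0000  Purity 1.0000
```

`converged: TRUE` means the consensus graph reached exactly c = 3 connected
components on two consecutive iterations; the labels are those components.
The view weights are the self-tuned w_v — here all three views end up
essentially identical to the consensus (the Frobenius distance hits its
floor, hence the large equal weights).  ACC is the fraction of samples
matched to the generating labels under the best one-to-one cluster/class
assignment; NMI and Purity are the usual partition-agreement scores.  Adding
a corrupted view (`corrupt_views = 4`) leaves recovery intact and visibly
shrinks that view's weight.

## Command line

```sh
exec/lrcmc fit --view mrna.csv --view methyl.csv --view mirna.csv \
    --clusters 3 --neighbors 10 --out results/
exec/lrcmc simulate --spec blobs.yaml --out simdata/
exec/lrcmc eval --truth truth.tsv --pred results/labels.tsv
```

`fit` writes `labels.tsv`, `consensus.mtx` (sparse MatrixMarket), a
reproducibility `manifest.json` and a per-iteration `trace.tsv`.

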