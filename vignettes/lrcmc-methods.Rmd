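---
title: "Multiview clustering with a rank-constrained consensus graph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview clustering with a rank-constrained consensus graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcmc)
```

## The model

`lrcmc` addresses one-step multiview clustering: m feature matrices
$X^v \in \mathbb{R}^{d_v \times n}$ describe the same $n$ samples (for
instance mRNA expression, DNA methylation and miRNA profiles of one patient
cohort), and we want a single partition into $c$ clusters without a separate
k-means stage whose own randomness and initialization would have to be
managed.

The device that makes this possible is a classical spectral fact: for a
nonnegative affinity matrix $S$ with Laplacian
$L = D - (S + S^\top)/2$ (where $D$ holds the column sums of the symmetrized
matrix), the multiplicity of the eigenvalue 0 of $L$ equals the number of
connected components of the graph. If we can force the bottom $c$
eigenvalues of the *consensus* graph's Laplacian to zero — equivalently
$\operatorname{rank}(L_Z) = n - c$ — the graph decomposes into exactly $c$
components and those components *are* the clusters.

Three ingredients are learned jointly:

1. **Adaptive-neighbor view graphs.** Each column $s_j^v$ of a view's graph
   solves
   $\min_{s \ge 0,\; \mathbf{1}^\top s = 1,\; s_j = 0}
   \sum_i p_{ij} s_{ij} + \alpha \lVert s \rVert^2 + w_v \lVert z_j - s\rVert^2$,
   where $p_{ij} = \lVert f_i^v - f_j^v \rVert^2$ are squared distances
   between rows of the view's spectral embedding $F^v$ (at initialization,
   raw squared distances between data columns), $z_j$ is the consensus
   column and $w_v$ the view weight. The $\ell_2$ term prevents the trivial
   one-hot solution; its coefficient $\alpha$ is *not* a user parameter —
   per column it is set implicitly so that exactly $k$ entries stay nonzero
   (see below).
2. **Self-weighted fusion.** View weights are re-derived from the current
   consensus as $w_v = 1 / (2\lVert Z - S^v\rVert_F)$: views whose graphs
   agree with the consensus count more. This is the stationary re-weighting
   of an implicit $\sum_v \lVert Z - S^v \rVert_F$ objective, and it is what
   lets a noisy or irrelevant view fade out without any user intervention.
3. **The rank penalty.** $2\beta\,\mathrm{Tr}(U^\top L_Z U)$ with
   $U^\top U = I$, $U \in \mathbb{R}^{n\times c}$. By the Ky Fan theorem the
   inner minimum over $U$ equals the sum of the $c$ smallest eigenvalues of
   $L_Z$, so driving it to zero realizes the rank constraint.

## The optimizer

All five blocks have exact updates, applied cyclically:

* $S^v$: per column, rank candidates $i \ne j$ by the effective cost
  $e_i = p_{ij}/2 - w_v z_{ij}$ (ascending, ties broken by sample index),
  keep the $k$ best, and set
  $s_{ij} = (e_{(k+1)} - e_i)/\delta$ with
  $\delta = k\,e_{(k+1)} - \sum_{l \le k} e_{(l)}$. This is the Euclidean
  projection of $(w_v z_j - p_j/2)/\delta$ onto the zero-diagonal simplex,
  with $\delta = \alpha + w_v$ pinned by the requirement of exactly $k$
  nonzeros. The closed form is verified in the test suite against an
  exhaustive active-set quadratic-programming oracle rather than trusted
  from algebra.
* $F^v$: the $c$ bottom eigenvectors of $L_v$ (dense symmetric
  eigendecomposition; eigenvalues ascending, each eigenvector's
  largest-magnitude entry made positive so runs are bit-reproducible).
* $w_v$: the inverse-distance formula above, with the Frobenius distance
  floored at $10^{-12}$ so a view identical to the consensus gets the
  largest finite weight instead of dividing by zero.
* $Z$: per column, the simplex projection of
  $\big(\sum_v w_v s_j^v - (\beta/2) q_j\big) / \sum_v w_v$, where
  $q_{ij} = \lVert u_i - u_j \rVert^2$. The consensus is *not* re-truncated
  to $k$ nonzeros — only the simplex constraint applies, and sparsity
  emerges from the projection.
* $U$: the $c$ bottom eigenvectors of $L_Z$.

After each cycle the connected components of $Z$ (combinatorial
breadth-first search on the support, not eigenvalue counting, which is
fragile near convergence) are compared with $c$ and $\beta$ is adapted:
halved when there are too many components, doubled when too few, unchanged
at the target. The run stops when $Z$ has exactly $c$ components on **two
consecutive** iterations — the stop rule is silent on oscillation, and the
doubling/halving rule can flip-flop around the target, so a single hit is
not trusted — or at `max_iter`.

If the cap is reached with the wrong component count the result is still
brought to $c$ clusters — by repeatedly merging the two components with the
largest inter-component similarity, or splitting the largest component by
the sign pattern of its submatrix's Fiedler vector — and flagged
`converged = FALSE`, never silently.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `c` | — | target cluster count; becomes the exact number of consensus components |
| `k` | — | adaptive neighbors per sample; 5–50 is the practical range, with `k` below the smallest expected cluster size |
| `beta0` | 1 | initial rank-penalty strength (dimensionless); self-adapting |
| `beta_min`, `beta_max` | $2^{\pm 20}$ | clamp range for the adaptation; wide because the doubling rule needs head-room in both directions |
| `max_iter` | 100 | iteration cap |
| `support_tol` | $10^{-8}$ | consensus entries at or below this are non-edges for component counting |
| `weight_exponent` | 1 | power on $\lVert Z - S^v\rVert_F$ in the weights; 2 selects the squared-distance variant |
| `min_cluster_size` | off | optional post-hoc check (e.g. 3 for clinical subtype work); flags, never alters |

Only `c` and `k` are mandatory. $\alpha$ never appears as an argument by
construction, and $\beta$ manages itself; this "one self-tuning parameter"
property is the main practical appeal of the formulation.

## The synthetic-data generator

`make_multiview_blobs()` produces the study conditions used throughout the
tests and the acceptance script: $c$ cluster centers per view placed on an
orthogonal frame scaled so every pairwise center distance equals
`separation` (a 1-D lattice when a view has fewer than $c$ dimensions),
isotropic Gaussian noise per view, and optionally *corrupted* views
generated from an independently shuffled label vector — such a view has
blob structure but zero information about the true classes, emulating an
uninformative omics layer. The defaults used in the acceptance experiments
are 30 samples per cluster, $c = 3$, $m = 3$ views of dimension 5,
separation 10 and unit noise, i.e. a separation-to-noise ratio of 10, with
$k = 10$: comfortably separated clusters that a correct implementation must
recover perfectly, chosen so that recovery failures indicate bugs rather
than statistical bad luck.

What the generator deliberately does **not** emulate: realistic omics
marginals (counts, methylation beta values, heavy tails), correlated noise
across views, unbalanced clusters, batch structure, or missing samples.
Passing the recovery tests therefore demonstrates correctness of the
optimization machinery, not performance on real cohorts.

`make_worked_fixture()` is a 12-sample, 2-view, 3-cluster instance whose
matrices are hard-coded literals, used for bit-exact regression and
constraint-conservation tests.

## Numerical choices

* **Ties** at the $k$-th/$(k{+}1)$-th neighbor are broken by sample index
  (stable radix sort) for deterministic output. When the tie is exact and
  $\delta = 0$ (duplicated points, or all costs equal) the column falls back
  to uniform weight over the tied nearest set, with a warning.
* **Eigendecompositions** use the deterministic dense symmetric solver;
  with a repeated eigenvalue at the $c$-th position the embedding subspace
  is genuinely non-unique and the solver picks one fixed representative —
  this non-uniqueness is inherent to the model, not to the implementation.
* **Component decisions** use breadth-first search on the graph support
  with `support_tol`; eigenvalue counting (`count_zero_eigenvalues`, absolute
  tolerance $10^{-8}$) is exposed and tested equivalent on clean graphs but
  is not what the solver's control flow relies on.
* **Objective accounting.** The reported objective trace evaluates the
  joint objective with the per-column $\alpha$ values of the current
  iteration. Because the exact-$k$ rule re-chooses $\alpha$ every iteration,
  monotone decrease of a single fixed functional is not guaranteed in
  theory; in practice the trace is non-increasing once $\beta$ stabilizes,
  and the test suite audits both this empirical behavior and the guaranteed
  per-update descent (each update minimizes its own subproblem exactly,
  which the QP and Ky Fan oracles confirm).
* **Weight floor** $10^{-12}$ on the Frobenius distance, and a positive
  floor on $\delta$, keep every quantity finite in degenerate limits.

## Design decisions that were genuinely open

* The printed closed form for the consensus column update is ambiguous
  about the sum over views; we solve the full weighted multi-view problem
  per column and verify the result against a constrained-QP oracle instead
  of transcribing the printed formula.
* The view-weight formula is ambiguous between distance and squared
  distance in the denominator; the distance version (exponent 1) is the
  default because it reproduces the standard self-weighted scheme's
  stationary condition, and the squared variant remains available as
  `weight_exponent = 2`.
* Labels are 0-based integers (component ids), matching the convention of
  the on-disk formats; the metrics are label-invariant so this is purely
  cosmetic.
* The β adaptation clamp is far wider than the $[1, 30]$ band used in the
  original benchmark experiments: the adaptation rule needs room to halve
  and double freely, and the clamp exists only to keep β finite.

## Problem sizes

The default test and acceptance experiments use $n = 90$–$300$ samples,
which dense $n \times n$ eigendecompositions handle in well under a second
per iteration; a full 20-seed recovery study runs in seconds. This matches
the intended application regime — patient cohorts of tens to a few hundred
samples — and the method's own scaling: each iteration is
$O(m\,n^2 \log n + n^3)$, so cohorts in the low thousands remain feasible,
while larger problems would need sparse eigensolvers, which are out of
scope.

## Known limitations

* Continuous features only: binary (mutation) and categorical (copy-number
  state) views violate the Euclidean-distance assumptions of the
  adaptive-neighbor construction.
* No missing values; every view must observe every sample.
* `c` must be supplied; the method does not select the cluster count.
* Degenerate embedding eigenspaces make the per-view penalties non-unique
  (see above); results are reproducible but can depend on the
  eigendecomposition's representative in such corner cases.
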