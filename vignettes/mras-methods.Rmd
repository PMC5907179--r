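---
title: "Multi-layer resource allocation with sequence kernels: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer resource allocation with sequence kernels: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mras)
```

## The problem and the model

Many non-coding RNAs (ncRNAs) are implicated in disease, but direct
disease–ncRNA annotations are sparse. What is far better covered are two
*indirect* layers of evidence: diseases annotated to molecular targets
(genes, proteins, microRNAs), and targets annotated to ncRNAs. `mras`
scores candidate disease–ncRNA associations by propagating resource through
the resulting tripartite network, with each propagation layer reweighted by
sequence similarity.

The data are a tripartite graph over $m$ diseases, $n$ targets and $p$
ncRNAs, stored as two binary adjacency matrices, $A^{DT}$ ($m \times n$)
and $A^{TR}$ ($n \times p$), plus one sequence per target and per ncRNA.

**Sequence features.** Each sequence is mapped to its *l*-gram spectrum:
the vector of counts of every contiguous length-$l$ substring, overlaps
included. Targets and ncRNAs are featurized separately (targets are
typically proteins, ncRNAs nucleotide sequences; the two vocabularies never
mix in any kernel). Each feature column $x$ is then standardized,
$x' = (x - \bar{x})/\sigma$, using the population standard deviation
(no Bessel correction appears in the defining formula; `sd_type = "sample"`
is available). Zero-variance columns are set to zero rather than dropped so
column indices stay stable.

**Kernels.** Pairwise similarity between standardized feature rows uses the
RBF kernel
$$k(i,j) = \exp\!\left(-\gamma \, \lVert x_i - x_j \rVert^2\right),
\qquad \gamma = \frac{1}{2\sigma^2}, \quad 0 < \sigma < 1,$$
with separate bandwidths for the ncRNA kernel ($\sigma_1$) and the target
kernel ($\sigma_2$). Linear and degree-2 polynomial kernels are provided as
comparators; for the polynomial kernel the common inhomogeneous form
$(x \cdot y + 1)^2$ is the default, with the offset exposed because the
bare name "polynomial (degree = 2)" does not pin down scale or offset.

**Propagation.** Layer 1 spreads resource from targets through shared
diseases and back, damped by each disease's degree and modulated by target
similarity:
$$W^T_{ij} = k_{target}(i,j) \sum_{l=1}^{m}
  \frac{a^{DT}_{li}\, a^{DT}_{lj}}{\deg(d_l)}.$$
Layer 2 does the same for ncRNAs through shared targets:
$$W^R_{ij} = k_{rna}(i,j) \sum_{l=1}^{n}
  \frac{a^{TR}_{li}\, a^{TR}_{lj}}{\deg'(t_l)}.$$
The layers combine across the target–ncRNA adjacency,
$W_C = W^T (A^{TR} W^R)$, and the final score matrix is
$P = A^{DT} W_C$: within a disease row, higher scores mean more certain
association. The ranking is the output; no row normalization is applied,
so scores are comparable within a disease, not across diseases.

With all-ones kernels the layer weights reduce to the classical
common-neighbour resource-allocation weights, and multiplying a kernel by a
constant scales the corresponding layer (hence $P$) linearly — sequence
similarity acts purely as a multiplicative modulation of path mass.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `l` | substring length of the spectrum features | 3 | 1–4 is the useful range; vocabulary grows as observed $\lvert\Sigma\rvert^l$ |
| `sigma1` | RBF width, ncRNA kernel | 0.5 | constrained to (0, 1); tuned by grid search |
| `sigma2` | RBF width, target kernel | 0.5 | as above |
| `kernel` | kernel family | `"rbf"` | `"linear"`, `"polynomial"`, `"ones"` for comparison |
| `k`, `repeats` | CV folds and re-randomizations | 5, 5 | |
| `cut_links` | remove held-out paths before scoring | `TRUE` | the honest evaluation mode |

Because standardized feature vectors of unrelated sequences are far apart
in high-dimensional feature space, small $\sigma$ values make the RBF
kernel behave almost like the identity plus blocks of near-1 entries for
highly similar sequences; that block structure is exactly what lets
sequence information rescue a link-cut prediction.

## Design choices made where the design was open

* **Which $\sigma$ goes with which kernel.** The kernel definitions
  introduce $\sigma_1$ inside the ncRNA kernel and $\sigma_2$ inside the
  target kernel, and `mras` follows that (`sigma_assignment =
  "sigma1_rna"`). Because the two subscripts are easy to swap when reading
  the layer order (layer 1 uses the *target* kernel), the swapped
  assignment is one option away.
* **Layer-2 denominator.** The layer-2 sum divides by a target's degree.
  A target has two degrees — one in the disease–target layer, one in the
  target–ncRNA layer. The package defaults to the degree *within the layer
  being propagated* (`layer2_degree = "tr_network"`), the exact parallel of
  layer 1; the other reading is selectable.
* **Zero-degree nodes** are handled by masked division: a disease or target
  with no incident edges in the relevant layer contributes nothing (its
  numerators are zero anyway), so no 0/0 ever forms.
* **Labels for evaluation.** A disease–ncRNA pair is a positive exactly
  when it is connected through at least one target,
  $(A^{DT} A^{TR})_{dr} \ge 1$. All $m \times p$ pairs enter the
  evaluation — restricting to connected pairs would leave no negatives for
  a ROC curve.
* **Link cutting** removes, for each held-out positive pair $(d, r)$, every
  target–ncRNA edge $(t, r)$ with $t$ adjacent to both. This severs every
  $d \to t \to r$ path while preserving disease–target evidence shared with
  training pairs; cutting the disease–target edges too is available as
  `cut_mode = "both"`. After cutting, a leakage check holds by
  construction: no held-out positive retains a path.
* **Stratified folds.** With sparse positives, uniform folds can easily
  produce single-class test groups. Folds are therefore stratified by label
  (positives spread round-robin, negatives balancing fold sizes), with the
  unstratified literal protocol available. Single-class folds are skipped
  with a warning and excluded from the mean rather than failing the run.
* **Standardization scope.** Feature means and standard deviations are
  computed once on the full sequence sets. Cross-validation holds out
  *links*, never sequences, so no information about the held-out labels
  flows through the standardization; recomputing it per fold would change
  nothing but the constant factors.
* **Grid-search honesty.** `grid_search_sigmas()` picks the $(\sigma_1,
  \sigma_2)$ with the best held-out-fold AUC, which is optimistic by
  construction (the selection uses the same folds it reports). This
  replicates the stated tuning protocol; treat the selected AUC as a tuned
  optimum, not an unbiased estimate. All 81 grid points share identical
  fold partitions so differences reflect the bandwidths alone, and ties
  resolve to the lexicographically smallest pair.

## The synthetic generator

`generate_network()` / `generate_sequences()` (or `simulate_dataset()`)
produce data whose *only* structure is the one the method claims to
exploit: ncRNAs fall into clusters (default $\lceil p/10 \rceil$), each
cluster prefers a small target set — edge odds to preferred targets are
multiplied by $e^{\text{signal}}$ — and cluster members are mutated copies
of a common ancestor with per-position mutation rate $e^{-\text{signal}}$.
So at `signal = 0` edges are independent Bernoulli draws and sequences are
i.i.d. uniform (mutation rate 1 resamples every position), while at high
signal sequence similarity and shared-target structure are strongly
coupled. `signal = 4` is used as the "high" setting in the package's own
evaluations: odds are boosted ~55-fold and within-cluster sequence identity
is ≈ 98%, a regime comparable to paralogous RNA families. Exact-count edge
sampling (`edges_dt`, `edges_tr`) exists to build networks with prescribed
average degree.

What the generator does **not** emulate: power-law degree distributions,
heterogeneous annotation biases, shared targets *between* clusters,
composition biases of real protein/RNA sequences, or length–function
correlations. Passing tests on synthetic data therefore demonstrate that
the implementation recovers the planted mechanism, not that the method
attains any particular accuracy on curated disease databases.

## Numerical choices

* Squared Euclidean distances for the RBF kernel are computed via the
  Gram-matrix identity; tiny negative values are clamped to zero, the
  self-distance is set to zero exactly (diagonal exactly 1), and the matrix
  is symmetrized, so the stated invariants (symmetry within 1e-12, entries
  in (0, 1]) hold exactly.
* AUC is the Mann–Whitney statistic with midrank ties; ROC points come from
  a threshold sweep over distinct score values, whose trapezoid area equals
  the midrank value identically (both are asserted against a brute-force
  concordant-pair count in the tests).
* Averaged ROC curves interpolate each fold's curve onto a common FPR grid
  (step 0.01) before averaging.
* One master seed drives everything; per-repeat sub-seeds are derived as
  `(seed * 1000003 + 7919 * i) mod (2^31 - 1)` so repeats are independent
  but reproducible, and all seeded code restores the caller's RNG state.
* Records shorter than `l` yield all-zero feature rows (real ncRNA lengths
  span orders of magnitude); if *no* record reaches length `l` the feature
  matrix has zero columns and every pairwise distance is zero.

## Problem sizes used in the package's own evaluations

The test suite and the acceptance script run at desk scale, chosen so the
statistical claims are testable with comfortable margins: oracle
comparisons on 100 random instances with $m, n, p \le 7$; AUC estimator
checks on 1000 random vectors; cross-validation at $m = 50$, $n = 40$,
$p = 40$ (2000 disease–ncRNA pairs, edge density 0.08, $l = 3$,
$\sigma_1 = \sigma_2 = 0.5$, 5 folds × 5 repeats); and a full 81-point
$\sigma$ grid search at $m = 50$, $n = 40$, $p = 30$ with one repeat.
At these conditions the label-shuffled null sits within a few hundredths
of AUC 0.5, the uncut evaluation is near-perfect (≈ 0.99, memorized
connectivity), and the link-cut evaluation retains AUC ≈ 0.61–0.65 across
seeds — signal recovered from sequence similarity alone, with the direct
paths removed.

```{r example, eval = FALSE}
sim <- simulate_dataset(50, 40, 40, density_dt = 0.08, density_tr = 0.08,
                        signal = 4, seed = 1)
cv <- cross_validate(sim$network, sim$target_seqs, sim$ncrna_seqs,
                     l = 3, sigma1 = 0.5, sigma2 = 0.5,
                     k = 5, repeats = 5, seed = 1)
cv$mean_auc
```

## Known limitations

* Scores are not normalized across diseases; rank within a disease row is
  the only contract.
* The grid search reports an optimistically selected AUC (see above); a
  nested protocol would be needed for honest tuning.
* Sequence standardization is global; if sequences themselves were ever
  held out, the standardization would have to move inside the folds.
* No iterative multi-step diffusion, significance testing, or multiple
  testing correction: the method is a single two-layer propagation pass.
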