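---
title: "Mapping single cells onto spatial spots: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single cells onto spatial spots: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotmap)
```

## The problem and the model

Spot-based spatial transcriptomics (ST) measures mixtures: each capture
spot aggregates the transcriptomes of the handful of cells sitting on it.
`spotmap` resolves those mixtures with a reference scRNA-seq dataset from
the same tissue by learning a cell-to-spot mapping score matrix
**M** ∈ ℝ^{m×w} (m cells, w spots), row-stochastic by construction
(row-wise softmax of free logits), and minimizing

$$
\mathcal{L} \;=\; \sum_{i,j} \mathrm{KL}(C_{i,*}\,\|\,S_{j,*})\,M_{ij}
\;+\; \sum_{i,j} D_{ij} M_{ij}
\;+\; \lambda \frac{1}{w} \sum_{j=1}^{w} \Bigl|\,N_j - \sum_{i=1}^m M_{ij}\Bigr|
$$

* the **expression term** scores each (cell, spot) pair by the
  Kullback–Leibler divergence between their normalized expression profiles,
  treated as probability distributions over genes;
* the **embedding term** uses the Pearson distance
  $D_{ij} = 1 - \mathrm{PCC}(Z^{sc}_{i,*}, Z^{st}_{j,*})$ between graph
  attention autoencoder (GATE) embeddings, which summarize each node
  together with its neighborhood (transcriptional neighbors for cells,
  spatial neighbors for spots) and therefore carry structure the raw
  profiles do not;
* the **cell-quantity term** pulls each spot's total mapped mass toward its
  expected cell count $N_j$, preventing mass from collapsing onto a few
  attractive spots. Its weight defaults to $\lambda = 0.1$, the calibrated
  value; the term matters in both mapping modes.

The optimizer is full-batch Adam on the logits. Because the first two terms
are linear in **M**, without the quantity term each row's optimum is a point
mass on its cheapest spot; the softmax parameterization plus the quantity
term turn this into a smooth assignment problem with a tunable degree of
sharing. Two extraction rules read the solved matrix:

* *regular*: for each spot $j$ independently, the $N_j$ cells with the
  highest scores in column $j$ (cells may repeat across spots or be left
  out); the result always contains exactly $\sum_j N_j$ assignments;
* *greedy*: each cell goes to its row-maximum spot; exactly $m$
  assignments.

Key modelling assumptions: the scRNA-seq reference and the ST section come
from the same tissue so that every spot's mixture is representable by
reference cells; per-spot UMI totals are a usable proxy for cell abundance
(or an external nucleus count is supplied); and expression similarity plus
local-neighborhood structure carry enough signal to discriminate spots.
Cell-type annotations are never used by the mapping itself — only by
evaluation and reporting — so ambiguous annotations cannot bias the fit.

## Preprocessing and cell-count estimation

Both matrices are filtered to genes detected in at least two rows (applied
to each dataset separately, before intersecting), restricted to their
common genes in lexicographic order, scaled per row to counts-per-million,
and transformed by $\log_2(1+x)$. Filtering before intersection is a
convention: it guarantees that a gene surviving preprocessing carries
signal in *both* datasets.

The UMI rule converts each spot's raw total $T_j$ to
$u_j = \log_2(1 + 10^6\, T_j / \sum_k T_k)$ and fits the line through two
anchors: $(u_{\min}, 1)$ — the minimum-UMI spot holds one cell — and
$(u_{\mathrm{median}}, \bar n)$ with $\bar n$ the mean cells per spot
(default 5, the conventional Visium figure). Values are rounded half-up and
clipped to ≥ 1, so extrapolation below the minimum cannot go to zero; equal
anchors (all spots the same total) are refused with a pointer to the
constant fallback. The exact normalization feeding the anchors is
underdetermined by the usual description of this rule; the formula above
preserves the intended relative scaling and the log transform, and the
estimate is monotone in the raw total by construction.

## The autoencoder and the comparability decision

Each GATE layer computes
$r_{ij} = \operatorname{sigmoid}(v_s^\top \sigma(W h_i) + v_t^\top \sigma(W h_j))$,
normalizes $\alpha_{ij} = \operatorname{softmax}_{j \in A_i}(r_{ij})$ over
the neighborhood $A_i$ (self-loop included), and aggregates
$h_i = \sum_j \alpha_{ij}\, \sigma(W h_j)$. The decoder mirrors the encoder
with transpose-tied weights $\hat W^{(k)} = W^{(k)\top}$ and its own
attention vectors, and training minimizes
$\sum_i \lVert x_i - \hat x_i \rVert^2$ by Adam with analytically derived
gradients (verified against numerical differentiation in the test suite).

Graphs: cells get a k-nearest-neighbor graph in normalized expression space
(default $k = 15$); spots get a spatial kNN graph (default $k = 6$,
matching the hexagonal packing of Visium arrays; a radius mode is also
available). Distances are Euclidean and ties break deterministically toward
the lower index.

A genuinely open design point is how the two embeddings become comparable
for the Pearson term. Training two autoencoders independently — even with
identical widths — yields latent spaces that differ by an arbitrary
invertible transform, so correlating a cell's coordinates with a spot's is
meaningless noise. The package therefore defaults to **joint training**:
one GATE, shared weights, trained on the row-concatenated cell and spot
matrices over a block-diagonal graph (no cross-modality edges). The same
encoder maps both modalities, so a spot — whose normalized profile
resembles a mixture of its member cells — lands near those cells in latent
space, and the Pearson term becomes informative.
`embedding = "separate"` retains the two-model reading, and
`embedding = "none"` drops the term entirely, which is also the recommended
ablation when judging how much the embeddings contribute on a given
dataset.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `mean_cells` | 5 | cells at the median-UMI anchor; Visium-scale spots |
| `lambda` | 0.1 | quantity-term weight; calibrated value |
| `gate_dims` | 512, 30 | encoder widths (lineage convention); last = embedding dim |
| `gate_epochs`, `gate_lr` | 500, 1e-4 | full-batch Adam budget for the autoencoder |
| `k_expression` | 15 | cell kNN graph degree |
| `k_spatial` | 6 | spot graph degree (hexagonal neighborhoods) |
| `map_epochs`, `map_lr` | 1000, 0.01 | Adam budget for the mapping logits |
| `seed` | 1 | drives weight init, mapping jitter, and simulation draws |

All randomness flows from the single `seed`, so repeated runs are
bit-identical; `run_pipeline()` snapshots the resolved configuration next
to its outputs.

At the problem sizes used throughout this package's own checks (about
1,600 cells, 300 spots, 500 genes), a lighter autoencoder configuration —
`gate_dims = c(128, 30)`, `gate_epochs = 150`, `gate_lr = 1e-3`, with
`map_epochs = 600` — is the package's desk-scale choice: the narrower
hidden layer is ample for a few hundred genes, and the larger learning rate
compensates for the shorter schedule. These are the settings the bundled
acceptance script and end-to-end tests run.

## The simulator: what it emulates and what it does not

`generate_synthetic_tissue()` emulates a spatially organized,
cell-type-annotated single-cell dataset of the kind produced by
high-resolution platforms: each of `n_types` cell types has a
negative-binomial expression program (log-normal baseline gene means,
`marker_fold`-elevated markers, dispersion `nb_size = 2`) and occupies a
coherent spatial patch (Gaussian cloud around a grid center in the unit
square) or a position along a gradient. Defaults — 8 types × 200 cells,
500 genes, 25 markers per type, baseline mean ≈ 2 counts per gene (≈ 1,600
counts per cell), marker fold 5 — give clearly separable types with
realistic count noise at a size every stage handles in minutes.

`bin_cells_to_spots()` coarsens the tissue the way spot-based ST coarsens a
section: square-grid bins, with the bin side searched (geometric bisection)
until the realized mean cells per occupied spot is within 10% of the
target; spot expression is the exact sum of member-cell counts, the spot
coordinate is the bin center, empty bins are dropped, and the ground-truth
cell→spot table is returned. `perturb_expression()` mimics cross-platform
technical variability: per cell, exactly `floor(pt·g)` genes are sampled
without replacement and each selected count is multiplied by $2^z$,
$z \sim \mathcal N(0,1)$, then re-rounded to a non-negative integer so
count semantics (and CPM normalization) stay valid. The multiplicative
reading of the noise is the only one that cannot produce negative counts;
perturbing per cell (rather than one shared gene set) follows the
per-cell selection language of the protocol this emulates.

Deliberate simplifications, and hence limits on what passing checks show
about real data: within a type, cells are i.i.d. draws from one program —
there are no continuous sub-states, no library-size gradients, and no
platform-specific gene dropout; spot boundaries are square, not hexagonal;
and the scRNA-seq copy contains exactly the binned cells, so every cell has
a true spot. On real data the reference and the section share cell
*populations* but not cell *identities*, so exact-spot precision is not an
observable there; the simulation is the setting where it is.

## Numerical choices and degenerate inputs

* KL direction is KL(cell‖spot), following the argument order; profiles are
  smoothed with ε = 1e-10 and renormalized before the divergence, so
  one-hot profiles give large finite costs rather than infinities.
* The probability vectors feeding KL come from the normalized
  (`cpm_log2`) layer renormalized to sum 1 per row.
* Mapping logits initialize at the log-proportions of `N` plus Gaussian
  jitter (sd 0.01, seeded): rows start near `N/ΣN`, the natural prior that
  big spots attract more mass, without hard-coding it.
* Ties break toward the lower index everywhere (kNN, regular top-N, greedy
  argmax), making every path deterministic.
* Zero-variance embedding rows get Pearson distance 1 (uncorrelated) with a
  warning; zero nucleus counts are raised to 1 so every spot stays
  mappable; all-zero expression rows, empty gene intersections, and
  degenerate UMI anchors are hard errors with actionable messages.
* The row softmax subtracts the row maximum before exponentiating; since
  attention relevances pass through a sigmoid first, the attention softmax
  needs no such guard.
* Cost matrices are dense m × w; the intended scale is desk scale
  (m·w up to ~10⁷ entries).

## Evaluation metrics

With the binning truth in hand, `pmap_precision()` (regular mapping) and
`ploc_precision()` (greedy) report, per cell type, the fraction of
assignments landing on the exact true spot — near-miss credit for adjacent
spots is deliberately not given, and duplicated cells count per assignment.
`celltype_error_rate()` compares each spot's predicted cell-type multiset
against the true one (minimal label mismatches; cardinality mismatches
count the excess as errors, with a warning) divided by the total cell
count. `proportion_pcc()` correlates predicted and true per-spot type
proportions, and `k_distance()` gives the mean distance from each query
cell to its k nearest reference cells — the proximity statistic used to
relate, e.g., mapped immune cells to tumor regions. Every metric is checked
in the test suite against an independent naive re-implementation.

## Known limitations

* Full-batch training keeps the implementation simple and exactly
  reproducible but bounds the practical size to tens of thousands of nodes;
  atlas-scale data would need neighbor sampling.
* The mapping objective is linear in **M** given the costs; it cannot model
  within-spot gene interactions or platform-specific noise beyond what the
  embeddings absorb.
* Independent per-spot top-N extraction can duplicate distinctive cells
  across neighboring spots; this is inherent to the regular-mapping
  contract, not a bug.
* The UMI→cell-count rule is a two-point linear heuristic; where H&E
  nucleus counts exist they should be preferred
  (`cells_per_spot_from_counts()`).
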