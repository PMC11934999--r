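# spotmap

Single-cell resolution for spatial transcriptomics by mapping scRNA-seq
cells onto ST spots.

Sequencing-based spatial transcriptomics (ST) platforms such as 10x Visium
measure expression at capture spots that each cover several cells, while
scRNA-seq resolves single cells but loses their positions. `spotmap` joins
the two: given a cells × genes scRNA-seq count matrix and a spots × genes ST
count matrix with spot coordinates, it learns which cells belong on which
spots. Two complementary outputs are supported:

* **regular mapping** — fill every spot *j* with its estimated number of
  cells *N<sub>j</sub>*, reconstructing the spot's single-cell composition
  (a cell may be used by several spots, or not at all);
* **greedy mapping** — give every scRNA-seq cell a spatial location by
  assigning it to its best-scoring spot.

Intended users are computational biologists analysing matched
scRNA-seq + ST data, and methodologists who need a ground-truthed simulation
and evaluation harness for cell-to-spot assignment.

## Method

After shared preprocessing (drop genes detected in ≤ 1 cell/spot, restrict
to common genes, CPM + log2 normalization), the package:

1. **Estimates cells per spot** N = [n₁…n_w] from per-spot UMI totals with a
   two-anchor linear rule (minimum-UMI spot ↦ 1 cell, median-UMI spot ↦ the
   mean cells per spot, default 5), or accepts nucleus counts from H&E
   segmentation.
2. **Embeds cells and spots** with a graph attention autoencoder (GATE) over
   an expression kNN graph (cells) and a spatial kNN graph (spots). Each
   encoder layer aggregates neighbours with learned softmax attention,

   h_i⁽ᵏ⁾ = Σ_{j∈A_i} α_ij⁽ᵏ⁾ σ(W⁽ᵏ⁾ h_j⁽ᵏ⁻¹⁾),
   α_ij = softmax_j( sigmoid(v_sᵀ σ(W h_i) + v_tᵀ σ(W h_j)) ),

   and a transpose-tied decoder minimises Σᵢ‖xᵢ − x̂ᵢ‖². By default one
   autoencoder is trained jointly on cells and spots (block-diagonal graph)
   so both modalities share a latent space.
3. **Learns an m × w row-stochastic mapping matrix** M (row softmax of free
   logits, Adam-optimized) by minimising the three-term objective

   L = Σ_ij KL(Cᵢ‖Sⱼ) M_ij + Σ_ij D_ij M_ij + λ (1/w) Σ_j |N_j − Σ_i M_ij|,

   with D_ij = 1 − PCC(Z_i^sc, Z_j^st) the Pearson distance in embedding
   space and λ = 0.1 the calibrated quantity-constraint weight.
4. **Extracts assignments**: top-N_j cells per spot (regular) or argmax spot
   per cell (greedy), plus per-spot cell-type proportions when annotations
   are available.

A simulator (`generate_synthetic_tissue`, `bin_cells_to_spots`,
`perturb_expression`) produces ground-truthed test data by binning located
cells into multi-cell spots and perturbing a per-cell fraction of gene
counts with multiplicative 2^z noise (z ~ N(0,1)); evaluation metrics
(`pmap_precision`, `ploc_precision`, `celltype_error_rate`,
`proportion_pcc`, `k_distance`) score the results.

## Worked example

```r
library(spotmap)

tissue <- generate_synthetic_tissue(n_types = 4, cells_per_type = 60,
                                    n_genes = 200, n_markers_per_type = 15,
                                    seed = 7)
st  <- bin_cells_to_spots(tissue, target_mean_cells = 5)
fit <- spotmap(tissue$cells, st$spots, st$geometry,
               annotation = tissue$annotation,
               gate_dims = c(64, 24), gate_epochs = 80, gate_lr = 1e-3,
               map_epochs = 400, seed = 7)
fit
#> Single-cell-to-spot mapping: 240 cells x 48 spots
#>   genes used: 200 | lambda = 0.1 | embedding: joint | seed 7
#>   mapping loss: 129.0716 -> 62.6019 (400 epochs)
#>   regular: 228 assignments | greedy: 240 assignments

median(pmap_precision(fit$regular, st$truth, tissue$annotation))
#> [1] 0.6854202
```

The printed fit reports the optimized three-term loss and the sizes of the
two assignment sets: 228 regular assignments (= Σ N_j, the UMI-estimated
cell counts over the 48 spots) and one greedy assignment per cell. The
median per-type `pmap_precision` of 0.69 means that, for the median cell
type, 69% of the regular assignments land on the exact spot the cell was
binned into — against a random-assignment baseline of 1/48 ≈ 0.02. `summary(fit)`, `coef(fit)` (the mapping matrix),
`residuals(fit)` (per-spot quantity gaps) and `plot(fit)` give further
views; `run_pipeline()` drives the same workflow from files on disk.

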