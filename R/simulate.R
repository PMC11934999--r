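#' Generate a spatially organized synthetic tissue
#'
#' Draws annotated single cells with negative-binomial expression programs.
#' Each cell type has its own mean-expression program: a shared baseline
#' (log-normal gene means) with a set of marker genes whose means are
#' multiplied by `marker_fold` in the owning type. Cell coordinates place
#' types either in coherent spatial patches (Gaussian clouds around grid
#' centers in the unit square) or along an x-axis gradient.
#'
#' @param n_types Number of cell types.
#' @param cells_per_type Cells drawn per type.
#' @param n_genes Total genes.
#' @param n_markers_per_type Marker genes per type
#'   (`n_markers_per_type * n_types <= n_genes`).
#' @param spatial_layout `"patches"` (default) or `"gradient"`.
#' @param seed Integer seed; the tissue is deterministic given the seed.
#' @param marker_fold Fold change of marker means in their own type
#'   (default 5).
#' @param base_meanlog,base_sdlog Log-normal parameters of the baseline gene
#'   means (default `log(2)`, 1; about 1600 counts per cell at 500 genes).
#' @param nb_size Negative-binomial size (dispersion) parameter (default 2).
#' @return An object of class `synthetic_tissue`: `cells`
#'   ([expression_matrix()], raw counts), `annotation`
#'   ([cell_annotation()]), `coords` (cells x 2 matrix),
#'   `type_programs` (types x genes mean matrix), `seed`.
#' @export
generate_synthetic_tissue <- function(n_types = 8, cells_per_type = 200,
                                      n_genes = 500, n_markers_per_type = 25,
                                      spatial_layout = c("patches", "gradient"),
                                      seed = 1, marker_fold = 5,
                                      base_meanlog = log(2), base_sdlog = 1,
                                      nb_size = 2) {
  spatial_layout <- match.arg(spatial_layout)
  if (n_markers_per_type * n_types > n_genes)
    stop("n_markers_per_type * n_types exceeds n_genes", call. = FALSE)
  if (n_types < 1 || cells_per_type < 1) stop("invalid sizes", call. = FALSE)
  set.seed(as.integer(seed))
  base <- stats::rlnorm(n_genes, meanlog = base_meanlog, sdlog = base_sdlog)
  programs <- matrix(rep(base, each = n_types), n_types, n_genes)
  marker_of <- rep(NA_integer_, n_genes)
  for (t in seq_len(n_types)) {
    idx <- ((t - 1) * n_markers_per_type + 1):(t * n_markers_per_type)
    programs[t, idx] <- programs[t, idx] * marker_fold
    marker_of[idx] <- t
  }
  n_cells <- n_types * cells_per_type
  type <- rep(seq_len(n_types), each = cells_per_type)
  counts <- matrix(0, n_cells, n_genes)
  for (t in seq_len(n_types)) {
    rows <- which(type == t)
    counts[rows, ] <- matrix(
      stats::rnbinom(length(rows) * n_genes, size = nb_size,
                     mu = rep(programs[t, ], each = length(rows))),
      length(rows), n_genes)
  }
  coords <- switch(spatial_layout,
    patches = {
      g <- ceiling(sqrt(n_types))
      centers <- cbind(((seq_len(n_types) - 1) %% g + 0.5) / g,
                       ((seq_len(n_types) - 1) %/% g + 0.5) / g)
      xy <- centers[type, , drop = FALSE] +
        matrix(stats::rnorm(2 * n_cells, 0, 0.45 / g), n_cells, 2)
      pmin(pmax(xy, 0), 1)
    },
    gradient = {
      x <- (type - 0.5) / n_types + stats::rnorm(n_cells, 0, 0.35 / n_types)
      cbind(pmin(pmax(x, 0), 1), stats::runif(n_cells))
    })
  colnames(coords) <- c("x", "y")
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  rownames(coords) <- cell_ids
  structure(list(
    cells = expression_matrix(counts, row_ids = cell_ids, gene_ids = gene_ids,
                              layer = "raw_counts", modality = "sc"),
    annotation = cell_annotation(cell_ids, paste0("type_", type)),
    coords = coords,
    type_programs = `dimnames<-`(programs,
                                 list(paste0("type_", seq_len(n_types)), gene_ids)),
    marker_type = marker_of,
    seed = as.integer(seed)), class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("<synthetic_tissue> %d cells, %d genes, %d types (seed %d)\n",
              nrow(x$cells$values), ncol(x$cells$values),
              length(unique(x$annotation$cell_type)), x$seed))
  invisible(x)
}

#' Bin located cells into multi-cell ST spots
#'
#' Emulates how higher-resolution data with known cell locations is coarsened
#' into spot-level ST data: cells are binned on a square grid whose side
#' length is searched so that the realized mean number of cells per occupied
#' spot comes within 10% of `target_mean_cells`. A spot's expression is the
#' sum of its member cells' raw counts, its coordinate is the bin center, and
#' empty bins are dropped. The true cell-to-spot table is returned alongside.
#'
#' @param tissue A [generate_synthetic_tissue()] result (or any list with
#'   `cells` and `coords` in the same shape).
#' @param target_mean_cells Desired mean cells per occupied spot (>= 1).
#' @return An object of class `simulated_st`: `spots`
#'   ([expression_matrix()], raw counts, modality `"st"`), `geometry`
#'   ([spot_geometry()]), `truth` (data frame `cell_id`, `spot_id`),
#'   `mean_cells_per_spot` (realized), `bin_side`.
#' @export
bin_cells_to_spots <- function(tissue, target_mean_cells) {
  n_cells <- nrow(tissue$cells$values)
  if (target_mean_cells < 1) stop("target_mean_cells must be >= 1", call. = FALSE)
  if (target_mean_cells > n_cells)
    stop("target_mean_cells exceeds the number of cells", call. = FALSE)
  xy <- tissue$coords
  span <- max(apply(xy, 2, function(v) diff(range(v))), .Machine$double.eps)
  realized <- function(side) {
    bx <- floor((xy[, 1] - min(xy[, 1])) / side)
    by <- floor((xy[, 2] - min(xy[, 2])) / side)
    bins <- paste(bx, by)
    n_cells / length(unique(bins))
  }
  lo <- span / (2 * ceiling(sqrt(n_cells)))   # ~1 cell per bin
  hi <- 2 * span                              # everything in one bin
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    if (realized(mid) < target_mean_cells) lo <- mid else hi <- mid
  }
  side <- hi
  if (abs(realized(side) - target_mean_cells) / target_mean_cells > 0.1)
    side <- if (abs(realized(lo) - target_mean_cells) <
                abs(realized(hi) - target_mean_cells)) lo else hi
  if (abs(realized(side) - target_mean_cells) / target_mean_cells > 0.1)
    stop("no bin side achieves the target mean cells per spot within 10%",
         call. = FALSE)
  bx <- floor((xy[, 1] - min(xy[, 1])) / side)
  by <- floor((xy[, 2] - min(xy[, 2])) / side)
  bin_key <- paste(bx, by, sep = "_")
  bins <- sort(unique(bin_key))
  spot_of_cell <- match(bin_key, bins)
  spot_ids <- sprintf("spot_%03d", seq_along(bins))
  expr <- rowsum(tissue$cells$values, spot_of_cell)
  centers <- cbind(
    (as.numeric(sub("_.*", "", bins)) + 0.5) * side + min(xy[, 1]),
    (as.numeric(sub(".*_", "", bins)) + 0.5) * side + min(xy[, 2]))
  structure(list(
    spots = expression_matrix(expr, row_ids = spot_ids,
                              gene_ids = tissue$cells$gene_ids,
                              layer = "raw_counts", modality = "st"),
    geometry = spot_geometry(spot_ids, centers),
    truth = data.frame(cell_id = tissue$cells$row_ids,
                       spot_id = spot_ids[spot_of_cell]),
    mean_cells_per_spot = n_cells / length(bins),
    bin_side = side), class = "simulated_st")
}

#' @export
print.simulated_st <- function(x, ...) {
  cat(sprintf("<simulated_st> %d spots, mean %.2f cells/spot (bin side %.3g)\n",
              nrow(x$spots$values), x$mean_cells_per_spot, x$bin_side))
  invisible(x)
}

#' Multiplicative gene-perturbation noise
#'
#' Emulates technical variability between platforms: independently for each
#' cell, a uniformly random fraction `pt` of genes (exactly
#' `floor(pt * n_genes)` per cell, sampled without replacement) is selected
#' and each selected count `x` is replaced by `round(x * 2^z)` with
#' `z ~ Normal(0, 1)`.
#'
#' @param E [expression_matrix()] with layer `"raw_counts"`.
#' @param pt Fraction of genes to perturb per cell, in `[0, 1]`.
#' @param seed Integer seed; the perturbation is reproducible.
#' @return The perturbed matrix (raw counts, non-negative integers).
#' @export
perturb_expression <- function(E, pt, seed = 1) {
  validate_expr_matrix(E)
  if (E$layer != "raw_counts")
    stop("perturb_expression expects raw counts", call. = FALSE)
  if (!is.finite(pt) || pt < 0 || pt > 1)
    stop("pt must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  V <- E$values
  g <- ncol(V)
  n_sel <- floor(pt * g)
  if (n_sel > 0) {
    for (i in seq_len(nrow(V))) {
      sel <- sample.int(g, n_sel)
      V[i, sel] <- pmax(0, round(V[i, sel] * 2^stats::rnorm(n_sel)))
    }
  }
  expression_matrix(V, row_ids = E$row_ids, gene_ids = E$gene_ids,
                    layer = "raw_counts", modality = E$modality)
}
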