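#' Map single cells onto spatial transcriptomics spots
#'
#' The main fitting function. Starting from raw scRNA-seq counts (cells x
#' genes) and raw ST counts (spots x genes) with spot coordinates, it
#' (1) filters rare genes, restricts both matrices to common genes and
#' CPM-log2 normalizes them; (2) estimates the expected number of cells per
#' spot (UMI two-anchor rule, external nucleus counts, or a constant);
#' (3) learns low-dimensional embeddings with a graph attention autoencoder
#' over an expression kNN graph (cells) and a spatial kNN graph (spots);
#' (4) learns an m x w row-stochastic mapping matrix by minimizing the
#' three-term objective (KL expression divergence + embedding Pearson
#' distance + lambda-weighted cell-quantity constraint) with Adam; and
#' (5) extracts regular (top-`N_j` cells per spot) and greedy (argmax spot
#' per cell) assignments.
#'
#' By default one autoencoder is trained jointly on the concatenated cell and
#' spot profiles over a block-diagonal graph, so both modalities share one
#' latent space and their embeddings are directly comparable by Pearson
#' correlation. `embedding = "separate"` trains two autoencoders of equal
#' width instead; `embedding = "none"` drops the embedding term from the
#' objective.
#'
#' @param sc scRNA-seq [expression_matrix()] (layer `"raw_counts"`).
#' @param st ST [expression_matrix()] (layer `"raw_counts"`).
#' @param geometry [spot_geometry()] for the ST spots.
#' @param annotation Optional [cell_annotation()]; only used by summaries and
#'   proportion outputs, never by the mapping itself.
#' @param cells_per_spot Optional [cells_per_spot()]; when `NULL`, counts are
#'   estimated from UMI totals with [estimate_cells_per_spot_umi()].
#' @param mean_cells Mean cells per spot for the UMI estimate (default 5).
#' @param lambda Weight of the cell-quantity constraint (default 0.1, the
#'   calibrated value).
#' @param embedding `"joint"` (default), `"separate"`, or `"none"`.
#' @param gate_dims,gate_epochs,gate_lr Autoencoder architecture and training
#'   settings (defaults `c(512, 30)`, 500, 1e-4).
#' @param k_expression,k_spatial Neighbor counts of the cell expression graph
#'   (default 15) and the spot spatial graph (default 6).
#' @param map_epochs,map_lr Mapping optimization settings (defaults 1000,
#'   0.01).
#' @param seed Single integer seed driving every stochastic step.
#' @param verbose Print stage progress.
#' @return An object of class `spotmap` with components `M` (the mapping
#'   matrix), `regular` and `greedy` (`mapping_result`s), `N`
#'   ([cells_per_spot()]), `costs` (list `kl`, `D`), `embeddings` (list
#'   `sc`, `st`), `losses` (list `gate`, `mapping`), `geometry`,
#'   `annotation`, `config`, and `call`.
#' @seealso [pmap_precision()], [ploc_precision()],
#'   [spot_celltype_proportions()], [run_pipeline()]
#' @export
#' @examples
#' tissue <- generate_synthetic_tissue(n_types = 3, cells_per_type = 40,
#'                                     n_genes = 120, n_markers_per_type = 10,
#'                                     seed = 7)
#' st <- bin_cells_to_spots(tissue, target_mean_cells = 4)
#' fit <- spotmap(tissue$cells, st$spots, st$geometry,
#'                annotation = tissue$annotation,
#'                gate_dims = c(32, 16), gate_epochs = 30, map_epochs = 150,
#'                seed = 7)
#' fit
#' median(pmap_precision(fit$regular, st$truth, tissue$annotation))
spotmap <- function(sc, st, geometry, annotation = NULL,
                    cells_per_spot = NULL, mean_cells = 5, lambda = 0.1,
                    embedding = c("joint", "separate", "none"),
                    gate_dims = c(512, 30), gate_epochs = 500, gate_lr = 1e-4,
                    k_expression = 15, k_spatial = 6,
                    map_epochs = 1000, map_lr = 0.01,
                    seed = 1, verbose = FALSE) {
  embedding <- match.arg(embedding)
  cl <- match.call()
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(sc, "expr_matrix"), inherits(st, "expr_matrix"),
            inherits(geometry, "spot_geometry"))
  if (!identical(geometry$spot_ids, st$row_ids))
    stop("geometry spot_ids must match the ST matrix rows", call. = FALSE)

  say("preprocessing: gene filtering + CPM-log2 normalization")
  sc_f <- filter_rare_genes(sc)
  st_f <- filter_rare_genes(st)
  common <- intersect_genes(sc_f, st_f)
  C_raw <- common$C; S_raw <- common$S
  C <- normalize_cpm_log2(C_raw)
  S <- normalize_cpm_log2(S_raw)

  say("estimating cells per spot")
  N <- cells_per_spot %||%
    estimate_cells_per_spot_umi(S_raw, mean_cells = mean_cells)
  if (!identical(N$spot_ids, st$row_ids))
    stop("cells_per_spot spot_ids must match the ST matrix rows", call. = FALSE)

  say("building graphs (k_expression = %d, k_spatial = %d)",
      k_expression, k_spatial)
  g_sc <- build_expression_knn_graph(C, k = min(k_expression, nrow(C$values) - 1))
  g_st <- build_spatial_graph(geometry, k = min(k_spatial, nrow(S$values) - 1))

  gate_losses <- NULL
  Z_sc <- NULL; Z_st <- NULL; D <- NULL
  if (embedding == "joint") {
    say("training joint graph attention autoencoder (dims %s, %d epochs)",
        paste(gate_dims, collapse = "-"), gate_epochs)
    X <- rbind(C$values, S$values)
    g_all <- graph_disjoint_union(g_sc, g_st)
    fit <- train_gate(X, g_all, dims = gate_dims, epochs = gate_epochs,
                      lr = gate_lr, seed = seed)
    m <- nrow(C$values)
    Z_sc <- fit$embedding[seq_len(m), , drop = FALSE]
    Z_st <- fit$embedding[m + seq_len(nrow(S$values)), , drop = FALSE]
    gate_losses <- list(joint = fit$losses)
  } else if (embedding == "separate") {
    say("training separate graph attention autoencoders")
    fit_sc <- train_gate(C, g_sc, dims = gate_dims, epochs = gate_epochs,
                         lr = gate_lr, seed = seed)
    fit_st <- train_gate(S, g_st, dims = gate_dims, epochs = gate_epochs,
                         lr = gate_lr, seed = seed + 1L)
    Z_sc <- fit_sc$embedding; Z_st <- fit_st$embedding
    gate_losses <- list(sc = fit_sc$losses, st = fit_st$losses)
  }

  say("building cost matrices")
  kl <- kl_cost_matrix(C, S)
  if (!is.null(Z_sc)) D <- pearson_distance_matrix(Z_sc, Z_st)

  say("optimizing the mapping matrix (lambda = %g, %d epochs)",
      lambda, map_epochs)
  M <- optimize_mapping(kl, D, N, lam = lambda, epochs = map_epochs,
                        lr = map_lr, seed = seed)

  structure(list(
    M = M,
    regular = extract_regular(M, N),
    greedy = extract_greedy(M),
    N = N,
    costs = list(kl = kl, D = D),
    embeddings = list(sc = Z_sc, st = Z_st),
    losses = list(gate = gate_losses, mapping = M$losses),
    geometry = geometry,
    annotation = annotation,
    genes = C$gene_ids,
    config = list(mean_cells = mean_cells, lambda = lambda,
                  embedding = embedding, gate_dims = gate_dims,
                  gate_epochs = gate_epochs, gate_lr = gate_lr,
                  k_expression = k_expression, k_spatial = k_spatial,
                  map_epochs = map_epochs, map_lr = map_lr, seed = seed),
    call = cl), class = "spotmap")
}

#' @export
print.spotmap <- function(x, ...) {
  m <- nrow(x$M$M); w <- ncol(x$M$M)
  cat(sprintf("Single-cell-to-spot mapping: %d cells x %d spots\n", m, w))
  cat(sprintf("  genes used: %d | lambda = %g | embedding: %s | seed %d\n",
              length(x$genes), x$config$lambda, x$config$embedding,
              x$config$seed))
  cat(sprintf("  mapping loss: %.4f -> %.4f (%d epochs)\n",
              x$losses$mapping[1], x$losses$mapping[length(x$losses$mapping)],
              length(x$losses$mapping) - 1))
  cat(sprintf("  regular: %d assignments | greedy: %d assignments\n",
              nrow(x$regular$assignments), nrow(x$greedy$assignments)))
  invisible(x)
}

#' @export
summary.spotmap <- function(object, ...) {
  M <- object$M$M
  gap <- object$N$counts - colSums(M)
  occ <- table(factor(object$greedy$assignments$spot_id,
                      levels = object$N$spot_ids))
  out <- list(
    n_cells = nrow(M), n_spots = ncol(M), n_genes = length(object$genes),
    expected_cells = sum(object$N$counts),
    quantity_gap = mean(abs(gap)),
    score_concentration = mean(apply(M, 1, max)),
    greedy_occupied = sum(occ > 0),
    final_loss = object$losses$mapping[length(object$losses$mapping)],
    config = object$config)
  class(out) <- "summary.spotmap"
  out
}

#' @export
print.summary.spotmap <- function(x, ...) {
  cat(sprintf("spotmap fit: %d cells -> %d spots over %d genes\n",
              x$n_cells, x$n_spots, x$n_genes))
  cat(sprintf("  expected cells (sum N_j): %d\n", x$expected_cells))
  cat(sprintf("  mean |N_j - column mass|: %.3f\n", x$quantity_gap))
  cat(sprintf("  mean max row score:       %.3f\n", x$score_concentration))
  cat(sprintf("  spots receiving >=1 cell (greedy): %d / %d\n",
              x$greedy_occupied, x$n_spots))
  cat(sprintf("  final mapping loss: %.4f\n", x$final_loss))
  invisible(x)
}

#' @export
#' @rdname spotmap
#' @param object,x A `spotmap` fit.
#' @param ... Unused.
coef.spotmap <- function(object, ...) object$M$M

#' Plot a mapping fit
#'
#' Scatter of spot locations sized by their expected cell count, with mapped
#' cells (greedy assignment) jittered around their assigned spot and colored
#' by cell type when an annotation is available.
#'
#' @param x A [spotmap()] fit.
#' @param mode `"greedy"` (default) or `"regular"`: which assignment set to
#'   draw.
#' @param jitter Spatial jitter radius as a fraction of the median
#'   nearest-spot distance (default 0.3).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spotmap <- function(x, mode = c("greedy", "regular"), jitter = 0.3, ...) {
  mode <- match.arg(mode)
  res <- if (mode == "greedy") x$greedy else x$regular
  xy <- x$geometry$coords
  d <- stats::dist(xy)
  step <- stats::median(as.numeric(d)[as.numeric(d) > 0]) * jitter
  graphics::plot(xy, pch = 1, col = "grey60", cex = 0.8, asp = 1,
                 xlab = "x", ylab = "y",
                 main = sprintf("%s mapping (%d assignments)", mode,
                                nrow(res$assignments)), ...)
  at <- xy[match(res$assignments$spot_id, x$geometry$spot_ids), , drop = FALSE]
  at <- at + matrix(stats::rnorm(length(at), 0, step / 2), nrow(at), 2)
  col <- if (!is.null(x$annotation)) {
    type <- annotation_lookup(x$annotation, res$assignments$cell_id)
    lv <- sort(unique(x$annotation$cell_type))
    pal <- grDevices::hcl.colors(max(3, length(lv)), "Dark 3")
    pal[match(type, lv)]
  } else "#00688B88"
  graphics::points(at, pch = 16, cex = 0.5, col = col)
  invisible(x)
}

#' Residual quantity gaps of a mapping fit
#'
#' The per-spot difference between the expected cell count and the mapping
#' matrix's column mass, `N_j - sum_i M_ij` — the quantity the lambda term
#' penalizes.
#'
#' @param object A [spotmap()] fit.
#' @param ... Unused.
#' @return Named numeric vector, one entry per spot.
#' @export
residuals.spotmap <- function(object, ...) {
  r <- object$N$counts - colSums(object$M$M)
  names(r) <- object$N$spot_ids
  r
}
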