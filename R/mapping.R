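#' Kullback-Leibler cost matrix between cells and spots
#'
#' Each cell's and each spot's normalized expression profile is converted to
#' a probability vector over genes (epsilon-smoothed, renormalized) and the
#' cost is `kl_ij = sum_g p_i(g) log(p_i(g)/q_j(g))`, i.e. KL(cell || spot).
#' Cells and spots with smaller divergence get higher mapping scores during
#' optimization.
#'
#' @param C,S [expression_matrix()] objects with layer `"cpm_log2"` and
#'   identical gene columns.
#' @param eps Smoothing constant added to every entry before renormalization
#'   (default 1e-10).
#' @return An m x w numeric matrix (cells x spots), non-negative.
#' @export
kl_cost_matrix <- function(C, S, eps = 1e-10) {
  validate_expr_matrix(C); validate_expr_matrix(S)
  if (!identical(C$gene_ids, S$gene_ids))
    stop("C and S must share the same gene columns (see intersect_genes)",
         call. = FALSE)
  P <- prob_rows(C$values, eps)
  Q <- prob_rows(S$values, eps)
  # kl_ij = sum_g P_ig log P_ig - sum_g P_ig log Q_jg
  ent <- rowSums(P * log(P))
  kl <- ent - P %*% t(log(Q))
  kl <- pmax(kl, 0)                 # guard tiny negative round-off
  dimnames(kl) <- list(C$row_ids, S$row_ids)
  kl
}

prob_rows <- function(V, eps) {
  V <- V + eps
  V / rowSums(V)
}

#' Pearson distance matrix between embeddings
#'
#' `D_ij = 1 - PCC(Z_sc[i, ], Z_st[j, ])`, the Pearson distance between a
#' cell's and a spot's embedding vector; values lie in `[0, 2]`.
#' Zero-variance embedding rows get `D = 1` (uncorrelated) with a warning.
#'
#' @param Z_sc Cell embedding matrix (m x d), `d >= 2`.
#' @param Z_st Spot embedding matrix (w x d).
#' @return An m x w numeric matrix.
#' @export
pearson_distance_matrix <- function(Z_sc, Z_st) {
  Z_sc <- as.matrix(Z_sc); Z_st <- as.matrix(Z_st)
  if (ncol(Z_sc) != ncol(Z_st))
    stop("embedding dimensions differ", call. = FALSE)
  if (ncol(Z_sc) < 2) stop("embedding dimension must be >= 2", call. = FALSE)
  sd_sc <- apply(Z_sc, 1, stats::sd)
  sd_st <- apply(Z_st, 1, stats::sd)
  flat <- sd_sc == 0
  flat_st <- sd_st == 0
  if (any(flat) || any(flat_st))
    warning("zero-variance embedding rows; their Pearson distance is set to 1")
  # avoid 0/0; flagged rows are overwritten below
  sd_sc[flat] <- 1; sd_st[flat_st] <- 1
  A <- (Z_sc - rowMeans(Z_sc)) / sd_sc
  B <- (Z_st - rowMeans(Z_st)) / sd_st
  D <- 1 - tcrossprod(A, B) / (ncol(Z_sc) - 1)
  D[flat, ] <- 1
  D[, flat_st] <- 1
  pmin(pmax(D, 0), 2)
}

#' Initialize the mapping matrix from estimated cell counts
#'
#' Logits start at the log-proportions of the expected cells per spot (so
#' each row of the softmax begins near `N / sum(N)`) plus a small seeded
#' Gaussian jitter that breaks symmetry.
#'
#' @param N A [cells_per_spot()].
#' @param m Number of cells.
#' @param seed Integer seed for the jitter.
#' @param jitter_sd Standard deviation of the jitter (default 0.01).
#' @return An object of class `mapping_matrix`: list with `logits` and the
#'   row-softmax `M` (both m x w).
#' @export
init_mapping <- function(N, m, seed = 1, jitter_sd = 0.01) {
  w <- length(N$counts)
  base <- log(N$counts / sum(N$counts))
  set.seed(as.integer(seed))
  logits <- matrix(base, m, w, byrow = TRUE) +
    matrix(stats::rnorm(m * w, 0, jitter_sd), m, w)
  colnames(logits) <- N$spot_ids
  mapping_matrix(logits)
}

mapping_matrix <- function(logits) {
  structure(list(logits = logits, M = row_softmax(logits)),
            class = "mapping_matrix")
}

row_softmax <- function(L) {
  E <- exp(L - apply(L, 1, max))
  E / rowSums(E)
}

#' Three-term mapping objective
#'
#' `L = sum_ij kl_ij M_ij + sum_ij D_ij M_ij +
#'  lambda * (1/w) * sum_j |N_j - colsum_j(M)|`:
#' an expression term, an embedding term, and the cell-quantity constraint
#' that ties each spot's mapped mass to its expected cell count.
#'
#' @param M m x w row-stochastic matrix (or a `mapping_matrix`).
#' @param kl m x w KL cost matrix ([kl_cost_matrix()]).
#' @param D m x w Pearson distance matrix ([pearson_distance_matrix()]), or
#'   `NULL`/0 to drop the embedding term.
#' @param N A [cells_per_spot()] (or numeric vector of counts).
#' @param lam Weight of the quantity term (default 0.1).
#' @return The scalar loss.
#' @export
mapping_loss <- function(M, kl, D, N, lam = 0.1) {
  if (inherits(M, "mapping_matrix")) M <- M$M
  counts <- if (inherits(N, "cells_per_spot")) N$counts else as.numeric(N)
  if (is.null(D)) D <- 0
  if (!all(is.finite(M)) || !all(is.finite(kl)))
    stop("non-finite inputs to mapping_loss", call. = FALSE)
  w <- ncol(M)
  sum(kl * M) + sum(D * M) + lam * sum(abs(counts - colSums(M))) / w
}

#' Learn the mapping matrix
#'
#' Adam gradient descent on the logits of a row-softmax mapping matrix,
#' minimizing [mapping_loss()]. With a fixed seed the optimization is
#' reproducible; the final loss never exceeds the initial loss.
#'
#' @inheritParams mapping_loss
#' @param kl,D Cost matrices; `D = NULL` drops the embedding term.
#' @param N A [cells_per_spot()].
#' @param lam Quantity-term weight (default 0.1, the calibrated value).
#' @param epochs Adam steps (default 1000).
#' @param lr Adam learning rate (default 0.01).
#' @param seed Seed for the initialization jitter.
#' @param init Optional `mapping_matrix` to start from (default
#'   [init_mapping()] from `N`).
#' @return A `mapping_matrix` whose element `losses` records the trajectory
#'   (position 1 = initial loss).
#' @export
optimize_mapping <- function(kl, D, N, lam = 0.1, epochs = 1000, lr = 0.01,
                             seed = 1, init = NULL) {
  counts <- N$counts
  m <- nrow(kl); w <- ncol(kl)
  if (length(counts) != w) stop("N length does not match spot count", call. = FALSE)
  cost <- kl + if (is.null(D)) 0 else D
  if (!all(is.finite(cost))) stop("non-finite cost matrix", call. = FALSE)
  mm <- if (is.null(init)) init_mapping(N, m, seed = seed) else init
  logits <- mm$logits
  M <- row_softmax(logits)
  losses <- numeric(epochs + 1)
  losses[1] <- sum(cost * M) + lam * sum(abs(counts - colSums(M))) / w
  ma <- array(0, dim(logits)); va <- ma
  for (ep in seq_len(epochs)) {
    gap <- counts - colSums(M)
    # dLoss/dM = cost - (lam/w) * sign(gap) per column
    dM <- sweep(cost, 2, (lam / w) * sign(gap), `-`)
    # softmax backward per row
    dL <- M * (dM - rowSums(M * dM))
    ma <- 0.9 * ma + 0.1 * dL
    va <- 0.999 * va + 0.001 * dL^2
    mhat <- ma / (1 - 0.9^ep)
    vhat <- va / (1 - 0.999^ep)
    logits <- logits - lr * mhat / (sqrt(vhat) + 1e-8)
    M <- row_softmax(logits)
    loss <- sum(cost * M) + lam * sum(abs(counts - colSums(M))) / w
    if (!is.finite(loss))
      stop("mapping optimization diverged at epoch ", ep, call. = FALSE)
    losses[ep + 1] <- loss
  }
  out <- mapping_matrix(logits)
  rownames(out$M) <- rownames(kl); rownames(out$logits) <- rownames(kl)
  colnames(out$M) <- N$spot_ids; colnames(out$logits) <- N$spot_ids
  out$losses <- losses
  out
}

mapping_result <- function(assignments, mode, cell_ids, spot_ids) {
  structure(list(assignments = assignments, mode = mode,
                 cell_ids = cell_ids, spot_ids = spot_ids),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> %s mode: %d assignments (%d cells, %d spots)\n",
              x$mode, nrow(x$assignments), length(x$cell_ids),
              length(x$spot_ids)))
  invisible(x)
}

#' Regular extraction: fill each spot with its expected number of cells
#'
#' For each spot `j` independently, the `N_j` cells with the highest mapping
#' scores in column `j` are selected (ties broken by lower cell index). A
#' cell may be mapped to several spots, and some cells may be left unmapped;
#' the result has exactly `sum(N)` assignments.
#'
#' @param M A `mapping_matrix` (from [optimize_mapping()]) or a plain m x w
#'   score matrix.
#' @param N A [cells_per_spot()].
#' @return A `mapping_result` with mode `"regular"`; `assignments` is a data
#'   frame with columns `cell_id`, `spot_id`, `score`.
#' @export
extract_regular <- function(M, N) {
  scores <- if (inherits(M, "mapping_matrix")) M$M else as.matrix(M)
  m <- nrow(scores); w <- ncol(scores)
  if (length(N$counts) != w) stop("N length does not match columns of M", call. = FALSE)
  if (any(N$counts > m))
    stop("a spot expects more cells than exist in the scRNA-seq data", call. = FALSE)
  cell_ids <- rownames(scores) %||% paste0("cell_", seq_len(m))
  picks <- lapply(seq_len(w), function(j) {
    top <- order(-scores[, j], seq_len(m))[seq_len(N$counts[j])]
    data.frame(cell_id = cell_ids[top], spot_id = N$spot_ids[j],
               score = scores[top, j])
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  mapping_result(out, "regular", cell_ids, N$spot_ids)
}

#' Greedy extraction: locate every cell
#'
#' Assigns each cell to the spot with its highest mapping score (ties broken
#' by lower spot index); exactly one assignment per cell.
#'
#' @inheritParams extract_regular
#' @param spot_ids Optional spot barcodes (defaults to `colnames(M)`).
#' @return A `mapping_result` with mode `"greedy"`.
#' @export
extract_greedy <- function(M, spot_ids = NULL) {
  scores <- if (inherits(M, "mapping_matrix")) M$M else as.matrix(M)
  m <- nrow(scores)
  cell_ids <- rownames(scores) %||% paste0("cell_", seq_len(m))
  spot_ids <- spot_ids %||% colnames(scores) %||% paste0("spot_", seq_len(ncol(scores)))
  best <- max.col(scores, ties.method = "first")
  out <- data.frame(cell_id = cell_ids, spot_id = spot_ids[best],
                    score = scores[cbind(seq_len(m), best)])
  mapping_result(out, "greedy", cell_ids, spot_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-spot cell-type proportions of a mapping result
#'
#' Sums the mapped cells per cell type within each spot and normalizes to
#' proportions. Spots that received no cells (possible in greedy mode) get an
#' all-zero row and are flagged in the `empty` column.
#'
#' @param R A `mapping_result`.
#' @param ann A [cell_annotation()] covering every mapped cell.
#' @return A data frame: one row per spot, one column per cell type
#'   (proportions summing to 1 for non-empty spots), plus columns `spot_id`,
#'   `n_cells` and `empty`.
#' @export
spot_celltype_proportions <- function(R, ann) {
  types <- annotation_lookup(ann, R$assignments$cell_id)
  lv <- sort(unique(ann$cell_type))
  tab <- table(factor(R$assignments$spot_id, levels = R$spot_ids),
               factor(types, levels = lv))
  counts <- matrix(as.numeric(tab), nrow = length(R$spot_ids),
                   dimnames = dimnames(tab))
  n <- rowSums(counts)
  prop <- counts / ifelse(n == 0, 1, n)
  out <- data.frame(spot_id = R$spot_ids, prop, n_cells = n, empty = n == 0,
                    check.names = FALSE, row.names = NULL)
  out
}
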