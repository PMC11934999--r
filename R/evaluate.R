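#' Per-type mapping precision (regular mapping)
#'
#' For each cell type, the fraction of regular-mapping assignments whose spot
#' exactly matches the cell's ground-truth spot:
#' `Pmap = N_T / N_map`, where `N_T` counts correct assignments and `N_map`
#' counts all assignments of that type with a known truth location.
#' Duplicated cells (mapped to several spots) are counted per assignment.
#'
#' @param R A `mapping_result` with mode `"regular"`.
#' @param truth Data frame with columns `cell_id`, `spot_id` (ground truth).
#' @param ann A [cell_annotation()].
#' @return Named numeric vector of Pmap per cell type, in `[0, 1]`; types
#'   with no mapped truth-covered cells are `NA`.
#' @export
pmap_precision <- function(R, truth, ann) {
  if (R$mode != "regular")
    stop("pmap_precision expects a regular mapping result", call. = FALSE)
  per_type_precision(R$assignments, truth, ann)
}

#' Per-type location precision (greedy mapping)
#'
#' `Ploc = N_t / N_ct`: per cell type, the fraction of cells assigned to
#' their true spot under greedy mapping.
#'
#' @inheritParams pmap_precision
#' @param R A `mapping_result` with mode `"greedy"`.
#' @return Named numeric vector of Ploc per cell type.
#' @export
ploc_precision <- function(R, truth, ann) {
  if (R$mode != "greedy")
    stop("ploc_precision expects a greedy mapping result", call. = FALSE)
  per_type_precision(R$assignments, truth, ann)
}

per_type_precision <- function(assign, truth, ann) {
  idx <- match(assign$cell_id, truth$cell_id)
  known <- !is.na(idx)
  assign <- assign[known, , drop = FALSE]
  correct <- assign$spot_id == truth$spot_id[idx[known]]
  type <- annotation_lookup(ann, assign$cell_id)
  lv <- sort(unique(ann$cell_type))
  n_map <- tapply(correct, factor(type, levels = lv), length)
  n_T <- tapply(correct, factor(type, levels = lv), sum)
  out <- as.numeric(n_T) / as.numeric(n_map)
  names(out) <- lv
  out
}

#' Cell-type misclassification error rate
#'
#' Compares, per spot, the multiset of predicted cell-type labels against the
#' ground-truth multiset (the types of the cells truly in that spot):
#' `N_error` is the number of labels that cannot be matched, and the error
#' rate is `sum(N_error) / N_cell` with `N_cell` the total number of cells in
#' the ST data. When predicted and true cardinalities differ at a spot, the
#' excess is counted as errors and a warning is raised.
#'
#' @param R A `mapping_result`.
#' @param truth_types Named list: per spot id, the character vector (multiset)
#'   of true cell types. Alternatively a `truth` data frame (`cell_id`,
#'   `spot_id`) combined with `ann` to derive it.
#' @param ann A [cell_annotation()] for the mapped cells.
#' @return The scalar error rate in `[0, 1]`.
#' @export
celltype_error_rate <- function(R, truth_types, ann) {
  if (is.data.frame(truth_types)) {
    tt <- annotation_lookup(ann, truth_types$cell_id)
    truth_types <- split(tt, truth_types$spot_id)
  }
  pred_types <- split(annotation_lookup(ann, R$assignments$cell_id),
                      R$assignments$spot_id)
  n_cell <- sum(lengths(truth_types))
  mismatched <- FALSE
  n_error <- 0
  for (s in names(truth_types)) {
    tru <- truth_types[[s]]
    prd <- pred_types[[s]]
    if (is.null(prd)) prd <- character(0)
    if (length(prd) != length(tru)) mismatched <- TRUE
    matched <- sum(pmin(table(factor(prd, levels = unique(c(prd, tru)))),
                        table(factor(tru, levels = unique(c(prd, tru))))))
    n_error <- n_error + max(length(prd), length(tru)) - matched
  }
  if (mismatched)
    warning("predicted and true per-spot cell counts differ; ",
            "excess cells counted as errors")
  n_error / n_cell
}

#' Agreement of predicted and true spot compositions
#'
#' Pearson correlation, per spot, between the predicted and true cell-type
#' proportion vectors (across types), plus their mean. Zero-variance rows
#' (e.g. a spot that is 100% one type in both tables) yield `NA` with a
#' warning.
#'
#' @param pred,true Data frames as returned by
#'   [spot_celltype_proportions()], or plain matrices (spots x types) with
#'   identical row and column order.
#' @return A list with `per_spot` (named numeric) and `mean` (over non-NA
#'   spots).
#' @export
proportion_pcc <- function(pred, true) {
  pm <- proportions_as_matrix(pred)
  tm <- proportions_as_matrix(true)
  if (!identical(dim(pm), dim(tm)) || !identical(colnames(pm), colnames(tm)))
    stop("prediction and truth tables have mismatched spots or types",
         call. = FALSE)
  per_spot <- vapply(seq_len(nrow(pm)), function(i) {
    if (stats::sd(pm[i, ]) == 0 || stats::sd(tm[i, ]) == 0) return(NA_real_)
    stats::cor(pm[i, ], tm[i, ])
  }, numeric(1))
  names(per_spot) <- rownames(pm)
  if (anyNA(per_spot)) warning("zero-variance proportion rows yield NA PCC")
  list(per_spot = per_spot, mean = mean(per_spot, na.rm = TRUE))
}

proportions_as_matrix <- function(x) {
  if (is.data.frame(x)) {
    keep <- setdiff(names(x), c("spot_id", "n_cells", "empty"))
    m <- as.matrix(x[, keep, drop = FALSE])
    rownames(m) <- x$spot_id
    m
  } else as.matrix(x)
}

#' K-distance spatial proximity
#'
#' For each query point, the mean Euclidean distance to its `k` nearest
#' reference points; used e.g. to quantify how close mapped immune cells lie
#' to tumor cells.
#'
#' @param query_coords,reference_coords Two-column matrices of coordinates.
#' @param k Number of nearest reference points (default 5).
#' @return Numeric vector, one mean distance per query point.
#' @export
k_distance <- function(query_coords, reference_coords, k = 5) {
  q <- as.matrix(query_coords); r <- as.matrix(reference_coords)
  if (k <= 0 || k > nrow(r))
    stop("k must be in 1..number of reference points", call. = FALSE)
  d2 <- outer(rowSums(q^2), rowSums(r^2), "+") - 2 * tcrossprod(q, r)
  d2 <- pmax(d2, 0)
  apply(d2, 1, function(row) mean(sqrt(sort(row)[seq_len(k)])))
}
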