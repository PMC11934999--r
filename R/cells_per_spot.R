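#' Cells-per-spot container
#'
#' Positive integer expected cell counts, one per ST spot.
#'
#' @param spot_ids Character vector of spot barcodes.
#' @param counts Integer vector (>= 1), one per spot.
#' @param source One of `"umi_linear"`, `"nucleus_counts"`, `"constant"`.
#' @return An object of class `cells_per_spot`.
#' @export
cells_per_spot <- function(spot_ids, counts,
                           source = c("umi_linear", "nucleus_counts", "constant")) {
  source <- match.arg(source)
  spot_ids <- as.character(spot_ids)
  counts <- as.integer(counts)
  if (length(spot_ids) != length(counts))
    stop("spot_ids and counts lengths differ", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("cell counts must be integers >= 1", call. = FALSE)
  structure(list(spot_ids = spot_ids, counts = counts, source = source),
            class = "cells_per_spot")
}

#' @export
print.cells_per_spot <- function(x, ...) {
  cat(sprintf("<cells_per_spot> %d spots, %d cells total (source: %s)\n",
              length(x$counts), sum(x$counts), x$source))
  invisible(x)
}

#' Estimate cells per spot from UMI totals
#'
#' The per-spot UMI total is taken as a proxy for cell abundance. Each spot's
#' total is converted to a normalized scalar
#' `u_j = log2(1 + 1e6 * T_j / sum(T))` and a line is fitted through two
#' anchors: the spot with the minimum nonzero normalized UMIs is assigned one
#' cell, and the spot with the median normalized UMIs is assigned
#' `mean_cells`. The line is evaluated at every spot, rounded half-up, and
#' clipped to at least one cell.
#'
#' @param S_raw ST [expression_matrix()] with layer `"raw_counts"`; every spot
#'   needs a positive UMI total.
#' @param mean_cells Mean cells per spot assigned to the median-UMI anchor
#'   (default 5, the conventional Visium figure).
#' @return A [cells_per_spot()] with source `"umi_linear"`.
#' @export
estimate_cells_per_spot_umi <- function(S_raw, mean_cells = 5) {
  validate_expr_matrix(S_raw)
  if (S_raw$layer != "raw_counts")
    stop("estimate_cells_per_spot_umi expects raw counts", call. = FALSE)
  if (mean_cells <= 0) stop("mean_cells must be positive", call. = FALSE)
  totals <- rowSums(S_raw$values)
  if (any(totals <= 0))
    stop("spots with zero UMI totals: ",
         paste(utils::head(S_raw$row_ids[totals <= 0], 5), collapse = ", "),
         call. = FALSE)
  u <- log2(1 + 1e6 * totals / sum(totals))
  u_min <- min(u)
  u_med <- stats::median(u)
  if (isTRUE(all.equal(u_min, u_med)) || u_med <= u_min)
    stop("degenerate UMI anchors (minimum equals median); ",
         "use constant_cells_per_spot() instead", call. = FALSE)
  slope <- (mean_cells - 1) / (u_med - u_min)
  n_hat <- 1 + slope * (u - u_min)
  counts <- pmax(1L, as.integer(floor(n_hat + 0.5)))   # round half-up, clip at 1
  cells_per_spot(S_raw$row_ids, counts, source = "umi_linear")
}

#' Cells per spot from external nucleus counts
#'
#' Accepts per-spot nucleus counts (e.g. from H&E image segmentation). Spots
#' counted as zero are raised to one with a warning, since every spot must
#' stay mappable.
#'
#' @param table Data frame with columns `spot_id` and `count` (integers >= 0),
#'   or a path to a CSV file with those columns.
#' @param spot_ids Spot barcodes the counts must cover, in output order.
#' @return A [cells_per_spot()] with source `"nucleus_counts"`.
#' @export
cells_per_spot_from_counts <- function(table, spot_ids) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.csv(table, check.names = FALSE)
  if (!all(c("spot_id", "count") %in% names(table)))
    stop("nucleus count table needs columns spot_id,count", call. = FALSE)
  idx <- match(spot_ids, table$spot_id)
  if (anyNA(idx))
    stop("missing nucleus counts for spots: ",
         paste(utils::head(spot_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  counts <- table$count[idx]
  if (any(!is.finite(counts)) || any(counts != round(counts)) || any(counts < 0))
    stop("nucleus counts must be integers >= 0", call. = FALSE)
  if (any(counts == 0)) {
    warning(sum(counts == 0), " spot(s) with zero nuclei raised to 1 cell")
    counts <- pmax(counts, 1)
  }
  cells_per_spot(spot_ids, counts, source = "nucleus_counts")
}

#' Constant cells per spot
#'
#' @param spot_ids Spot barcodes (or a single integer, the number of spots).
#' @param n Cells per spot (integer >= 1).
#' @return A [cells_per_spot()] with source `"constant"`.
#' @export
constant_cells_per_spot <- function(spot_ids, n) {
  if (is.numeric(spot_ids) && length(spot_ids) == 1L)
    spot_ids <- paste0("spot_", seq_len(spot_ids))
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1", call. = FALSE)
  cells_per_spot(spot_ids, rep(as.integer(n), length(spot_ids)),
                 source = "constant")
}
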