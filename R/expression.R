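#' Construct an expression matrix
#'
#' The central data container: a dense non-negative matrix of cells or spots
#' (rows) by genes (columns), tagged with a layer (`"raw_counts"` or
#' `"cpm_log2"`) and a modality (`"sc"` or `"st"`).
#'
#' @param values Numeric matrix, rows are cells or spots, columns are genes.
#'   All entries must be finite and non-negative.
#' @param row_ids Character vector of unique cell/spot barcodes. Defaults to
#'   `rownames(values)`.
#' @param gene_ids Character vector of unique gene identifiers. Defaults to
#'   `colnames(values)`.
#' @param layer One of `"raw_counts"`, `"cpm_log2"`.
#' @param modality One of `"sc"` (single cells), `"st"` (spatial spots).
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `row_ids`, `gene_ids`, `layer`, `modality`.
#' @export
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' expression_matrix(m, layer = "raw_counts", modality = "sc")
expression_matrix <- function(values, row_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("raw_counts", "cpm_log2"),
                              modality = c("sc", "st")) {
  layer <- match.arg(layer)
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(row_ids)) row_ids <- paste0("row_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  obj <- structure(
    list(values = values, row_ids = as.character(row_ids),
         gene_ids = as.character(gene_ids), layer = layer, modality = modality),
    class = "expr_matrix")
  validate_expr_matrix(obj)
  dimnames(obj$values) <- list(obj$row_ids, obj$gene_ids)
  obj
}

validate_expr_matrix <- function(x) {
  if (!inherits(x, "expr_matrix")) stop("not an expr_matrix", call. = FALSE)
  v <- x$values
  if (ncol(v) < 1L) stop("expression matrix has no genes", call. = FALSE)
  if (nrow(v) < 1L) stop("expression matrix has no rows", call. = FALSE)
  if (any(!is.finite(v))) stop("expression matrix contains NaN/Inf/NA values", call. = FALSE)
  if (any(v < 0)) stop("expression matrix contains negative values", call. = FALSE)
  if (length(x$row_ids) != nrow(v))
    stop("row_ids length does not match the number of rows", call. = FALSE)
  if (length(x$gene_ids) != ncol(v))
    stop("gene_ids length does not match the number of columns", call. = FALSE)
  if (anyDuplicated(x$row_ids))
    stop("duplicated row barcodes: ",
         paste(unique(x$row_ids[duplicated(x$row_ids)])[1:3], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$gene_ids))
    stop("duplicated gene ids: ",
         paste(unique(x$gene_ids[duplicated(x$gene_ids)])[1:3], collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d %s x %d genes, layer = %s\n",
              nrow(x$values), if (x$modality == "sc") "cells" else "spots",
              ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Spot geometry
#'
#' Pairs each ST spot id with an (x, y) coordinate, in arbitrary but
#' consistent units.
#'
#' @param spot_ids Character vector of spot barcodes.
#' @param coords Two-column numeric matrix or data frame of x/y coordinates.
#' @return An object of class `spot_geometry` with elements `spot_ids` and
#'   `coords` (matrix with columns `x`, `y`).
#' @export
spot_geometry <- function(spot_ids, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (x, y)", call. = FALSE)
  storage.mode(coords) <- "double"
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != nrow(coords))
    stop("spot_ids length does not match coords", call. = FALSE)
  if (anyDuplicated(spot_ids)) stop("duplicated spot ids", call. = FALSE)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  colnames(coords) <- c("x", "y")
  rownames(coords) <- spot_ids
  structure(list(spot_ids = spot_ids, coords = coords), class = "spot_geometry")
}

#' Cell-type annotation
#'
#' @param cell_ids Character vector of cell barcodes.
#' @param cell_type Character vector of cell-type labels, one per cell.
#' @return An object of class `cell_annotation`.
#' @export
cell_annotation <- function(cell_ids, cell_type) {
  cell_ids <- as.character(cell_ids)
  cell_type <- as.character(cell_type)
  if (length(cell_ids) != length(cell_type))
    stop("cell_ids and cell_type lengths differ", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids", call. = FALSE)
  if (any(is.na(cell_type) | !nzchar(cell_type)))
    stop("empty cell-type labels", call. = FALSE)
  structure(list(cell_ids = cell_ids, cell_type = cell_type),
            class = "cell_annotation")
}

annotation_lookup <- function(ann, cell_ids) {
  idx <- match(cell_ids, ann$cell_ids)
  if (anyNA(idx)) {
    missing <- cell_ids[is.na(idx)]
    stop("unannotated cells: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  ann$cell_type[idx]
}

#' Read an expression matrix from disk
#'
#' Three dialects are supported. `"csv"` is a dense table whose header row
#' holds gene ids and whose first column holds cell/spot barcodes. `"mtx_dir"`
#' is a directory in the usual genes-by-barcodes MatrixMarket layout
#' (`matrix.mtx`, `barcodes.tsv`, `features.tsv`); the matrix is transposed on
#' read so rows are barcodes. `"h5ad"` is an HDF5 single-cell container and is
#' read through the `python` interpreter on the PATH (requires the `anndata`
#' python package).
#'
#' @param path File (csv, h5ad) or directory (mtx_dir) path.
#' @param format One of `"csv"`, `"mtx_dir"`, `"h5ad"`.
#' @param modality Modality tag for the returned object, `"sc"` or `"st"`.
#' @return An [expression_matrix()] with layer `"raw_counts"`, ids in source
#'   order.
#' @export
read_expression <- function(path, format = c("csv", "mtx_dir", "h5ad"),
                            modality = c("sc", "st")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop("cannot read expression data: no such path '", path, "'", call. = FALSE)
  switch(format,
    csv = {
      tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
      expression_matrix(as.matrix(tab), row_ids = rownames(tab),
                        gene_ids = colnames(tab), layer = "raw_counts",
                        modality = modality)
    },
    mtx_dir = read_mtx_dir(path, modality),
    h5ad = {
      tmp <- tempfile("h5ad_mtx_")
      h5ad_bridge("to_mtx", path, tmp)
      on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
      read_mtx_dir(tmp, modality)
    })
}

read_mtx_dir <- function(path, modality) {
  if (!dir.exists(path))
    stop("mtx_dir format expects a directory: '", path, "'", call. = FALSE)
  mtx <- file.path(path, "matrix.mtx")
  bc <- file.path(path, "barcodes.tsv")
  ft <- file.path(path, "features.tsv")
  for (f in c(mtx, bc, ft)) if (!file.exists(f))
    stop("mtx_dir is missing '", basename(f), "' in '", path, "'", call. = FALSE)
  m <- Matrix::readMM(mtx)            # genes x barcodes on disk
  barcodes <- readLines(bc)
  features <- read.delim(ft, header = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop("mtx dimensions do not match barcodes/features files", call. = FALSE)
  expression_matrix(t(as.matrix(m)), row_ids = barcodes,
                    gene_ids = as.character(features),
                    layer = "raw_counts", modality = modality)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(E))`
#' reproduces `E`'s values (within 1e-9) and ids exactly, for every dialect.
#'
#' @param E An [expression_matrix()].
#' @param path Destination file (csv, h5ad) or directory (mtx_dir).
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(E, path, format = c("csv", "mtx_dir", "h5ad")) {
  format <- match.arg(format)
  validate_expr_matrix(E)
  switch(format,
    csv = {
      tab <- as.data.frame(E$values)
      utils::write.csv(tab, path, row.names = TRUE)
    },
    mtx_dir = write_mtx_dir(E, path),
    h5ad = {
      tmp <- tempfile("h5ad_mtx_")
      write_mtx_dir(E, tmp)
      on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
      h5ad_bridge("from_mtx", tmp, path)
    })
  invisible(path)
}

write_mtx_dir <- function(E, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(E$values), sparse = TRUE)   # genes x barcodes on disk
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(E$row_ids, file.path(path, "barcodes.tsv"))
  writeLines(E$gene_ids, file.path(path, "features.tsv"))
}

h5ad_bridge <- function(action, src, dst) {
  script <- system.file("python", "h5ad_io.py", package = "spotmap")
  if (!nzchar(script)) stop("bundled h5ad converter not found", call. = FALSE)
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("h5ad support needs a 'python' interpreter with anndata on the PATH",
         call. = FALSE)
  status <- system2(py, shQuote(c(script, action, src, dst)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("h5ad conversion failed: ", paste(status, collapse = "\n"), call. = FALSE)
  invisible(dst)
}

#' Read spot coordinates
#'
#' @param path CSV file with columns `spot_id`, `x`, `y`.
#' @return A [spot_geometry()].
#' @export
read_spot_geometry <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("coordinate file must have columns spot_id,x,y", call. = FALSE)
  spot_geometry(tab$spot_id, as.matrix(tab[, c("x", "y")]))
}

#' @rdname read_spot_geometry
#' @param G A [spot_geometry()].
#' @export
write_spot_geometry <- function(G, path) {
  utils::write.csv(
    data.frame(spot_id = G$spot_ids, x = G$coords[, 1], y = G$coords[, 2]),
    path, row.names = FALSE)
  invisible(path)
}

#' Drop genes detected in fewer than two rows
#'
#' Removes genes with a nonzero count in no more than one cell (or one spot):
#' only genes detected in at least two rows are retained. Applied to the
#' scRNA-seq and ST matrices independently, before taking common genes.
#'
#' @param E An [expression_matrix()] with layer `"raw_counts"`.
#' @return The filtered matrix; the row set is unchanged.
#' @export
filter_rare_genes <- function(E) {
  validate_expr_matrix(E)
  if (E$layer != "raw_counts")
    stop("filter_rare_genes expects raw counts", call. = FALSE)
  prevalence <- colSums(E$values > 0)
  keep <- prevalence >= 2
  if (!any(keep))
    stop("no gene is detected in 2 or more rows; inputs look incompatible",
         call. = FALSE)
  expression_matrix(E$values[, keep, drop = FALSE], row_ids = E$row_ids,
                    gene_ids = E$gene_ids[keep], layer = E$layer,
                    modality = E$modality)
}

#' Counts-per-million log2 normalization
#'
#' Scales each row to a total of one million and applies `log2(1 + x)`
#' entrywise; the layer tag becomes `"cpm_log2"`.
#'
#' @param E An [expression_matrix()] with layer `"raw_counts"`; every row must
#'   have a positive total.
#' @return The normalized matrix.
#' @export
normalize_cpm_log2 <- function(E) {
  validate_expr_matrix(E)
  if (E$layer != "raw_counts")
    stop("normalize_cpm_log2 expects raw counts", call. = FALSE)
  totals <- rowSums(E$values)
  if (any(totals <= 0))
    stop("all-zero rows cannot be normalized: ",
         paste(utils::head(E$row_ids[totals <= 0], 5), collapse = ", "),
         call. = FALSE)
  cpm <- E$values / totals * 1e6
  expression_matrix(log2(1 + cpm), row_ids = E$row_ids, gene_ids = E$gene_ids,
                    layer = "cpm_log2", modality = E$modality)
}

#' Restrict two expression matrices to their common genes
#'
#' Both outputs carry the shared gene set in lexicographic order, so their
#' columns line up gene-for-gene.
#'
#' @param C,S [expression_matrix()] objects (any layer).
#' @return A list with elements `C` and `S`.
#' @export
intersect_genes <- function(C, S) {
  validate_expr_matrix(C); validate_expr_matrix(S)
  common <- sort(intersect(C$gene_ids, S$gene_ids))
  if (length(common) == 0L)
    stop("the two matrices share no genes", call. = FALSE)
  take <- function(E) {
    expression_matrix(E$values[, match(common, E$gene_ids), drop = FALSE],
                      row_ids = E$row_ids, gene_ids = common,
                      layer = E$layer, modality = E$modality)
  }
  list(C = take(C), S = take(S))
}
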