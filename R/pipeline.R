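#' Run the full mapping workflow from files on disk
#'
#' File-in/file-out wrapper around [spotmap()] for scripted use. The
#' configuration is a named list (or a YAML file path, parsed with the
#' `yaml` package) with entries:
#' \describe{
#'   \item{sc, st}{paths to the scRNA-seq and ST expression inputs}
#'   \item{sc_format, st_format}{`"csv"`, `"mtx_dir"` or `"h5ad"`
#'     (default `"csv"`)}
#'   \item{coords}{path to the spot coordinate CSV (`spot_id,x,y`)}
#'   \item{annotations}{optional CSV `cell_id,cell_type`}
#'   \item{cells_per_spot_file}{optional nucleus-count CSV `spot_id,count`}
#'   \item{mean_cells, lambda, embedding, gate_dims, gate_epochs, gate_lr,
#'     k_expression, k_spatial, map_epochs, map_lr, seed}{forwarded to
#'     [spotmap()] when present}
#'   \item{out_dir}{output directory}
#' }
#'
#' Written artifacts: `assignments_regular.csv` and `assignments_greedy.csv`
#' (`cell_id,spot_id,score`), `cells_per_spot.csv`,
#' `proportions_regular.csv` (when annotations are given),
#' `embedding_sc.csv` / `embedding_st.csv`, the resolved configuration
#' snapshot `config.json`, and a run manifest `manifest.json` with per-stage
#' timing and the seed.
#'
#' @param config Named list or path to a YAML file.
#' @return The [spotmap()] fit, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  need <- c("sc", "st", "coords", "out_dir")
  if (!all(need %in% names(config)))
    stop("config must name: ", paste(setdiff(need, names(config)), collapse = ", "),
         call. = FALSE)
  t0 <- Sys.time()
  stage <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    val <- force(expr)
    stage[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    val
  }
  sc <- tick("read_sc", read_expression(config$sc,
             format = config$sc_format %||% "csv", modality = "sc"))
  st <- tick("read_st", read_expression(config$st,
             format = config$st_format %||% "csv", modality = "st"))
  geom <- read_spot_geometry(config$coords)
  geom <- spot_geometry(st$row_ids,
                        geom$coords[match(st$row_ids, geom$spot_ids), , drop = FALSE])
  ann <- NULL
  if (!is.null(config$annotations)) {
    tab <- utils::read.csv(config$annotations, check.names = FALSE)
    ann <- cell_annotation(tab$cell_id, tab$cell_type)
  }
  N <- NULL
  if (!is.null(config$cells_per_spot_file))
    N <- cells_per_spot_from_counts(config$cells_per_spot_file, st$row_ids)

  fit_args <- config[intersect(names(config),
    c("mean_cells", "lambda", "embedding", "gate_dims", "gate_epochs",
      "gate_lr", "k_expression", "k_spatial", "map_epochs", "map_lr",
      "seed", "verbose"))]
  if (!is.null(fit_args$gate_dims)) fit_args$gate_dims <- unlist(fit_args$gate_dims)
  fit <- tick("fit", do.call(spotmap, c(list(sc = sc, st = st, geometry = geom,
                                             annotation = ann,
                                             cells_per_spot = N), fit_args)))

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$regular$assignments,
                   file.path(out, "assignments_regular.csv"), row.names = FALSE)
  utils::write.csv(fit$greedy$assignments,
                   file.path(out, "assignments_greedy.csv"), row.names = FALSE)
  utils::write.csv(data.frame(spot_id = fit$N$spot_ids, count = fit$N$counts),
                   file.path(out, "cells_per_spot.csv"), row.names = FALSE)
  if (!is.null(ann))
    utils::write.csv(spot_celltype_proportions(fit$regular, ann),
                     file.path(out, "proportions_regular.csv"),
                     row.names = FALSE)
  for (mod in c("sc", "st")) {
    Z <- fit$embeddings[[mod]]
    if (!is.null(Z))
      utils::write.csv(data.frame(row_id = rownames(Z), Z, check.names = FALSE),
                       file.path(out, paste0("embedding_", mod, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(fit$config, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = fit$config$seed,
         n_cells = nrow(fit$M$M), n_spots = ncol(fit$M$M),
         n_genes = length(fit$genes),
         stage_seconds = stage,
         total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         final_loss = fit$losses$mapping[length(fit$losses$mapping)]),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Write a deterministic miniature dataset to disk
#'
#' Generates a small annotated tissue, bins it into spots, perturbs the
#' scRNA-seq copy, and writes every input the mapping workflow consumes:
#' `sc.csv`, `st.csv`, `coords.csv`, `annotations.csv`, `truth.csv`.
#' Intended for tests and examples; everything is reproducible from the seed.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_types,cells_per_type,n_genes,target_mean_cells,noise Size and
#'   noise knobs, kept small by default (3 types x 40 cells, 120 genes, ~4
#'   cells/spot, 5% perturbed genes).
#' @return Named list of the written file paths, invisibly.
#' @export
make_fixture <- function(dir, seed = 1, n_types = 3, cells_per_type = 40,
                         n_genes = 120, target_mean_cells = 4, noise = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tissue <- generate_synthetic_tissue(
    n_types = n_types, cells_per_type = cells_per_type, n_genes = n_genes,
    n_markers_per_type = max(3, n_genes %/% (4 * n_types)), seed = seed)
  st <- bin_cells_to_spots(tissue, target_mean_cells)
  sc <- perturb_expression(tissue$cells, noise, seed = seed + 1L)
  paths <- list(
    sc = file.path(dir, "sc.csv"), st = file.path(dir, "st.csv"),
    coords = file.path(dir, "coords.csv"),
    annotations = file.path(dir, "annotations.csv"),
    truth = file.path(dir, "truth.csv"))
  write_expression(sc, paths$sc, "csv")
  write_expression(st$spots, paths$st, "csv")
  write_spot_geometry(st$geometry, paths$coords)
  utils::write.csv(data.frame(cell_id = tissue$annotation$cell_ids,
                              cell_type = tissue$annotation$cell_type),
                   paths$annotations, row.names = FALSE)
  utils::write.csv(st$truth, paths$truth, row.names = FALSE)
  invisible(paths)
}
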