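# Small builders shared across test files; everything is generated in code.

toy_expr <- function(values, ids = NULL, genes = NULL, layer = "raw_counts",
                     modality = "sc") {
  values <- as.matrix(values)
  expression_matrix(values,
                    row_ids = ids %||% paste0("c", seq_len(nrow(values))),
                    gene_ids = genes %||% paste0("g", seq_len(ncol(values))),
                    layer = layer, modality = modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_tissue <- function(seed = 7, n_types = 3, cells_per_type = 40,
                         n_genes = 120) {
  generate_synthetic_tissue(n_types = n_types, cells_per_type = cells_per_type,
                            n_genes = n_genes, n_markers_per_type = 10,
                            seed = seed)
}

# Naive double-loop reference for the three-term objective; deliberately
# written without any matrix algebra so it is independent of mapping_loss().
naive_mapping_loss <- function(M, kl, D, counts, lam) {
  tot <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
    tot <- tot + kl[i, j] * M[i, j] + D[i, j] * M[i, j]
  pen <- 0
  for (j in seq_len(ncol(M))) {
    s <- 0
    for (i in seq_len(nrow(M))) s <- s + M[i, j]
    pen <- pen + abs(counts[j] - s)
  }
  tot + lam * pen / ncol(M)
}

naive_kl_matrix <- function(C, S, eps = 1e-10) {
  out <- matrix(0, nrow(C), nrow(S))
  for (i in seq_len(nrow(C))) {
    p <- C[i, ] + eps; p <- p / sum(p)
    for (j in seq_len(nrow(S))) {
      q <- S[j, ] + eps; q <- q / sum(q)
      out[i, j] <- sum(p * log(p / q))
    }
  }
  out
}

naive_pearson_distance <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    out[i, j] <- 1 - stats::cor(A[i, ], B[j, ])
  out
}
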