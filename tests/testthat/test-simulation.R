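test_that("synthetic tissue has elevated marker programs and spatial patches", {
  tis <- generate_synthetic_tissue(n_types = 2, cells_per_type = 50,
                                   n_genes = 100, n_markers_per_type = 10,
                                   seed = 4)
  V <- tis$cells$values
  type <- tis$annotation$cell_type
  own <- colMeans(V[type == "type_1", 1:10])
  other <- colMeans(V[type == "type_2", 1:10])
  expect_true(all(own > 2 * other))
  # the two types form spatially separable clusters
  cx <- tapply(tis$coords[, 1], type, mean)
  cy <- tapply(tis$coords[, 2], type, mean)
  expect_gt(sqrt(diff(cx)^2 + diff(cy)^2), 0.2)
  expect_true(all(V >= 0) && all(V == round(V)))
})

test_that("tissue generation is deterministic per seed and validates sizes", {
  a <- generate_synthetic_tissue(n_types = 2, cells_per_type = 10, n_genes = 40,
                                 n_markers_per_type = 5, seed = 9)
  b <- generate_synthetic_tissue(n_types = 2, cells_per_type = 10, n_genes = 40,
                                 n_markers_per_type = 5, seed = 9)
  expect_identical(a$cells$values, b$cells$values)
  expect_identical(a$coords, b$coords)
  cc <- generate_synthetic_tissue(n_types = 2, cells_per_type = 10, n_genes = 40,
                                  n_markers_per_type = 5, seed = 10)
  expect_false(identical(a$cells$values, cc$cells$values))
  expect_error(generate_synthetic_tissue(n_types = 4, n_markers_per_type = 30,
                                         n_genes = 100), "exceeds")
})

test_that("binning sums member cells and returns a total truth table", {
  corners <- list(cells = toy_expr(matrix(rpois(12, 6), 4, 3)),
                  coords = rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  one <- bin_cells_to_spots(corners, target_mean_cells = 4)
  expect_identical(nrow(one$spots$values), 1L)
  expect_equal(one$spots$values[1, ], colSums(corners$cells$values),
               ignore_attr = TRUE)
  expect_identical(sort(one$truth$cell_id), sort(corners$cells$row_ids))

  # target 1 with well-separated cells: each spot is one cell
  sep <- list(cells = toy_expr(matrix(rpois(12, 6), 4, 3)),
              coords = cbind(c(0, 10, 20, 30), 0))
  iso <- bin_cells_to_spots(sep, target_mean_cells = 1)
  expect_identical(nrow(iso$spots$values), 4L)
  perm <- match(iso$truth$spot_id, iso$spots$row_ids)
  expect_equal(iso$spots$values[perm, ], sep$cells$values, ignore_attr = TRUE)
})

test_that("bin side search hits the target mean and conserves counts", {
  tis <- small_tissue(seed = 15, n_types = 2, cells_per_type = 50, n_genes = 60)
  st <- bin_cells_to_spots(tis, target_mean_cells = 5)
  expect_gte(st$mean_cells_per_spot, 4.5)
  expect_lte(st$mean_cells_per_spot, 5.5)
  # conservation: total counts unchanged by binning
  expect_equal(sum(st$spots$values), sum(tis$cells$values))
  # the truth table is a function: every cell appears exactly once
  expect_identical(sort(st$truth$cell_id), sort(tis$cells$row_ids))
  expect_false(anyDuplicated(st$truth$cell_id) > 0)
  # spot expression equals the sum over member cells
  s1 <- st$truth$spot_id[1]
  members <- st$truth$cell_id[st$truth$spot_id == s1]
  expect_equal(st$spots$values[s1, ],
               colSums(tis$cells$values[members, , drop = FALSE]))
  expect_error(bin_cells_to_spots(tis, target_mean_cells = 1e6), "exceeds")
})

test_that("perturbation respects the selection fraction and the seed", {
  E <- toy_expr(matrix(rpois(200 * 20, 50), 20, 200))
  expect_identical(perturb_expression(E, 0, seed = 1)$values, E$values)

  P <- perturb_expression(E, 0.25, seed = 2)
  changed <- rowSums(P$values != E$values)
  expect_true(all(changed <= floor(0.25 * 200)))   # exactly 50 genes selected
  expect_true(all(changed >= 1))
  expect_true(all(P$values >= 0) && all(P$values == round(P$values)))

  expect_identical(perturb_expression(E, 0.25, seed = 2)$values, P$values)
  expect_false(identical(perturb_expression(E, 0.25, seed = 3)$values, P$values))
  expect_error(perturb_expression(E, 1.2), "\\[0, 1\\]")
})

test_that("noise factors follow the exponentiated standard Gaussian", {
  # large counts so integer rounding barely distorts the log2 ratio
  E <- toy_expr(matrix(rpois(60 * 400, 500), 60, 400))
  P <- perturb_expression(E, 1, seed = 6)
  sel <- E$values > 0 & P$values > 0 & P$values != E$values
  ratio <- log2(P$values[sel] / E$values[sel])
  expect_gt(length(ratio), 1e4)
  expect_lt(abs(mean(ratio)), 0.05)
  expect_gt(stats::sd(ratio), 0.9)
  expect_lt(stats::sd(ratio), 1.1)
})
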