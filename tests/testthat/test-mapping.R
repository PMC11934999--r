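test_that("KL cost matrix matches hand-computed values", {
  # proportional profiles have zero divergence
  C <- toy_expr(rbind(c(2, 2, 4), c(9, 1, 0)), layer = "cpm_log2")
  S <- toy_expr(rbind(c(1, 1, 2)), layer = "cpm_log2", modality = "st")
  kl <- kl_cost_matrix(C, S)
  expect_equal(kl[1, 1], 0, tolerance = 1e-9)
  expect_gt(kl[2, 1], 0)

  # orthogonal one-hot profiles: value follows the documented epsilon formula
  C1 <- toy_expr(rbind(c(1, 0)), layer = "cpm_log2")
  S1 <- toy_expr(rbind(c(0, 1)), layer = "cpm_log2", modality = "st")
  eps <- 1e-10
  p <- c(1 + eps, eps) / (1 + 2 * eps); q <- rev(p)
  expect_equal(kl_cost_matrix(C1, S1)[1, 1], sum(p * log(p / q)),
               tolerance = 1e-9)
  expect_gt(kl_cost_matrix(C1, S1)[1, 1], 10)

  # 2x2 toy against the double-loop oracle
  C2 <- toy_expr(rbind(c(0.5, 0.5), c(0.9, 0.1)), layer = "cpm_log2")
  S2 <- toy_expr(rbind(c(0.5, 0.5), c(0.8, 0.2)), layer = "cpm_log2",
                 modality = "st")
  expect_equal(unname(kl_cost_matrix(C2, S2)),
               naive_kl_matrix(C2$values, S2$values), tolerance = 1e-12)

  expect_error(kl_cost_matrix(C2, toy_expr(matrix(1, 1, 3), modality = "st")),
               "gene")
})

test_that("Pearson distance spans [0, 2] and matches the closed form", {
  z <- rbind(c(1, 2, 3))
  expect_equal(pearson_distance_matrix(z, z)[1, 1], 0, tolerance = 1e-12)
  expect_equal(pearson_distance_matrix(z, -z)[1, 1], 2, tolerance = 1e-12)
  expect_equal(pearson_distance_matrix(rbind(c(1, 2, 3)), rbind(c(1, 2, 4)))[1, 1],
               1 - stats::cor(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_warning(
    D <- pearson_distance_matrix(rbind(c(5, 5, 5)), rbind(c(1, 2, 4))),
    "zero-variance")
  expect_equal(D[1, 1], 1)
})

test_that("KL and Pearson matrices equal naive oracles on random instances", {
  set.seed(21)
  for (rep in 1:20) {
    Cv <- matrix(rexp(5 * 6), 5, 6)
    Sv <- matrix(rexp(4 * 6), 4, 6)
    kl <- kl_cost_matrix(toy_expr(Cv, layer = "cpm_log2"),
                         toy_expr(Sv, layer = "cpm_log2", modality = "st"))
    expect_equal(unname(kl), naive_kl_matrix(Cv, Sv), tolerance = 1e-9)
    expect_true(all(kl >= 0))
    A <- matrix(rnorm(5 * 7), 5, 7); B <- matrix(rnorm(4 * 7), 4, 7)
    expect_equal(pearson_distance_matrix(A, B), naive_pearson_distance(A, B),
                 tolerance = 1e-9)
  }
})

test_that("mapping initialization reflects expected cell proportions", {
  N <- cells_per_spot(c("s1", "s2"), c(1, 1), "constant")
  M0 <- init_mapping(N, m = 3, jitter_sd = 0)
  expect_equal(unname(M0$M), matrix(0.5, 3, 2))
  N2 <- cells_per_spot(c("s1", "s2"), c(1, 3), "constant")
  expect_equal(unname(init_mapping(N2, 2, jitter_sd = 0)$M),
               matrix(c(0.25, 0.25, 0.75, 0.75), 2, 2))
  a <- init_mapping(N2, 4, seed = 5); b <- init_mapping(N2, 4, seed = 5)
  expect_identical(a$logits, b$logits)
})

test_that("mapping loss equals hand evaluation and the naive oracle", {
  kl <- rbind(c(0, 1), c(1, 0)); D0 <- matrix(0, 2, 2)
  N <- cells_per_spot(c("s1", "s2"), c(1, 1), "constant")
  expect_equal(mapping_loss(diag(2), kl, D0, N, lam = 7), 0)
  M_half <- matrix(0.5, 2, 2)
  expect_equal(mapping_loss(M_half, kl, D0, N, lam = 3), 1)
  # lambda = 0 makes the quantity term (and N) irrelevant
  N_big <- cells_per_spot(c("s1", "s2"), c(50, 60), "constant")
  expect_equal(mapping_loss(M_half, kl, D0, N, lam = 0),
               mapping_loss(M_half, kl, D0, N_big, lam = 0))

  set.seed(33)
  for (rep in 1:100) {
    M <- exp(matrix(rnorm(20), 5, 4))
    M <- M / rowSums(M)
    klr <- matrix(rexp(20), 5, 4); Dr <- matrix(runif(20, 0, 2), 5, 4)
    counts <- sample(1:4, 4, replace = TRUE)
    Nr <- cells_per_spot(paste0("s", 1:4), counts, "constant")
    lam <- runif(1, 0, 2)
    expect_equal(mapping_loss(M, klr, Dr, Nr, lam),
                 naive_mapping_loss(M, klr, Dr, counts, lam),
                 tolerance = 1e-9)
  }
})

test_that("optimization finds block-diagonal optima and respects symmetry", {
  # unique zero-cost spot per row; lambda 0 -> all mass moves there
  kl <- matrix(5, 4, 4); diag(kl) <- 0
  N <- constant_cells_per_spot(paste0("s", 1:4), 1)
  M <- optimize_mapping(kl, NULL, N, lam = 0, epochs = 400, lr = 0.05, seed = 1)
  expect_true(all(diag(M$M) > 0.99))
  expect_lte(M$losses[length(M$losses)], M$losses[1])
  expect_equal(unname(rowSums(M$M)), rep(1, 4), tolerance = 1e-6)

  # identical costs leave the row distribution near uniform
  M2 <- optimize_mapping(matrix(1, 3, 3), NULL, N3 <- constant_cells_per_spot(3, 1),
                         lam = 0, epochs = 200, lr = 0.05, seed = 2)
  expect_true(all(abs(M2$M - 1 / 3) < 0.05))

  # deterministic under a fixed seed
  Ma <- optimize_mapping(kl, NULL, N, lam = 0.1, epochs = 50, seed = 7)
  Mb <- optimize_mapping(kl, NULL, N, lam = 0.1, epochs = 50, seed = 7)
  expect_identical(Ma$M, Mb$M)
})

test_that("the quantity term pulls column masses toward the expected counts", {
  # every cell's cheapest spot is s1, so without the quantity term all mass
  # drifts there and the column masses leave N = (2, 2) behind
  m <- 4
  kl_skew <- cbind(rep(0, m), rep(1, m))
  N <- cells_per_spot(c("s1", "s2"), c(2, 2), "constant")
  gap <- function(lam) {
    M <- optimize_mapping(kl_skew, NULL, N, lam = lam, epochs = 400, lr = 0.05,
                          seed = 3)
    mean(abs(N$counts - colSums(M$M)))
  }
  expect_gt(gap(0), 1.5)
  expect_lt(gap(100), 0.2)
  # row sums stay stochastic along the trajectory (spot checks at 3 horizons)
  for (ep in c(1, 25, 400)) {
    M <- optimize_mapping(kl_skew, NULL, N, lam = 100, epochs = ep, lr = 0.05,
                          seed = 3)
    expect_equal(unname(rowSums(M$M)), rep(1, m), tolerance = 1e-6)
  }
})

test_that("regular extraction fills each spot with its top-N cells", {
  M <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  rownames(M) <- c("c1", "c2")
  N <- cells_per_spot(c("s1", "s2"), c(1, 1), "constant")
  out <- extract_regular(M, N)
  expect_identical(out$assignments$cell_id, c("c1", "c2"))
  expect_identical(out$assignments$spot_id, c("s1", "s2"))
  expect_equal(out$assignments$score, c(0.9, 0.8))

  # N_j = m: every cell goes to that spot regardless of score
  N2 <- cells_per_spot(c("s1", "s2"), c(2, 1), "constant")
  out2 <- extract_regular(M, N2)
  expect_identical(sort(out2$assignments$cell_id[out2$assignments$spot_id == "s1"]),
                   c("c1", "c2"))
  expect_equal(nrow(out2$assignments), sum(N2$counts))

  # ties resolve to the lowest cell index, deterministically
  Mt <- matrix(0.5, 3, 2, dimnames = list(paste0("c", 1:3), NULL))
  out3 <- extract_regular(Mt, cells_per_spot(c("s1", "s2"), c(2, 1), "constant"))
  expect_identical(out3$assignments$cell_id, c("c1", "c2", "c1"))

  expect_error(extract_regular(M, cells_per_spot(c("s1", "s2"), c(3, 1),
                                                 "constant")), "more cells")
})

test_that("greedy extraction assigns every cell to its argmax spot", {
  M <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  dimnames(M) <- list(c("c1", "c2"), c("s1", "s2"))
  out <- extract_greedy(M)
  expect_identical(out$assignments$spot_id, c("s1", "s2"))
  expect_identical(out$mode, "greedy")
  # uniform rows pick the first spot
  Mu <- matrix(1 / 3, 2, 3, dimnames = list(c("c1", "c2"), paste0("s", 1:3)))
  expect_identical(extract_greedy(Mu)$assignments$spot_id, c("s1", "s1"))
  # random matrix against an exhaustive row-max scan
  set.seed(14)
  Mr <- matrix(runif(9), 3, 3, dimnames = list(paste0("c", 1:3), paste0("s", 1:3)))
  got <- extract_greedy(Mr)$assignments$spot_id
  oracle <- paste0("s", apply(Mr, 1, which.max))
  expect_identical(got, oracle)
})

test_that("per-spot cell-type proportions match a hand count", {
  ann <- cell_annotation(paste0("c", 1:5), c("A", "A", "B", "B", "A"))
  res <- spotmap:::mapping_result(
    data.frame(cell_id = c("c1", "c2", "c3", "c4", "c5"),
               spot_id = c("s1", "s1", "s1", "s2", "s3"),
               score = 1),
    "regular", paste0("c", 1:5), c("s1", "s2", "s3", "s4"))
  tab <- spot_celltype_proportions(res, ann)
  expect_equal(tab$A, c(2 / 3, 0, 1, 0))
  expect_equal(tab$B, c(1 / 3, 1, 0, 0))
  expect_true(tab$empty[4])
  expect_equal(rowSums(tab[1:3, c("A", "B")]), rep(1, 3), ignore_attr = TRUE)
  # an unannotated mapped cell is an error
  res_bad <- spotmap:::mapping_result(
    data.frame(cell_id = "c9", spot_id = "s1", score = 1),
    "regular", "c9", "s1")
  expect_error(spot_celltype_proportions(res_bad, ann), "c9")
})
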