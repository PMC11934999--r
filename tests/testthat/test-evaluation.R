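mk_result <- function(cell_id, spot_id, mode = "regular",
                      spots = sort(unique(spot_id))) {
  spotmap:::mapping_result(
    data.frame(cell_id = cell_id, spot_id = spot_id, score = 1),
    mode, unique(cell_id), spots)
}

test_that("per-type mapping precision counts correct assignments", {
  truth <- data.frame(cell_id = paste0("c", 1:6),
                      spot_id = c("s1", "s1", "s2", "s2", "s3", "s3"))
  ann <- cell_annotation(paste0("c", 1:6), c("A", "A", "A", "B", "B", "B"))
  # A: 2/3 correct, B: 1/2 correct (c5 unmapped -> not in the denominator)
  R <- mk_result(c("c1", "c2", "c3", "c4", "c6"),
                 c("s1", "s2", "s2", "s2", "s1"))
  pm <- pmap_precision(R, truth, ann)
  expect_equal(pm, c(A = 2 / 3, B = 1 / 2))

  perfect <- mk_result(truth$cell_id, truth$spot_id)
  expect_equal(pmap_precision(perfect, truth, ann), c(A = 1, B = 1))

  # a type with no truth-covered assignments is NA
  ann2 <- cell_annotation(paste0("c", 1:6), c(rep("A", 5), "C"))
  R2 <- mk_result(paste0("c", 1:5), truth$spot_id[1:5])
  expect_true(is.na(pmap_precision(R2, truth, ann2)["C"]))
  expect_error(pmap_precision(mk_result("c1", "s1", mode = "greedy"),
                              truth, ann), "regular")
})

test_that("greedy location precision mirrors the counting oracle", {
  set.seed(31)
  n <- 60
  truth <- data.frame(cell_id = paste0("c", 1:n),
                      spot_id = paste0("s", sample(1:10, n, TRUE)))
  ann <- cell_annotation(paste0("c", 1:n),
                         sample(c("A", "B", "C"), n, TRUE))
  pred <- ifelse(runif(n) < 0.6, truth$spot_id,
                 paste0("s", sample(1:10, n, TRUE)))
  R <- mk_result(truth$cell_id, pred, mode = "greedy", spots = paste0("s", 1:10))
  pl <- ploc_precision(R, truth, ann)
  for (tp in c("A", "B", "C")) {
    rows <- ann$cell_type == tp
    expect_equal(unname(pl[tp]), sum((pred == truth$spot_id)[rows]) / sum(rows))
  }
  expect_true(all(pl >= 0 & pl <= 1))
})

test_that("misclassification error rate is a per-spot multiset difference", {
  ann <- cell_annotation(paste0("c", 1:6), c("A", "A", "B", "A", "B", "B"))
  truth <- data.frame(cell_id = paste0("c", 1:6),
                      spot_id = c("s1", "s1", "s1", "s2", "s2", "s2"))
  # identical multisets -> 0, regardless of within-spot order
  perfect <- mk_result(c("c2", "c1", "c3", "c5", "c4", "c6"),
                       c("s1", "s1", "s1", "s2", "s2", "s2"))
  expect_equal(celltype_error_rate(perfect, truth, ann), 0)
  # s1 true (A,A,B) vs predicted (A,B,B): one unmatched label out of 6 cells
  swapped <- mk_result(c("c1", "c3", "c5", "c4", "c5", "c6"),
                       c("s1", "s1", "s1", "s2", "s2", "s2"))
  expect_equal(celltype_error_rate(swapped, truth, ann), 1 / 6)
  # every label wrong -> 1
  annX <- cell_annotation(paste0("c", 1:6), rep(c("A", "B"), each = 3))
  truthX <- data.frame(cell_id = paste0("c", 1:6),
                       spot_id = rep(c("s1", "s2"), each = 3))
  allwrong <- mk_result(c("c4", "c5", "c6", "c1", "c2", "c3"),
                        rep(c("s1", "s2"), each = 3))
  expect_equal(celltype_error_rate(allwrong, truthX, annX), 1)
  # cardinality mismatch: excess counted as errors, with a warning
  extra <- mk_result(c("c1", "c2", "c3", "c1"), c("s1", "s1", "s1", "s2"))
  expect_warning(er <- celltype_error_rate(extra, truth, ann), "differ")
  expect_gt(er, 0)
})

test_that("proportion agreement PCC matches direct correlation", {
  pred <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3))
  true <- rbind(c(1, 0, 0), c(0, 1, 0))
  dimnames(pred) <- dimnames(true) <- list(c("s1", "s2"), c("A", "B", "C"))
  out <- proportion_pcc(pred, true)
  expect_equal(unname(out$per_spot),
               c(stats::cor(pred[1, ], true[1, ]), stats::cor(pred[2, ], true[2, ])),
               tolerance = 1e-12)
  expect_equal(out$mean, mean(out$per_spot))
  expect_equal(unname(proportion_pcc(pred, pred)$per_spot), c(1, 1))
  # anti-ordered proportions correlate negatively
  anti <- proportion_pcc(rbind(c(0.6, 0.3, 0.1)), rbind(c(0.1, 0.3, 0.6)))
  expect_lt(anti$per_spot[1], 0)
  # zero-variance row -> NA with warning
  expect_warning(z <- proportion_pcc(rbind(c(1 / 3, 1 / 3, 1 / 3)), rbind(c(1, 0, 0))),
                 "zero-variance")
  expect_true(is.na(z$per_spot[1]))
  expect_error(proportion_pcc(pred, true[, c(2, 1, 3)]), "mismatched")
})

test_that("k-distance averages the k nearest reference distances", {
  refs <- cbind(c(1, 2, 3, 4, 5, 9), 0)
  expect_equal(k_distance(cbind(0, 0), refs, k = 5), 3)
  expect_equal(k_distance(cbind(1, 0), refs, k = 1), 0)
  # translation invariance
  shift <- matrix(c(13, -4), 7, 2, byrow = TRUE)
  q <- cbind(c(0, 1), c(0, 0))
  expect_equal(k_distance(q, refs, k = 3),
               k_distance(q + shift[1:2, ], refs + shift[1:6, ], k = 3),
               tolerance = 1e-9)
  expect_error(k_distance(q, refs, k = 7), "reference")
})

test_that("metrics equal naive re-implementations on random instances", {
  set.seed(77)
  for (rep in 1:30) {
    n <- 25
    cells <- paste0("c", 1:n)
    truth <- data.frame(cell_id = cells, spot_id = paste0("s", sample(1:6, n, TRUE)))
    ann <- cell_annotation(cells, sample(c("A", "B"), n, TRUE))
    pred <- paste0("s", sample(1:6, n, TRUE))
    R <- mk_result(cells, pred, mode = "greedy", spots = paste0("s", 1:6))
    pl <- ploc_precision(R, truth, ann)
    for (tp in c("A", "B")) {
      idx <- which(ann$cell_type == tp)
      expect_equal(unname(pl[tp]),
                   sum(pred[idx] == truth$spot_id[idx]) / length(idx),
                   tolerance = 1e-12)
    }
    q <- matrix(rnorm(10), 5, 2); r <- matrix(rnorm(16), 8, 2)
    kd <- k_distance(q, r, k = 3)
    for (i in 1:5) {
      ds <- sort(sqrt(colSums((t(r) - q[i, ])^2)))
      expect_equal(kd[i], mean(ds[1:3]), tolerance = 1e-12)
    }
  }
})
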