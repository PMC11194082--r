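test_that("diversity and ubiquity equal the defining sums", {
  ident <- diag(2)
  dimnames(ident) <- list(c("a", "b"), c("x", "y"))
  expect_equal(unname(cell_diversity(ident)), c(1, 1))
  expect_equal(unname(gene_ubiquity(ident)), c(1, 1))

  m <- rbind(c(2, 3, 0), c(1, 1, 4))
  dimnames(m) <- list(c("a", "b"), c("x", "y", "z"))
  expect_equal(cell_diversity(m)[["a"]], 5)
  expect_equal(gene_ubiquity(m)[["z"]], 4)

  r <- rand_connected_matrix(5, 7, seed = 3)
  expect_equal(unname(cell_diversity(r)), oracle_diversity(r), tolerance = 1e-12)
  expect_equal(unname(gene_ubiquity(r)), oracle_ubiquity(r), tolerance = 1e-12)

  zr <- rbind(c(1, 1), c(0, 0))
  expect_error(cell_diversity(zr), "zero-diversity")
})

test_that("reflections recursion matches the explicit loop oracle", {
  toy <- toy_bipartite_fixture()
  r <- reflections(toy, n_max = 4, normalize = FALSE)
  o <- oracle_reflections(toy, 4)
  expect_equal(unname(r$cell), o$cell, tolerance = 1e-12)
  expect_equal(unname(r$gene), o$gene, tolerance = 1e-12)

  # hand check of first-order values on the toy fixture:
  # k_{c,1} = sum_g M_cg * k_{g,0} / k_{c,0}; k_{g,0} = (2, 3, 8, 7)
  kg0 <- c(2, 3, 8, 7)
  expect_equal(unname(r$cell[, "k1"]),
               unname(as.numeric(toy %*% kg0) / rowSums(toy)), tolerance = 1e-12)

  rnd <- rand_connected_matrix(6, 9, seed = 5)
  rr <- reflections(rnd, n_max = 6, normalize = FALSE)
  oo <- oracle_reflections(rnd, 6)
  expect_equal(unname(rr$cell), oo$cell, tolerance = 1e-10)
  expect_equal(unname(rr$gene), oo$gene, tolerance = 1e-10)

  expect_error(reflections(toy, n_max = -1), "non-negative")
})

test_that("uniform matrices yield constant complexity at every order", {
  u <- matrix(2, 5, 4, dimnames = list(paste0("c", 1:5), paste0("g", 1:4)))
  r <- reflections(u, n_max = 5, normalize = FALSE)
  for (N in 0:5) {
    expect_equal(diff(range(r$cell_raw[, N + 1])), 0)
    expect_equal(diff(range(r$gene_raw[, N + 1])), 0)
  }
})

test_that("two reflection steps equal one application of the cell-cell matrix", {
  for (seed in 1:3) {
    m <- rand_connected_matrix(8, 12, seed = seed)
    r <- reflections(m, n_max = 2, normalize = FALSE)
    mt <- cell_cell_matrix(m)
    expect_equal(unname(r$cell_raw[, "k2"]), as.numeric(mt %*% rowSums(m)),
                 tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("cell-cell matrix matches the triple-loop oracle and is row-stochastic", {
  m <- rand_connected_matrix(6, 9, seed = 7)
  mt <- cell_cell_matrix(m)
  expect_equal(unname(mt), oracle_mtilde(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rowSums(mt)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(mt >= 0))
  # constant vector is the trivial eigenpair with eigenvalue 1
  expect_equal(as.numeric(mt %*% rep(1, 6)), rep(1, 6), tolerance = 1e-8)

  one <- matrix(5, 1, 1, dimnames = list("c", "g"))
  expect_equal(unname(cell_cell_matrix(one)), matrix(1, 1, 1), ignore_attr = TRUE)

  # disjoint support: block identity
  disj <- rbind(c(1, 2, 0, 0), c(0, 0, 3, 1))
  dimnames(disj) <- list(c("a", "b"), paste0("g", 1:4))
  mtd <- cell_cell_matrix(disj)
  expect_equal(unname(mtd), diag(2), tolerance = 1e-12, ignore_attr = TRUE)

  # sparse input gives the same matrix
  expect_equal(cell_cell_matrix(Matrix::Matrix(m, sparse = TRUE)), mt, tolerance = 1e-12)
})

test_that("analytic CCI is a genuine eigenpair oriented by diversity", {
  sim <- generate_trajectory(trajectory_config(seed = 2, cells_per_stage = 20,
                                               genes_per_tier = 40))
  idx <- sctc_cci(sim$matrix, compute_gci = FALSE)
  mt <- cell_cell_matrix(sim$matrix)
  K <- idx$K_raw
  expect_lt(abs(idx$second_eigenvalue), 1)
  expect_equal(as.numeric(mt %*% K), unname(idx$second_eigenvalue * K), tolerance = 1e-8)
  expect_gt(idx$sign_scc, 0)
  expect_equal(min(idx$cells$cci), 0)
  expect_equal(max(idx$cells$cci), 1)

  # uniform matrix: second eigenvalue is 0 with multiplicity n-1 -> degenerate
  u <- matrix(1, 6, 5, dimnames = list(paste0("c", 1:6), paste0("g", 1:5)))
  expect_error(sctc_cci(u), "degenerate")

  # disconnected bipartite network is refused
  disj <- rbind(c(1, 2, 0, 0), c(1, 1, 0, 0), c(0, 0, 3, 1), c(0, 0, 1, 1))
  dimnames(disj) <- list(paste0("c", 1:4), paste0("g", 1:4))
  expect_error(sctc_cci(disj), "disconnected")
})

test_that("analytic CCI ranking agrees with high even-order recursion", {
  sim <- generate_trajectory(trajectory_config(seed = 3))
  idx <- sctc_cci(sim$matrix, compute_gci = FALSE)
  r <- reflections(sim$matrix, n_max = 40)
  n_star <- select_order(r, idx)
  expect_gte(n_star, 2)
  expect_equal(cor(r$cell[, n_star + 1], idx$cells$cci, method = "spearman"), 1)
})

test_that("GCI matches the loop oracle and its trivial cases", {
  m <- rand_connected_matrix(7, 10, seed = 9)
  idx <- sctc_cci(m)
  q <- numeric(ncol(m))
  for (g in seq_len(ncol(m))) {
    q[g] <- sum(m[, g] * idx$cells$cci) / sum(m[, g])
  }
  expect_equal(unname(idx$Q_raw), q, tolerance = 1e-12)
  expect_equal(idx$genes$gci, (q - min(q)) / (max(q) - min(q)), tolerance = 1e-12)

  # a gene expressed only in the max-CCI cell tops the index
  top_cell <- which.max(idx$cells$cci)
  m2 <- cbind(m, private = 0)
  m2[top_cell, "private"] <- 1
  idx2 <- sctc_cci(m2)
  expect_equal(idx2$genes$gci[idx2$genes$gene == "private"], 1)

  # constant CCI degenerates with a warning
  fake <- idx
  fake$cells$cci <- rep(0.5, nrow(m))
  expect_warning(gci_from_cci(m, fake), "constant")
})

test_that("external-GCI transfer is self-consistent and guards its inputs", {
  sim <- generate_trajectory(trajectory_config(seed = 4, cells_per_stage = 25,
                                               genes_per_tier = 50))
  idx <- sctc_cci(sim$matrix)
  own_gci <- stats::setNames(idx$genes$gci, idx$genes$gene)
  tr <- cci_from_external_gci(sim$matrix, own_gci)
  # self-transfer = one reflection step applied to own GCI
  ktot <- rowSums(sim$matrix)
  expected <- unname(as.numeric(sim$matrix %*% own_gci) / ktot)
  expect_equal(unname(tr$K_raw), expected, tolerance = 1e-12)
  expect_true(tr$transferred)

  expect_warning(
    out <- cci_from_external_gci(sim$matrix, stats::setNames(rep(0.3, ncol(sim$matrix)),
                                                             colnames(sim$matrix))),
    "constant")
  expect_error(cci_from_external_gci(sim$matrix, c(nope = 1)), "no genes shared")
  expect_error(cci_from_external_gci(sim$matrix, unname(own_gci)), "named")
})

test_that("pseudotime is the complement of CCI", {
  m <- rand_connected_matrix(10, 14, seed = 12)
  idx <- sctc_cci(m, compute_gci = FALSE)
  pt <- pseudotime(idx)
  expect_equal(unname(pt), 1 - idx$cells$cci)
  expect_equal(unname(pt[which.max(idx$cells$cci)]), 0)   # most complex = earliest
})

test_that("convergence threshold reports collapse of the raw recursion", {
  u <- matrix(3, 4, 4, dimnames = list(paste0("c", 1:4), paste0("g", 1:4)))
  expect_identical(convergence_threshold(reflections(u, 4), tol = 1e-9), 0L)

  sim <- generate_trajectory(trajectory_config(seed = 5, cells_per_stage = 15,
                                               genes_per_tier = 30))
  r <- reflections(sim$matrix, n_max = 100)
  expect_identical(convergence_threshold(r, tol = 0), NA_integer_)
  nth <- convergence_threshold(r, tol = 1e-3)
  expect_false(is.na(nth))
  expect_gt(nth, 0)
  # by the collapse order the recursion ranking has locked onto the CCI ranking
  idx <- sctc_cci(sim$matrix, compute_gci = FALSE)
  expect_gte(cor(r$cell_raw[, nth + 1], idx$cells$cci, method = "spearman"), 0.99)
})

test_that("order selection maximizes agreement with CCI", {
  m <- rand_connected_matrix(12, 16, seed = 20)
  idx <- sctc_cci(m, compute_gci = FALSE)
  r0 <- reflections(m, n_max = 0)
  expect_identical(select_order(r0, idx), 0L)
  # when CCI is rank-identical to a column, that column's order wins
  r <- reflections(m, n_max = 30)
  n_star <- select_order(r, idx)
  sccs <- sapply(seq(0, 30, 2), function(N) cor(r$cell_raw[, N + 1], idx$cells$cci,
                                                method = "spearman"))
  expect_equal(max(sccs), cor(r$cell_raw[, n_star + 1], idx$cells$cci, method = "spearman"))
})

test_that("gene and cell columns respect the weighted-average bounds", {
  sim <- generate_trajectory(trajectory_config(seed = 6, cells_per_stage = 15,
                                               genes_per_tier = 30))
  r <- reflections(sim$matrix, n_max = 7, normalize = FALSE)
  for (N in 1:7) {
    expect_gte(min(r$cell_raw[, N + 1]), min(r$gene_raw[, N]) - 1e-10)
    expect_lte(max(r$cell_raw[, N + 1]), max(r$gene_raw[, N]) + 1e-10)
    expect_gte(min(r$gene_raw[, N + 1]), min(r$cell_raw[, N]) - 1e-10)
    expect_lte(max(r$gene_raw[, N + 1]), max(r$cell_raw[, N]) + 1e-10)
  }
})

test_that("even and odd cell orders anticorrelate on nested data", {
  sim <- generate_trajectory(trajectory_config(seed = 1))
  r <- reflections(sim$matrix, n_max = 4, normalize = FALSE)
  expect_lt(cor(r$cell_raw[, "k1"], r$cell_raw[, "k2"], method = "spearman"), 0)
  expect_lt(cor(r$cell_raw[, "k2"], r$cell_raw[, "k3"], method = "spearman"), 0)
})

test_that("positive rescaling of the matrix leaves all rankings unchanged", {
  m <- rand_connected_matrix(9, 13, seed = 30)
  idx1 <- sctc_cci(m)
  idx2 <- sctc_cci(m * 7.3)
  expect_equal(idx1$cells$cci, idx2$cells$cci, tolerance = 1e-8)
  expect_equal(idx1$genes$gci, idx2$genes$gci, tolerance = 1e-8)
  r1 <- reflections(m, 6, normalize = FALSE)
  r2 <- reflections(m * 7.3, 6, normalize = FALSE)
  for (N in 0:6) {
    expect_equal(cor(r1$cell_raw[, N + 1], r2$cell_raw[, N + 1], method = "spearman"), 1)
  }
})
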