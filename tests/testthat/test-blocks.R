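test_that("block enumeration partitions the upper triangle exactly", {
  d <- simulation_design(nodes_per_module = reference_module_sizes())
  bi <- enumerate_blocks(generate_parcellation(d))
  expect_equal(nrow(bi$blocks), 45L)
  expect_equal(sum(bi$blocks$n_edges), 21736L)
  expect_equal(sum(bi$blocks$n_edges), 209L * 208L / 2L)
  # within-module block sizes k(k-1)/2, between-module k*l
  sizes <- reference_module_sizes()
  within <- bi$blocks$module_a == bi$blocks$module_b
  expect_equal(bi$blocks$n_edges[within],
               unname(sizes * (sizes - 1) / 2))
  kl <- mapply(function(a, b) sizes[[a]] * sizes[[b]],
               bi$blocks$module_a[!within], bi$blocks$module_b[!within])
  expect_equal(bi$blocks$n_edges[!within], unname(kl))
  # every edge assigned to exactly one block
  expect_equal(sort(unname(unlist(lapply(bi$edges, function(e)
    (e[, 2L] - 1L) * 209L + e[, 1L])))),
    sort(unname((bi$edge_pairs[, 2L] - 1L) * 209L + bi$edge_pairs[, 1L])))
})

test_that("two modules give three blocks; one module errors", {
  parc <- data.frame(node_id = 1:5, module = factor(rep(c("A", "B"), c(2, 3))))
  bi <- enumerate_blocks(parc)
  expect_equal(bi$blocks$block, c("A-A", "A-B", "B-B"))
  expect_equal(bi$blocks$n_edges, c(1L, 6L, 3L))
  expect_error(enumerate_blocks(data.frame(node_id = 1:3,
                                           module = rep("A", 3))),
               "at least 2 modules")
})

test_that("block edge matrices round-trip connectome entries", {
  ch <- generate_group_timeseries(tiny_design())
  cn <- cohort_connectomes(ch)
  bi <- enumerate_blocks(ch$parcellation)
  em <- block_edge_matrix(cn, bi, "M1-M2")
  expect_equal(dim(em), c(12L, length(cn)))  # 3*4 between-module edges
  e <- bi$edges[["M1-M2"]]
  for (s in c(1L, 5L)) {
    expect_equal(unname(em[, s]), cn[[s]][e])
  }
  # single-edge block is a 1 x n row
  em1 <- block_edge_matrix(cn, bi, "M1-M1")
  expect_equal(nrow(block_edge_matrix(cn, bi, "M3-M3")), 3L)
  expect_equal(dim(em1), c(3L, length(cn)))
  # node-order mismatch is refused
  cn_bad <- cn
  colnames(cn_bad[[2]]) <- rev(colnames(cn_bad[[2]]))
  expect_error(block_edge_matrix(cn_bad, bi, "M1-M2"), "node order")
})

test_that("block SVD recovers a planted rank-1 structure exactly", {
  set.seed(31)
  u <- stats::rnorm(10)
  u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(8)
  v <- v - mean(v)  # zero-sum coordinates, as after row-demeaning
  X <- 3 * u %*% t(v)
  # arbitrary per-edge offsets: row-demeaning must remove them exactly
  X_raw <- X + outer(stats::rnorm(10), rep(1, 8))
  s <- block_svd_summary(X_raw)
  expect_equal(abs(sum(s$left_vector * u)), 1, tolerance = 1e-10)
  expect_equal(abs(stats::cor(s$coordinates, drop(v))), 1, tolerance = 1e-10)
  expect_equal(s$variance_explained, 1, tolerance = 1e-12)
})

test_that("single-edge blocks yield the demeaned edge values as coordinates", {
  x <- matrix(c(0.3, 0.5, 0.1, 0.4), 1, 4)
  s <- block_svd_summary(x)
  centered <- drop(x) - mean(x)
  expect_equal(abs(stats::cor(s$coordinates, centered)), 1, tolerance = 1e-12)
  expect_equal(sort(abs(s$coordinates)), sort(abs(centered)),
               tolerance = 1e-12)
})

test_that("block SVD matches an independent Gram-matrix eigendecomposition", {
  set.seed(17)
  for (i in 1:5) {
    m <- sample(2:60, 1)
    X <- matrix(stats::rnorm(m * 24), m, 24)
    s <- block_svd_summary(X)
    Xd <- X - rowMeans(X)
    G <- crossprod(Xd)  # 24 x 24 Gram matrix
    eg <- eigen(G, symmetric = TRUE)
    sigma1 <- sqrt(eg$values[1])
    expect_equal(s$singular_value, sigma1, tolerance = 1e-10)
    v1 <- eg$vectors[, 1]
    expect_equal(abs(sum(s$coordinates / s$singular_value * v1)), 1,
                 tolerance = 1e-10)
  }
  expect_error(block_svd_summary(matrix(1, 4, 6)), "no between-subject")
})

test_that("coordinates sum to zero and are subject-order equivariant", {
  set.seed(23)
  X <- matrix(stats::rnorm(20 * 24), 20, 24)
  s <- block_svd_summary(X)
  expect_lt(abs(sum(s$coordinates)), 1e-10)
  expect_true(s$variance_explained >= 0 && s$variance_explained <= 1)
  perm <- sample(24)
  s2 <- block_svd_summary(X[, perm])
  expect_equal(abs(unname(s2$coordinates)), abs(unname(s$coordinates[perm])),
               tolerance = 1e-8)
  # edge order within the block is irrelevant
  s3 <- block_svd_summary(X[sample(20), ])
  expect_equal(abs(unname(s3$coordinates)), abs(unname(s$coordinates)),
               tolerance = 1e-8)
})

test_that("block mean connectivity matches a hand-computed toy fixture", {
  # 4 nodes, 2 modules of 2; two subjects with known matrices
  M1 <- diag(4)
  M1[upper.tri(M1)] <- c(0.5, 0.1, 0.2, 0.3, 0.4, -0.5)
  M1[lower.tri(M1)] <- t(M1)[lower.tri(M1)]
  M2 <- diag(4)
  M2[upper.tri(M2)] <- c(0.7, -0.1, 0.0, 0.1, 0.2, -0.3)
  M2[lower.tri(M2)] <- t(M2)[lower.tri(M2)]
  colnames(M1) <- rownames(M1) <- colnames(M2) <- rownames(M2) <-
    paste0("n", 1:4)
  parc <- data.frame(node_id = paste0("n", 1:4),
                     module = factor(rep(c("A", "B"), each = 2)))
  bi <- enumerate_blocks(parc)
  groups <- factor(c("g1", "g2"))
  bm <- block_mean_connectivity(list(M1, M2), bi, "A-B", groups)
  # A-B edges of M1: (1,3),(2,3),(1,4),(2,4) = 0.1,0.3,0.2,0.4 -> mean 0.25
  expect_equal(unname(bm$subject_means), c(0.25, 0.05))
  expect_equal(as.numeric(bm$group_means), c(0.25, 0.05))
  expect_equal(as.numeric(bm$dominant_sign), c(1, 1))
  bmB <- block_mean_connectivity(list(M1, M2), bi, "B-B", groups)
  expect_equal(unname(bmB$subject_means), c(-0.5, -0.3))
  expect_equal(as.numeric(bmB$dominant_sign), c(-1, -1))
  # degenerate means: edges (+0.2, -0.2) average to zero
  expect_equal(mean(c(0.2, -0.2)), 0)
})

test_that("summarize_blocks aligns coordinates with block mean strength", {
  ch <- generate_group_timeseries(
    tiny_design(planted_effects = list(list(module_a = 1, module_b = 2,
                                            delta = 0.3, group = 1)),
                n_timepoints = 1000L))
  cn <- cohort_connectomes(ch)
  bi <- enumerate_blocks(ch$parcellation)
  sm <- summarize_blocks(cn, bi, ch$group)
  expect_equal(dim(sm$coordinates), c(8L, 6L))
  expect_lt(max(abs(colSums(sm$coordinates))), 1e-10)
  # positive alignment with per-subject block means for every block
  for (b in colnames(sm$coordinates)) {
    al <- stats::cor(sm$coordinates[, b], sm$mean_connectivity[, b])
    expect_gte(al, 0)
  }
  # the planted block separates the groups in the planted direction
  co <- sm$coordinates[, "M1-M2"]
  expect_gt(mean(co[ch$group == "g1"]), mean(co[ch$group == "g2"]))
})
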