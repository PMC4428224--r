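test_that("edge sign classes partition all edges", {
  m1 <- matrix(c(1, 0.3, -0.2, 0.3, 1, 0.4, -0.2, 0.4, 1), 3, 3)
  m2 <- matrix(c(1, 0.1, 0.1, 0.1, 1, 0.2, 0.1, 0.2, 1), 3, 3)
  cls <- classify_edge_signs(m1, m2)
  expect_equal(cls, c("positive", "mixed", "positive"))
  set.seed(12)
  a <- matrix(stats::rnorm(100), 10, 10); a <- (a + t(a)) / 2
  b <- matrix(stats::rnorm(100), 10, 10); b <- (b + t(b)) / 2
  cls2 <- classify_edge_signs(a, b)
  expect_equal(length(cls2), 45L)
  expect_equal(sum(cls2 == "positive") + sum(cls2 == "negative") +
                 sum(cls2 == "mixed"), 45L)
  expect_message(classify_edge_signs(a * 0, b), "zero")
  expect_error(classify_edge_signs(a, b[1:5, 1:5]), "conformable")
})

test_that("consistency metric closed forms", {
  for (k in c(1, 5, 100)) {
    expect_equal(consistency_metric(2 * k, k), 1 / 3)
    expect_equal(consistency_metric(k, 0), 1)
    expect_equal(consistency_metric(0, k), -1)
    expect_equal(consistency_metric(k, k), 0)
  }
  expect_error(consistency_metric(0, 0), "undefined")
  expect_error(consistency_metric(-1, 2), "nonnegative")
})

make_edge_table <- function(n_per_block, d_values, sign_class = "positive",
                            blocks = names(n_per_block)) {
  stopifnot(sum(n_per_block) == length(d_values))
  structure(
    data.frame(node_i = seq_along(d_values), node_j = seq_along(d_values) + 1L,
               block = rep(blocks, n_per_block),
               sign_class = sign_class,
               cohens_d = d_values,
               suprathreshold = abs(d_values) >= 0.5,
               stringsAsFactors = FALSE),
    class = c("edge_effects", "data.frame"))
}

fake_block_index <- function(blocks) {
  structure(list(blocks = data.frame(block = blocks,
                                     stringsAsFactors = FALSE)),
            class = "block_index")
}

test_that("retention and consistency rules follow the screening protocol", {
  # block A: 100 edges, 4 suprathreshold -> below the 5% rule, no metric
  # block B: 100 edges, 10 suprathreshold, 8 favoring group 1 -> 0.6
  # block C: 100 edges, exactly 5 suprathreshold -> boundary retained
  d <- c(c(rep(0.6, 4), rep(0.1, 96)),
         c(rep(0.7, 8), rep(-0.7, 2), rep(0.05, 90)),
         c(rep(-0.55, 5), rep(0.2, 95)))
  et <- make_edge_table(c(A = 100L, B = 100L, C = 100L), d)
  ct <- block_consistency(et, fake_block_index(c("A", "B", "C")), "positive")
  expect_equal(ct$retained_fraction, c(0.04, 0.10, 0.05))
  expect_true(is.na(ct$consistency[ct$block == "A"]))
  expect_equal(ct$consistency[ct$block == "B"], 0.6)
  expect_true(ct$highly_consistent[ct$block == "B"])
  expect_equal(ct$direction[ct$block == "B"], "G1")
  # boundary case: exactly 5% is retained ("at least 5%")
  expect_equal(ct$consistency[ct$block == "C"], -1)
  expect_equal(ct$direction[ct$block == "C"], "G2")
  # consistency magnitude below 0.33 is not flagged
  d2 <- c(rep(0.6, 6), rep(-0.6, 5), rep(0, 89))
  et2 <- make_edge_table(c(A = 100L), d2)
  ct2 <- block_consistency(et2, fake_block_index("A"), "positive")
  expect_equal(ct2$consistency, (6 - 5) / 11)
  expect_false(ct2$highly_consistent)
})

test_that("swapping group labels negates edgewise d and consistency", {
  ch <- generate_group_timeseries(
    tiny_design(planted_effects = list(list(module_a = 1, module_b = 2,
                                            delta = 0.3, group = 1)),
                n_timepoints = 800L, seed = 8L))
  cn <- cohort_connectomes(ch)
  bi <- enumerate_blocks(ch$parcellation)
  ee1 <- edgewise_effects(cn, ch$group, bi)
  flipped <- factor(ch$group, levels = rev(levels(ch$group)))
  ee2 <- edgewise_effects(cn, flipped, bi)
  expect_equal(ee1$cohens_d, -ee2$cohens_d, tolerance = 1e-12)
  expect_equal(ee1$sign_class, ee2$sign_class)
  ct1 <- block_consistency(ee1, bi, "positive")
  ct2 <- block_consistency(ee2, bi, "positive")
  expect_equal(ct1$consistency, -ct2$consistency, tolerance = 1e-12)
})

test_that("per-class eligible edges account for every edge of the class", {
  ch <- generate_group_timeseries(tiny_design(seed = 15L))
  cn <- cohort_connectomes(ch)
  bi <- enumerate_blocks(ch$parcellation)
  ee <- edgewise_effects(cn, ch$group, bi)
  for (cls in c("positive", "negative")) {
    ct <- block_consistency(ee, bi, cls)
    expect_equal(sum(ct$n_edges_class), sum(ee$sign_class == cls))
  }
  expect_equal(nrow(ee), sum(bi$blocks$n_edges))
  expect_true(all(ee$suprathreshold == (abs(ee$cohens_d) >= 0.5)))
})

test_that("modulewise overlap flags blocks passing both screens", {
  ch <- generate_group_timeseries(
    tiny_design(planted_effects = list(list(module_a = 1, module_b = 2,
                                            delta = 0.3, group = 1)),
                base_between_corr = 0.1,  # planted block positive in both groups
                n_timepoints = 1000L, seed = 4L))
  cn <- cohort_connectomes(ch)
  bi <- enumerate_blocks(ch$parcellation)
  sm <- summarize_blocks(cn, bi, ch$group)
  cmp <- compare_blocks(sm)
  ee <- edgewise_effects(cn, ch$group, bi)
  ct <- block_consistency(ee, bi, "positive", modulewise = cmp)
  mw_pos <- cmp$block[cmp$selected & cmp$sign_class == "positive"]
  expect_equal(ct$modulewise_overlap, ct$block %in% mw_pos)
  expect_true(ct$modulewise_overlap[ct$block == "M1-M2"])
})
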