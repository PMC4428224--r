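#' Classify edges by the sign of their group-average connectivity
#'
#' An edge is `positive` if its group-mean correlation is positive in both
#' groups, `negative` if negative in both, and `mixed` otherwise; exact
#' zeros are classed `mixed` (with a message). The edgewise screens are run
#' separately on the positive and negative classes; mixed edges are excluded.
#'
#' @param group1_mean_matrix,group2_mean_matrix Symmetric group-average
#'   connectivity matrices.
#' @param edge_pairs Optional `E x 2` matrix of node-index pairs; defaults to
#'   the full upper triangle in canonical edge order.
#' @return Character vector over edges: "positive", "negative" or "mixed".
#' @export
classify_edge_signs <- function(group1_mean_matrix, group2_mean_matrix,
                                edge_pairs = NULL) {
  if (!identical(dim(group1_mean_matrix), dim(group2_mean_matrix)))
    stop("group mean matrices are not conformable")
  if (is.null(edge_pairs)) edge_pairs <- upper_tri_pairs(nrow(group1_mean_matrix))
  m1 <- group1_mean_matrix[edge_pairs]
  m2 <- group2_mean_matrix[edge_pairs]
  if (any(m1 == 0 | m2 == 0))
    message(sum(m1 == 0 | m2 == 0),
            " edge(s) with an exactly zero group mean classed as 'mixed'")
  ifelse(m1 > 0 & m2 > 0, "positive",
         ifelse(m1 < 0 & m2 < 0, "negative", "mixed"))
}

#' Edgewise effect sizes over a cohort
#'
#' Computes the signed Cohen's d (group 1 minus group 2) of every unique
#' edge, its block membership, its sign class, and whether it passes the
#' effect-size threshold.
#'
#' @param connectomes List of subject connectivity matrices.
#' @param groups Two-level factor of subject group labels.
#' @param block_index A [enumerate_blocks()] result.
#' @param d_threshold Effect-size threshold (default 0.5).
#' @return An `edge_effects` data frame: `node_i`, `node_j`, `block`,
#'   `sign_class`, `cohens_d`, `suprathreshold`.
#' @export
edgewise_effects <- function(connectomes, groups, block_index,
                             d_threshold = 0.5) {
  connectomes <- as_connectome_list(connectomes)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  pairs <- block_index$edge_pairs
  E <- nrow(pairs)
  vals <- vapply(connectomes, function(M) M[pairs], numeric(E))
  is_g1 <- groups == levels(groups)[1L]
  x <- vals[, is_g1, drop = FALSE]
  y <- vals[, !is_g1, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  sp2 <- ((n1 - 1) * row_vars(x) + (n2 - 1) * row_vars(y)) / (n1 + n2 - 2)
  d <- (rowMeans(x) - rowMeans(y)) / sqrt(sp2)
  mx <- rowMeans(x); my <- rowMeans(y)
  cls <- ifelse(mx > 0 & my > 0, "positive",
                ifelse(mx < 0 & my < 0, "negative", "mixed"))
  out <- data.frame(node_i = pairs[, 1L], node_j = pairs[, 2L],
                    block = block_index$blocks$block[block_index$edge_block],
                    sign_class = cls,
                    cohens_d = d,
                    suprathreshold = abs(d) >= d_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "d_threshold") <- d_threshold
  attr(out, "groups") <- levels(groups)
  class(out) <- c("edge_effects", "data.frame")
  out
}

row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

#' Directional consistency metric
#'
#' `(n1 - n2) / (n1 + n2)` over the suprathreshold edges of a block favoring
#' group 1 (`n1`) versus group 2 (`n2`). A value of 1 (or -1) is full
#' directional consistency; 0 is a complete lack of it. A threshold of 0.33
#' corresponds to at least twice as many edges favoring one group as the
#' other.
#'
#' @param n1,n2 Nonnegative edge counts, `n1 + n2 > 0`.
#' @return Value in \[-1, 1\].
#' @export
consistency_metric <- function(n1, n2) {
  if (any(n1 < 0) || any(n2 < 0)) stop("counts must be nonnegative")
  if (any(n1 + n2 == 0)) stop("consistency metric undefined for n1 + n2 = 0")
  (n1 - n2) / (n1 + n2)
}

#' Per-block directional consistency of edgewise effects
#'
#' For one sign class at a time, counts each block's suprathreshold edges by
#' direction of the group difference, computes the fraction of the block's
#' (sign-class) edges retained by the effect-size threshold, and — for blocks
#' retaining at least `retention_threshold` of their edges — the consistency
#' metric and a high-consistency flag. The retention comparison is exact
#' (">= 5%" keeps a block sitting exactly on the boundary). Direction counts
#' use the sign of the raw-correlation d: for the negative class, an edge
#' with `d < 0` favors group 1's (stronger) negative connectivity.
#'
#' @param edge_effects An [edgewise_effects()] table.
#' @param block_index A [enumerate_blocks()] result.
#' @param sign_class `"positive"` or `"negative"`.
#' @param retention_threshold Minimum retained fraction (default 0.05). The
#'   denominator is the number of the block's edges belonging to the current
#'   sign class, since the analysis is run separately per class.
#' @param consistency_threshold High-consistency cutoff on `|metric|`
#'   (default 0.33).
#' @param modulewise Optional [compare_blocks()] table; if given, blocks are
#'   cross-referenced: `modulewise_overlap` is `TRUE` when the block also
#'   passed the modulewise effect-size screen with matching sign class.
#' @return A `consistency_table` data frame, one row per block with at least
#'   one sign-class edge: counts by direction, `retained_fraction`,
#'   `consistency` (NA when below retention), `highly_consistent`,
#'   `direction`, and optionally `modulewise_overlap`.
#' @export
block_consistency <- function(edge_effects, block_index,
                              sign_class = c("positive", "negative"),
                              retention_threshold = 0.05,
                              consistency_threshold = 0.33,
                              modulewise = NULL) {
  sign_class <- match.arg(sign_class)
  ee <- edge_effects[edge_effects$sign_class == sign_class, , drop = FALSE]
  ids <- block_index$blocks$block
  n_class <- table(factor(ee$block, levels = ids))
  supra <- ee[ee$suprathreshold, , drop = FALSE]
  n1 <- table(factor(supra$block[supra$cohens_d > 0], levels = ids))
  n2 <- table(factor(supra$block[supra$cohens_d < 0], levels = ids))
  keep <- n_class > 0L
  out <- data.frame(block = ids[keep],
                    sign_class = sign_class,
                    n_edges_class = as.integer(n_class[keep]),
                    n_g1_gt_g2 = as.integer(n1[keep]),
                    n_g2_gt_g1 = as.integer(n2[keep]),
                    stringsAsFactors = FALSE)
  out$retained_fraction <- (out$n_g1_gt_g2 + out$n_g2_gt_g1) / out$n_edges_class
  retained <- mapply(frac_ge, out$n_g1_gt_g2 + out$n_g2_gt_g1,
                     out$n_edges_class,
                     MoreArgs = list(threshold = retention_threshold))
  total <- out$n_g1_gt_g2 + out$n_g2_gt_g1
  out$consistency <- ifelse(retained & total > 0,
                            (out$n_g1_gt_g2 - out$n_g2_gt_g1) /
                              pmax(total, 1L), NA_real_)
  if (any(retained & total == 0))
    message("block(s) retained with zero suprathreshold edges skipped: ",
            paste(out$block[retained & total == 0], collapse = ", "))
  out$highly_consistent <- !is.na(out$consistency) &
    abs(out$consistency) >= consistency_threshold
  out$direction <- ifelse(is.na(out$consistency), NA_character_,
                          ifelse(out$consistency >= 0, "G1", "G2"))
  if (!is.null(modulewise)) {
    mw <- modulewise[modulewise$selected &
                       modulewise$sign_class == sign_class, , drop = FALSE]
    out$modulewise_overlap <- out$block %in% mw$block
  }
  attr(out, "retention_threshold") <- retention_threshold
  attr(out, "consistency_threshold") <- consistency_threshold
  class(out) <- c("consistency_table", "data.frame")
  out
}

#' @export
print.consistency_table <- function(x, ...) {
  cat("Edgewise consistency (", x$sign_class[1], " edges): ",
      sum(x$highly_consistent), " of ", nrow(x),
      " blocks highly consistent\n", sep = "")
  sel <- x[x$highly_consistent, , drop = FALSE]
  if (nrow(sel))
    print(as.data.frame(sel)[order(-abs(sel$consistency)),
                             c("block", "consistency", "retained_fraction",
                               "direction")],
          row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write consistency tables and an edge list
#'
#' One CSV per sign class mirroring the per-block consistency summary, plus
#' an optional suprathreshold edge list (node pairs and d) for external
#' graph rendering.
#'
#' @param tables Named list of `consistency_table`s (names = sign classes).
#' @param dir Output directory.
#' @param edge_effects Optional [edgewise_effects()] table for the edge list.
#' @return Invisibly, the written paths.
#' @export
write_consistency_csv <- function(tables, dir, edge_effects = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0("consistency_", nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(edge_effects)) {
    p <- file.path(dir, "suprathreshold_edges.csv")
    utils::write.csv(
      as.data.frame(edge_effects[edge_effects$suprathreshold, , drop = FALSE]),
      p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
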