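block_id <- function(a, b, module_names) {
  ia <- match(a, module_names)
  ib <- match(b, module_names)
  if (is.na(ia) || is.na(ib)) stop("unknown module in block id")
  if (ia <= ib) paste0(a, "-", b) else paste0(b, "-", a)
}

#' Enumerate module-module blocks of the upper-triangle edge set
#'
#' Partitions the strict upper triangle of the node-by-node connectivity
#' matrix into `K` within-module plus `K(K-1)/2` between-module blocks, in
#' canonical module order. For the reference 9-module system this yields 45
#' blocks covering all 21,736 unique edges of the 209-node network.
#'
#' @param parcellation Parcellation data frame whose `module` factor carries
#'   the canonical level order.
#' @return An object of class `"block_index"`: a data frame `blocks`
#'   (`block`, `module_a`, `module_b`, `n_edges`), an `edges` list of
#'   `m_i x 2` node-index matrices (i < j, ordered by column then row), and
#'   the global edge-to-block assignment.
#' @export
enumerate_blocks <- function(parcellation) {
  mod <- parcellation$module
  if (!is.factor(mod)) mod <- factor(mod, levels = unique(mod))
  mod <- droplevels(mod)
  K <- nlevels(mod)
  if (K < 2L) stop("need at least 2 modules to enumerate blocks")
  n <- length(mod)
  pairs <- upper_tri_pairs(n)
  ma <- as.integer(mod)[pairs[, 1L]]
  mb <- as.integer(mod)[pairs[, 2L]]
  lo <- pmin(ma, mb)
  hi <- pmax(ma, mb)

  combos <- cbind(rep(seq_len(K), times = K - seq_len(K) + 1L),
                  unlist(lapply(seq_len(K), function(a) a:K)))
  ids <- paste0(levels(mod)[combos[, 1L]], "-", levels(mod)[combos[, 2L]])
  key <- (lo - 1L) * K + hi
  combo_key <- (combos[, 1L] - 1L) * K + combos[, 2L]
  edge_block <- match(key, combo_key)

  edges <- lapply(seq_len(nrow(combos)), function(b) {
    e <- pairs[edge_block == b, , drop = FALSE]
    e[order(e[, 2L], e[, 1L]), , drop = FALSE]
  })
  names(edges) <- ids
  blocks <- data.frame(block = ids,
                       module_a = levels(mod)[combos[, 1L]],
                       module_b = levels(mod)[combos[, 2L]],
                       n_edges = vapply(edges, nrow, 0L),
                       stringsAsFactors = FALSE)
  structure(list(blocks = blocks, edges = edges, edge_block = edge_block,
                 edge_pairs = pairs, modules = levels(mod), n_nodes = n),
            class = "block_index")
}

#' @export
print.block_index <- function(x, ...) {
  cat("Block index:", nrow(x$blocks), "blocks over", x$n_nodes, "nodes (",
      length(x$modules), "modules ),", sum(x$blocks$n_edges),
      "edges in total\n")
  invisible(x)
}

as_connectome_list <- function(connectomes) {
  if (is.matrix(connectomes)) connectomes <- list(connectomes)
  ref <- colnames(connectomes[[1]])
  for (M in connectomes) {
    if (!identical(dim(M)[1], dim(connectomes[[1]])[1]))
      stop("connectomes have mismatched node counts")
    if (!is.null(ref) && !identical(colnames(M), ref))
      stop("connectomes have mismatched node order")
  }
  connectomes
}

#' Edge-by-subject matrix for one block
#'
#' Stacks each subject's edge values of one block side by side: entry
#' `(e, s)` is subject `s`'s correlation at the block's `e`-th edge in the
#' block's canonical edge order.
#'
#' @param connectomes List of subject connectivity matrices in a shared node
#'   order.
#' @param block_index A [enumerate_blocks()] result.
#' @param block Block id (e.g. `"EC-FPR"`) or index.
#' @return `m_i x n_subjects` matrix.
#' @export
block_edge_matrix <- function(connectomes, block_index, block) {
  connectomes <- as_connectome_list(connectomes)
  e <- block_edges(block_index, block)
  out <- vapply(connectomes, function(M) M[e], numeric(nrow(e)))
  out <- matrix(out, nrow = nrow(e))
  colnames(out) <- vapply(seq_along(connectomes), function(s)
    as.character(attr(connectomes[[s]], "subject_id") %||%
                   names(connectomes)[s] %||% s), "")
  out
}

block_edges <- function(block_index, block) {
  if (is.numeric(block)) {
    block_index$edges[[block]]
  } else {
    if (!block %in% names(block_index$edges)) stop("unknown block: ", block)
    block_index$edges[[block]]
  }
}

#' First-principal-component summary of one block
#'
#' Removes the mean from each row (edge) of the `m_i x n_subjects` block
#' matrix and takes the first singular pair of the result. The first left
#' singular vector is the block's edge-loading pattern; the per-subject
#' coordinates are the first right singular vector scaled by the first
#' singular value (principal-component scores). Because row-demeaning puts
#' the all-ones vector in the null space, coordinates sum to zero by
#' construction. SVD sign is fixed by aligning coordinates to correlate
#' positively with per-subject block mean connectivity; if that correlation
#' is exactly zero the first nonzero loading is made positive instead, with
#' a warning.
#'
#' @param edge_matrix Raw (not demeaned) `m_i x n_subjects` block matrix, as
#'   from [block_edge_matrix()].
#' @return An object of class `"block_summary"`: `left_vector` (unit norm),
#'   `coordinates` (length `n_subjects`), `variance_explained`
#'   (sigma_1^2 / sum sigma_k^2), and `mean_connectivity` (per-subject block
#'   means).
#' @export
block_svd_summary <- function(edge_matrix) {
  edge_matrix <- as.matrix(edge_matrix)
  m <- nrow(edge_matrix)
  n <- ncol(edge_matrix)
  if (n < 2L) stop("need at least 2 subjects")
  subject_means <- colMeans(edge_matrix)
  X <- edge_matrix - rowMeans(edge_matrix)
  if (all(abs(X) < 1e-14))
    stop("block has no between-subject variation after row-demeaning")
  sv <- svd(X)
  u <- sv$u[, 1L]
  v <- sv$v[, 1L]
  d1 <- sv$d[1L]
  coords <- d1 * v
  al <- stats::cov(coords, subject_means)
  if (is.finite(al) && abs(al) > 1e-14) {
    if (al < 0) { u <- -u; coords <- -coords }
  } else {
    warning("coordinates uncorrelated with block mean connectivity; ",
            "sign fixed by first nonzero loading")
    nz <- which(abs(u) > 1e-14)[1L]
    if (u[nz] < 0) { u <- -u; coords <- -coords }
  }
  structure(list(left_vector = u,
                 coordinates = stats::setNames(coords, colnames(edge_matrix)),
                 singular_value = d1,
                 variance_explained = d1^2 / sum(sv$d^2),
                 mean_connectivity = subject_means,
                 m_edges = m),
            class = "block_summary")
}

#' Per-subject and per-group block mean connectivity
#'
#' Arithmetic mean of all edgewise correlations in a block, per subject, plus
#' group means and the dominant connectivity sign of each group. These means
#' restore the sign context that the SVD coordinates lack.
#'
#' @param connectomes List of subject connectivity matrices.
#' @param block_index A [enumerate_blocks()] result.
#' @param block Block id or index.
#' @param groups Optional factor of group labels (two levels).
#' @return List with `subject_means`, and when `groups` is given,
#'   `group_means` and `dominant_sign` (+1/-1 per group).
#' @export
block_mean_connectivity <- function(connectomes, block_index, block,
                                    groups = NULL) {
  em <- block_edge_matrix(connectomes, block_index, block)
  subject_means <- colMeans(em)
  out <- list(subject_means = subject_means)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    gm <- tapply(subject_means, groups, mean)
    out$group_means <- gm
    out$dominant_sign <- sign(gm)
  }
  out
}

#' Summarize every block of a cohort of connectomes
#'
#' Runs [block_svd_summary()] and [block_mean_connectivity()] over all blocks
#' jointly across subjects of both groups (a single SVD per block, all
#' subject columns together).
#'
#' @param connectomes List of subject connectivity matrices.
#' @param block_index A [enumerate_blocks()] result.
#' @param groups Optional two-level factor of subject group labels.
#' @return An object of class `"block_summaries"`: `coordinates`
#'   (`subject x block` matrix), `summaries` (list of `block_summary`),
#'   `mean_connectivity` (`subject x block`), `block_info` data frame with
#'   per-group mean connectivity and sign class
#'   (positive/negative/mixed across the two group means).
#' @export
summarize_blocks <- function(connectomes, block_index, groups = NULL) {
  connectomes <- as_connectome_list(connectomes)
  ids <- block_index$blocks$block
  summaries <- vector("list", length(ids))
  names(summaries) <- ids
  n_sub <- length(connectomes)
  coords <- matrix(NA_real_, n_sub, length(ids),
                   dimnames = list(NULL, ids))
  meanc <- coords
  for (b in seq_along(ids)) {
    em <- block_edge_matrix(connectomes, block_index, b)
    s <- block_svd_summary(em)
    summaries[[b]] <- s
    coords[, b] <- s$coordinates
    meanc[, b] <- s$mean_connectivity
  }
  subj <- colnames(block_edge_matrix(connectomes, block_index, 1L))
  rownames(coords) <- rownames(meanc) <- subj
  info <- data.frame(block = ids,
                     n_edges = block_index$blocks$n_edges,
                     variance_explained =
                       vapply(summaries, `[[`, 0, "variance_explained"),
                     stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
    g1 <- levels(groups)[1L]
    info$group1_mean <- colMeans(meanc[groups == g1, , drop = FALSE])
    info$group2_mean <- colMeans(meanc[groups != g1, , drop = FALSE])
    info$sign_class <- sign_class(info$group1_mean, info$group2_mean)
  }
  structure(list(coordinates = coords, summaries = summaries,
                 mean_connectivity = meanc, block_info = info,
                 groups = groups),
            class = "block_summaries")
}

sign_class <- function(m1, m2) {
  out <- ifelse(m1 > 0 & m2 > 0, "positive",
                ifelse(m1 < 0 & m2 < 0, "negative", "mixed"))
  if (any(m1 == 0 | m2 == 0))
    message("exact zero group-mean connectivity classed as 'mixed'")
  out
}

#' @export
print.block_summaries <- function(x, ...) {
  cat("Block summaries:", ncol(x$coordinates), "blocks x",
      nrow(x$coordinates), "subjects\n")
  cat("  median variance explained by first PC:",
      round(stats::median(x$block_info$variance_explained), 3), "\n")
  invisible(x)
}

#' Write the subject-by-block coordinate table as CSV
#'
#' @param summaries A [summarize_blocks()] result.
#' @param path Output CSV path.
#' @export
write_coordinates_csv <- function(summaries, path) {
  df <- data.frame(subject_id = rownames(summaries$coordinates),
                   summaries$coordinates, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
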