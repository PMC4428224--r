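#' Cohen's d standardized mean difference
#'
#' Classical pooled-standard-deviation form, without small-sample (Hedges)
#' correction: `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`. Positive `d`
#' means group 1 exceeds group 2; `|d| >= 0.5` is conventionally a medium
#' effect.
#'
#' @param x,y Numeric vectors for groups 1 and 2 (each of length >= 2).
#' @return Signed d.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin policy wrapper around [stats::wilcox.test()]: the exact null
#' distribution is used for combined samples of 20 or fewer without ties,
#' and the normal approximation with tie-corrected variance (no continuity
#' correction) otherwise.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) mode;
#'   `NULL` applies the size/ties rule.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= 20L) && !has_ties
  if (exact && has_ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value
}

#' Modulewise group comparison of block coordinates
#'
#' Compares the two groups on each block's principal-component coordinates:
#' signed Cohen's d (group 1 minus group 2), a two-sided rank-sum p-value
#' (uncorrected — no multiplicity adjustment is applied, and output headers
#' say so), and a selection flag at `|d| >= d_threshold`. Each block carries
#' its sign class from the group-mean connectivity so selected blocks can be
#' reported separately for positive and negative connectivity, with a
#' direction label: for positive blocks `G1>G2`/`G2>G1`; for negative blocks
#' `G1->G2-` means group 1's negative connectivity is the stronger (more
#' negative), which corresponds to a negative coordinate d under the
#' mean-aligned sign convention.
#'
#' @param summaries A [summarize_blocks()] result computed with `groups`.
#' @param groups Optional override of the group factor.
#' @param d_threshold Effect-size threshold (default 0.5).
#' @return A `block_comparison` data frame, one row per block: `block`,
#'   `sign_class`, `cohens_d`, `direction`, `p_uncorrected`, `selected`.
#' @export
compare_blocks <- function(summaries, groups = NULL, d_threshold = 0.5) {
  stopifnot(inherits(summaries, "block_summaries"))
  groups <- as.factor(groups %||% summaries$groups)
  if (is.null(groups)) stop("group labels required")
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  coords <- summaries$coordinates
  if (length(groups) != nrow(coords))
    stop("every subject must carry a group label")
  info <- summaries$block_info
  if (is.null(info$sign_class)) {
    g1 <- levels(groups)[1L]
    m <- summaries$mean_connectivity
    info$group1_mean <- colMeans(m[groups == g1, , drop = FALSE])
    info$group2_mean <- colMeans(m[groups != g1, , drop = FALSE])
    info$sign_class <- sign_class(info$group1_mean, info$group2_mean)
  }
  is_g1 <- groups == levels(groups)[1L]
  d <- apply(coords, 2L, function(v) cohens_d(v[is_g1], v[!is_g1]))
  p <- apply(coords, 2L, function(v) rank_sum_test(v[is_g1], v[!is_g1]))
  direction <- mapply(direction_label, d, info$sign_class)
  out <- data.frame(block = info$block,
                    sign_class = info$sign_class,
                    cohens_d = unname(d),
                    direction = unname(direction),
                    p_uncorrected = unname(p),
                    selected = unname(abs(d) >= d_threshold),
                    stringsAsFactors = FALSE)
  attr(out, "d_threshold") <- d_threshold
  attr(out, "groups") <- levels(groups)
  attr(out, "note") <- "p-values are uncorrected for multiple comparisons"
  class(out) <- c("block_comparison", "data.frame")
  out
}

direction_label <- function(d, sign_class) {
  if (identical(sign_class, "negative")) {
    # coordinates align with (less negative) mean strength, so d < 0 means
    # group 1 carries the stronger negative connectivity
    if (d < 0) "G1->G2-" else "G2->G1-"
  } else {
    if (d >= 0) "G1>G2" else "G2>G1"
  }
}

#' @export
print.block_comparison <- function(x, ...) {
  cat("Modulewise group comparison (", attr(x, "note"), ")\n", sep = "")
  for (cls in c("positive", "negative")) {
    sel <- x[x$selected & x$sign_class == cls, , drop = FALSE]
    cat(sprintf("%s-connectivity blocks with |d| >= %.2f: %d\n",
                cls, attr(x, "d_threshold"), nrow(sel)))
    if (nrow(sel))
      print(as.data.frame(sel)[order(-abs(sel$cohens_d)),
                               c("block", "cohens_d", "direction",
                                 "p_uncorrected")],
            row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write comparison tables split by dominant connectivity sign
#'
#' Writes one CSV of selected blocks per sign class (positive/negative),
#' with columns block, d, direction, uncorrected p.
#'
#' @param comparison A [compare_blocks()] table.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_comparison_csv <- function(comparison, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cls in c("positive", "negative")) {
    sel <- comparison[comparison$selected & comparison$sign_class == cls, ,
                      drop = FALSE]
    p <- file.path(dir, paste0("modulewise_", cls, ".csv"))
    utils::write.csv(sel[order(-abs(sel$cohens_d)),
                         c("block", "cohens_d", "direction", "p_uncorrected")],
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
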