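#' Detrend time series against low-order Legendre polynomials
#'
#' Removes slow signal drift by regressing each column on Legendre
#' polynomials of degree 0..`poly_order` evaluated on time rescaled to
#' \[-1, 1\], and keeping the residuals. The default (order 2) removes mean,
#' linear, and quadratic drift.
#'
#' @param series Numeric `time x unit` matrix (a vector is treated as one
#'   unit).
#' @param poly_order Highest polynomial degree to regress out.
#' @return Residual matrix of the same shape, orthogonal to the polynomial
#'   basis.
#' @export
detrend_series <- function(series, poly_order = 2L) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  if (Tn <= poly_order + 1L)
    stop("series too short to detrend at polynomial order ", poly_order)
  basis <- legendre_basis(Tn, poly_order)
  series - basis %*% qr.solve(basis, series)
}

legendre_basis <- function(Tn, order) {
  x <- seq(-1, 1, length.out = Tn)
  P <- matrix(0, Tn, order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      # Bonnet recursion: (k) P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  P
}

#' Standardize series to zero mean and unit variance
#'
#' Per-column variance normalization: each unit's series is demeaned and
#' scaled to sample variance 1. This is the scaling step of the
#' detrend/demean/normalize preprocessing; Pearson correlation downstream is
#' invariant to it, so it is a conservative reading of "whitening" (temporal
#' AR(1) pre-whitening is available separately via [prewhiten_ar1()]).
#'
#' @param series Numeric `time x unit` matrix.
#' @return Standardized matrix.
#' @export
standardize_series <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 2L) stop("need at least 2 timepoints")
  sds <- sqrt(col_vars(series))
  zero <- which(sds <= .Machine$double.eps * 100)
  if (length(zero))
    stop("constant series for unit ",
         paste(colnames(series)[zero] %||% zero, collapse = ", "))
  scale(series, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' AR(1) temporal pre-whitening
#'
#' Optional sensitivity-analysis variant of whitening: estimates each
#' column's lag-1 autocorrelation and filters `x_t - phi x_{t-1}`.
#'
#' @param series Numeric `time x unit` matrix.
#' @return Pre-whitened matrix with one fewer row.
#' @export
prewhiten_ar1 <- function(series) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  if (Tn < 3L) stop("series too short for AR(1) pre-whitening")
  apply(series, 2L, function(col) {
    phi <- stats::cor(col[-1L], col[-Tn])
    col[-1L] - phi * col[-Tn]
  })
}

#' Extract a node's representative time series by SVD
#'
#' Summarizes the voxel series of one node as the first left singular vector
#' of the (detrended, standardized) `time x voxel` matrix. The SVD sign is
#' arbitrary, so the vector is aligned to correlate positively with the mean
#' voxel series; if that correlation is numerically zero (e.g. two voxels in
#' perfect antiphase) the sign of the largest-magnitude voxel loading is used
#' instead, with a warning. The result is rescaled to unit variance, which is
#' irrelevant to the downstream Pearson correlations.
#'
#' @param voxel_matrix Numeric `time x voxel` matrix.
#' @return Numeric vector of length `time`.
#' @export
extract_node_series <- function(voxel_matrix) {
  voxel_matrix <- as.matrix(voxel_matrix)
  if (all(abs(voxel_matrix) < .Machine$double.eps))
    stop("all-zero voxel matrix")
  if (ncol(voxel_matrix) == 1L)
    return(drop(standardize_series(voxel_matrix)))
  sv <- svd(voxel_matrix, nu = 1L, nv = 1L)
  u <- sv$u[, 1L]
  mean_series <- rowMeans(voxel_matrix)
  al <- sum(u * mean_series)
  if (abs(al) > 1e-12 * sqrt(sum(mean_series^2))) {
    if (al < 0) u <- -u
  } else {
    warning("mean voxel series ~ 0; sign of representative series taken ",
            "from the largest-magnitude voxel loading")
    v <- sv$v[, 1L]
    if (v[which.max(abs(v))] < 0) u <- -u
  }
  u <- u - mean(u)
  u / stats::sd(u)
}

#' Build a subject's Pearson connectivity matrix
#'
#' Computes the full signed `node x node` Pearson correlation matrix of the
#' per-node representative time series. No thresholding is applied: the
#' analysis operates on fully connected graphs with both positive and
#' negative weights.
#'
#' @param node_series Numeric `time x node` matrix (columns named by node).
#' @param subject_id Optional identifier stored on the result.
#' @return A symmetric correlation matrix of class `"connectome"`, unit
#'   diagonal.
#' @export
build_connectome <- function(node_series, subject_id = NULL) {
  node_series <- as.matrix(node_series)
  if (nrow(node_series) < 3L) stop("need at least 3 timepoints")
  sds <- sqrt(col_vars(node_series))
  if (any(sds <= .Machine$double.eps * 100))
    stop("constant node series: ",
         paste(colnames(node_series)[sds <= .Machine$double.eps * 100] %||%
                 which(sds <= .Machine$double.eps * 100), collapse = ", "))
  M <- stats::cor(node_series)
  diag(M) <- 1
  attr(M, "subject_id") <- subject_id
  class(M) <- c("connectome", class(M))
  M
}

#' Full node-series preprocessing and connectome construction for a cohort
#'
#' Applies detrending and standardization to each subject's node series and
#' correlates them into connectomes.
#'
#' @param series List of `time x node` matrices (one per subject).
#' @param poly_order Detrending polynomial order.
#' @return List of `connectome` matrices.
#' @export
build_connectomes <- function(series, poly_order = 2L) {
  lapply(seq_along(series), function(s) {
    x <- standardize_series(detrend_series(series[[s]], poly_order))
    build_connectome(x, subject_id = names(series)[s] %||% s)
  })
}

#' Write a connectivity matrix as TSV
#'
#' @param connectome Square correlation matrix.
#' @param path Output path.
#' @export
write_connectome_tsv <- function(connectome, path) {
  utils::write.table(format(unclass(connectome), digits = 10), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(connectome)))
  invisible(path)
}

#' Heat-map of a connectivity matrix
#'
#' Plots the signed correlation matrix with nodes in parcellation order, a
#' blue-white-red palette, and module boundaries if a parcellation is given.
#'
#' @param x A `connectome` matrix.
#' @param parcellation Optional parcellation to draw module boundaries.
#' @param ... Passed to [graphics::image()].
#' @export
plot.connectome <- function(x, parcellation = NULL, ...) {
  n <- nrow(x)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x)[n:1, ]),
                  zlim = c(-1, 1), col = pal, xlab = "node", ylab = "node",
                  useRaster = TRUE, ...)
  if (!is.null(parcellation)) {
    b <- cumsum(table(parcellation$module)) + 0.5
    graphics::abline(v = b, h = n - b + 1, col = "grey40", lwd = 0.5)
  }
  invisible(x)
}
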