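#' Assign nodes to modules by winner-take-all over z-statistic maps
#'
#' For each node, finds the resting-state-network map with the largest
#' z-statistic at the node's location; the node joins that module if the
#' maximum exceeds `z_threshold`, and is labeled `"unassigned"` otherwise.
#' Ties at the maximum are broken in favor of the earliest map in the
#' supplied (canonical) order, and every tie is reported via a message.
#'
#' @param node_z Numeric `node x map` matrix of z-statistics; column names
#'   are the candidate module labels (in canonical order).
#' @param z_threshold Assignment threshold (default 3).
#' @return Character vector of module labels (or `"unassigned"`), with the
#'   winning z-value in attribute `"max_z"`.
#' @export
assign_modules <- function(node_z, z_threshold = 3) {
  node_z <- as.matrix(node_z)
  if (is.null(colnames(node_z)))
    colnames(node_z) <- paste0("M", seq_len(ncol(node_z)))
  bad <- which(is.na(node_z), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("NaN/NA z-value for node ",
         rownames(node_z)[bad[1, 1]] %||% bad[1, 1],
         " in map ", colnames(node_z)[bad[1, 2]])
  maxz <- apply(node_z, 1L, max)
  winner <- apply(node_z, 1L, which.max)  # first max wins: canonical order
  ties <- which(rowSums(node_z == maxz) > 1L & maxz > z_threshold)
  if (length(ties))
    message("tie at argmax for ", length(ties), " node(s): ",
            paste(utils::head(rownames(node_z)[ties] %||% ties, 5L),
                  collapse = ", "),
            "; first module in canonical order wins")
  labels <- ifelse(maxz > z_threshold, colnames(node_z)[winner], "unassigned")
  attr(labels, "max_z") <- maxz
  labels
}

#' Sample a statistic image within a spherical node
#'
#' Reads the value of a 3D statistic volume "at the location of a node":
#' the mean (default) or peak of all voxels whose mm-space centers lie within
#' `radius` of the node center. Voxel-to-mm mapping uses the image affine;
#' voxels outside the image are ignored.
#'
#' @param volume A 3D image readable by RNifti (path or `niftiImage`), or a
#'   plain 3D array (then a unit/identity affine is assumed).
#' @param center Numeric length-3 MNI mm coordinate of the node center.
#' @param radius Sphere radius in mm (default 5: a 10 mm diameter node).
#' @param statistic `"mean"` or `"peak"` over in-sphere voxels.
#' @return The scalar statistic.
#' @export
sample_sphere_statistic <- function(volume, center, radius = 5,
                                    statistic = c("mean", "peak")) {
  statistic <- match.arg(statistic)
  stopifnot(length(center) == 3L, radius > 0)
  if (is.character(volume)) volume <- RNifti::readNifti(volume)
  arr <- as.array(volume)
  if (length(dim(arr)) != 3L) stop("volume must be 3D")
  dims <- dim(arr)
  if (inherits(volume, "niftiImage")) {
    vox_center <- RNifti::worldToVoxel(matrix(center, 1L), volume)
    pixdim <- RNifti::pixdim(volume)[1:3]
  } else {
    vox_center <- matrix(center + 1, 1L)  # identity affine, 1-based voxels
    pixdim <- c(1, 1, 1)
  }
  # Voxel-space bounding box around the sphere, then exact mm test inside.
  half <- ceiling(radius / pixdim) + 1L
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, floor(vox_center[k] - half[k]))
    hi <- min(dims[k], ceiling(vox_center[k] + half[k]))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) stop("sphere entirely outside image")
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  world <- if (inherits(volume, "niftiImage")) {
    RNifti::voxelToWorld(grid, volume)
  } else {
    grid - 1
  }
  d2 <- rowSums(sweep(world, 2L, as.numeric(center))^2)
  inside <- d2 <= radius^2
  if (!any(inside)) stop("sphere entirely outside image")
  vals <- arr[grid[inside, , drop = FALSE]]
  switch(statistic, mean = mean(vals), peak = vals[which.max(abs(vals))])
}

#' Prune unassigned nodes and undersized modules
#'
#' Drops nodes labeled `"unassigned"`, then drops every module with fewer
#' than `min_module_size` nodes together with its nodes (the general form of
#' discarding a single-node cerebellum module). Errors if fewer than two
#' modules survive, since no between-module block would exist.
#'
#' @param parcellation A data frame with at least `node_id` and `module`
#'   columns; `module` may contain `"unassigned"`.
#' @param min_module_size Minimum nodes a module must retain (default 2).
#' @return A `parcellation` whose `module` factor keeps only surviving
#'   canonical levels, with a `"pruning"` attribute summarizing what was
#'   dropped. Idempotent.
#' @export
prune_parcellation <- function(parcellation, min_module_size = 2L) {
  stopifnot(is.data.frame(parcellation),
            all(c("node_id", "module") %in% names(parcellation)))
  mod <- as.character(parcellation$module)
  levels_in <- if (is.factor(parcellation$module)) {
    setdiff(levels(parcellation$module), "unassigned")
  } else {
    unique(mod[mod != "unassigned"])
  }
  keep <- mod != "unassigned"
  n_unassigned <- sum(!keep)
  sizes <- table(factor(mod[keep], levels = levels_in))
  dropped_modules <- names(sizes)[sizes > 0 & sizes < min_module_size]
  keep <- keep & !(mod %in% dropped_modules)
  surviving <- names(sizes)[sizes >= min_module_size]
  if (length(surviving) < 2L)
    stop("fewer than 2 modules survive pruning; ",
         "no between-module blocks are possible")
  out <- parcellation[keep, , drop = FALSE]
  out$module <- factor(as.character(out$module), levels = surviving)
  rownames(out) <- NULL
  class(out) <- c("parcellation", "data.frame")
  attr(out, "pruning") <- list(
    n_unassigned_dropped = n_unassigned,
    modules_dropped = dropped_modules,
    n_nodes_dropped = nrow(parcellation) - nrow(out),
    n_retained = nrow(out))
  out
}

#' Read a node table from CSV
#'
#' @param path CSV with columns `node_id`, `x`, `y`, `z` and optionally
#'   `module`.
#' @param module_levels Canonical module order for the `module` factor; by
#'   default the order of first appearance.
#' @return A `parcellation` data frame.
#' @export
read_parcellation_csv <- function(path, module_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("node table must have columns: ", paste(need, collapse = ", "))
  if ("module" %in% names(df)) {
    lv <- module_levels %||% unique(df$module[df$module != "unassigned"])
    keepun <- any(df$module == "unassigned")
    df$module <- factor(df$module, levels = c(lv, if (keepun) "unassigned"))
  }
  class(df) <- c("parcellation", "data.frame")
  df
}

#' Write node module labels to CSV
#'
#' @param parcellation Parcellation with a `module` column.
#' @param path Output CSV path.
#' @param max_z Optional per-node winning z-values to include.
#' @export
write_labels_csv <- function(parcellation, path, max_z = NULL) {
  df <- data.frame(node_id = parcellation$node_id,
                   module = as.character(parcellation$module))
  if (!is.null(max_z)) df$max_z <- max_z
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation:", nrow(x), "nodes in",
      nlevels(factor(x$module)), "modules\n")
  print(table(x$module))
  invisible(x)
}
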