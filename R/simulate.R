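#' Specify a block-covariance simulation design
#'
#' Defines a two-group, multi-subject simulation whose node-level time series
#' are drawn from a multivariate normal with a block-structured correlation
#' matrix: a common within-module correlation, a module-pair matrix of
#' between-module correlations, and optional planted group differences that
#' shift the population correlation of selected blocks for one group. The
#' design mirrors the data regime of a two-group resting-state study: 12
#' subjects per group, ~200 nodes in 9 modules, 200 time points, and a mix of
#' positively and negatively correlated module pairs.
#'
#' @param n_subjects_per_group Subjects in each of the two groups.
#' @param nodes_per_module Integer vector of module sizes; its length sets the
#'   number of modules.
#' @param module_names Module labels in canonical order; defaults to
#'   [rsn_modules()] when 9 modules are requested, otherwise `M1..MK`.
#' @param n_timepoints Length of each node time series.
#' @param base_within_corr Population correlation between any two nodes of the
#'   same module.
#' @param base_between_corr Either a single number, or a `K x K` symmetric
#'   matrix of module-pair correlations (diagonal ignored). The default is a
#'   two-community pattern: +0.1 among the sensory modules and among the
#'   association modules, -0.1 across the two communities, giving sign-mixed
#'   block means as seen in real group-average connectomes.
#' @param planted_effects List of planted group differences, each a list with
#'   `module_a`, `module_b` (labels or indices), `delta` (signed shift of the
#'   population correlation) and `group` (1 or 2: which group receives the
#'   shift).
#' @param voxels_per_node Voxels simulated per node when voxel-level output is
#'   requested.
#' @param voxel_noise_sd Standard deviation of independent voxel noise around
#'   the node latent series.
#' @param behavior_couplings List of behavior measures; each element is a list
#'   with `blocks` (character vector of block ids, e.g. `"EC-FPR"`),
#'   `loadings` (numeric, recycled), `noise_sd`, and optionally `name`.
#' @param ar1 Lag-1 autocorrelation of the node series (0 = temporally white).
#' @param psd_tol Maximum tolerated change of any target correlation during
#'   positive-semidefiniteness repair.
#' @param seed Master seed; all subject streams derive from it.
#'
#' @return An object of class `"simulation_design"`, including the two
#'   validated (and, if necessary, repaired) group target correlation
#'   matrices.
#' @export
simulation_design <- function(n_subjects_per_group = 12L,
                              nodes_per_module = reference_module_sizes(),
                              module_names = NULL,
                              n_timepoints = 200L,
                              base_within_corr = 0.4,
                              base_between_corr = NULL,
                              planted_effects = list(),
                              voxels_per_node = 1L,
                              voxel_noise_sd = 0.5,
                              behavior_couplings = list(),
                              ar1 = 0,
                              psd_tol = 0.01,
                              seed = 1L) {
  K <- length(nodes_per_module)
  if (K < 1L || any(nodes_per_module < 1L))
    stop("every module must contain at least one node")
  if (is.null(module_names)) {
    module_names <- if (K == 9L) rsn_modules() else paste0("M", seq_len(K))
  }
  if (length(module_names) != K)
    stop("nodes_per_module and module_names lengths differ")
  if (n_subjects_per_group < 2L) stop("need at least 2 subjects per group")
  if (n_timepoints < 4L) stop("n_timepoints too small")
  if (abs(base_within_corr) >= 1) stop("base_within_corr must be in (-1, 1)")
  if (abs(ar1) >= 1) stop("ar1 must be in (-1, 1)")
  if (voxel_noise_sd < 0) stop("voxel_noise_sd must be nonnegative")

  B <- base_between_corr
  if (is.null(B)) B <- default_between_corr(K)
  if (length(B) == 1L) B <- matrix(B, K, K)
  if (!isTRUE(all.equal(B, t(B)))) stop("base_between_corr must be symmetric")
  if (any(abs(B[upper.tri(B)]) >= 1))
    stop("between-module correlations must be in (-1, 1)")
  dimnames(B) <- list(module_names, module_names)

  planted_effects <- lapply(planted_effects, function(pe) {
    pe$module_a <- resolve_module(pe$module_a, module_names)
    pe$module_b <- resolve_module(pe$module_b, module_names)
    if (is.null(pe$group)) pe$group <- 1L
    if (!pe$group %in% 1:2) stop("planted effect group must be 1 or 2")
    if (is.null(pe$delta)) stop("planted effect needs a delta")
    pe
  })

  design <- structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_modules = K,
         nodes_per_module = as.integer(nodes_per_module),
         module_names = module_names,
         n_timepoints = as.integer(n_timepoints),
         base_within_corr = base_within_corr,
         base_between_corr = B,
         planted_effects = planted_effects,
         voxels_per_node = as.integer(voxels_per_node),
         voxel_noise_sd = voxel_noise_sd,
         behavior_couplings = behavior_couplings,
         ar1 = ar1,
         psd_tol = psd_tol,
         seed = as.integer(seed)),
    class = "simulation_design")

  # Build + validate both group targets now so invalid designs fail early.
  design$target_corr <- lapply(1:2, function(g) group_target_corr(design, g))
  design
}

# Two-community default: sensory modules (visual x3, SM, Aud) and
# association modules (DMN, EC, FPR, FPL) are mildly positively correlated
# within community and mildly anticorrelated across, echoing the
# task-positive/task-negative organization of resting-state data.
default_between_corr <- function(K) {
  if (K == 9L) {
    sensory <- c(1L, 2L, 3L, 5L, 6L)
    comm <- ifelse(seq_len(K) %in% sensory, 1L, 2L)
  } else {
    comm <- rep(1:2, length.out = K)
  }
  0.1 * ifelse(outer(comm, comm, "=="), 1, -1)
}

resolve_module <- function(m, module_names) {
  if (is.numeric(m)) {
    if (m < 1 || m > length(module_names)) stop("module index out of range")
    return(module_names[as.integer(m)])
  }
  m <- as.character(m)
  if (!m %in% module_names) stop("unknown module: ", m)
  m
}

# Node-level population correlation matrix for one group, with planted
# effects applied and PSD enforced by eigenvalue clipping.
group_target_corr <- function(design, group) {
  K <- design$n_modules
  sizes <- design$nodes_per_module
  block_target <- design$base_between_corr
  diag(block_target) <- design$base_within_corr
  for (pe in design$planted_effects) {
    if (pe$group != group) next
    ia <- match(pe$module_a, design$module_names)
    ib <- match(pe$module_b, design$module_names)
    block_target[ia, ib] <- block_target[ia, ib] + pe$delta
    if (ia != ib) block_target[ib, ia] <- block_target[ia, ib]
    if (abs(block_target[ia, ib]) >= 1)
      stop("planted delta pushes target correlation of block ",
           pe$module_a, "-", pe$module_b, " outside (-1, 1)")
  }
  mod <- rep(seq_len(K), sizes)
  R <- block_target[mod, mod]
  diag(R) <- 1
  repair_correlation(R, tol = design$psd_tol)
}

# Clip negative eigenvalues and renormalize to a correlation matrix. Errors
# if the repair moves any entry by more than `tol`.
repair_correlation <- function(R, tol = 0.01) {
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) > 1e-10) return(R)
  warning("target correlation matrix is not positive semi-definite; ",
          "repairing by eigenvalue clipping (min eigenvalue ",
          signif(min(eig$values), 3), ")")
  vals <- pmax(eig$values, 1e-8)
  R2 <- eig$vectors %*% (vals * t(eig$vectors))
  R2 <- stats::cov2cor(R2)
  shift <- max(abs(R2 - R))
  if (shift > tol)
    stop("PSD repair changed a target correlation by ", signif(shift, 3),
         " (> tolerance ", tol, ")")
  R2
}

#' Generate a synthetic parcellation from a simulation design
#'
#' Creates the node table the analysis stages consume: node ids, synthetic
#' MNI-style coordinates (module centers spread on a sphere, nodes jittered
#' around them, deterministic under the design seed) and module labels in
#' canonical order.
#'
#' @param design A [simulation_design()].
#' @return A `parcellation` data frame with columns `node_id`, `x`, `y`, `z`,
#'   `module` (factor over the canonical module levels).
#' @export
generate_parcellation <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  K <- design$n_modules
  sizes <- design$nodes_per_module
  n <- sum(sizes)
  module <- factor(rep(design$module_names, sizes),
                   levels = design$module_names)
  # Module centers on a 60 mm sphere; 8 mm isotropic jitter per node.
  theta <- 2 * pi * (seq_len(K) - 1) / K
  phi <- acos(seq(-0.9, 0.9, length.out = K))
  centers <- 60 * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                        cos(phi))
  xyz <- with_seed(bitwXor(design$seed, 101L), {
    centers[rep(seq_len(K), sizes), , drop = FALSE] +
      matrix(stats::rnorm(3 * n, sd = 8), n, 3)
  })
  parc <- data.frame(node_id = sprintf("N%03d", seq_len(n)),
                     x = round(xyz[, 1], 1), y = round(xyz[, 2], 1),
                     z = round(xyz[, 3], 1), module = module,
                     stringsAsFactors = FALSE)
  class(parc) <- c("parcellation", "data.frame")
  parc
}

#' Generate node-level time series for both groups
#'
#' Draws each subject's `n_timepoints x n_nodes` series from a multivariate
#' normal whose correlation matrix is the subject's group target (planted
#' effects included). Subject streams are spawned deterministically from the
#' master seed, so regenerating with more subjects leaves existing subjects'
#' data untouched. With `ar1 > 0` an AR(1) filter is applied per node,
#' preserving the cross-sectional correlation structure.
#'
#' @param design A [simulation_design()].
#' @param parcellation Parcellation from [generate_parcellation()]; used for
#'   node naming and to cross-check module sizes.
#' @return A list of class `"simulated_cohort"`: `series` (list of subject
#'   matrices), `subject_id`, `group` (factor `g1`/`g2`), and `ground_truth`
#'   (target block means per group, planted blocks with signed direction,
#'   behavior couplings).
#' @export
generate_group_timeseries <- function(design, parcellation = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(parcellation)) parcellation <- generate_parcellation(design)
  n_nodes <- sum(design$nodes_per_module)
  if (nrow(parcellation) != n_nodes)
    stop("parcellation does not match design module sizes")
  n_per <- design$n_subjects_per_group
  n_sub <- 2L * n_per
  Tn <- design$n_timepoints

  chol_g <- lapply(design$target_corr, chol)
  # one seed stream per group: enlarging a group never reseeds the subjects
  # already present in either group
  seeds <- c(spawn_seeds(design$seed, n_per, offset = 1L),
             spawn_seeds(design$seed, n_per, offset = 2L))
  group <- factor(rep(c("g1", "g2"), each = n_per), levels = c("g1", "g2"))
  series <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    L <- chol_g[[as.integer(group[s])]]
    series[[s]] <- with_seed(seeds[s], {
      z <- matrix(stats::rnorm(Tn * n_nodes), Tn, n_nodes)
      if (design$ar1 != 0) {
        z <- apply(z, 2L, function(col)
          as.numeric(stats::filter(col * sqrt(1 - design$ar1^2),
                                   design$ar1, method = "recursive")))
      }
      x <- z %*% L
      colnames(x) <- parcellation$node_id
      x
    })
  }
  names(series) <- sprintf("S%02d", seq_len(n_sub))

  gt <- list(
    target_block_means = lapply(1:2, function(g) {
      bt <- design$base_between_corr
      diag(bt) <- design$base_within_corr
      for (pe in design$planted_effects) {
        if (pe$group != g) next
        ia <- match(pe$module_a, design$module_names)
        ib <- match(pe$module_b, design$module_names)
        bt[ia, ib] <- bt[ia, ib] + pe$delta
        if (ia != ib) bt[ib, ia] <- bt[ia, ib]
      }
      bt
    }),
    planted_blocks = lapply(design$planted_effects, function(pe) {
      list(block = block_id(pe$module_a, pe$module_b, design$module_names),
           delta = pe$delta, group = pe$group,
           # sign of the expected group1 - group2 difference
           direction = if (pe$group == 1L) sign(pe$delta) else -sign(pe$delta))
    }),
    behavior_couplings = design$behavior_couplings)

  structure(list(series = series, subject_id = names(series), group = group,
                 parcellation = parcellation, ground_truth = gt,
                 design = design),
            class = "simulated_cohort")
}

#' Expand a node series into correlated voxel series
#'
#' Each voxel is the shared node latent series plus independent Gaussian
#' noise, so the expected first principal component of the voxel set is the
#' latent series itself — the regime the SVD node-summarization step assumes.
#'
#' @param node_series Numeric vector: the node's latent time series.
#' @param voxels_per_node Number of voxels to generate (>= 1).
#' @param voxel_noise_sd Noise standard deviation; 0 replicates the latent
#'   series exactly.
#' @param seed Integer seed.
#' @return A `time x voxel` matrix.
#' @export
generate_voxel_timeseries <- function(node_series, voxels_per_node,
                                      voxel_noise_sd, seed = 1L) {
  if (voxels_per_node < 1L) stop("voxels_per_node must be >= 1")
  node_series <- as.numeric(node_series)
  Tn <- length(node_series)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(Tn * voxels_per_node, sd = voxel_noise_sd),
                    Tn, voxels_per_node)
    matrix(node_series, Tn, voxels_per_node) + noise
  })
}

#' Generate behavior scores coupled to block strengths
#'
#' Each behavior measure is a linear combination of the supplied
#' subject-by-block coordinates plus Gaussian noise:
#' `score_s = sum_b loading_b * coordinate_{s,b} + e_s`.
#'
#' @param coords Subject-by-block numeric matrix with block ids as column
#'   names (e.g. block-mean strengths from the generator's ground truth, or
#'   principal-component coordinates from [summarize_blocks()]).
#' @param couplings List of measures; each element has `blocks` (character
#'   vector of column names of `coords`), `loadings` (recycled to match),
#'   `noise_sd`, and optionally `name`.
#' @param seed Integer seed.
#' @return Data frame, one row per subject, one column per measure.
#' @export
generate_behavior_scores <- function(coords, couplings, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(couplings) == 0L) stop("no behavior couplings supplied")
  out <- with_seed(seed, {
    cols <- lapply(seq_along(couplings), function(i) {
      cp <- couplings[[i]]
      miss <- setdiff(cp$blocks, colnames(coords))
      if (length(miss))
        stop("coupled block not present in coordinates: ",
             paste(miss, collapse = ", "))
      loadings <- rep_len(cp$loadings %||% 1, length(cp$blocks))
      drop(coords[, cp$blocks, drop = FALSE] %*% loadings) +
        stats::rnorm(n, sd = cp$noise_sd %||% 0)
    })
    names(cols) <- vapply(seq_along(couplings), function(i)
      couplings[[i]]$name %||% paste0("measure", i), "")
    cols
  })
  data.frame(subject_id = rownames(coords) %||% sprintf("S%02d", seq_len(n)),
             out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Noise level giving a target behavior-block correlation
#'
#' For a single-block coupling `score = loading * coord + e`, returns the
#' noise standard deviation that makes the population correlation between
#' score and coordinate equal `target_r`, given the realized spread of the
#' coordinates.
#'
#' @param coord_sd Standard deviation of the coupled block's coordinates.
#' @param loading Coupling loading.
#' @param target_r Desired correlation magnitude, in (0, 1).
#' @return Noise standard deviation.
#' @export
coupling_noise_for_r <- function(coord_sd, loading, target_r) {
  stopifnot(target_r > 0, target_r < 1, coord_sd > 0)
  abs(loading) * coord_sd * sqrt(1 / target_r^2 - 1)
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Simulation design:", 2L * x$n_subjects_per_group, "subjects (",
      x$n_subjects_per_group, "per group ),", sum(x$nodes_per_module),
      "nodes in", x$n_modules, "modules,", x$n_timepoints, "timepoints\n")
  cat("  within-module r =", x$base_within_corr,
      "| planted effects:", length(x$planted_effects),
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes per-subject time series as TSV (`time x node`), the parcellation as
#' CSV, behavior scores (if supplied) as CSV, and the ground truth as JSON.
#'
#' @param cohort A `simulated_cohort` from [generate_group_timeseries()].
#' @param dir Output directory (created if absent).
#' @param behavior Optional behavior data frame to write alongside.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, behavior = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in seq_along(cohort$series)) {
    f <- file.path(dir, paste0(cohort$subject_id[s], "_timeseries.tsv"))
    utils::write.table(format(cohort$series[[s]], digits = 10), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  pf <- file.path(dir, "parcellation.csv")
  utils::write.csv(as.data.frame(cohort$parcellation), pf, row.names = FALSE)
  gf <- file.path(dir, "groups.csv")
  utils::write.csv(data.frame(subject_id = cohort$subject_id,
                              group = as.character(cohort$group)),
                   gf, row.names = FALSE)
  tf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(cohort$ground_truth, tf, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, pf, gf, tf)
  if (!is.null(behavior)) {
    bf <- file.path(dir, "behavior.csv")
    utils::write.csv(behavior, bf, row.names = FALSE)
    files <- c(files, bf)
  }
  invisible(files)
}
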