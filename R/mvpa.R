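#' Linear max-margin classification with stratified cross-validation
#'
#' Classifies subjects from a feature matrix (e.g. the 45 modulewise
#' principal-component coordinates) with a linear support vector machine
#' (unit cost). Accuracy is estimated by stratified k-fold cross-validation:
#' folds are drawn per group from the seed, each fold's model is trained on
#' the remaining folds, and features are z-scored with the training fold's
#' means and SDs (applied unchanged to the test fold). Dimensional
#' classification scores — the signed distance of each subject from the
#' separating hyperplane, read as confidence of group membership — come from
#' a full-data refit; positive scores point to the first group level.
#'
#' @param features Numeric `subject x feature` matrix; no missing values.
#' @param labels Two-level factor (first level = "group 1", positive score
#'   direction).
#' @param n_folds Number of folds (default 4: train on 75%, test on 25%).
#' @param cost SVM regularization constant (default 1).
#' @param seed Integer seed for the fold assignment.
#' @param feature_set Label stored on the result (e.g. `"connectivity"`).
#' @return An object of class `"mvpa_result"`: `cv_accuracy`, `predicted`
#'   (held-out fold predictions), `dimensional_scores`, `weights` (on the
#'   z-scored feature scale), `intercept`, `folds`, `seed`.
#' @export
fit_classifier_cv <- function(features, labels, n_folds = 4L, cost = 1,
                              seed = 1L, feature_set = "connectivity") {
  features <- as.matrix(features)
  if (anyNA(features)) stop("missing feature values")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  n <- nrow(features)
  if (length(labels) != n) stop("labels do not match feature rows")
  if (any(table(labels) < n_folds))
    stop("need at least n_folds subjects per group for stratified folds")

  folds <- with_seed(seed, {
    f <- integer(n)
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })

  predicted <- factor(rep(NA_character_, n), levels = levels(labels))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    stopifnot(nlevels(droplevels(labels[tr])) == 2L)
    mu <- colMeans(features[tr, , drop = FALSE])
    sd_ <- sqrt(col_vars(features[tr, , drop = FALSE]))
    sd_[sd_ < .Machine$double.eps * 100] <- 1
    ztr <- scale(features[tr, , drop = FALSE], mu, sd_)
    zte <- scale(features[!tr, , drop = FALSE], mu, sd_)
    fit <- e1071::svm(ztr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    predicted[!tr] <- stats::predict(fit, zte)
  }
  cv_accuracy <- mean(predicted == labels)

  # Full-data refit for weights and dimensional scores.
  mu <- colMeans(features)
  sd_ <- sqrt(col_vars(features))
  sd_[sd_ < .Machine$double.eps * 100] <- 1
  z <- scale(features, mu, sd_)
  fit <- e1071::svm(z, labels, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  scores <- drop(z %*% w) + b
  # e1071 orients the decision function toward its internal first class;
  # fix orientation so positive scores mean the first factor level.
  pred_full <- stats::predict(fit, z)
  agree <- sign(scores) == ifelse(pred_full == levels(labels)[1L], 1, -1)
  if (mean(agree[sign(scores) != 0]) < 0.5) {
    w <- -w; b <- -b; scores <- -scores
  }
  names(w) <- colnames(features)

  structure(list(feature_set = feature_set,
                 cv_accuracy = cv_accuracy,
                 predicted = predicted,
                 labels = labels,
                 dimensional_scores =
                   stats::setNames(scores, rownames(features)),
                 weights = w, intercept = b,
                 folds = folds, n_folds = n_folds, cost = cost, seed = seed),
            class = "mvpa_result")
}

#' @export
print.mvpa_result <- function(x, ...) {
  cat(sprintf("SVM (%s features): %d-fold CV accuracy %.1f%% (%d/%d)\n",
              x$feature_set, x$n_folds, 100 * x$cv_accuracy,
              round(x$cv_accuracy * length(x$labels)), length(x$labels)))
  invisible(x)
}

#' Rank classifier features by weight magnitude
#'
#' @param result An [fit_classifier_cv()] result (linear model).
#' @param top_k How many features to return (default: all).
#' @return Data frame of features ranked by `|weight|`, with signed weights.
#' @export
classifier_weights <- function(result, top_k = length(result$weights)) {
  stopifnot(inherits(result, "mvpa_result"))
  if (is.null(result$weights))
    stop("feature weights are undefined for a nonlinear kernel")
  ord <- order(-abs(result$weights))
  k <- min(top_k, length(ord))
  data.frame(feature = names(result$weights)[ord[seq_len(k)]],
             weight = unname(result$weights[ord[seq_len(k)]]),
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Correlate two sets of dimensional classification scores
#'
#' Pearson correlation with the usual two-sided t-approximation p-value,
#' e.g. between connectivity-based and behavior-based SVM scores of the same
#' subjects.
#'
#' @param scores_a,scores_b Numeric vectors over the same subjects (n >= 3).
#' @return List with `r`, `p`, `n`.
#' @export
correlate_dimensional_scores <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors differ in length")
  if (length(scores_a) < 3L) stop("need at least 3 subjects")
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0)
    stop("scores have zero variance")
  ct <- stats::cor.test(scores_a, scores_b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores_a))
}

#' Screen block coordinates against behavioral measures
#'
#' Pearson-correlates every block's subject coordinates with every behavior
#' measure across all subjects pooled (both groups together), reporting
#' uncorrected p-values and flagging associations of at least large effect
#' size (`|r| >= r_threshold`). Subjects with a missing value on a measure
#' are excluded from that measure's correlations (with a message).
#'
#' @param coordinates `subject x block` numeric matrix.
#' @param behavior Data frame or matrix of behavior scores, one row per
#'   subject (a `subject_id` column is ignored for computation).
#' @param r_threshold Selection threshold on `|r|` (default 0.5).
#' @return A `behavior_correlations` data frame: `block`, `measure`, `r`,
#'   `p_uncorrected`, `n`, `selected`.
#' @export
behavior_block_correlations <- function(coordinates, behavior,
                                        r_threshold = 0.5) {
  coordinates <- as.matrix(coordinates)
  if (is.data.frame(behavior)) {
    behavior <- behavior[, setdiff(names(behavior), "subject_id"),
                         drop = FALSE]
  }
  behavior <- as.matrix(behavior)
  if (nrow(behavior) != nrow(coordinates))
    stop("behavior and coordinates have different subject counts")
  if (is.null(colnames(behavior)))
    colnames(behavior) <- paste0("measure", seq_len(ncol(behavior)))
  if (is.null(colnames(coordinates)))
    colnames(coordinates) <- paste0("block", seq_len(ncol(coordinates)))
  rows <- list()
  for (m in colnames(behavior)) {
    bm <- behavior[, m]
    ok <- !is.na(bm)
    if (!all(ok))
      message(sum(!ok), " subject(s) excluded from measure ", m,
              " for missing values")
    if (stats::sd(bm[ok]) == 0) stop("constant behavior measure: ", m)
    for (b in colnames(coordinates)) {
      ct <- stats::cor.test(coordinates[ok, b], bm[ok])
      rows[[length(rows) + 1L]] <-
        data.frame(block = b, measure = m, r = unname(ct$estimate),
                   p_uncorrected = ct$p.value, n = sum(ok),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$selected <- abs(out$r) >= r_threshold
  attr(out, "r_threshold") <- r_threshold
  class(out) <- c("behavior_correlations", "data.frame")
  out
}

#' @export
print.behavior_correlations <- function(x, ...) {
  cat("Brain-behavior screen: ", sum(x$selected), " of ", nrow(x),
      " block x measure correlations with |r| >= ",
      attr(x, "r_threshold"), " (uncorrected p)\n", sep = "")
  sel <- as.data.frame(x)[x$selected, , drop = FALSE]
  if (nrow(sel))
    print(sel[order(-abs(sel$r)), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an MVPA result as JSON
#'
#' @param result An `mvpa_result`.
#' @param path Output path.
#' @export
write_mvpa_json <- function(result, path) {
  jsonlite::write_json(
    list(feature_set = result$feature_set,
         cv_accuracy = result$cv_accuracy,
         n_folds = result$n_folds,
         folds = result$folds,
         seed = result$seed,
         predicted = as.character(result$predicted),
         labels = as.character(result$labels),
         dimensional_scores = as.list(result$dimensional_scores),
         weights = as.list(result$weights)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
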