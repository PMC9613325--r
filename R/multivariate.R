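# Multivariate exploration: PCA on the scaled matrix and random-forest
# pairwise classification with out-of-bag metrics and permutation
# significance.

#' Principal component analysis of the scaled matrix
#'
#' Centred decomposition via `stats::prcomp`.  Component signs are
#' canonicalised (the largest-magnitude loading entry of each component is
#' made positive) so repeated runs are bit-identical.
#'
#' @param x An `abundance_table` in state `"scaled"`.
#' @param design Optional design; when given, group labels are attached to
#'   the score table for plotting.
#' @param n_components Number of components to return (default 10).
#' @return List with `scores` (data frame, one row per sample),
#'   `loadings` (proteins x components matrix) and `variance_explained`
#'   (percent per component).
#' @export
pca_explore <- function(x, design = NULL, n_components = 10) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$state != "scaled") stop("pca_explore expects state 'scaled'")
  kmax <- min(nrow(x$values), ncol(x$values))
  if (n_components > kmax) {
    stop("n_components (", n_components, ") exceeds min(samples, proteins) = ", kmax)
  }
  pc <- stats::prcomp(x$values, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {          # sign canonicalisation
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sc[, j] <- -sc[, j]
    }
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(sample_id = rownames(x$values), sc,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(design)) {
    scores$group <- as.character(design_groups(x, design))
  }
  list(scores = scores, loadings = load,
       variance_explained = ve[seq_len(k)])
}

# Out-of-bag classification metrics for a fitted two-class random forest.
# `positive` is the factor level treated as the positive class.  Samples
# that were never out of bag (possible with few trees) carry no OOB
# prediction and are excluded.
rf_oob_metrics <- function(fit, y, positive) {
  pred <- fit$predicted
  ok <- !is.na(pred)
  pred <- pred[ok]
  y <- y[ok]
  negative <- setdiff(levels(y), positive)
  acc <- mean(pred == y)
  sens <- mean(pred[y == positive] == positive)
  spec <- mean(pred[y == negative] == negative)
  votes <- fit$votes[ok, positive]
  roc <- pROC::roc(response = y, predictor = votes,
                   levels = c(negative, positive), direction = "<",
                   quiet = TRUE)
  c(accuracy = 100 * acc, specificity = 100 * spec,
    sensitivity = 100 * sens, auroc = 100 * as.numeric(roc$auc))
}

#' Random-forest classification with permutation significance
#'
#' Fits a two-class random forest and reports out-of-bag accuracy,
#' specificity, sensitivity and AUROC (percent), each with a permutation
#' p-value: labels are permuted within the pooled two-group sample set, the
#' full forest is refit per permutation with a derived seed, and
#' `p = (1 + #\{permuted metric >= observed\}) / (n_permutations + 1)`.
#' The first factor level of `labels` is the positive class (sensitivity
#' refers to it).
#'
#' @param x A complete `abundance_table`.
#' @param labels Factor (or coercible) with exactly two levels over the
#'   samples of `x`.
#' @param n_trees Trees per forest (default 500).
#' @param n_permutations Label permutations (default 1000).
#' @param seed Integer seed; per-permutation seeds are derived from it.
#' @return An object of class `classifier_report`: data frame with columns
#'   `metric`, `value`, `p`, plus attributes `n_permutations` and `levels`.
#' @export
rf_permutation_classifier <- function(x, labels, n_trees = 500,
                                      n_permutations = 1000, seed = 1) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values)) stop("classification requires a complete matrix")
  y <- factor(labels)
  if (nlevels(y) != 2) stop("exactly two classes required")
  if (any(table(y) < 5)) stop("every class needs at least 5 samples")
  positive <- levels(y)[1]
  X <- x$values

  fit_metrics <- function(yy, s) {
    with_seed(s, {
      fit <- randomForest::randomForest(X, yy, ntree = n_trees)
      rf_oob_metrics(fit, yy, positive)
    })
  }

  obs <- fit_metrics(y, derive_seed(seed, "rf/observed"))
  exceed <- rep(0L, 4)
  for (b in seq_len(n_permutations)) {
    yp <- with_seed(derive_seed(seed, paste0("rf/permute/", b)),
                    sample(y))
    perm <- fit_metrics(yp, derive_seed(seed, paste0("rf/fit/", b)))
    exceed <- exceed + (perm >= obs)
  }
  pvals <- (1 + exceed) / (n_permutations + 1)
  out <- data.frame(metric = names(obs), value = unname(obs),
                    p = unname(pvals), stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "levels") <- levels(y)
  class(out) <- c("classifier_report", class(out))
  out
}
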