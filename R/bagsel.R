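# Feature-bagged classification scores with permutation statistics: the
# pipeline's core estimator.

classifier_code <- function(classifier) {
  match(match.arg(classifier, c("ridge", "centroid", "stump", "svm")),
        c("ridge", "centroid", "stump", "svm")) - 1L
}

# +1 = patient, -1 = control
encode_labels <- function(labels) {
  lab <- as.character(labels)
  if (!all(lab %in% c("patient", "control"))) {
    stop("labels must be 'patient'/'control'")
  }
  ifelse(lab == "patient", 1L, -1L)
}

standardize_columns <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  s[s < 1e-12] <- 1  # constant feature: leave centered at 0
  sweep(sweep(x, 2, m), 2, s, "/")
}

make_folds <- function(y, k) {
  # stratified fold assignment
  id <- integer(length(y))
  for (g in unique(y)) {
    gi <- which(y == g)
    id[gi] <- sample(rep_len(seq_len(k), length(gi)))
  }
  id
}

#' Draw feature bags and record cross-validated accuracies
#'
#' Each bag is a uniform draw of `bag_size` distinct features (without
#' replacement within a bag, independently across bags). The two groups are
#' classified from the bag's features with cross-validated linear
#' classification and the accuracy recorded, yielding a distribution of
#' accuracies across random feature subsets.
#'
#' Features are standardized (globally, label-free) before classification.
#' The default classifier is an L2-regularized least-squares linear
#' discriminant (`lambda = 1`) whose leave-one-out predictions are computed
#' in closed form; `"svm"` (squared-hinge max-margin), `"centroid"`
#' (nearest class-centroid) and `"stump"` (mean-split decision stumps,
#' majority vote) are alternatives.
#'
#' @param x Numeric matrix, subjects x features.
#' @param labels `"patient"`/`"control"` per subject (each group >= 3).
#' @param bag_size Features per bag (default 10).
#' @param n_draw Number of bags.
#' @param classifier One of `"ridge"`, `"centroid"`, `"stump"`, `"svm"`.
#' @param cv `"loo"` (leave-one-out) or a fold count (e.g. `5`, `10`).
#' @param lambda Ridge/margin regularization.
#' @return A `"bag_result"`: list with `accuracy` (per bag), `bags`
#'   (n_draw x bag_size feature indices), `n_features`, `bag_size`, `n`.
#' @export
run_feature_bagging <- function(x, labels, bag_size = 10, n_draw = 2e4,
                                classifier = "ridge", cv = "loo",
                                lambda = 1) {
  x <- as.matrix(x)
  y <- encode_labels(labels)
  if (min(table(y)) < 3) stop("each group needs >= 3 subjects")
  xs <- standardize_columns(x)
  foldid <- if (identical(cv, "loo")) NULL else make_folds(y, as.integer(cv))
  res <- cpp_feature_bagging(xs, y, as.integer(n_draw),
                             as.integer(bag_size), classifier_code(classifier),
                             foldid, lambda)
  structure(list(accuracy = res$accuracy, bags = res$bags,
                 n_features = ncol(x), bag_size = bag_size, n = nrow(x)),
            class = "bag_result")
}

#' Per-feature classification scores from a bag distribution
#'
#' Selects the bags whose accuracy reaches the given percentile of the
#' accuracy distribution (inclusive at the threshold, so ties are kept) and
#' scores each feature by the probability of belonging to a selected bag:
#' `score_f = #\{selected bags containing f\} / #\{selected bags\}`. If no
#' feature carries group information every score is ~ `bag_size /
#' n_features`; informative features rise above that floor.
#'
#' @param bags A [run_feature_bagging()] result.
#' @param percentile Accuracy threshold percentile (default 75, i.e. the top
#'   quartile of bags).
#' @return Numeric vector of scores (one per feature, summing to
#'   `bag_size`) with attributes `threshold` (accuracy cut), `n_selected`,
#'   `selected_fraction`.
#' @export
classification_scores <- function(bags, percentile = 75) {
  stopifnot(inherits(bags, "bag_result"))
  if (length(bags$accuracy) < 100) stop("need >= 100 bags for stable scores")
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0, 100)")
  thr <- stats::quantile(bags$accuracy, percentile / 100, type = 7,
                         names = FALSE)
  sel <- bags$accuracy >= thr
  n_sel <- sum(sel)
  if (n_sel == length(bags$accuracy) && stats::var(bags$accuracy) == 0) {
    warning("all bag accuracies tied: scores are uninformative")
  }
  counts <- tabulate(bags$bags[sel, , drop = FALSE], nbins = bags$n_features)
  score <- counts / n_sel
  stopifnot(abs(sum(score) - bags$bag_size) < 1e-8)  # exact identity
  structure(score, threshold = thr, n_selected = n_sel,
            selected_fraction = n_sel / length(bags$accuracy))
}

#' Pooled permutation null of classification scores
#'
#' Randomly reassigns subjects to the two groups (group sizes preserved),
#' redraws fresh feature bags, and recomputes all per-feature classification
#' scores, `n_perm` times. All `n_perm x n_features` null scores are pooled
#' into one component-independent null distribution.
#'
#' @inheritParams run_feature_bagging
#' @param n_perm Number of label permutations (>= 100 recommended for
#'   p-value resolution).
#' @param percentile Accuracy threshold percentile.
#' @return Matrix `n_perm x n_features` of null scores.
#' @export
permutation_null <- function(x, labels, n_perm = 200, bag_size = 10,
                             n_draw = 2e4, percentile = 75,
                             classifier = "ridge", cv = "loo", lambda = 1) {
  if (n_perm < 1) stop("n_perm must be positive")
  x <- as.matrix(x)
  lab <- as.character(labels)
  null_scores <- matrix(0, n_perm, ncol(x))
  for (b in seq_len(n_perm)) {
    perm <- sample(lab)
    br <- run_feature_bagging(x, perm, bag_size = bag_size, n_draw = n_draw,
                              classifier = classifier, cv = cv,
                              lambda = lambda)
    null_scores[b, ] <- classification_scores(br, percentile)
  }
  null_scores
}

#' Feature significance against a pooled permutation null
#'
#' P-values use the add-one estimator
#' `p_f = (1 + #\{null >= score_f\}) / (1 + pooled size)` and are
#' Benjamini-Hochberg corrected across features.
#'
#' @param scores Observed per-feature classification scores.
#' @param null_scores Pooled null (matrix or vector of null scores).
#' @param q FDR level (default 0.05).
#' @return data.frame `score`, `p`, `q`, `significant`.
#' @export
score_significance <- function(scores, null_scores, q = 0.05) {
  pooled <- sort(as.numeric(null_scores))
  N <- length(pooled)
  if (N == 0) stop("empty permutation null")
  # #\{null >= s\} = N - #\{null < s\}
  n_ge <- N - findInterval(as.numeric(scores), pooled, left.open = TRUE)
  p <- (1 + n_ge) / (1 + N)
  qv <- stats::p.adjust(p, method = "BH")
  data.frame(score = as.numeric(scores), p = p, q = qv,
             significant = qv < q)
}

#' Global (pooled-count) significance of the classification
#'
#' Compares the observed number of significant components against its
#' permutation distribution: `p = (1 + #\{perm counts >= observed\}) /
#' (1 + n_perm)`.
#'
#' @param observed_count Number of significant features in the real data.
#' @param perm_counts Significant-feature counts per permutation.
#' @return The permutation p-value.
#' @export
global_significance <- function(observed_count, perm_counts) {
  (1 + sum(perm_counts >= observed_count)) / (1 + length(perm_counts))
}

#' Fit feature-bagged classification scores with permutation selection
#'
#' The package's core estimator. Given a subjects x features matrix of
#' coupling-component scores and two group labels, `fcbag`:
#' \enumerate{
#'   \item draws `n_draw` random feature bags and records cross-validated
#'     group-classification accuracy per bag
#'     ([run_feature_bagging()]);
#'   \item scores each feature by its probability of belonging to the bags in
#'     the top accuracy quartile ([classification_scores()]);
#'   \item builds one pooled permutation null by repeating the full
#'     procedure, fresh bags included, under `n_perm` group-label
#'     permutations ([permutation_null()]);
#'   \item flags features whose score is FDR-significant against the pooled
#'     null, and tests the overall count of significant features against its
#'     permutation distribution ([global_significance()]).
#' }
#'
#' @inheritParams run_feature_bagging
#' @inheritParams permutation_null
#' @param q FDR level for feature selection.
#' @param percentile Accuracy threshold percentile (75 = top quartile).
#' @param feature_index Optional data.frame describing the columns (e.g. the
#'   `feature_index` attribute of a feature matrix); recovered automatically
#'   from `"feature_matrix"` inputs.
#' @param seed Integer seed making the whole fit reproducible; `NULL` uses
#'   the current RNG state.
#' @param keep_x Store the training data in the object (needed by
#'   [predict.fcbag()]).
#' @return An object of class `"fcbag"`: list with `selection` (per-feature
#'   data.frame: index columns, `score`, `p`, `q`, `significant`),
#'   `global_p`, `perm_counts`, `null_scores`, `accuracy` (observed bag
#'   accuracies), `threshold`, `config`, `labels`.
#' @seealso [summary.fcbag()], [predict.fcbag()], [nested_loo_accuracy()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30 * 40), 30)
#' x[, 7] <- x[, 7] + rep(c(2, 0), each = 15)  # one informative feature
#' labels <- rep(c("patient", "control"), each = 15)
#' fit <- fcbag(x, labels, n_draw = 500, n_perm = 20, seed = 1)
#' which.max(coef(fit))
#' @export
fcbag <- function(x, labels, bag_size = 10, n_draw = 2e4, n_perm = 200,
                  percentile = 75, q = 0.05, classifier = "ridge",
                  cv = "loo", lambda = 1, feature_index = NULL, seed = NULL,
                  keep_x = TRUE) {
  if (is.null(feature_index) && !is.null(attr(x, "feature_index"))) {
    feature_index <- attr(x, "feature_index")
  }
  if (missing(labels) && !is.null(attr(x, "labels"))) {
    labels <- attr(x, "labels")
  }
  x <- as.matrix(unclass(x))
  lab <- as.character(labels)
  if (!is.null(seed)) set.seed(seed)
  br <- run_feature_bagging(x, lab, bag_size = bag_size, n_draw = n_draw,
                            classifier = classifier, cv = cv, lambda = lambda)
  sc <- classification_scores(br, percentile)
  null_scores <- permutation_null(x, lab, n_perm = n_perm,
                                  bag_size = bag_size, n_draw = n_draw,
                                  percentile = percentile,
                                  classifier = classifier, cv = cv,
                                  lambda = lambda)
  sel <- score_significance(sc, null_scores, q = q)
  # per-permutation significant counts against the same pooled null
  pooled <- sort(as.numeric(null_scores))
  N <- length(pooled)
  perm_counts <- vapply(seq_len(nrow(null_scores)), function(b) {
    pb <- (1 + N - findInterval(null_scores[b, ], pooled, left.open = TRUE)) /
      (1 + N)
    sum(stats::p.adjust(pb, method = "BH") < q)
  }, integer(1))
  global_p <- global_significance(sum(sel$significant), perm_counts)
  selection <- if (!is.null(feature_index)) {
    cbind(feature_index, sel)
  } else {
    cbind(data.frame(column = seq_len(ncol(x))), sel)
  }
  structure(list(
    call = match.call(), selection = selection, global_p = global_p,
    perm_counts = perm_counts, null_scores = null_scores,
    accuracy = br$accuracy, threshold = attr(sc, "threshold"),
    selected_fraction = attr(sc, "selected_fraction"),
    config = list(bag_size = bag_size, n_draw = n_draw, n_perm = n_perm,
                  percentile = percentile, q = q, classifier = classifier,
                  cv = cv, lambda = lambda, seed = seed),
    labels = lab, x = if (keep_x) x else NULL
  ), class = "fcbag")
}

#' @export
print.fcbag <- function(x, ...) {
  cat("Feature-bagged classification scores\n")
  cat(sprintf("  %d features, %d subjects (%d patients / %d controls)\n",
              nrow(x$selection), length(x$labels),
              sum(x$labels == "patient"), sum(x$labels == "control")))
  cat(sprintf("  %d bags of %d, accuracy threshold %.3f (top %.0f%%, %.1f%% of bags selected)\n",
              x$config$n_draw, x$config$bag_size, x$threshold,
              100 - x$config$percentile, 100 * x$selected_fraction))
  cat(sprintf("  %d significant features (q < %.2g, %d permutations), global p = %.4g\n",
              sum(x$selection$significant), x$config$q, x$config$n_perm,
              x$global_p))
  invisible(x)
}

#' @export
coef.fcbag <- function(object, ...) {
  structure(object$selection$score,
            names = if (!is.null(rownames(object$selection))) {
              rownames(object$selection)
            } else {
              NULL
            })
}

#' Summarize a feature-bagging fit
#'
#' @param object An `"fcbag"` object.
#' @param n_top Number of top-scoring features to tabulate.
#' @param ... Unused.
#' @return A `"summary.fcbag"` list: `top` (data.frame of the highest
#'   scores), counts, global p, mean bag accuracy.
#' @export
summary.fcbag <- function(object, n_top = 10, ...) {
  ord <- order(object$selection$score, decreasing = TRUE)
  structure(list(
    top = object$selection[head(ord, n_top), , drop = FALSE],
    n_significant = sum(object$selection$significant),
    n_features = nrow(object$selection),
    global_p = object$global_p,
    mean_accuracy = mean(object$accuracy),
    uniform_score = object$config$bag_size / nrow(object$selection),
    config = object$config
  ), class = "summary.fcbag")
}

#' @export
print.summary.fcbag <- function(x, ...) {
  cat(sprintf(
    "fcbag fit: %d/%d significant features, global p = %.4g, mean bag accuracy %.3f\n",
    x$n_significant, x$n_features, x$global_p, x$mean_accuracy))
  cat(sprintf("uninformative score floor: %.4g\nTop features:\n",
              x$uniform_score))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fcbag <- function(x, ...) {
  s <- x$selection
  col <- if ("mode" %in% names(s)) {
    ifelse(s$mode == "amplitude", "#7b3294", "#008837")
  } else {
    "grey30"
  }
  plot(seq_len(nrow(s)), s$score, pch = 16, cex = 0.6, col = col,
       xlab = "feature", ylab = "classification score", ...)
  abline(h = x$config$bag_size / nrow(s), lty = 3)
  if (any(s$significant)) {
    points(which(s$significant), s$score[s$significant], pch = 1, cex = 1.2)
  }
  if ("mode" %in% names(s)) {
    legend("topright", c("amplitude", "phase", "significant"),
           col = c("#7b3294", "#008837", "black"),
           pch = c(16, 16, 1), bty = "n")
  }
  invisible(x)
}

# Ridge training on +-1 labels; returns the separating direction.
train_linear <- function(x, y, lambda = 1) {
  Z <- cbind(1, x)
  G <- crossprod(Z) + lambda * diag(ncol(Z))
  beta <- solve(G, crossprod(Z, y))
  list(intercept = beta[1], w = beta[-1])
}

linear_distance <- function(model, x) {
  f <- model$intercept + as.matrix(x) %*% model$w
  wn <- sqrt(sum(model$w^2))
  if (wn < 1e-12) wn <- 1
  as.numeric(f) / wn
}

#' Classify subjects with the selected features
#'
#' Trains the default linear classifier on the significant features of a fit
#' (falling back to the `bag_size` top-scoring features when none is
#' significant) and returns signed distances to the decision boundary
#' (positive = patient side) and predicted classes.
#'
#' @param object An `"fcbag"` fitted with `keep_x = TRUE`.
#' @param newdata Matrix with the same feature columns; defaults to the
#'   training data.
#' @param features `"significant"` (with fallback) or explicit column
#'   indices.
#' @param ... Unused.
#' @return data.frame `distance`, `class`.
#' @export
predict.fcbag <- function(object, newdata = NULL, features = "significant",
                          ...) {
  if (is.null(object$x)) stop("refit with keep_x = TRUE to enable predict()")
  cols <- if (identical(features, "significant")) {
    w <- which(object$selection$significant)
    if (length(w) == 0) {
      order(object$selection$score, decreasing = TRUE)[
        seq_len(object$config$bag_size)]
    } else {
      w
    }
  } else {
    features
  }
  xtr <- object$x[, cols, drop = FALSE]
  m <- colMeans(xtr)
  s <- sqrt(colMeans(sweep(xtr, 2, m)^2))
  s[s < 1e-12] <- 1
  xtr <- sweep(sweep(xtr, 2, m), 2, s, "/")
  y <- encode_labels(object$labels)
  model <- train_linear(xtr, y, object$config$lambda)
  xn <- if (is.null(newdata)) xtr else {
    sweep(sweep(as.matrix(newdata)[, cols, drop = FALSE], 2, m), 2, s, "/")
  }
  d <- linear_distance(model, xn)
  data.frame(distance = d,
             class = ifelse(d >= 0, "patient", "control"))
}
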