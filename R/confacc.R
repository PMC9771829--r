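# Classification confidence (leave-one-out Mahalanobis distances), severity
# correlation, and the unbiased second-level leave-one-out accuracy
# estimator with Gaussian fits.

shrunk_covariance <- function(x, shrinkage) {
  C <- stats::cov(x)
  target <- mean(diag(C)) * diag(ncol(x))
  gam <- shrinkage
  repeat {
    Cs <- (1 - gam) * C + gam * target
    ok <- tryCatch({
      R <- chol(Cs)
      min(diag(R)) > sqrt(mean(diag(Cs))) * 1e-7
    }, error = function(e) FALSE)
    if (ok) return(list(C = Cs, shrinkage = gam))
    if (gam >= 0.95) {
      return(list(C = 0.05 * C + 0.95 * target, shrinkage = 0.95))
    }
    gam <- min(0.95, gam + 0.2)
  }
}

#' Mahalanobis classification confidence
#'
#' For each subject i, computes the squared Mahalanobis distance of its
#' feature vector to the patient and to the control feature distribution,
#' `D = (f_i - mu_g) C_g^-1 (f_i - mu_g)'`, always excluding subject i from
#' its own group's mean and covariance. Classification confidence is
#' `D_control - D_patient`: positive values mean the subject's coupling is
#' closer to the patient group. The distance is used in its squared form
#' throughout (no square root).
#'
#' When a group covariance is singular (feature count close to group size)
#' it is shrunk toward the average-variance diagonal; the shrinkage actually
#' used is reported.
#'
#' @param x Feature matrix (subjects x features), typically restricted to
#'   the significant components of an [fcbag()] fit.
#' @param labels `"patient"`/`"control"` per subject.
#' @param shrinkage Initial diagonal-loading weight in \[0, 1); increased
#'   automatically (with a warning) if the covariance remains singular.
#' @return A `"confidence_scores"` data.frame: `subject`, `group`,
#'   `d_control`, `d_patient`, `confidence`; attribute `shrinkage_used`.
#' @export
mahalanobis_confidence <- function(x, labels, shrinkage = 0.1) {
  x <- as.matrix(unclass(x))
  lab <- as.character(labels)
  stopifnot(all(lab %in% c("patient", "control")))
  d <- ncol(x)
  for (g in c("patient", "control")) {
    if (sum(lab == g) < 3) stop("each group needs >= 3 subjects")
  }
  n <- nrow(x)
  D <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("patient", "control")))
  gam_used <- 0
  for (g in c("patient", "control")) {
    members <- which(lab == g)
    # distances of non-members to the full group
    full <- shrunk_covariance(x[members, , drop = FALSE], shrinkage)
    gam_used <- max(gam_used, full$shrinkage)
    mu <- colMeans(x[members, , drop = FALSE])
    Cinv <- solve(full$C)
    for (i in setdiff(seq_len(n), members)) {
      v <- x[i, ] - mu
      D[i, g] <- drop(t(v) %*% Cinv %*% v)
    }
    # leave-self-out distances of members
    for (i in members) {
      rest <- setdiff(members, i)
      sc <- shrunk_covariance(x[rest, , drop = FALSE], shrinkage)
      gam_used <- max(gam_used, sc$shrinkage)
      mu_i <- colMeans(x[rest, , drop = FALSE])
      v <- x[i, ] - mu_i
      D[i, g] <- drop(t(v) %*% solve(sc$C) %*% v)
    }
  }
  if (gam_used > shrinkage) {
    warning(sprintf("singular group covariance: shrinkage raised to %.2f",
                    gam_used))
  }
  out <- data.frame(
    subject = if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(n)),
    group = lab,
    d_control = D[, "control"], d_patient = D[, "patient"],
    confidence = D[, "control"] - D[, "patient"])
  structure(out, shrinkage_used = gam_used,
            class = c("confidence_scores", "data.frame"))
}

#' Correlation of classification confidence with disease severity
#'
#' Product-moment correlation between per-patient classification confidence
#' and each clinical severity score, over patients only, with pairwise
#' deletion of missing scores and Benjamini-Hochberg correction across the
#' scores tested. A rank (Spearman) option is available.
#'
#' @param confidence A [mahalanobis_confidence()] result (or numeric vector
#'   of patient confidences).
#' @param severity data.frame of severity scores (rows = patients, in the
#'   same order as the patients in `confidence`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_n Minimum number of complete pairs per score.
#' @return data.frame `score`, `n`, `r`, `p`, `q`.
#' @export
severity_correlation <- function(confidence, severity,
                                 method = c("pearson", "spearman"),
                                 min_n = 5) {
  method <- match.arg(method)
  conf <- if (inherits(confidence, "confidence_scores")) {
    confidence$confidence[confidence$group == "patient"]
  } else {
    as.numeric(confidence)
  }
  severity <- as.data.frame(severity)
  if (nrow(severity) != length(conf)) {
    stop("severity rows must match the number of patients")
  }
  rows <- lapply(names(severity), function(nm) {
    s <- severity[[nm]]
    ok <- is.finite(conf) & is.finite(s)
    if (sum(ok) < min_n) {
      return(data.frame(score = nm, n = sum(ok), r = NA_real_, p = NA_real_))
    }
    if (stats::sd(conf[ok]) == 0 || stats::sd(s[ok]) == 0) {
      warning(sprintf("zero variance for score %s: correlation undefined", nm))
      return(data.frame(score = nm, n = sum(ok), r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(conf[ok], s[ok], method = method, exact = FALSE)
    data.frame(score = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Gaussian accuracy estimate from signed boundary distances
#'
#' Fits one Gaussian per group to the signed, SD-normalized distances from
#' the decision boundary (positive = classified patient) and derives
#' sensitivity (patient-Gaussian mass above 0), specificity
#' (control-Gaussian mass below 0) and the group-size-weighted accuracy
#' `(n_pat * sensitivity + n_con * specificity) / n_all`.
#'
#' @param distances Signed distances, one per subject.
#' @param labels `"patient"`/`"control"` per subject.
#' @return An `"accuracy_estimate"`: list with `sensitivity`, `specificity`,
#'   `accuracy`, per-group Gaussian `mean`/`sd`, group sizes, `distances`,
#'   `labels`.
#' @export
gaussian_accuracy <- function(distances, labels) {
  lab <- as.character(labels)
  stopifnot(length(distances) == length(lab),
            all(lab %in% c("patient", "control")))
  dp <- distances[lab == "patient"]
  dc <- distances[lab == "control"]
  if (length(dp) < 2 || length(dc) < 2) stop("each group needs >= 2 subjects")
  gauss_mass <- function(d, above) {
    m <- mean(d)
    s <- stats::sd(d)
    if (s == 0) {
      warning("zero-SD group: Gaussian degenerates to a step function")
      if (m == 0) return(0.5)
      return(as.numeric(if (above) m > 0 else m < 0))
    }
    if (above) stats::pnorm(0, m, s, lower.tail = FALSE)
    else stats::pnorm(0, m, s)
  }
  sens <- gauss_mass(dp, above = TRUE)
  spec <- gauss_mass(dc, above = FALSE)
  np <- length(dp)
  nc <- length(dc)
  acc <- (np * sens + nc * spec) / (np + nc)
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 mean = c(patient = mean(dp), control = mean(dc)),
                 sd = c(patient = stats::sd(dp), control = stats::sd(dc)),
                 n = c(patient = np, control = nc, all = np + nc),
                 distances = distances, labels = lab),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf(
    "Gaussian accuracy estimate (n = %d patients + %d controls)\n  sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
    x$n["patient"], x$n["control"], x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

# One nested fold: select features on the training subjects, train the
# linear classifier, return the held-out subject's SD-normalized signed
# distance.
nested_fold_distance <- function(x, lab, i, bag_size, n_draw, n_perm,
                                 percentile, q, classifier, cv, lambda) {
  xtr <- x[-i, , drop = FALSE]
  ltr <- lab[-i]
  br <- run_feature_bagging(xtr, ltr, bag_size = bag_size, n_draw = n_draw,
                            classifier = classifier, cv = cv, lambda = lambda)
  sc <- classification_scores(br, percentile)
  nul <- permutation_null(xtr, ltr, n_perm = n_perm, bag_size = bag_size,
                          n_draw = n_draw, percentile = percentile,
                          classifier = classifier, cv = cv, lambda = lambda)
  sig <- score_significance(sc, nul, q = q)
  cols <- which(sig$significant)
  if (length(cols) == 0) {
    cols <- order(sig$score, decreasing = TRUE)[seq_len(bag_size)]
  }
  xs <- xtr[, cols, drop = FALSE]
  m <- colMeans(xs)
  s <- sqrt(colMeans(sweep(xs, 2, m)^2))
  s[s < 1e-12] <- 1
  xs <- sweep(sweep(xs, 2, m), 2, s, "/")
  model <- train_linear(xs, encode_labels(ltr), lambda)
  d_in <- linear_distance(model, xs)
  sd_in <- stats::sd(d_in)
  if (!is.finite(sd_in) || sd_in == 0) sd_in <- 1
  xho <- sweep(sweep(x[i, cols, drop = FALSE], 2, m), 2, s, "/")
  linear_distance(model, xho) / sd_in
}

#' Nested leave-one-out accuracy of the full selection pipeline
#'
#' The naive accuracy of a classifier built on components that were selected
#' using all subjects is optimistically biased. This estimator removes the
#' bias by cross-validating the *entire* pipeline: leaving out each subject
#' in turn, feature selection (bagging + permutation FDR) is redone on the
#' remaining subjects only, a linear classifier is trained on the selected
#' features, and the held-out subject's distance to the decision boundary is
#' recorded, divided by the SD of the in-sample subjects' distances (signed
#' positive when classified patient). [gaussian_accuracy()] of these
#' distances gives the unbiased sensitivity/specificity/accuracy.
#'
#' Folds that select zero significant features fall back to the `bag_size`
#' top-scoring features. The component basis is assumed fixed (fit on the
#' independent reference cohort, never on study subjects), so it does not
#' participate in the cross-validation.
#'
#' @inheritParams fcbag
#' @param subset Optional feature-column subset (e.g. one coupling mode or
#'   frequency range) to restrict the pipeline to.
#' @param seed Integer; fold f is run under seed `seed + f` so folds are
#'   order-independent.
#' @return An `"accuracy_estimate"` (see [gaussian_accuracy()]) with the
#'   per-subject normalized distances.
#' @export
nested_loo_accuracy <- function(x, labels, bag_size = 10, n_draw = 2000,
                                n_perm = 50, percentile = 75, q = 0.05,
                                classifier = "ridge", cv = "loo", lambda = 1,
                                subset = NULL, seed = 1) {
  x <- as.matrix(unclass(x))
  if (!is.null(subset)) x <- x[, subset, drop = FALSE]
  lab <- as.character(labels)
  n <- nrow(x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    d[i] <- nested_fold_distance(x, lab, i, bag_size, n_draw, n_perm,
                                 percentile, q, classifier, cv, lambda)
  }
  gaussian_accuracy(d, lab)
}
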