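# Principal coupling components: per-(mode, frequency) PCA bases fit on the
# reference cohort, projection of study profiles, sign alignment, band
# summaries.

#' Fit a principal coupling-component basis on the reference cohort
#'
#' PCA of the subjects x connections matrix of (z-scored) reference coupling
#' profiles after subtracting the cross-subject mean profile, computed via
#' singular value decomposition (the subject dimension is the small side).
#' Because the basis is fit on an independent cohort, between-group variance
#' of any later study cohort cannot leak into the feature space, and one
#' fitted basis can be reused across studies.
#'
#' @param reference_profiles Matrix (reference subjects x connections) of
#'   per-subject z-scored coupling profiles.
#' @param k Number of retained components (default 30); silently reduced to
#'   the available rank with a warning if the data are rank-deficient.
#' @param mode,frequency Optional labels.
#' @return A `"component_basis"`: list with `vectors` (connections x k,
#'   orthonormal columns), `values` (component variances across subjects,
#'   nonincreasing), `mean_profile`, `k`, `n_ref`, `mode`, `frequency`.
#' @export
fit_component_basis <- function(reference_profiles, k = 30,
                                mode = NA_character_, frequency = NA_real_) {
  X <- as.matrix(reference_profiles)
  n_ref <- nrow(X)
  if (n_ref < k + 1) stop("need at least k + 1 reference subjects")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  kk <- min(k, rank, n_ref - 1)
  if (kk < k) {
    warning(sprintf("rank deficiency: retaining %d of %d requested components",
                    kk, k))
  }
  structure(list(
    vectors = sv$v[, seq_len(kk), drop = FALSE],
    values = sv$d[seq_len(kk)]^2 / (n_ref - 1),
    mean_profile = mu, k = kk, n_ref = n_ref,
    mode = mode, frequency = frequency
  ), class = "component_basis")
}

#' @export
print.component_basis <- function(x, ...) {
  cat(sprintf(
    "<component_basis> mode=%s %.4g Hz: %d components over %d connections (n_ref=%d)\n",
    x$mode, x$frequency, x$k, nrow(x$vectors), x$n_ref))
  invisible(x)
}

#' Project coupling profiles onto a component basis
#'
#' Component scores are inner products of the (z-scored) profiles with the
#' basis eigenvectors. By default the reference mean profile is subtracted
#' first (standard PCA projection); `center = FALSE` reproduces the plain
#' eigenvector-product reading. Centering shifts all subjects equally per
#' component, so group contrasts are identical under both conventions.
#'
#' @param profiles Matrix (subjects x connections).
#' @param basis A [fit_component_basis()] result.
#' @param center Subtract the reference mean profile before projecting.
#' @return Matrix of component scores (subjects x k).
#' @export
project_profiles <- function(profiles, basis, center = TRUE) {
  X <- as.matrix(profiles)
  if (ncol(X) != nrow(basis$vectors)) {
    stop("connection count does not match the component basis")
  }
  if (center) X <- sweep(X, 2, basis$mean_profile)
  X %*% basis$vectors
}

#' Assemble the feature matrix across modes and frequencies
#'
#' Fits (or reuses) one component basis per (mode, frequency) on the
#' reference subjects of a profile cohort, z-scores every subject's profile
#' within subject, projects the study subjects, and concatenates the
#' component scores into one subjects x features matrix with a feature index
#' mapping each column to (mode, frequency, component rank).
#'
#' @param cohort A profile-type `"coupling_cohort"` containing reference and
#'   study subjects.
#' @param k Components per (mode, frequency).
#' @param bases Optional precomputed list of bases (as returned in the
#'   `bases` attribute) to reuse; when given, `k` is ignored.
#' @param zscore Z-score profiles within subject before fitting/projecting.
#' @param center Passed to [project_profiles()].
#' @return A `"feature_matrix"`: numeric matrix (study subjects x features)
#'   with attributes `feature_index` (data.frame `column`, `mode`,
#'   `frequency`, `rank`), `labels` (group factor), `bases`.
#' @export
build_feature_matrix <- function(cohort, k = 30, bases = NULL, zscore = TRUE,
                                 center = TRUE) {
  stopifnot(inherits(cohort, "coupling_cohort"),
            identical(attr(cohort, "type"), "profile"))
  man <- cohort$manifest
  is_ref <- man$group == "reference"
  is_study <- !is_ref
  scores <- list()
  index <- list()
  fitted <- list()
  for (m in names(cohort$profiles)) {
    for (fl in names(cohort$profiles[[m]])) {
      P <- cohort$profiles[[m]][[fl]]
      f <- as.numeric(sub("^f", "", fl))
      if (zscore) P <- t(apply(P, 1, zscore_profile))
      key <- paste(m, fl, sep = ".")
      b <- if (!is.null(bases)) bases[[key]] else {
        fit_component_basis(P[is_ref, , drop = FALSE], k = k, mode = m,
                            frequency = f)
      }
      fitted[[key]] <- b
      sc <- project_profiles(P[is_study, , drop = FALSE], b, center = center)
      scores[[key]] <- sc
      index[[key]] <- data.frame(mode = m, frequency = f, rank = seq_len(b$k))
    }
  }
  X <- do.call(cbind, scores)
  idx <- do.call(rbind, index)
  idx <- data.frame(column = seq_len(nrow(idx)), idx, row.names = NULL)
  colnames(X) <- sprintf("%s.f%.4g.c%02d", substr(idx$mode, 1, 3),
                         idx$frequency, idx$rank)
  rownames(X) <- man$subject_id[is_study]
  structure(X, feature_index = idx,
            labels = factor(man$group[is_study], c("control", "patient")),
            bases = fitted, class = c("feature_matrix", "matrix"))
}

#' Align component signs to the patient-minus-control contrast
#'
#' PCA eigenvector signs are arbitrary. Components whose mean score is
#' smaller in patients than controls are negated (both the score column and
#' the eigenvector), so that afterwards a positive loading always means
#' coupling relatively increased in patients. The operation is idempotent.
#'
#' @param features A `"feature_matrix"`.
#' @param labels Group factor/character (`"patient"`/`"control"`); defaults
#'   to the matrix's `labels` attribute.
#' @return The feature matrix with aligned columns, aligned `bases`, and a
#'   logical attribute `flipped` per column.
#' @export
align_component_signs <- function(features, labels = attr(features, "labels")) {
  lab <- as.character(labels)
  if (!any(lab == "patient") || !any(lab == "control")) {
    stop("both groups must be present")
  }
  X <- unclass(features)
  pm <- colMeans(X[lab == "patient", , drop = FALSE])
  cm <- colMeans(X[lab == "control", , drop = FALSE])
  flip <- pm < cm
  X[, flip] <- -X[, flip, drop = FALSE]
  idx <- attr(features, "feature_index")
  bases <- attr(features, "bases")
  if (!is.null(bases)) {
    for (ci in which(flip)) {
      key <- paste(idx$mode[ci],
                   freq_label(idx$frequency[ci]), sep = ".")
      bases[[key]]$vectors[, idx$rank[ci]] <-
        -bases[[key]]$vectors[, idx$rank[ci]]
    }
  }
  structure(X, feature_index = idx, labels = attr(features, "labels"),
            bases = bases, flipped = flip,
            class = c("feature_matrix", "matrix"))
}

#' Canonical frequency bands
#'
#' @return data.frame with `band`, `lo`, `hi` (Hz): delta 2.8-3.4, theta
#'   4-6.7, alpha 8-13, beta 16-27, low gamma 32-54, high gamma 64-128.
#' @export
default_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "low gamma",
                      "high gamma"),
             lo = c(2.8, 4, 8, 16, 32, 64),
             hi = c(3.4, 6.7, 13, 27, 54, 128))
}

#' Band-averaged loading maps of significant components
#'
#' For each band and coupling mode, averages the (sign-aligned) loading
#' vectors of all significant components whose frequency falls inside the
#' band, after dividing each component by the absolute 98th percentile of its
#' loadings (linear-interpolation percentile); at most the top 2% of
#' connections can exceed 1 in magnitude. Also returns the mean absolute
#' loading per connection split at `split_hz` (default 35 Hz, above which
#' MEG coupling increasingly reflects residual muscle activity).
#'
#' @param features A sign-aligned `"feature_matrix"` (for its `bases` and
#'   `feature_index`).
#' @param significant Logical vector (per feature column) flagging the
#'   significant components.
#' @param bands Band definitions as in [default_bands()].
#' @param split_hz Split frequency for the absolute-loading maps.
#' @return List with `bands` (list of per-(band, mode) normalized mean
#'   loading vectors, `NULL`-flagged empty bands recorded in `empty`),
#'   `split` (per mode, `low`/`high` mean absolute loadings), `empty`.
#' @export
band_average_components <- function(features, significant,
                                    bands = default_bands(), split_hz = 35) {
  idx <- attr(features, "feature_index")
  bases <- attr(features, "bases")
  stopifnot(length(significant) == nrow(idx))
  if (!any(significant)) stop("no significant components to summarize")
  loading <- function(ci) {
    key <- paste(idx$mode[ci], freq_label(idx$frequency[ci]), sep = ".")
    v <- bases[[key]]$vectors[, idx$rank[ci]]
    v / stats::quantile(abs(v), 0.98, type = 7, names = FALSE)
  }
  out_bands <- list()
  empty <- character(0)
  for (m in unique(idx$mode)) {
    for (b in seq_len(nrow(bands))) {
      sel <- which(significant & idx$mode == m &
                     idx$frequency >= bands$lo[b] &
                     idx$frequency <= bands$hi[b])
      nm <- paste(m, bands$band[b], sep = ".")
      if (length(sel) == 0) {
        empty <- c(empty, nm)
        next
      }
      L <- vapply(sel, loading, numeric(nrow(bases[[1]]$vectors)))
      out_bands[[nm]] <- rowMeans(L)
    }
  }
  split <- list()
  for (m in unique(idx$mode)) {
    for (side in c("low", "high")) {
      sel <- which(significant & idx$mode == m &
                     (if (side == "low") idx$frequency < split_hz
                      else idx$frequency >= split_hz))
      nm <- paste(m, side, sep = ".")
      if (length(sel) == 0) {
        empty <- c(empty, nm)
        next
      }
      L <- vapply(sel, function(ci) abs(loading(ci)),
                  numeric(nrow(bases[[1]]$vectors)))
      split[[nm]] <- rowMeans(L)
    }
  }
  list(bands = out_bands, split = split, empty = empty)
}
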