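# Volume-conduction-insensitive coupling metrics and coupling profiles.

#' Construct a coupling matrix
#'
#' Wraps a symmetric matrix of pairwise coupling values with its mode and
#' carrier frequency; the diagonal (self-coupling) is undefined and set to
#' `NA`.
#'
#' @param values Symmetric numeric matrix (sources x sources).
#' @param mode `"amplitude"` or `"phase"`.
#' @param frequency Carrier frequency in Hz.
#' @return A `"coupling_matrix"`.
#' @export
coupling_matrix <- function(values, mode, frequency) {
  diag(values) <- NA_real_
  structure(values, mode = mode, frequency = frequency,
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> mode=%s %.4g Hz, %d sources\n",
              attr(x, "mode"), attr(x, "frequency"), nrow(x)))
  invisible(x)
}

#' Orthogonalized amplitude-envelope correlation
#'
#' For each ordered source pair (X -> Y) the component of Y's complex
#' coefficient orthogonal to X's instantaneous phase is retained
#' (`|Y_orth| = |Im(Y * Conj(X))| / |X|`), log-power envelopes
#' `log |Y_orth|^2` and `log |X|^2` are formed and their product-moment
#' correlation computed. The two directed values per pair are averaged into a
#' symmetric matrix. Because the orthogonalized envelope cannot contain any
#' instantaneously mixed copy of X, zero-lag field spread does not contribute.
#'
#' Degenerate pairs (an orthogonalized envelope with zero variance, e.g.
#' exactly collinear signals) are set to 0 with a warning.
#'
#' @param frame A [`morlet_transform()`] spectral frame (or complex matrix
#'   sources x time steps).
#' @param min_steps Minimum number of valid time steps required.
#' @return A symmetric `"coupling_matrix"` with mode `"amplitude"`; values in
#'   \[-1, 1\], diagonal `NA`.
#' @export
aec_orth <- function(frame, min_steps = 20) {
  C <- unclass(frame)
  n <- nrow(C)
  nt <- ncol(C)
  if (nt < min_steps) {
    stop(sprintf("need >= %d time steps for envelope correlation, got %d",
                 min_steps, nt))
  }
  logpow <- log(Mod(C)^2)
  D <- matrix(NA_real_, n, n)
  n_degen <- 0L
  for (i in seq_len(n)) {
    ci <- C[i, ]
    absi <- Mod(ci)
    # row j of `orth`: envelope of source j orthogonalized on source i
    orth <- abs(Im(C * matrix(Conj(ci), n, nt, byrow = TRUE))) /
      matrix(absi, n, nt, byrow = TRUE)
    le <- 2 * log(orth)
    pi_ <- logpow[i, ]
    pc <- pi_ - mean(pi_)
    den_i <- sqrt(sum(pc^2))
    rows_ok <- is.finite(rowSums(le))
    lec <- le - rowMeans(le)
    den_j <- sqrt(rowSums(lec^2))
    r <- as.vector(lec %*% pc) / (den_j * den_i)
    bad <- !rows_ok | den_j < 1e-12 | den_i < 1e-12
    r[bad] <- 0
    n_degen <- n_degen + sum(bad[-i])
    D[, i] <- r  # D[j, i] = cor(log|X_i|^2, log|Y_j orth X_i|^2)
  }
  if (n_degen > 0) {
    warning(sprintf(
      "%d degenerate orthogonalized pair(s) set to 0 (zero-variance envelope)",
      n_degen))
  }
  A <- (D + t(D)) / 2
  coupling_matrix(A, "amplitude",
                  frequency = attr(frame, "frequency") %||% NA_real_)
}

#' Weighted phase-lag index
#'
#' For each source pair with cross-spectral terms
#' `S(t) = coef_i(t) * Conj(coef_j(t))`, computes
#' `wPLI = |mean(Im S)| / mean(|Im S|)`. Values lie in \[0, 1\]; any purely
#' real (zero-lag) mixing gives `Im S = 0` everywhere, which the degeneracy
#' guard maps to 0, so instantaneous volume conduction cannot produce
#' spurious coupling.
#'
#' @inheritParams aec_orth
#' @return A symmetric `"coupling_matrix"` with mode `"phase"`; values in
#'   \[0, 1\], diagonal `NA`.
#' @export
wpli <- function(frame, min_steps = 20) {
  C <- unclass(frame)
  n <- nrow(C)
  nt <- ncol(C)
  if (nt < min_steps) {
    stop(sprintf("need >= %d time steps for wPLI, got %d", min_steps, nt))
  }
  W <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    rows <- (i + 1):n
    cross <- C[rows, , drop = FALSE] *
      matrix(Conj(C[i, ]), length(rows), nt, byrow = TRUE)
    imS <- Im(cross)
    num <- abs(rowMeans(imS))
    den <- rowMeans(abs(imS))
    # degeneracy guard: an imaginary part at rounding level of the
    # cross-spectral magnitude is a zero-lag (purely real) pair
    floor_ <- 1e-12 * rowMeans(Mod(cross))
    w <- ifelse(den > floor_, num / den, 0)
    W[rows, i] <- w
    W[i, rows] <- w
  }
  coupling_matrix(W, "phase",
                  frequency = attr(frame, "frequency") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

connection_index_map <- function(n) {
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n), use.names = FALSE)
  data.frame(index = seq_along(i), i = i, j = j)
}

#' Vectorize a symmetric coupling matrix into a coupling profile
#'
#' Extracts the upper triangle (i < j) in row-major order, the pipeline's
#' atomic measurement: one vector of all unique connections per subject,
#' frequency and coupling mode. The mapping from vector position to source
#' pair is attached as `connection_index`.
#'
#' @param mat A `"coupling_matrix"` or symmetric numeric matrix.
#' @param tol Largest tolerated absolute asymmetry.
#' @return A `"coupling_profile"` numeric vector of length `n (n - 1) / 2`
#'   with attributes `n`, `mode`, `frequency`, `connection_index`.
#' @export
vectorize_profile <- function(mat, tol = 1e-8) {
  v <- unclass(mat)
  n <- nrow(v)
  offdiag <- abs(v - t(v))
  offdiag[!is.finite(offdiag)] <- 0
  if (max(offdiag) > tol * max(1, max(abs(v), na.rm = TRUE))) {
    stop("coupling matrix is not symmetric within tolerance")
  }
  tv <- t(v)
  out <- tv[lower.tri(tv)]  # row-major upper triangle of v
  structure(out, n = n,
            mode = attr(mat, "mode"),
            frequency = attr(mat, "frequency"),
            connection_index = connection_index_map(n),
            class = "coupling_profile")
}

#' Rebuild the symmetric matrix from a coupling profile
#'
#' Inverse of [vectorize_profile()]; the round trip is lossless.
#'
#' @param profile A `"coupling_profile"` (or plain vector plus `n`).
#' @param n Source count; taken from the profile attribute when absent.
#' @return A `"coupling_matrix"`.
#' @export
profile_to_matrix <- function(profile, n = attr(profile, "n")) {
  if (is.null(n)) stop("source count n is required")
  if (length(profile) != n * (n - 1) / 2) {
    stop("profile length does not equal n (n - 1) / 2")
  }
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- as.numeric(profile)
  m <- t(tm)
  m <- m + t(m)
  coupling_matrix(m, attr(profile, "mode") %||% "amplitude",
                  attr(profile, "frequency") %||% NA_real_)
}

#' Z-score a coupling profile within subject
#'
#' Subtracts the mean across connections and divides by the SD across
#' connections, so that profiles from subjects with globally stronger or
#' weaker coupling become comparable before projection into component space.
#' The population SD convention (denominator `n`) is the default; the sample
#' convention (`n - 1`) is available.
#'
#' @param profile Numeric vector (coupling profile).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The standardized profile (attributes preserved); mean 0, SD 1.
#' @export
zscore_profile <- function(profile, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- as.numeric(profile)
  m <- mean(v)
  s <- if (sd_type == "population") {
    sqrt(mean((v - m)^2))
  } else {
    stats::sd(v)
  }
  if (!is.finite(s) || s <= 0) stop("constant coupling profile: zero SD")
  out <- (v - m) / s
  attributes(out) <- attributes(profile)
  out
}
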