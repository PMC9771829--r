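# Mass-univariate connection-wise comparison and the binomial
# sign-asymmetry test.

# Tie-corrected normal-approximation two-tailed Mann-Whitney p for one
# connection (continuity-corrected), vectorized over connections.
mw_normal_approx <- function(xp, xc) {
  n1 <- nrow(xp)
  n2 <- nrow(xc)
  nc <- ncol(xp)
  U <- numeric(nc)
  p <- numeric(nc)
  for (k in seq_len(nc)) {
    v <- c(xp[, k], xc[, k])
    r <- rank(v)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    U[k] <- u
    nt <- n1 + n2
    ties <- table(v)
    tiecor <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - tiecor)
    if (sigma2 <= 0) {
      p[k] <- 1
      next
    }
    z <- u - n1 * n2 / 2
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
    p[k] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Connection-wise two-group Mann-Whitney tests
#'
#' Tests every connection of one (mode, frequency) profile pair for a group
#' difference in coupling strength with two-tailed Mann-Whitney U tests,
#' applies Benjamini-Hochberg FDR correction across connections (i.e. within
#' frequency), and records the sign of the group difference
#' (+1 = patients greater, by difference of group medians). Exact p-values
#' are used for group sizes up to 8 without ties; otherwise the
#' tie-corrected, continuity-corrected normal approximation.
#'
#' @param patient_profiles,control_profiles Numeric matrices
#'   (subjects x connections) with equal connection counts.
#' @param mode,frequency Optional labels carried into the result.
#' @return A `"connection_tests"` data.frame with columns `connection`, `U`,
#'   `p`, `q`, `sign`, plus attributes `mode`, `frequency`,
#'   `n_sig_pos`/`n_sig_neg` (uncorrected p < 0.05 counts by sign).
#' @export
connection_tests <- function(patient_profiles, control_profiles,
                             mode = NA_character_, frequency = NA_real_) {
  xp <- as.matrix(patient_profiles)
  xc <- as.matrix(control_profiles)
  if (ncol(xp) != ncol(xc)) stop("unequal connection counts")
  if (nrow(xp) < 2 || nrow(xc) < 2) stop("both groups need >= 2 subjects")
  nc <- ncol(xp)
  small <- nrow(xp) <= 8 && nrow(xc) <= 8
  if (small) {
    U <- numeric(nc)
    p <- numeric(nc)
    for (k in seq_len(nc)) {
      v <- c(xp[, k], xc[, k])
      has_ties <- anyDuplicated(v) > 0
      wt <- suppressWarnings(
        stats::wilcox.test(xp[, k], xc[, k], exact = !has_ties))
      U[k] <- unname(wt$statistic)
      p[k] <- wt$p.value
    }
  } else {
    mw <- mw_normal_approx(xp, xc)
    U <- mw$U
    p <- mw$p
  }
  sgn <- sign(apply(xp, 2, stats::median) - apply(xc, 2, stats::median))
  allsame <- vapply(seq_len(nc), function(k) {
    length(unique(c(xp[, k], xc[, k]))) == 1
  }, logical(1))
  p[allsame] <- 1
  sgn[allsame] <- 0
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(connection = seq_len(nc), U = U, p = p, q = q, sign = sgn)
  structure(out, mode = mode, frequency = frequency,
            n_sig_pos = sum(p < 0.05 & sgn > 0),
            n_sig_neg = sum(p < 0.05 & sgn < 0),
            class = c("connection_tests", "data.frame"))
}

#' Binomial sign-asymmetry test across frequencies
#'
#' Among connections with uncorrected p below `alpha`, tests whether
#' significantly increased and decreased coupling are equally likely. The
#' observed proportion of positive signs is rescaled to `k = round(prop * df)`
#' successes out of `df` effective trials -- connections are massively
#' dependent, and `df` conservatively reflects the number of independently
#' separable sources (default 40, the typical rank of an MEG forward model)
#' -- and tested two-tailed against 0.5 with an exact binomial test
#' (minimum-likelihood convention). P-values are FDR-corrected across
#' frequencies.
#'
#' @param tests A list of [connection_tests()] results (one per frequency,
#'   one coupling mode).
#' @param alpha Uncorrected significance threshold defining "significant"
#'   connections.
#' @param df Effective number of independent trials.
#' @return A `"sign_asymmetry"` data.frame: `mode`, `frequency`, `n_sig`,
#'   `prop_pos`, `df`, `p`, `q`, `defined`.
#' @export
sign_asymmetry <- function(tests, alpha = 0.05, df = 40) {
  if (inherits(tests, "connection_tests")) tests <- list(tests)
  if (df < 1) stop("df must be >= 1")
  rows <- lapply(tests, function(tt) {
    sig <- tt$p < alpha
    n_sig <- sum(sig)
    if (n_sig == 0) {
      return(data.frame(mode = attr(tt, "mode"),
                        frequency = attr(tt, "frequency"),
                        n_sig = 0L, prop_pos = NA_real_, df = df, p = 1,
                        defined = FALSE))
    }
    prop <- mean(tt$sign[sig] > 0)
    k <- round(prop * df)
    p <- stats::binom.test(k, df, p = 0.5)$p.value
    data.frame(mode = attr(tt, "mode"), frequency = attr(tt, "frequency"),
               n_sig = n_sig, prop_pos = prop, df = df, p = p, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  structure(out[, c("mode", "frequency", "n_sig", "prop_pos", "df", "p", "q",
                    "defined")],
            class = c("sign_asymmetry", "data.frame"))
}
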