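# Synthetic study and reference cohorts with the statistical structure the
# analysis assumes: either raw band-limited oscillatory time series, or
# directly parameterized coupling profiles with planted low-rank group
# effects.

#' Simulation configuration
#'
#' Defines a two-group study cohort plus an independent reference cohort of
#' band-limited oscillatory sources. Envelope correlations are imposed through
#' a Gaussian copula on log-envelopes, phase coupling through correlated
#' slow phase jitter with a static nonzero lag (the weighted phase-lag index
#' is blind to zero-lag coupling), and group effects are planted as low-rank
#' shifts in coupling-component space.
#'
#' The default desk-scale geometry is 30 sources (435 connections), 6
#' octave-spaced carrier frequencies from 2^1.5 to 2^6.5 Hz (one per
#' canonical band), 60 s at 250 Hz, with 17 patients, 17 controls and a
#' 95-subject reference cohort.
#'
#' @param n_sources Number of cortical sources (>= 3).
#' @param n_patients,n_controls,n_reference Group sizes.
#' @param sampling_rate Hz.
#' @param duration Seconds per subject.
#' @param carrier_frequencies Center frequencies (Hz) of the band-limited
#'   oscillations.
#' @param envelope_correlation Per-frequency list (or single matrix recycled
#'   across frequencies) of symmetric unit-diagonal matrices of latent
#'   log-envelope correlations; default identity (uncoupled).
#' @param phase_lag Per-frequency list (or single matrix) of pairwise phase
#'   lags in radians; a nonzero entry marks a phase-coupled pair. Default all
#'   zero (uncoupled).
#' @param phase_coupling Optional per-frequency list (or matrix) of phase
#'   jitter correlations in \[0, 1\]; by default pairs with a nonzero lag get
#'   0.8 and all others 0.
#' @param planted_effect `NULL` or a data.frame with columns `mode`
#'   (`"amplitude"`/`"phase"`), `frequency` (must match a carrier), `rank`
#'   (generative component index) and `effect_size` (patient-group mean shift
#'   in units of the reference component-score SD). Used by the profile
#'   generator; see [planted_effect()].
#' @param noise_sd Additive noise SD: sensor noise for time series, profile
#'   noise per connection for the profile path.
#' @param n_generative Number of generative coupling components per
#'   (mode, frequency) for the profile path.
#' @param score_sds Component-score SDs of the generative components
#'   (descending), default `8 * 0.82^(0:(n_generative - 1))`.
#' @param envelope_log_sd SD of the latent log-envelope process.
#' @param phase_jitter_sd SD (radians) of the slow phase-jitter process.
#' @param lag_default Default lag (radians) assigned by [planted_effect()]
#'   helpers; pi/4 so phase coupling is visible to the wPLI.
#' @param seed Integer seed; every generated cohort is a pure function of the
#'   configuration.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_sources = 30, n_patients = 17, n_controls = 17,
                       n_reference = 95, sampling_rate = 250, duration = 60,
                       carrier_frequencies = 2^seq(1.5, 6.5, by = 1),
                       envelope_correlation = NULL, phase_lag = NULL,
                       phase_coupling = NULL, planted_effect = NULL,
                       noise_sd = 0.5, n_generative = 8, score_sds = NULL,
                       envelope_log_sd = 0.5, phase_jitter_sd = 0.7,
                       lag_default = pi / 4, seed = 1) {
  if (n_sources < 3) stop("n_sources must be >= 3")
  if (any(c(n_patients, n_controls) < 2) || n_reference < 3) {
    stop("group sizes too small")
  }
  nf <- length(carrier_frequencies)
  as_freq_list <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.matrix(x)) x <- rep(list(x), nf)
    if (length(x) != nf) stop("need one matrix per carrier frequency")
    x
  }
  envelope_correlation <- as_freq_list(envelope_correlation, diag(n_sources))
  phase_lag <- as_freq_list(phase_lag, matrix(0, n_sources, n_sources))
  for (k in seq_len(nf)) {
    R <- envelope_correlation[[k]]
    if (nrow(R) != n_sources || max(abs(R - t(R))) > 1e-10 ||
        max(abs(diag(R) - 1)) > 1e-10 || max(abs(R)) > 1 + 1e-10) {
      stop("envelope_correlation must be symmetric with unit diagonal in [-1, 1]")
    }
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      stop(sprintf(
        "envelope correlation matrix at %.3g Hz is not positive semi-definite (min eigenvalue %.3g)",
        carrier_frequencies[k], ev))
    }
    if (max(abs(phase_lag[[k]] + t(phase_lag[[k]]))) > 1e-10 &&
        max(abs(phase_lag[[k]] - t(phase_lag[[k]]))) > 1e-10) {
      stop("phase_lag must be symmetric or antisymmetric")
    }
  }
  if (is.null(phase_coupling)) {
    phase_coupling <- lapply(phase_lag, function(L) {
      P <- (abs(L) > 0) * 0.8
      diag(P) <- 1
      P
    })
  } else {
    phase_coupling <- as_freq_list(phase_coupling, diag(n_sources))
  }
  # geometric decay: adjacent eigenvalue gaps (~33%) stay well above their
  # sampling fluctuation at n_reference = 95, so the generative components
  # are identifiable from the reference PCA and planted effects recoverable
  if (is.null(score_sds)) score_sds <- 8 * 0.82^(seq_len(n_generative) - 1)
  if (!is.null(planted_effect)) {
    stopifnot(is.data.frame(planted_effect),
              all(c("mode", "frequency", "rank", "effect_size") %in%
                    names(planted_effect)))
    if (!all(planted_effect$mode %in% c("amplitude", "phase"))) {
      stop("planted_effect$mode must be 'amplitude' or 'phase'")
    }
    if (!all(planted_effect$frequency %in% carrier_frequencies)) {
      stop("planted_effect$frequency must match a carrier frequency")
    }
    if (any(planted_effect$rank > n_generative)) {
      stop("planted_effect rank exceeds the number of generative components")
    }
  }
  # >= 100 wavelet steps at the lowest carrier
  f0 <- min(carrier_frequencies)
  n_steps <- duration / (morlet_sd(f0)$sigma_t / 2)
  if (n_steps < 100) {
    stop(sprintf(
      "duration x sampling_rate gives only %.0f wavelet steps at %.3g Hz (>= 100 required)",
      n_steps, f0))
  }
  structure(list(
    n_sources = n_sources, n_patients = n_patients, n_controls = n_controls,
    n_reference = n_reference, sampling_rate = sampling_rate,
    duration = duration, carrier_frequencies = carrier_frequencies,
    envelope_correlation = envelope_correlation, phase_lag = phase_lag,
    phase_coupling = phase_coupling, planted_effect = planted_effect,
    noise_sd = noise_sd, n_generative = n_generative, score_sds = score_sds,
    envelope_log_sd = envelope_log_sd, phase_jitter_sd = phase_jitter_sd,
    lag_default = lag_default, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Describe a planted group effect
#'
#' Convenience constructor for the `planted_effect` slot of [sim_config()].
#' The default plants effect size 2 on the rank-1 amplitude component at the
#' third carrier frequency and on the rank-2 phase component at the fifth.
#'
#' @param mode,frequency_index,rank,effect_size Vectors of equal length (or
#'   length 1, recycled).
#' @param carrier_frequencies Carrier grid used to resolve `frequency_index`.
#' @return data.frame suitable for `sim_config(planted_effect = ...)`.
#' @export
planted_effect <- function(mode = c("amplitude", "phase"),
                           frequency_index = c(3, 5), rank = c(1, 2),
                           effect_size = 2,
                           carrier_frequencies = 2^seq(1.5, 6.5, by = 1)) {
  data.frame(mode = mode,
             frequency = carrier_frequencies[frequency_index],
             rank = rank, effect_size = effect_size)
}

subject_manifest <- function(config) {
  ids <- c(sprintf("pat%02d", seq_len(config$n_patients)),
           sprintf("con%02d", seq_len(config$n_controls)),
           sprintf("ref%03d", seq_len(config$n_reference)))
  data.frame(subject_id = ids,
             group = rep(c("patient", "control", "reference"),
                         c(config$n_patients, config$n_controls,
                           config$n_reference)),
             edss_like = NA_real_, msfc_like = NA_real_,
             sampling_rate = config$sampling_rate,
             stringsAsFactors = FALSE)
}

freq_label <- function(f) sprintf("f%.10g", f)

# Stationary correlated Ornstein-Uhlenbeck processes: n x T, unit marginal
# variance, cross-correlation L %*% t(L), AR(1) time constant tau seconds.
ou_processes <- function(n, T, dt, tau, L) {
  a <- exp(-dt / tau)
  E <- L %*% matrix(rnorm(n * T), n, T)
  z <- matrix(0, n, T)
  innov_sd <- sqrt(1 - a^2)
  init <- as.numeric(L %*% rnorm(n))  # stationary, correlated start
  for (r in seq_len(n)) {
    z[r, ] <- stats::filter(E[r, ] * innov_sd, a, method = "recursive",
                            init = init[r])
  }
  z
}

#' Generate a synthetic time-series cohort
#'
#' Each subject's recording is a sum over carrier frequencies of
#' amplitude-modulated sinusoids with stochastic log-normal envelopes
#' (Gaussian copula on log-envelopes imposes the envelope correlation) and
#' slow Ornstein-Uhlenbeck phase jitter (correlated jitter plus a static lag
#' imposes phase coupling), plus white sensor noise. Patient-group coupling
#' matrices may be modulated via `config$planted_effect` with a
#' `loading` column of per-connection deltas (see Details).
#'
#' @details For the time-series path a planted amplitude effect adds
#' `effect_size * delta` to the patient envelope-correlation matrix on the
#' listed connections (`planted_effect$loading` as a list column of
#' connection-indexed vectors is supported); rank-style effects are the
#' domain of [simulate_profile_cohort()].
#'
#' @param config A [sim_config()].
#' @return A `"coupling_cohort"` (type `"timeseries"`): `manifest`,
#'   `recordings` (list of sources x samples matrices), `ground_truth`,
#'   `config`.
#' @export
simulate_timeseries_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sources
  T <- round(config$duration * config$sampling_rate)
  dt <- 1 / config$sampling_rate
  manifest <- subject_manifest(config)
  chol_psd <- function(R) {
    e <- eigen(R, symmetric = TRUE)
    v <- pmax(e$values, 1e-10)
    e$vectors %*% diag(sqrt(v), length(v))
  }
  L_env <- lapply(config$envelope_correlation, chol_psd)
  L_phs <- lapply(config$phase_coupling, chol_psd)
  # static phase offsets realising the requested pairwise lags (least squares
  # on the potential psi: psi_i - psi_j ~ lag_ij over flagged pairs)
  psi <- lapply(config$phase_lag, function(Lg) {
    idx <- which(abs(Lg) > 0 & upper.tri(Lg), arr.ind = TRUE)
    psi <- rep(0, n)
    if (nrow(idx) > 0) {
      A <- matrix(0, nrow(idx), n)
      b <- numeric(nrow(idx))
      for (r in seq_len(nrow(idx))) {
        A[r, idx[r, 1]] <- 1
        A[r, idx[r, 2]] <- -1
        b[r] <- Lg[idx[r, 1], idx[r, 2]]
      }
      psi <- as.numeric(solve(crossprod(A) + 1e-8 * diag(n),
                              crossprod(A, b)))
    }
    psi
  })
  tgrid <- (seq_len(T) - 1) * dt
  recordings <- vector("list", nrow(manifest))
  names(recordings) <- manifest$subject_id
  for (s in seq_len(nrow(manifest))) {
    x <- matrix(0, n, T)
    for (k in seq_along(config$carrier_frequencies)) {
      f <- config$carrier_frequencies[k]
      tau_env <- 5 / f
      tau_phs <- 2 / f
      logA <- config$envelope_log_sd *
        ou_processes(n, T, dt, tau_env, L_env[[k]])
      theta <- config$phase_jitter_sd *
        ou_processes(n, T, dt, tau_phs, L_phs[[k]])
      phase <- 2 * pi * f * matrix(tgrid, n, T, byrow = TRUE) + theta +
        psi[[k]]
      x <- x + exp(logA) * cos(phase)
    }
    x <- x + config$noise_sd * matrix(rnorm(n * T), n, T)
    recordings[[s]] <- x
  }
  structure(list(manifest = manifest, recordings = recordings,
                 ground_truth = config$planted_effect, config = config),
            type = "timeseries", class = "coupling_cohort")
}

#' Apply instantaneous linear mixing (volume-conduction surrogate)
#'
#' Replaces each time sample by `mixing %*% sample`. Purely real, zero-lag
#' mixing is exactly what field spread does to source estimates; both
#' coupling metrics are built to reject it, and this operation exists to
#' verify that.
#'
#' @param cohort A time-series `"coupling_cohort"`.
#' @param mixing Square, full-rank real matrix (sources x sources).
#' @return The cohort with mixed recordings.
#' @export
apply_mixing <- function(cohort, mixing) {
  stopifnot(inherits(cohort, "coupling_cohort"))
  if (!identical(attr(cohort, "type"), "timeseries")) {
    stop("apply_mixing needs a time-series cohort")
  }
  n <- nrow(cohort$recordings[[1]])
  if (!is.matrix(mixing) || nrow(mixing) != n || ncol(mixing) != n) {
    stop("mixing matrix dimensions do not match the source count")
  }
  if (qr(mixing)$rank < n) stop("mixing matrix must be full rank")
  cohort$recordings <- lapply(cohort$recordings, function(x) mixing %*% x)
  cohort
}

#' Generate a synthetic coupling-profile cohort
#'
#' Fast path that skips spectral estimation: per (mode, frequency), profiles
#' are drawn as `mean profile + low-rank subject variation + isotropic
#' noise`. Reference and study subjects share the generative basis; patient
#' means are shifted by `effect_size` (in units of the generative
#' component-score SD) along the planted components only. Patient severity
#' scores are a noisy monotone function of each patient's realized shift
#' (SNR 1), with missingness mimicking incomplete clinical scoring
#' (one patient lacks the EDSS-like score, four the MSFC-like score).
#'
#' @param config A [sim_config()].
#' @return A `"coupling_cohort"` (type `"profile"`): `manifest`, `profiles`
#'   (nested list `profiles[[mode]][[frequency]]`, subjects x connections),
#'   `ground_truth` (planted components incl. loading vectors), `config`.
#' @export
simulate_profile_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sources
  nc <- n * (n - 1) / 2
  r <- config$n_generative
  tau <- config$score_sds
  manifest <- subject_manifest(config)
  n_all <- nrow(manifest)
  is_pat <- manifest$group == "patient"
  modes <- c("amplitude", "phase")
  profiles <- list()
  truth <- list()
  shift_realized <- rep(0, sum(is_pat))
  for (m in modes) {
    profiles[[m]] <- list()
    for (k in seq_along(config$carrier_frequencies)) {
      f <- config$carrier_frequencies[k]
      mu <- rnorm(nc)
      B <- qr.Q(qr(matrix(rnorm(nc * r), nc, r)))  # orthonormal loadings
      S <- matrix(rnorm(n_all * r), n_all, r) %*% diag(tau, r)
      pe <- config$planted_effect
      if (!is.null(pe)) {
        hit <- which(pe$mode == m & pe$frequency == f)
        for (h in hit) {
          j <- pe$rank[h]
          S[is_pat, j] <- S[is_pat, j] + pe$effect_size[h] * tau[j]
          shift_realized <- shift_realized +
            sign(pe$effect_size[h]) * S[is_pat, j] / tau[j]
          truth[[length(truth) + 1]] <- list(
            mode = m, frequency = f, rank = j,
            effect_size = pe$effect_size[h], loading = B[, j])
        }
      }
      E <- config$noise_sd * matrix(rnorm(n_all * nc), n_all, nc)
      P <- matrix(mu, n_all, nc, byrow = TRUE) + S %*% t(B) + E
      rownames(P) <- manifest$subject_id
      profiles[[m]][[freq_label(f)]] <- P
    }
  }
  # severity: noisy monotone function of the realized planted shift
  np <- sum(is_pat)
  if (any(shift_realized != 0)) {
    s0 <- shift_realized
    noise_scale <- stats::sd(s0)
    if (!is.finite(noise_scale) || noise_scale == 0) noise_scale <- 1
  } else {
    s0 <- rep(0, np)
    noise_scale <- 1
  }
  edss <- s0 + rnorm(np, sd = noise_scale)
  msfc <- s0 + rnorm(np, sd = noise_scale)
  edss[np] <- NA
  msfc[seq.int(np - 3, np)] <- NA
  manifest$edss_like[is_pat] <- edss
  manifest$msfc_like[is_pat] <- msfc
  structure(list(manifest = manifest, profiles = profiles,
                 ground_truth = truth, config = config),
            type = "profile", class = "coupling_cohort")
}

#' @export
print.coupling_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("<coupling_cohort> type=%s, %s\n", attr(x, "type"),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  if (identical(attr(x, "type"), "profile")) {
    cat(sprintf("  %d modes x %d frequencies, %d connections\n",
                length(x$profiles), length(x$profiles[[1]]),
                ncol(x$profiles[[1]][[1]])))
  } else {
    cat(sprintf("  recordings: %d sources x %d samples\n",
                nrow(x$recordings[[1]]), ncol(x$recordings[[1]])))
  }
  invisible(x)
}

#' Coupling profiles from a time-series cohort
#'
#' Runs the spectral and coupling stages: Morlet transform at each carrier
#' frequency, both coupling metrics, vectorization to coupling profiles.
#'
#' @param cohort A time-series `"coupling_cohort"`.
#' @param frequencies Analysis frequencies (default the cohort's carriers).
#' @param bandwidth Wavelet bandwidth in octaves.
#' @return A profile-type `"coupling_cohort"`.
#' @export
coupling_profiles <- function(cohort, frequencies = NULL, bandwidth = 0.5) {
  stopifnot(inherits(cohort, "coupling_cohort"))
  if (!identical(attr(cohort, "type"), "timeseries")) {
    stop("coupling_profiles needs a time-series cohort")
  }
  if (is.null(frequencies)) frequencies <- cohort$config$carrier_frequencies
  srate <- cohort$config$sampling_rate
  modes <- c("amplitude", "phase")
  profiles <- list(amplitude = list(), phase = list())
  for (f in frequencies) {
    fl <- freq_label(f)
    pa <- list()
    pp <- list()
    for (s in seq_along(cohort$recordings)) {
      frame <- morlet_transform(cohort$recordings[[s]], srate, f, bandwidth)
      pa[[s]] <- as.numeric(vectorize_profile(aec_orth(frame)))
      pp[[s]] <- as.numeric(vectorize_profile(wpli(frame)))
    }
    profiles$amplitude[[fl]] <- do.call(rbind, pa)
    profiles$phase[[fl]] <- do.call(rbind, pp)
    rownames(profiles$amplitude[[fl]]) <- cohort$manifest$subject_id
    rownames(profiles$phase[[fl]]) <- cohort$manifest$subject_id
  }
  out <- list(manifest = cohort$manifest, profiles = profiles,
              ground_truth = cohort$ground_truth, config = cohort$config)
  structure(out, type = "profile", class = "coupling_cohort")
}
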