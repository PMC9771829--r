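test_that("cohorts are a pure function of the configuration", {
  cfg <- small_ts_config(seed = 3, duration = 10)
  a <- simulate_timeseries_cohort(cfg)
  b <- simulate_timeseries_cohort(cfg)
  expect_identical(a$recordings, b$recordings)

  cfgp <- small_profile_config(seed = 3)
  p1 <- simulate_profile_cohort(cfgp)
  p2 <- simulate_profile_cohort(cfgp)
  expect_identical(p1$profiles, p2$profiles)
  expect_identical(p1$manifest, p2$manifest)
})

test_that("invalid configurations are rejected with diagnostics", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9  # infeasible triple
  expect_error(sim_config(n_sources = 3, envelope_correlation = R,
                          carrier_frequencies = 16),
               "positive semi-definite")
  expect_error(sim_config(n_sources = 2), "n_sources")
  expect_error(
    sim_config(planted_effect = data.frame(mode = "amplitude",
                                           frequency = 999, rank = 1,
                                           effect_size = 2)),
    "carrier frequency")
  expect_error(
    sim_config(planted_effect = data.frame(mode = "amplitude",
                                           frequency = 2^3.5, rank = 99,
                                           effect_size = 2)),
    "rank")
  expect_error(sim_config(duration = 1, carrier_frequencies = 2.8),
               "wavelet steps")
})

test_that("uncoupled sources give near-zero orthogonalized AEC", {
  cfg <- small_ts_config(seed = 8, n_sources = 5, duration = 40)
  co <- simulate_timeseries_cohort(cfg)
  fr <- morlet_transform(co$recordings[[1]], 250, 16)
  A <- aec_orth(fr)
  vals <- A[upper.tri(A)]
  expect_lt(abs(mean(vals)), 3 / sqrt(ncol(fr)))
})

test_that("imposed envelope correlation is recovered near its Monte-Carlo oracle", {
  # frozen oracle: mean orthogonalized AEC 0.2123 over 50 realizations of a
  # 0.6 log-envelope correlation at 16 Hz, 60 s
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.6
  cfg <- small_ts_config(seed = 21, duration = 60, envelope_correlation = R)
  co <- simulate_timeseries_cohort(cfg)
  fr <- morlet_transform(co$recordings[[1]], 250, 16)
  expect_lt(abs(aec_orth(fr)[1, 2] - 0.2123), 0.1)
})

test_that("phase-lagged coupling is visible to the wPLI, zero-lag is not", {
  lag <- matrix(0, 4, 4)
  lag[3, 4] <- lag[4, 3] <- pi / 4
  cfg <- small_ts_config(seed = 5, duration = 40, phase_lag = lag)
  co <- simulate_timeseries_cohort(cfg)
  fr <- morlet_transform(co$recordings[[1]], 250, 16)
  W <- wpli(fr)
  expect_gt(W[3, 4], 0.8)   # planted lag pi/4
  expect_lt(W[1, 2], 0.35)  # uncoupled pair: finite-sample floor only
})

test_that("mixing validates inputs and identity mixing is a no-op", {
  cfg <- small_ts_config(seed = 2, duration = 10)
  co <- simulate_timeseries_cohort(cfg)
  expect_identical(apply_mixing(co, diag(4))$recordings, co$recordings)
  expect_error(apply_mixing(co, diag(3)), "dimensions")
  expect_error(apply_mixing(co, matrix(1, 4, 4)), "full rank")
})

test_that("zero-lag mixing does not create spurious coupling", {
  # random orthogonal mixing of an uncoupled cohort: mixed-pair metrics stay
  # below the unmixed null's 97.5th percentile region
  null_a <- c()
  null_w <- c()
  mix_a <- c()
  mix_w <- c()
  set.seed(99)
  for (s in 1:8) {
    cfg <- small_ts_config(seed = 300 + s, n_sources = 6, duration = 30)
    co <- simulate_timeseries_cohort(cfg)
    Q <- qr.Q(qr(matrix(rnorm(36), 6)))
    com <- apply_mixing(co, Q)
    fr <- morlet_transform(co$recordings[[1]], 250, 16)
    frm <- morlet_transform(com$recordings[[1]], 250, 16)
    A <- aec_orth(fr); W <- wpli(fr)
    Am <- aec_orth(frm); Wm <- wpli(frm)
    # signed AEC: spurious coupling would appear as *positive* correlations
    null_a <- c(null_a, A[upper.tri(A)])
    null_w <- c(null_w, W[upper.tri(W)])
    mix_a <- c(mix_a, Am[upper.tri(Am)])
    mix_w <- c(mix_w, Wm[upper.tri(Wm)])
  }
  expect_lte(stats::quantile(mix_a, 0.95), stats::quantile(null_a, 0.975))
  expect_lte(stats::quantile(mix_w, 0.95), stats::quantile(null_w, 0.975))
})

test_that("null profile cohorts have Student-distributed feature contrasts", {
  cfg <- small_profile_config(seed = 9)
  co <- simulate_profile_cohort(cfg)
  P <- co$profiles$amplitude[[1]]
  grp <- co$manifest$group
  tstat <- apply(P, 2, function(v) {
    stats::t.test(v[grp == "patient"], v[grp == "control"],
                  var.equal = TRUE)$statistic
  })
  df <- sum(grp != "reference") - 2
  ks <- stats::ks.test(stats::pt(tstat, df), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted effect separates groups on the planted component", {
  # effect size 2 -> expected AUC = Phi(sqrt(2)) ~ 0.92 on the generative
  # component score; averaged over seeds to tame n = 17 + 17 noise
  aucs <- sapply(1:8, function(s) {
    pe <- data.frame(mode = "amplitude", frequency = 2^3.5, rank = 1,
                     effect_size = 2)
    co <- simulate_profile_cohort(sim_config(planted_effect = pe, seed = s))
    tr <- co$ground_truth[[1]]
    sc <- co$profiles$amplitude[[freq_label_test(tr$frequency)]] %*% tr$loading
    pat <- co$manifest$group == "patient"
    con <- co$manifest$group == "control"
    a <- mean(outer(sc[pat], sc[con], ">"))
    max(a, 1 - a)
  })
  expect_gt(mean(aucs), 0.9)
})

test_that("severity scores track the planted effect with realistic missingness", {
  co <- simulate_profile_cohort(sim_config(planted_effect = planted_effect(),
                                           seed = 4))
  man <- co$manifest
  expect_equal(sum(is.finite(man$edss_like)), 16)  # one patient unscored
  expect_equal(sum(is.finite(man$msfc_like)), 13)
  expect_true(all(is.na(man$edss_like[man$group != "patient"])))
  # both scores share the planted-shift component -> positively related
  ok <- is.finite(man$edss_like) & is.finite(man$msfc_like)
  expect_gt(stats::cor(man$edss_like[ok], man$msfc_like[ok]), 0)
})

test_that("planted components surface among the top classification scores", {
  hits <- sapply(1:3, function(s) {
    co <- simulate_profile_cohort(sim_config(planted_effect = planted_effect(),
                                             seed = 40 + s))
    fm <- build_feature_matrix(co)
    idx <- attr(fm, "feature_index")
    set.seed(40 + s)
    br <- run_feature_bagging(unclass(fm), attr(fm, "labels"),
                              n_draw = 5000)
    sc <- classification_scores(br)
    top5 <- order(sc, decreasing = TRUE)[1:5]
    planted_cols <- which(
      (idx$mode == "amplitude" & abs(idx$frequency - 2^3.5) < 1e-6 &
         idx$rank == 1) |
        (idx$mode == "phase" & abs(idx$frequency - 2^5.5) < 1e-6 &
           idx$rank == 2))
    all(planted_cols %in% top5)
  })
  expect_gte(sum(hits), 2)
})
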