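test_that("planted orthogonal loading patterns are recovered by the PCA basis", {
  set.seed(1)
  nc <- 120
  B <- qr.Q(qr(matrix(rnorm(nc * 5), nc, 5)))
  # orthonormal zero-mean subject scores: the planted patterns are exactly
  # the principal axes of the sample covariance
  S0 <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 5), 60))))[, 2:6]
  S <- S0 %*% diag(c(10, 8, 6, 4, 3)) * sqrt(59)
  X <- S %*% t(B) + 0.05 * matrix(rnorm(60 * nc), 60)
  basis <- fit_component_basis(X, k = 5)
  cosines <- abs(colSums(B * basis$vectors))
  expect_true(all(cosines > 0.99))
  expect_true(all(diff(basis$values) <= 1e-12))  # nonincreasing
})

test_that("eigenvalues partition the cross-subject variance", {
  set.seed(2)
  X <- matrix(rnorm(10 * 20), 10)
  total <- sum(apply(X, 2, stats::var))
  b5 <- fit_component_basis(X, k = 5)
  expect_lte(sum(b5$values), total + 1e-10)
  b_full <- fit_component_basis(X, k = 9)
  expect_equal(sum(b_full$values), total, tolerance = 1e-10)
})

test_that("duplicating every reference subject leaves eigenvectors unchanged", {
  set.seed(3)
  X <- matrix(rnorm(15 * 30), 15)
  b1 <- fit_component_basis(X, k = 5)
  b2 <- fit_component_basis(rbind(X, X), k = 5)
  agree <- abs(colSums(b1$vectors * b2$vectors))
  expect_equal(agree, rep(1, 5), tolerance = 1e-8)
})

test_that("rank deficiency reduces k with a warning", {
  set.seed(4)
  X <- matrix(rnorm(8 * 4), 8) %*% matrix(rnorm(4 * 30), 4)  # rank 4
  expect_warning(b <- fit_component_basis(X, k = 6), "rank")
  expect_equal(b$k, 4)
})

test_that("projection is linear and diagonalizes the reference cohort", {
  set.seed(5)
  X <- matrix(rnorm(40 * 60), 40)
  basis <- fit_component_basis(X, k = 10)
  sc <- project_profiles(X, basis)
  cv <- stats::cov(sc)
  expect_lt(max(abs(cv - diag(basis$values[1:10]))) / basis$values[1],
            1e-6)
  u <- matrix(rnorm(60), 1)
  v <- matrix(rnorm(60), 1)
  lhs <- project_profiles(2 * u + 3 * v, basis, center = FALSE)
  rhs <- 2 * project_profiles(u, basis, center = FALSE) +
    3 * project_profiles(v, basis, center = FALSE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(project_profiles(matrix(0, 1, 59), basis), "connection count")
})

test_that("the full study geometry yields 690 features per mode, 1380 total", {
  cfg <- sim_config(carrier_frequencies = as.numeric(frequency_grid()),
                    n_patients = 3, n_controls = 3, n_reference = 40,
                    n_sources = 10, seed = 6)
  co <- simulate_profile_cohort(cfg)
  fm <- build_feature_matrix(co, k = 30)
  idx <- attr(fm, "feature_index")
  expect_equal(ncol(fm), 1380)
  expect_equal(sum(idx$mode == "amplitude"), 690)
  expect_equal(sum(idx$mode == "phase"), 690)
  # the index is a bijection onto columns
  expect_equal(idx$column, seq_len(1380))
  expect_equal(nrow(unique(idx[, c("mode", "frequency", "rank")])), 1380)
})

test_that("sign alignment puts patients above controls and is idempotent", {
  cfg <- small_profile_config(seed = 7)
  fm <- build_feature_matrix(simulate_profile_cohort(cfg), k = 4)
  lab <- attr(fm, "labels")
  al <- align_component_signs(fm)
  pm <- colMeans(unclass(al)[lab == "patient", ])
  cm <- colMeans(unclass(al)[lab == "control", ])
  expect_true(all(pm >= cm))
  al2 <- align_component_signs(al)
  expect_equal(as.vector(unclass(al2)), as.vector(unclass(al)))
  expect_true(!any(attr(al2, "flipped")))
  # flipped columns have negated basis loadings
  idx <- attr(fm, "feature_index")
  ci <- which(attr(al, "flipped"))[1]
  if (!is.na(ci)) {
    key <- paste(idx$mode[ci], sprintf("f%.10g", idx$frequency[ci]),
                 sep = ".")
    expect_equal(attr(al, "bases")[[key]]$vectors[, idx$rank[ci]],
                 -attr(fm, "bases")[[key]]$vectors[, idx$rank[ci]])
  }
})

test_that("band averaging normalizes by the absolute 98th percentile", {
  cfg <- small_profile_config(seed = 8)
  fm <- build_feature_matrix(simulate_profile_cohort(cfg), k = 4)
  al <- align_component_signs(fm)
  idx <- attr(al, "feature_index")
  sig <- rep(FALSE, ncol(al))
  one <- which(idx$mode == "amplitude" & idx$frequency == 8 &
                 idx$rank == 2)
  sig[one] <- TRUE
  out <- band_average_components(al, sig)
  v <- attr(al, "bases")[["amplitude.f8"]]$vectors[, 2]
  expected <- v / stats::quantile(abs(v), 0.98, type = 7, names = FALSE)
  expect_equal(out$bands[["amplitude.alpha"]], expected)
  # only the top tail beyond the 98th percentile may exceed 1 in magnitude
  # (interpolated percentile: at most 2 of the 66 connections here)
  expect_lte(sum(abs(out$bands[["amplitude.alpha"]]) > 1), 2)
  # averaging a component with itself changes nothing
  sig2 <- sig
  two <- which(idx$mode == "amplitude" & idx$frequency == 8 & idx$rank == 3)
  out_pair <- band_average_components(al, sig | (idx$column %in% two))
  expect_length(out_pair$bands[["amplitude.alpha"]], length(expected))
  # split maps exist for the selected mode and are absolute-valued
  expect_true(all(out$split[["amplitude.low"]] >= 0))
  expect_true(any(grepl("phase", out$empty)))
})

test_that("band definitions match the canonical table", {
  b <- default_bands()
  expect_equal(b$band, c("delta", "theta", "alpha", "beta", "low gamma",
                         "high gamma"))
  expect_equal(b$lo, c(2.8, 4, 8, 16, 32, 64))
  expect_equal(b$hi, c(3.4, 6.7, 13, 27, 54, 128))
})
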