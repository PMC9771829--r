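test_that("Mahalanobis distances match hand-computed values", {
  # controls constructed with sample mean (0,0) and sample covariance
  # diag(2, 1); a patient at f - mu = (2, 1) has D = 4/2 + 1/1 = 3
  controls <- rbind(c(2, 0), c(-2, 0), c(0, sqrt(2)), c(0, -sqrt(2)),
                    c(0, 0))
  patients <- rbind(c(2, 1), c(1, -1), c(-1, 2))
  x <- rbind(patients, controls)
  lab <- rep(c("patient", "control"), c(3, 5))
  # the 3-member patient group is singular under leave-one-out, so its own
  # distances are shrunk (with a warning); distances *to the controls* use
  # the exact unshrunk control covariance
  cs <- suppressWarnings(mahalanobis_confidence(x, lab, shrinkage = 0))
  expect_equal(cs$d_control[1], 3)
  # identity covariance: controls with sample covariance I, patient at (1,1)
  a <- sqrt(3 / 2)
  controls2 <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  x2 <- rbind(c(1, 1), c(0, 2), c(2, 0), controls2)
  lab2 <- rep(c("patient", "control"), c(3, 4))
  cs2 <- suppressWarnings(mahalanobis_confidence(x2, lab2, shrinkage = 0))
  expect_equal(cs2$d_control[1], 2)
})

test_that("a subject at its leave-one-out group mean has distance zero", {
  # patient 3 sits at the mean of patients 1 and 2
  patients <- rbind(c(1, 2), c(3, 0), c(2, 1))
  set.seed(1)
  controls <- matrix(rnorm(8), 4) + 5
  x <- rbind(patients, controls)
  lab <- rep(c("patient", "control"), c(3, 4))
  cs <- suppressWarnings(mahalanobis_confidence(x, lab, shrinkage = 0.2))
  expect_equal(cs$d_patient[3], 0)
})

test_that("swapping group labels negates every confidence", {
  set.seed(2)
  x <- matrix(rnorm(14 * 3), 14)
  lab <- rep(c("patient", "control"), each = 7)
  swapped <- ifelse(lab == "patient", "control", "patient")
  c1 <- mahalanobis_confidence(x, lab, shrinkage = 0.1)
  c2 <- mahalanobis_confidence(x, swapped, shrinkage = 0.1)
  expect_equal(c1$confidence, -c2$confidence, tolerance = 1e-10)
})

test_that("singular covariances trigger documented shrinkage", {
  set.seed(3)
  x <- matrix(rnorm(10 * 8), 10)  # dimension 8 ~ group size 5
  lab <- rep(c("patient", "control"), each = 5)
  # positive diagonal loading keeps the covariance invertible silently...
  cs <- mahalanobis_confidence(x, lab, shrinkage = 0.1)
  expect_true(all(is.finite(cs$confidence)))
  expect_true(all(cs$d_patient >= 0 & cs$d_control >= 0))
  # ...while starting from zero forces a documented shrinkage bump
  expect_warning(mahalanobis_confidence(x, lab, shrinkage = 0), "shrinkage")
})

test_that("severity correlation is exact for self- and null relationships", {
  set.seed(4)
  conf <- rnorm(16)
  res <- severity_correlation(conf, data.frame(edss = conf))
  expect_equal(res$r, 1)
  # missing scores are dropped pairwise
  s2 <- conf + rnorm(16, sd = 1)
  s2[c(2, 5)] <- NA
  res2 <- severity_correlation(conf, data.frame(edss = s2))
  expect_equal(res2$n, 14)
  expect_equal(res2$q, stats::p.adjust(res2$p, "BH"))
  expect_warning(severity_correlation(conf, data.frame(flat = rep(1, 16))),
                 "zero variance")
})

test_that("a monotone severity ground truth is detected with power", {
  detected <- sapply(1:10, function(s) {
    set.seed(700 + s)
    conf <- rnorm(16)
    sev <- conf + rnorm(16, sd = stats::sd(conf))  # SNR 1
    severity_correlation(conf, data.frame(edss = sev))$p < 0.05
  })
  expect_gte(mean(detected), 0.5)
})

test_that("Gaussian accuracy reproduces closed-form values", {
  # symmetric zero-mean groups -> everything 0.5
  d <- c(1, -1, 2, -2, 0.5, -0.5)
  lab <- rep(c("patient", "control"), 3)
  g0 <- gaussian_accuracy(c(1, -1, 2, -2), rep(c("patient", "patient",
                                                 "control", "control")))
  expect_equal(g0$sensitivity, 0.5)
  expect_equal(g0$specificity, 0.5)
  expect_equal(g0$accuracy, 0.5)
  # unit-separated unit-variance groups -> Phi(1) everywhere
  set.seed(5)
  zp <- as.numeric(scale(rnorm(17))) + 1
  zc <- as.numeric(scale(rnorm(17))) - 1
  g1 <- gaussian_accuracy(c(zp, zc), rep(c("patient", "control"), each = 17))
  expect_equal(g1$sensitivity, stats::pnorm(1), tolerance = 1e-12)
  expect_equal(g1$specificity, stats::pnorm(1), tolerance = 1e-12)
  expect_equal(g1$accuracy, stats::pnorm(1), tolerance = 1e-12)
  # accuracy identity holds exactly for unbalanced groups
  set.seed(6)
  dd <- rnorm(13)
  ll <- rep(c("patient", "control"), c(8, 5))
  g2 <- gaussian_accuracy(dd, ll)
  expect_equal(g2$accuracy,
               (8 * g2$sensitivity + 5 * g2$specificity) / 13)
  # separation limit
  g3 <- gaussian_accuracy(c(5.1, 4.9, 5, -5.1, -4.9, -5),
                          rep(c("patient", "control"), each = 3))
  expect_gt(g3$accuracy, 0.999)
  expect_warning(gaussian_accuracy(c(1, 1, -1, -1.5),
                                   rep(c("patient", "control"), each = 2)),
                 "zero-SD")
})

test_that("nested LOO is deterministic and finds a strong planted effect", {
  set.seed(7)
  x <- matrix(rnorm(12 * 30), 12)
  lab <- rep(c("patient", "control"), each = 6)
  x[, 5] <- x[, 5] + ifelse(lab == "patient", 3, -3)
  a1 <- nested_loo_accuracy(x, lab, bag_size = 5, n_draw = 300, n_perm = 10,
                            seed = 3)
  a2 <- nested_loo_accuracy(x, lab, bag_size = 5, n_draw = 300, n_perm = 10,
                            seed = 3)
  expect_identical(a1$distances, a2$distances)
  expect_gt(a1$accuracy, 0.8)
  # feature-subset restriction drops the planted feature -> chance-level
  a3 <- nested_loo_accuracy(x, lab, bag_size = 5, n_draw = 300, n_perm = 10,
                            seed = 3, subset = 10:30)
  expect_lt(a3$accuracy, a1$accuracy)
})

test_that("nested selection never inflates null accuracy above the leaky estimate", {
  diffs <- sapply(1:20, function(s) {
    set.seed(800 + s)
    x <- matrix(rnorm(16 * 60), 16)
    lab <- rep(c("patient", "control"), each = 8)
    nested <- nested_loo_accuracy(x, lab, bag_size = 6, n_draw = 400,
                                  n_perm = 12, seed = 800 + s)$accuracy
    # leaky alternative: select on all subjects, then LOO the classifier only
    br <- run_feature_bagging(x, lab, bag_size = 6, n_draw = 400)
    cols <- order(classification_scores(br), decreasing = TRUE)[1:6]
    leaky <- run_feature_bagging(x[, cols, drop = FALSE], lab, bag_size = 6,
                                 n_draw = 1)$accuracy
    leaky - nested
  })
  # sign test: the leaky estimate is systematically the larger one
  n_pos <- sum(diffs > 0)
  p_sign <- stats::pbinom(n_pos - 1, 20, 0.5, lower.tail = FALSE)
  expect_lt(p_sign, 0.05)
})
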