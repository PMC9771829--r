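test_that("closed-form LOO accuracies equal explicit refit on every bag", {
  set.seed(1)
  n <- 16
  x <- matrix(rnorm(n * 12), n)
  labels <- rep(c("patient", "control"), each = 8)
  y <- ifelse(labels == "patient", 1, -1)
  xs <- scale(x, scale = apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))))
  set.seed(2)
  br <- run_feature_bagging(x, labels, bag_size = 4, n_draw = 25)
  oracle <- apply(br$bags, 1, function(cols) {
    mean(sapply(seq_len(n), function(i) {
      Z <- cbind(1, xs[-i, cols])
      beta <- solve(crossprod(Z) + diag(ncol(Z)), crossprod(Z, y[-i]))
      (drop(c(1, xs[i, cols]) %*% beta) >= 0) == (y[i] > 0)
    }))
  })
  expect_equal(br$accuracy, oracle)
})

test_that("pure-noise features classify at chance, like permuted labels", {
  set.seed(3)
  x <- matrix(rnorm(20 * 40), 20)
  labels <- rep(c("patient", "control"), each = 10)
  br <- run_feature_bagging(x, labels, n_draw = 4000, bag_size = 5)
  # the observed labeling is just one draw from the relabeling distribution
  perm_means <- replicate(12, mean(run_feature_bagging(
    x, sample(labels), n_draw = 2000, bag_size = 5)$accuracy))
  expect_lt(abs(mean(br$accuracy) - mean(perm_means)),
            3.5 * stats::sd(perm_means))
  # cross-validated accuracy on noise sits at chance up to the usual small
  # anti-learning deficit
  expect_lt(abs(mean(br$accuracy) - 0.5), 0.1)
})

test_that("bags containing a perfectly separating feature reach accuracy 1", {
  set.seed(4)
  x <- matrix(rnorm(20 * 30), 20)
  labels <- rep(c("patient", "control"), each = 10)
  x[, 9] <- ifelse(labels == "patient", 4, -4) + rnorm(20, sd = 0.1)
  br <- run_feature_bagging(x, labels, n_draw = 500, bag_size = 5)
  has <- apply(br$bags == 9, 1, any)
  expect_true(all(br$accuracy[has] == 1))
})

test_that("n_features == bag_size degenerates to one repeated bag", {
  set.seed(5)
  x <- matrix(rnorm(14 * 6), 14)
  labels <- rep(c("patient", "control"), each = 7)
  br <- run_feature_bagging(x, labels, bag_size = 6, n_draw = 200)
  expect_equal(length(unique(br$accuracy)), 1)
  expect_true(all(apply(br$bags, 1, sort) == 1:6))
})

test_that("classification scores sum to the bag size and honor the threshold", {
  set.seed(6)
  x <- matrix(rnorm(20 * 50), 20)
  labels <- rep(c("patient", "control"), each = 10)
  br <- run_feature_bagging(x, labels, n_draw = 2000, bag_size = 10)
  sc <- classification_scores(br, 75)
  expect_equal(sum(sc), 10)
  expect_gte(attr(sc, "n_selected"), 0.25 * 2000)  # inclusive ties
  # percentile 0: every bag selected, scores equal membership fractions
  sc0 <- classification_scores(br, 0)
  memb <- tabulate(br$bags, nbins = 50) / 2000
  expect_equal(as.numeric(sc0), memb)
  expect_equal(attr(sc0, "n_selected"), 2000)
})

test_that("an informative feature earns the top score across seeds", {
  top <- sapply(1:20, function(s) {
    set.seed(600 + s)
    x <- matrix(rnorm(20 * 40), 20)
    labels <- rep(c("patient", "control"), each = 10)
    x[, 13] <- x[, 13] + ifelse(labels == "patient", 2.5, -2.5)
    br <- run_feature_bagging(x, labels, n_draw = 1500, bag_size = 5)
    which.max(classification_scores(br))
  })
  expect_gte(mean(top == 13), 0.95)
})

test_that("permutation p-values use the add-one convention", {
  nul <- matrix(seq(0, 0.5, length.out = 1000), 10)
  res <- score_significance(c(0.9, 0), nul, q = 0.05)
  expect_equal(res$p[1], 1 / 1001)  # above every null value
  expect_equal(res$p[2], 1)         # below-or-equal to all (ties count)
  expect_true(all(res$q >= res$p))
})

test_that("global significance counts ties and extremes by definition", {
  expect_equal(global_significance(0, rep(0, 100)), 1)
  expect_equal(global_significance(5, rep(0, 199)), 1 / 200)
  # observed equal to the permutation maximum: >= rule counts the tie
  expect_equal(global_significance(3, c(rep(0, 98), 3)), 2 / 100)
})

test_that("q = 1 flags every feature", {
  set.seed(7)
  res <- score_significance(runif(20), matrix(runif(200), 10), q = 1)
  expect_true(all(res$significant))
})

test_that("the fit is deterministic given a seed and finds planted structure", {
  set.seed(8)
  x <- matrix(rnorm(20 * 30), 20)
  labels <- rep(c("patient", "control"), each = 10)
  x[, 4] <- x[, 4] + ifelse(labels == "patient", 2.2, -2.2)
  f1 <- fcbag(x, labels, n_draw = 1500, n_perm = 40, seed = 99)
  f2 <- fcbag(x, labels, n_draw = 1500, n_perm = 40, seed = 99)
  expect_identical(f1$selection, f2$selection)
  expect_identical(f1$perm_counts, f2$perm_counts)
  expect_equal(which.max(f1$selection$score), 4)
  expect_true(f1$selection$significant[4])
  expect_lt(f1$global_p, 0.05)
  # methods run
  expect_output(print(f1), "significant")
  expect_equal(length(coef(f1)), 30)
  s <- summary(f1)
  expect_equal(s$n_features, 30)
  expect_output(print(s), "Top features")
  pr <- predict(f1)
  expect_true(all(pr$distance[labels == "patient"] > 0))
})

test_that("feature-matrix inputs carry labels and index into the fit", {
  co <- simulate_profile_cohort(small_profile_config(seed = 10))
  fm <- build_feature_matrix(co, k = 4)
  fit <- fcbag(fm, n_draw = 300, n_perm = 5, bag_size = 5, seed = 1)
  expect_true(all(c("mode", "frequency", "rank") %in% names(fit$selection)))
  expect_equal(nrow(fit$selection), ncol(fm))
})

test_that("alternative classifier families order a separable problem correctly", {
  set.seed(11)
  x <- matrix(rnorm(20 * 12), 20)
  labels <- rep(c("patient", "control"), each = 10)
  x[, 3] <- x[, 3] + ifelse(labels == "patient", 3, -3)
  for (cl in c("centroid", "stump", "svm")) {
    br <- run_feature_bagging(x, labels, bag_size = 3, n_draw = 150,
                              classifier = cl)
    has <- apply(br$bags == 3, 1, any)
    expect_gt(mean(br$accuracy[has]) - mean(br$accuracy[!has]), 0.2)
  }
  # k-fold cross-validation path
  set.seed(12)
  br5 <- run_feature_bagging(x, labels, bag_size = 3, n_draw = 300, cv = 5)
  has <- apply(br5$bags == 3, 1, any)
  expect_gt(mean(br5$accuracy[has]), 0.85)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(12), 4)
  expect_error(run_feature_bagging(x, c("patient", "patient", "control",
                                        "control")), ">= 3 subjects")
  expect_error(run_feature_bagging(matrix(rnorm(60), 6),
                                   rep(c("patient", "control"), 3),
                                   bag_size = 99), "bag_size")
  set.seed(13)
  br <- run_feature_bagging(matrix(rnorm(120), 6),
                            rep(c("patient", "control"), 3), bag_size = 4,
                            n_draw = 120)
  expect_error(classification_scores(br, 100), "percentile")
})
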