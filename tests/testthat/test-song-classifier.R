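test_that("the stratified split preserves class counts and reproduces", {
  data <- tibble::tibble(label = rep(c(1L, 0L), c(60, 40)), f = rnorm(100))
  sp <- split_train_validation(data, fraction = 0.75, seed = 2)
  expect_equal(nrow(sp$train), 75)
  expect_equal(sum(sp$train$label == 1), 45)
  expect_equal(sum(sp$train$label == 0), 30)
  expect_equal(nrow(dplyr::bind_rows(sp)), 100) # disjoint + exhaustive
  sp2 <- split_train_validation(data, fraction = 0.75, seed = 2)
  expect_identical(sp$train, sp2$train)
  expect_warning(split_train_validation(data, fraction = 1, seed = 1),
                 regexp = "empty")
  expect_error(split_train_validation(dplyr::filter(data, label == 1)),
               class = "songclock_invalid_parameter")
})

test_that("Cohen's kappa matches the agreement formula", {
  expect_equal(cohens_kappa(matrix(c(50, 0, 0, 50), 2)), 1)
  # hand oracle: p_o = 0.85, p_e = 0.5 -> kappa = 0.35 / 0.5
  m <- matrix(c(40, 5, 10, 45), 2)
  po <- (40 + 45) / 100
  pe <- (50 * 45 + 50 * 55) / 100^2
  expect_equal(cohens_kappa(m), (po - pe) / (1 - pe))
  expect_equal(cohens_kappa(m), 0.70)
  expect_equal(cohens_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
  # degenerate marginals: defined as 1 only under perfect agreement
  expect_equal(cohens_kappa(matrix(c(100, 0, 0, 0), 2)), 1)
  # one-sided predictions: observed equals expected agreement, kappa 0
  expect_equal(cohens_kappa(matrix(c(60, 40, 0, 0), 2)), 0)
})

test_that("accuracy CI equals the beta-quantile Clopper-Pearson bounds", {
  ci <- accuracy_ci(10, n = 10)
  expect_equal(unname(ci["lo"]), qbeta(0.025, 10, 1)) # ~0.6915
  expect_equal(unname(ci["hi"]), 1)
  ci2 <- accuracy_ci(197, n = 200)
  expect_equal(unname(ci2["lo"]), qbeta(0.025, 197, 4))
  expect_equal(unname(ci2["hi"]), qbeta(0.975, 198, 3))
  expect_true(all(ci2 >= 0 & ci2 <= 1))
  expect_error(accuracy_ci(0, n = 0), class = "songclock_invalid_parameter")
})

test_that("cross-validation separates well-separated Gaussian clouds", {
  data <- gaussian_feature_data(n = 400, sep = 6, seed = 1)
  cv <- cross_validate(data, k = 10, n_trees = 200, seed = 1)
  expect_gte(cv$accuracy, 0.99) # Bayes error of the generator is ~0
  expect_equal(cv$accuracy, sum(diag(cv$confusion)) / sum(cv$confusion))
  expect_equal(nrow(cv$per_fold), 10)
  expect_equal(sum(cv$per_fold$n), 400)
})

test_that("shuffled labels score at chance-level kappa", {
  data <- gaussian_feature_data(n = 400, sep = 6, seed = 2)
  data$label <- withr::with_seed(99, sample(data$label))
  cv <- cross_validate(data, k = 10, n_trees = 200, seed = 1)
  expect_lt(abs(cv$kappa), 0.15) # permutation-null regime
})

test_that("fold-count preconditions are enforced", {
  data <- gaussian_feature_data(n = 40, seed = 3)
  expect_error(cross_validate(data, k = 1), class = "songclock_invalid_parameter")
  expect_error(cross_validate(data, k = 25), class = "songclock_invalid_parameter")
})

test_that("fit and predict are deterministic and validate features", {
  data <- gaussian_feature_data(n = 100, sep = 8, seed = 5)
  m <- fit_song_classifier(data, seed = 7)
  p <- predict(m, data)
  expect_equal(p, data$label) # separable training points recover own labels
  expect_identical(p, predict(fit_song_classifier(data, seed = 7), data))
  expect_error(predict(m, data[, c("label", "f1", "f2")]), regexp = "f3")
})

test_that("alternative learners handle separable data", {
  data <- gaussian_feature_data(n = 200, sep = 8, seed = 6)
  for (lrn in c("cart", "knn")) {
    cv <- cross_validate(data, k = 5, learner = lrn, seed = 2)
    expect_gte(cv$accuracy, 0.95)
  }
})

test_that("the forest agrees with an independent random-forest fit", {
  skip_if_not_installed("randomForest")
  data <- gaussian_feature_data(n = 200, sep = 6, seed = 7)
  sp <- split_train_validation(data, seed = 3)
  ours <- predict(fit_song_classifier(sp$train, seed = 1), sp$validation)
  rf <- randomForest::randomForest(
    x = as.data.frame(sp$train[c("f1", "f2", "f3")]),
    y = factor(sp$train$label), ntree = 500)
  theirs <- as.integer(as.character(predict(
    rf, as.data.frame(sp$validation[c("f1", "f2", "f3")]))))
  expect_gt(mean(ours == theirs), 0.97) # two forests, same signal
})
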