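test_that("perfectly separable features give holdout accuracy 1", {
  d <- separable_training_set(n = 120, seed = 2)
  m <- fit_count_model(d[, feature_names()], d$count, seed = 2)
  expect_identical(m$holdout_accuracy, 1)
  # an object identical to a training exemplar gets that exemplar's label
  expect_identical(predict(m, d[5, feature_names()]), d$count[5])
})

test_that("fitting and prediction are deterministic given the seed", {
  d <- shared_training_set()
  m1 <- fit_count_model(d[, feature_names()], d$count, seed = 31)
  m2 <- fit_count_model(d[, feature_names()], d$count, seed = 31)
  p1 <- predict(m1, d[, feature_names()])
  p2 <- predict(m2, d[, feature_names()])
  expect_identical(p1, p2)
  expect_identical(m1$holdout_accuracy, m2$holdout_accuracy)
  expect_identical(m1$oob_error, m2$oob_error)
})

test_that("fitting does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  d <- separable_training_set(n = 60, seed = 3)
  set.seed(99)
  invisible(fit_count_model(d[, feature_names()], d$count, seed = 8))
  expect_identical(.Random.seed, before)
})

test_that("tied votes resolve to the smaller count", {
  votes <- rbind(c(10, 10, 0), c(0, 7, 7), c(1, 2, 3))
  cls <- emergekit:::vote_decision(votes, c(2L, 3L, 5L))
  expect_identical(cls, c(2L, 3L, 5L))
})

test_that("batch prediction is order-invariant", {
  d <- shared_training_set()
  m <- fit_count_model(d[, feature_names()], d$count, seed = 5)
  set.seed(1); perm <- sample(nrow(d))
  p <- predict(m, d[, feature_names()])
  expect_identical(p[perm], predict(m, d[perm, feature_names()]))
})

test_that("invalid training inputs are rejected", {
  d <- separable_training_set(n = 40, seed = 4)
  f <- d[, feature_names()]
  expect_error(fit_count_model(f, rep(3L, nrow(f))), "single class")
  expect_error(fit_count_model(f[1:5, ], d$count[1:5]), "at least 10")
  expect_error(fit_count_model(f, d$count + 4L), "1..8")
  expect_error(fit_count_model(f, d$count, train_fraction = 1), "between")
  expect_error(predict(fit_count_model(f, d$count, seed = 1),
                       f[, -1]), "missing feature")
})

test_that("importance ranks the only informative feature first", {
  set.seed(6)
  n <- 200
  k <- sample(1:4, n, replace = TRUE)
  d <- data.frame(signal = k * 10 + rnorm(n, 0, 1),
                  junk1 = rnorm(n), junk2 = runif(n))
  m <- fit_count_model(d, k, seed = 6)
  imp <- variable_importance(m)
  expect_identical(names(which.max(imp)), "signal")
  expect_lt(max(imp[c("junk1", "junk2")]), 0.02)
})

test_that("destroying the labels flattens importance to near zero", {
  d <- shared_training_set()
  set.seed(17)
  y_perm <- sample(d$count)
  m <- fit_count_model(d[, feature_names()], y_perm, seed = 17)
  imp <- variable_importance(m)
  expect_true(all(imp >= 0))
  expect_lt(max(imp), 0.05)
})

test_that("confusion matrix counts actual x predicted and the correct rate", {
  d <- separable_training_set(n = 120, seed = 9)
  m <- fit_count_model(d[, feature_names()], d$count, seed = 9)
  cm <- confusion_matrix(m, d[, feature_names()], d$count)
  expect_identical(cm$correct_rate, 1)
  expect_true(all(cm$table[upper.tri(cm$table)] == 0))
  expect_true(all(cm$table[lower.tri(cm$table)] == 0))
  expect_equal(unname(rowSums(cm$table)),
               as.integer(table(factor(d$count, sort(unique(d$count))))))
  expect_error(confusion_matrix(m, d[0, feature_names()], integer()),
               "no labelled objects")
})

test_that("a constant predictor on balanced classes scores 1/K", {
  # features carry no signal and heavily favour one class via imbalance
  set.seed(44)
  train <- data.frame(x = rnorm(60), y = rnorm(60))
  lab <- c(rep(1L, 52), rep(2L, 8))
  m <- fit_count_model(train, lab, seed = 44)
  eval_feats <- data.frame(x = rnorm(40), y = rnorm(40))
  eval_lab <- rep(1:4, each = 10)
  cm <- confusion_matrix(m, eval_feats, eval_lab)
  if (all(predict(m, eval_feats) == 1L))    # majority class everywhere
    expect_equal(cm$correct_rate, 0.25)
  expect_equal(sum(cm$table), 40)
})

test_that("models survive a save/load round trip with identical predictions", {
  d <- shared_training_set()
  m <- fit_count_model(d[, feature_names()], d$count, seed = 12)
  path <- tempfile(fileext = ".rds")
  save_count_model(m, path)
  m2 <- read_count_model(path)
  expect_identical(predict(m, d[, feature_names()]),
                   predict(m2, d[, feature_names()]))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(sidecar$n_trees, 100L)
  expect_identical(unlist(sidecar$feature_order), feature_names())
  unlink(c(path, paste0(path, ".json")))
})

test_that("out-of-bag error is stable between 100 and 300 trees", {
  d <- shared_training_set()
  m100 <- fit_count_model(d[, feature_names()], d$count, n_trees = 100,
                          seed = 3)
  m300 <- fit_count_model(d[, feature_names()], d$count, n_trees = 300,
                          seed = 3)
  expect_lt(abs(m100$oob_error - m300$oob_error), 0.02)
})

test_that("training CSV round trip preserves the schema", {
  d <- separable_training_set(n = 50, seed = 14)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(d, path, row.names = FALSE)
  d2 <- read_training_csv(path)
  expect_identical(colnames(d2), c(feature_names(), "count"))
  expect_equal(d2$count, d$count)
  unlink(path)
})
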