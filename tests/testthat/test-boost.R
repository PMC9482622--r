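test_that("a perfectly separating feature is learned by a depth-1 ensemble", {
  set.seed(1)
  x <- cbind(sep = c(rnorm(50, -2), rnorm(50, 2)), noise = rnorm(100))
  y <- rep(0:1, each = 50)
  fit <- gbt(x, y, max_depth = 1, nrounds = 5, lambda = 0, seed = 1)
  expect_equal(auc_roc(predict(fit, x), y), 1.0)
  expect_lte(length(fit$trees), 5)
})

test_that("noiseless XOR requires and is solved at depth 2", {
  set.seed(2)
  x <- cbind(a = rbinom(400, 1, 0.5), b = rbinom(400, 1, 0.5))
  y <- as.integer(xor(x[, "a"], x[, "b"]))
  fit1 <- gbt(x, y, max_depth = 1, nrounds = 30, seed = 1)
  expect_lt(auc_roc(predict(fit1, x), y), 0.6) # stumps cannot express XOR
  fit2 <- gbt(x, y, max_depth = 2, nrounds = 30, seed = 1)
  expect_equal(auc_roc(predict(fit2, x), y), 1.0)
})

test_that("sparsity-aware splits route missing values toward the gain side", {
  # the informative feature is missing for most positives; the split must
  # learn to send the missing block toward the positive leaf
  set.seed(3)
  x <- cbind(f = c(runif(60), runif(5, 2, 3), rep(NA, 55)),
             g = rnorm(120))
  y <- rep(0:1, each = 60)
  fit <- gbt(x, y, max_depth = 1, nrounds = 5, seed = 1)
  pred <- predict(fit, x, type = "prob")
  expect_equal(mean((pred > 0.5) == (y == 1)), 1.0)
  tr <- fit$trees[[1]]
  root_f <- tr$feature[1]
  expect_equal(root_f, 0L) # splits on the informative feature
  # missing values routed right, where the positive leaf sits
  expect_equal(tr$default_left[1], 0L)
  expect_gt(tr$value[tr$right[1] + 1], tr$value[tr$left[1] + 1])
})

test_that("one-round leaf values obey the closed form -eta * G / (H + lambda)", {
  x <- cbind(f = c(-1, -1, 1, 1))
  y <- c(0, 0, 1, 1)
  fit <- gbt(x, y, eta = 0.3, max_depth = 1, nrounds = 1, lambda = 0,
             min_child_weight = 0)
  p0 <- mean(y)
  g <- p0 - y
  h <- rep(p0 * (1 - p0), 4)
  tr <- fit$trees[[1]]
  leaves <- sort(tr$value[tr$feature == -1L])
  expected <- sort(c(-0.3 * sum(g[1:2]) / sum(h[1:2]),
                     -0.3 * sum(g[3:4]) / sum(h[3:4])))
  expect_equal(leaves, expected, tolerance = 1e-12)
  # cover equals the hessian mass in each leaf
  expect_equal(sort(tr$cover[tr$feature == -1L]),
               rep(sum(h[1:2]), 2), tolerance = 1e-12)
})

test_that("infinite regularization shrinks every prediction to the base score", {
  set.seed(4)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- as.integer(x[, 1] > 0)
  fit <- gbt(x, y, lambda = 1e12, nrounds = 10, seed = 1)
  expect_equal(predict(fit, x), rep(fit$base_score, 200), tolerance = 1e-6)
})

test_that("cover is conserved at every internal node of fitted trees", {
  set.seed(5)
  x <- matrix(rnorm(300 * 6), 300, 6)
  y <- as.integer(x[, 1] + rnorm(300) > 0)
  x[sample(length(x), 200)] <- NA
  fit <- gbt(x, y, max_depth = 4, nrounds = 20, subsample = 0.7, seed = 2)
  for (tr in fit$trees) {
    internal <- which(tr$feature >= 0)
    if (!length(internal)) next
    expect_equal(tr$cover[internal],
                 tr$cover[tr$left[internal] + 1] +
                   tr$cover[tr$right[internal] + 1], tolerance = 1e-9)
  }
})

test_that("early stopping halts on pure-noise labels and truncates the model", {
  set.seed(6)
  x <- matrix(rnorm(400 * 5), 400, 5)
  y <- rbinom(400, 1, 0.5)
  fit <- gbt(x[1:300, ], y[1:300], nrounds = 400, early_stopping_rounds = 30,
             eval_set = list(x = x[301:400, ], y = y[301:400]), seed = 3)
  expect_lt(fit$n_rounds_run, 400)
  expect_equal(fit$n_rounds_run - fit$best_iteration, 30)
  expect_length(fit$trees, fit$best_iteration)
})

test_that("margins decompose as base plus routed leaf values (oracle walk)", {
  set.seed(7)
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[sample(length(x), 30)] <- NA
  y <- as.integer(rowSums(x, na.rm = TRUE) > 0)
  fit <- gbt(x, y, max_depth = 3, nrounds = 8, seed = 1)
  marg <- predict(fit, x)
  for (i in c(1, 17, 50)) {
    expect_equal(marg[i], oracle_margin(fit, x[i, ]), tolerance = 1e-12)
  }
  expect_equal(predict(fit, x, type = "prob"), plogis(marg))
  # with zero trees the prediction is the base score
  expect_equal(predict(fit, x, ntree = 0), rep(fit$base_score, 50))
})

test_that("probability transform matches the logistic closed forms", {
  expect_equal(plogis(0), 0.5)
  m <- and_tree_model()
  m$base_score <- log(3)
  x <- matrix(c(-1, -1), 1, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(predict(m, x, type = "prob"), 0.75) # margin ln(3)
  # monotone in the margin
  set.seed(8)
  fit <- gbt(matrix(rnorm(100), 50, 2), rbinom(50, 1, 0.5), nrounds = 5,
             seed = 1)
  X <- matrix(rnorm(60), 30, 2)
  mm <- predict(fit, X)
  pp <- predict(fit, X, type = "prob")
  expect_equal(order(mm), order(pp))
})

test_that("AUC follows the rank statistic with tie midranks", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_roc(rep(0.4, 10), rep(0:1, 5)), 0.5)
  expect_equal(auc_roc(c(3, 2, 1, 0), c(1, 0, 1, 0)), 0.75)
  expect_error(auc_roc(1:4, rep(1, 4)), "both classes")
})

test_that("single-class labels and malformed inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(gbt(x, rep(1, 10)), "both classes")
  expect_error(gbt(x, c(rep(0, 9), 2)), "binary")
  fit <- gbt(x, rep(0:1, 5), nrounds = 2, seed = 1)
  bad <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("z1", "z2")))
  expect_error(predict(fit, bad), "registry")
})

test_that("JSON serialization round-trips the ensemble exactly", {
  set.seed(9)
  x <- matrix(rnorm(200 * 4), 200, 4)
  x[sample(length(x), 80)] <- NA
  y <- as.integer(x[, 2] > 0 | is.na(x[, 2]))
  fit <- gbt(x, y, max_depth = 3, nrounds = 12, subsample = 0.9, seed = 4)
  path <- file.path(tempdir(), "model.json")
  gbt_to_json(fit, path)
  back <- gbt_from_json(path)
  expect_identical(back$trees, fit$trees)
  expect_identical(back$base_score, fit$base_score)
  expect_identical(predict(back, x), predict(fit, x))
})

test_that("refitting with the same seed reproduces the ensemble", {
  set.seed(10)
  x <- matrix(rnorm(150 * 3), 150, 3)
  y <- rbinom(150, 1, plogis(x[, 1]))
  f1 <- gbt(x, y, subsample = 0.6, nrounds = 10, seed = 7)
  f2 <- gbt(x, y, subsample = 0.6, nrounds = 10, seed = 7)
  expect_identical(f1$trees, f2$trees)
})

test_that("AUC is comparable to an established boosting implementation", {
  skip_if_not_installed("xgboost")
  set.seed(11)
  n <- 500
  x <- matrix(rnorm(n * 6), n, 6)
  y <- as.integer(x[, 1] + 0.7 * x[, 2] - 0.5 * x[, 3] + rnorm(n) > 0)
  tr <- 1:350; te <- 351:500
  fit <- gbt(x[tr, ], y[tr], eta = 0.1, max_depth = 3, nrounds = 60,
             lambda = 1, seed = 1)
  a1 <- auc_roc(predict(fit, x[te, ]), y[te])
  dtr <- xgboost::xgb.DMatrix(x[tr, ], label = y[tr])
  ref <- xgboost::xgb.train(params = list(eta = 0.1, max_depth = 3,
                                          lambda = 1,
                                          objective = "binary:logistic"),
                            data = dtr, nrounds = 60)
  a2 <- auc_roc(predict(ref, xgboost::xgb.DMatrix(x[te, ])), y[te])
  expect_lt(abs(a1 - a2), 0.05)
})
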