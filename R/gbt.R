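#' Gradient tree boosting for a binary outcome
#'
#' Fits an additive ensemble of regression trees to a binary outcome by
#' second-order boosting of the logistic loss. Each round fits one tree to
#' the gradient/hessian statistics `g = p - y`, `h = p (1 - p)`; splits are
#' found by exact greedy search over the sorted observed values of every
#' feature, with the split gain
#' \deqn{\frac{1}{2}\left[\frac{G_L^2}{H_L+\lambda}+\frac{G_R^2}{H_R+\lambda}
#'   -\frac{(G_L+G_R)^2}{H_L+H_R+\lambda}\right]}
#' and leaf values \eqn{-\eta G/(H+\lambda)}. Missing values are handled by
#' sparsity-aware split finding: both routings of the missing block are
#' scored and the higher-gain direction becomes the split's default
#' direction. Rows can be subsampled per tree, and training stops early when
#' the evaluation-set loss fails to improve for `early_stopping_rounds`
#' consecutive rounds.
#'
#' The base score is the log-odds of the training prevalence, so the heavily
#' imbalanced outcomes this learner is aimed at need no reweighting. The
#' learning rate is folded into the stored leaf values, so a margin
#' prediction is the base score plus the sum of routed leaf values.
#'
#' @param x numeric matrix (or data frame coerced to one) of features;
#'   `NA` entries are allowed and routed by the learned default directions.
#' @param y binary 0/1 outcome vector; both classes must be present.
#' @param eta learning rate (shrinkage), positive.
#' @param max_depth maximum tree depth, positive integer.
#' @param subsample fraction of rows drawn (without replacement) per tree,
#'   in (0, 1].
#' @param lambda L2 regularization on leaf values, non-negative.
#' @param nrounds maximum number of boosting rounds.
#' @param early_stopping_rounds stop after this many rounds without
#'   evaluation-loss improvement (ignored without `eval_set`); the returned
#'   model is truncated to its best iteration.
#' @param min_gain minimum split gain, non-negative.
#' @param min_child_weight minimum hessian sum in each child.
#' @param eval_set optional `list(x = , y = )` held-out set used for the
#'   early-stopping metric.
#' @param metric early-stopping metric, `"logloss"` (minimized) or
#'   `"auc"` (maximized).
#' @param seed optional integer seed controlling the subsampling stream;
#'   the caller's RNG state is left untouched.
#'
#' @return An object of class `"gbt"`: a list with the fitted trees, base
#'   score (log-odds), feature names, the evaluation log, and
#'   `best_iteration`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 4), 200, 4)
#' y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(200, sd = 0.5) > 0)
#' fit <- gbt(x, y, max_depth = 2, nrounds = 30, seed = 1)
#' auc_roc(predict(fit, x), y)
#' @export
gbt <- function(x, y, eta = 0.1, max_depth = 6, subsample = 1, lambda = 1,
                nrounds = 500, early_stopping_rounds = 30, min_gain = 0,
                min_child_weight = 1, eval_set = NULL,
                metric = c("logloss", "auc"), seed = NULL) {
  metric <- match.arg(metric)
  x <- as_feature_matrix(x)
  y <- check_binary_labels(y, nrow(x))
  stopifnot(eta > 0, max_depth >= 1, subsample > 0, subsample <= 1,
            lambda >= 0, nrounds >= 1, min_gain >= 0, min_child_weight >= 0)
  n <- nrow(x)
  p <- ncol(x)

  presort <- lapply(seq_len(p), function(j) order(x[, j], na.last = NA) - 1L)
  base <- qlogis(mean(y))
  margin <- rep(base, n)
  has_eval <- !is.null(eval_set)
  if (has_eval) {
    xe <- as_feature_matrix(eval_set$x, template = colnames(x))
    ye <- check_binary_labels(eval_set$y, nrow(xe), require_both = FALSE)
    eval_margin <- rep(base, nrow(xe))
  }

  trees <- vector("list", nrounds)
  log_rows <- matrix(NA_real_, nrounds, 2,
                     dimnames = list(NULL, c("train_logloss", "eval_metric")))
  n_sub <- max(2L, as.integer(floor(subsample * n)))
  best_metric <- if (metric == "logloss") Inf else -Inf
  best_iter <- 0L
  stall <- 0L
  n_built <- 0L

  with_seed(seed, {
    for (round in seq_len(nrounds)) {
      prob <- plogis(margin)
      g <- prob - y
      h <- prob * (1 - prob)
      rows <- if (subsample < 1) sort(sample.int(n, n_sub)) - 1L else seq_len(n) - 1L
      tree <- cpp_build_tree(x, g, h, rows, presort, as.integer(max_depth),
                             lambda, min_gain, min_child_weight, eta)
      trees[[round]] <- tree
      n_built <- round
      margin <- margin + cpp_predict_trees(list(tree), x)
      log_rows[round, 1] <- logloss(y, plogis(margin))
      if (has_eval) {
        eval_margin <- eval_margin + cpp_predict_trees(list(tree), xe)
        m <- if (metric == "logloss") logloss(ye, plogis(eval_margin))
             else auc_roc(eval_margin, ye)
        log_rows[round, 2] <- m
        improved <- if (metric == "logloss") m < best_metric else m > best_metric
        if (improved) {
          best_metric <- m
          best_iter <- round
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= early_stopping_rounds) break
        }
      }
    }
  })

  if (!has_eval) best_iter <- n_built
  if (best_iter == 0L) best_iter <- 1L
  structure(list(
    trees = trees[seq_len(best_iter)],
    base_score = base,
    feature_names = colnames(x),
    params = list(eta = eta, max_depth = max_depth, subsample = subsample,
                  lambda = lambda, nrounds = nrounds,
                  early_stopping_rounds = early_stopping_rounds,
                  min_gain = min_gain, min_child_weight = min_child_weight,
                  metric = metric, seed = seed),
    best_iteration = best_iter,
    n_rounds_run = n_built,
    evaluation_log = as.data.frame(cbind(iter = seq_len(n_built),
                                         log_rows[seq_len(n_built), , drop = FALSE])),
    fitted_margin = NULL,
    y = y
  ), class = "gbt")
}

as_feature_matrix <- function(x, template = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(template)) {
    if (!all(template %in% colnames(x)))
      stop("feature columns do not match the model's feature registry")
    x <- x[, template, drop = FALSE]
  }
  x
}

check_binary_labels <- function(y, n, require_both = TRUE) {
  y <- as.numeric(y)
  if (length(y) != n) stop("length of `y` does not match `x`")
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("`y` must be binary 0/1")
  if (require_both && length(unique(y)) < 2)
    stop("both classes must be present in `y`")
  y
}

logloss <- function(y, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict from a gradient tree boosting model
#'
#' @param object a fitted [gbt()] model.
#' @param newdata feature matrix or data frame containing (at least) the
#'   model's feature columns; `NA` entries follow the learned default
#'   directions.
#' @param type `"margin"` for log-odds, `"prob"` for probabilities.
#' @param ntree number of trees to use (defaults to all retained trees).
#' @param ... unused.
#' @return numeric vector of per-row predictions.
#' @export
predict.gbt <- function(object, newdata, type = c("margin", "prob"),
                        ntree = NULL, ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata, template = object$feature_names)
  ntree <- ntree %||% length(object$trees)
  stopifnot(ntree >= 0, ntree <= length(object$trees))
  m <- object$base_score + if (ntree > 0)
    cpp_predict_trees(object$trees[seq_len(ntree)], x) else rep(0, nrow(x))
  if (type == "prob") plogis(m) else m
}

#' @export
print.gbt <- function(x, ...) {
  cat("Gradient tree boosting model (logistic loss)\n")
  cat(sprintf("  trees: %d (best iteration %d of %d rounds run)\n",
              length(x$trees), x$best_iteration, x$n_rounds_run))
  cat(sprintf("  features: %d   base score (log-odds): %.4f\n",
              length(x$feature_names), x$base_score))
  cat(sprintf("  eta %.3g, max_depth %d, subsample %.2g, lambda %.3g\n",
              x$params$eta, x$params$max_depth, x$params$subsample,
              x$params$lambda))
  invisible(x)
}

#' @export
summary.gbt <- function(object, ...) {
  used <- table(factor(unlist(lapply(object$trees, function(t)
    t$feature[t$feature >= 0] + 1L)), levels = seq_along(object$feature_names),
    labels = object$feature_names))
  out <- list(model = object, splits_per_feature = sort(used, decreasing = TRUE),
              final_train_logloss = utils::tail(object$evaluation_log$train_logloss, 1))
  class(out) <- "summary.gbt"
  out
}

#' @export
print.summary.gbt <- function(x, ...) {
  print(x$model)
  cat(sprintf("  final training logloss: %.4f\n", x$final_train_logloss))
  top <- utils::head(x$splits_per_feature[x$splits_per_feature > 0], 10)
  if (length(top)) {
    cat("  most-split features:\n")
    for (nm in names(top)) cat(sprintf("    %-24s %d\n", nm, top[[nm]]))
  }
  invisible(x)
}

#' @export
plot.gbt <- function(x, ...) {
  log <- x$evaluation_log
  plot(log$iter, log$train_logloss, type = "l", xlab = "boosting round",
       ylab = "logloss", main = "Training curve", ...)
  if (!all(is.na(log$eval_metric))) {
    graphics::lines(log$iter, log$eval_metric, lty = 2)
    graphics::legend("topright", legend = c("train", "eval"), lty = 1:2,
                     bty = "n")
    graphics::abline(v = x$best_iteration, col = "grey60", lty = 3)
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation with midranks: the probability that a randomly
#' chosen positive is scored above a randomly chosen negative, ties counted
#' one half. 0.5 corresponds to chance-level discrimination.
#'
#' @param scores numeric scores (any monotone scale).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_roc(c(3, 2, 1, 0), c(1, 0, 1, 0)) # 0.75
#' @export
auc_roc <- function(scores, labels) {
  labels <- check_binary_labels(labels, length(scores))
  if (anyNA(scores)) stop("`scores` must not contain NA")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize a gbt model to JSON
#'
#' Versioned JSON schema with the explicit per-node default direction for
#' missing values; numbers are written at full precision so a round trip
#' through [gbt_from_json()] reproduces the model exactly.
#'
#' @param model a [gbt()] model.
#' @param path file path to write to; with `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
gbt_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "gbt"))
  payload <- list(
    schema = "shapboost-gbt/1",
    base_score = model$base_score,
    feature_names = model$feature_names,
    params = model$params,
    best_iteration = model$best_iteration,
    trees = model$trees
  )
  # digits = I(17): decimal representation that round-trips doubles exactly
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a gbt model from JSON
#'
#' @param x a file path or JSON string produced by [gbt_to_json()].
#' @return a `"gbt"` model usable with [predict.gbt()] and the Shapley
#'   attribution functions.
#' @export
gbt_from_json <- function(x) {
  payload <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  if (!identical(payload$schema, "shapboost-gbt/1"))
    stop("unrecognized model schema")
  trees <- lapply(payload$trees, function(tr) {
    list(feature = as.integer(tr$feature),
         threshold = as.numeric(tr$threshold),
         default_left = as.integer(tr$default_left),
         left = as.integer(tr$left),
         right = as.integer(tr$right),
         cover = as.numeric(tr$cover),
         value = as.numeric(tr$value))
  })
  structure(list(
    trees = trees,
    base_score = payload$base_score,
    feature_names = unlist(payload$feature_names),
    params = payload$params,
    best_iteration = payload$best_iteration,
    n_rounds_run = payload$best_iteration,
    evaluation_log = data.frame(),
    y = NULL
  ), class = "gbt")
}
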