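#' Binarize the ordinal use outcome into the five analysis labels
#'
#' The ordinal lifetime-use category (0, 1+, 10+, 100+, 1000+) yields four
#' cumulative binary outcomes -- 1+ vs none, 10+ vs fewer, 100+ vs fewer,
#' 1000+ vs fewer -- each defined over the entire sample, plus the
#' dependence diagnosis. Participants with no use are forced to
#' non-dependent.
#'
#' @param use_category integer vector in 0..4.
#' @param dependence binary vector.
#' @return data frame with columns `use1plus`, `use10plus`, `use100plus`,
#'   `use1000plus`, `dependence` (0/1 integers).
#' @export
binarize_outcomes <- function(use_category, dependence) {
  if (any(!use_category %in% 0:4)) stop("`use_category` must be in 0..4")
  stopifnot(length(dependence) == length(use_category),
            all(dependence %in% 0:1))
  data.frame(
    use1plus = as.integer(use_category >= 1),
    use10plus = as.integer(use_category >= 2),
    use100plus = as.integer(use_category >= 3),
    use1000plus = as.integer(use_category >= 4),
    dependence = as.integer(dependence == 1 & use_category >= 1)
  )
}

#' Family-blocked cross-validation folds
#'
#' Families are shuffled (seeded) and assigned greedily to the currently
#' smallest fold by participant count, so all members of a family share a
#' fold and the spread between fold sizes is bounded by the largest family.
#'
#' @param family_ids family label per participant.
#' @param k number of folds, at least 2; there must be at least `k`
#'   families.
#' @param seed optional integer seed.
#' @return integer fold label (1..k) per participant.
#' @export
family_folds <- function(family_ids, k = 5, seed = NULL) {
  stopifnot(k >= 2)
  fams <- unique(family_ids)
  if (length(fams) < k) stop("fewer families than folds")
  sizes <- table(factor(family_ids, levels = fams))
  ord <- with_seed(seed, sample.int(length(fams)))
  fold_of_fam <- integer(length(fams))
  fold_sizes <- integer(k)
  for (i in ord) {
    f <- which.min(fold_sizes)
    fold_of_fam[i] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[i]
  }
  fold_of_fam[match(family_ids, fams)]
}

#' The printed hyperparameter grid
#'
#' Cartesian product of learning rate {0.01, 0.02, 0.05, 0.1, 0.2}, maximum
#' tree depth {4, 6, 8, 10, 12} and subsampling {0.6, 0.8, 1} -- 75
#' combinations, enumerated in the deterministic tie-breaking order (lower
#' learning rate, then lower depth, then lower subsample first).
#' @return data frame with columns `eta`, `max_depth`, `subsample`.
#' @export
default_grid <- function() {
  g <- expand.grid(subsample = c(0.6, 0.8, 1), max_depth = c(4L, 6L, 8L, 10L, 12L),
                   eta = c(0.01, 0.02, 0.05, 0.1, 0.2))
  g <- g[order(g$eta, g$max_depth, g$subsample), c("eta", "max_depth", "subsample")]
  rownames(g) <- NULL
  g
}

#' Reduced three-point grid for simulation experiments
#'
#' A small diagonal of the full grid (shallow trees, moderate-to-fast
#' learning rates) used by the package's repeated-seed simulation studies,
#' where refitting the full 75-combination grid per seed would dominate the
#' runtime without changing what the experiment measures.
#' @return data frame with columns `eta`, `max_depth`, `subsample`.
#' @export
reduced_grid <- function() {
  data.frame(eta = c(0.05, 0.1, 0.2), max_depth = c(4L, 4L, 4L),
             subsample = c(0.8, 0.8, 1))
}

#' Family-aware nested cross-validation for one binary outcome
#'
#' Outer k-fold loop (family-blocked) for performance estimation; for each
#' outer training set an inner k-fold loop (family-blocked again)
#' grid-searches the hyperparameter combinations by mean inner-validation
#' AUC, with early stopping on each inner fit. The inner winner (ties
#' broken toward lower learning rate, then lower depth, then lower
#' subsample) is refit on the outer training set with a carved-out
#' family-blocked early-stopping split, and scored once on the outer test
#' fold.
#'
#' @param x feature matrix (missing values allowed).
#' @param y binary outcome.
#' @param family_ids family label per row.
#' @param grid hyperparameter data frame (`eta`, `max_depth`, `subsample`).
#' @param k folds for both loops.
#' @param seed integer seed; folds and fits are deterministic given it.
#' @param nrounds,early_stopping_rounds,lambda passed to [gbt()].
#' @param inner_metric inner-loop selection metric, `"auc"` (default) or
#'   `"logloss"`.
#' @return object of class `"nested_cv"`: outer AUCs, selected parameters,
#'   fitted per-fold models, fold labels and test-row indices.
#' @export
nested_cv <- function(x, y, family_ids, grid = default_grid(), k = 5,
                      seed = 1, nrounds = 500, early_stopping_rounds = 30,
                      lambda = 1, inner_metric = c("auc", "logloss")) {
  inner_metric <- match.arg(inner_metric)
  x <- as_feature_matrix(x)
  y <- check_binary_labels(y, nrow(x))
  stopifnot(length(family_ids) == nrow(x))
  grid <- grid[order(grid$eta, grid$max_depth, grid$subsample), , drop = FALSE]

  folds <- draw_folds_with_both_classes(family_ids, y, k, seed)
  outer_auc <- numeric(k)
  selected <- vector("list", k)
  models <- vector("list", k)
  test_rows <- vector("list", k)

  for (fold in seq_len(k)) {
    test <- which(folds == fold)
    train <- which(folds != fold)
    if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2)
      stop("a fold is missing a class even after redraws")
    inner_seed <- (seed * 131 + fold * 17) %% 2147483647
    inner_folds <- draw_folds_with_both_classes(family_ids[train], y[train],
                                                k, inner_seed)
    scores <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      vals <- numeric(k)
      for (j in seq_len(k)) {
        itr <- train[inner_folds != j]
        iva <- train[inner_folds == j]
        fit <- gbt(x[itr, , drop = FALSE], y[itr],
                   eta = grid$eta[gi], max_depth = grid$max_depth[gi],
                   subsample = grid$subsample[gi], lambda = lambda,
                   nrounds = nrounds,
                   early_stopping_rounds = early_stopping_rounds,
                   eval_set = list(x = x[iva, , drop = FALSE], y = y[iva]),
                   metric = "logloss",
                   seed = (inner_seed + 1000L * gi + j) %% 2147483647)
        pred <- predict(fit, x[iva, , drop = FALSE])
        vals[j] <- if (inner_metric == "auc") auc_roc(pred, y[iva])
                   else -logloss(y[iva], plogis(pred))
      }
      scores[gi] <- mean(vals)
    }
    best <- which.max(scores) # first max: the documented tie-break order
    # refit on the outer training set with a carved early-stopping split
    es_folds <- draw_folds_with_both_classes(family_ids[train], y[train], 5,
                                             (inner_seed + 7) %% 2147483647)
    es_hold <- train[es_folds == 1]
    es_fit <- train[es_folds != 1]
    model <- gbt(x[es_fit, , drop = FALSE], y[es_fit],
                 eta = grid$eta[best], max_depth = grid$max_depth[best],
                 subsample = grid$subsample[best], lambda = lambda,
                 nrounds = nrounds,
                 early_stopping_rounds = early_stopping_rounds,
                 eval_set = list(x = x[es_hold, , drop = FALSE],
                                 y = y[es_hold]),
                 metric = "logloss",
                 seed = (inner_seed + 99991) %% 2147483647)
    outer_auc[fold] <- auc_roc(predict(model, x[test, , drop = FALSE]), y[test])
    selected[[fold]] <- grid[best, , drop = FALSE]
    models[[fold]] <- model
    test_rows[[fold]] <- test
  }
  structure(list(outer_auc = outer_auc,
                 selected = do.call(rbind, selected),
                 models = models, folds = folds, test_rows = test_rows,
                 grid = grid, k = k, seed = seed),
            class = "nested_cv")
}

# Redraw family folds (advancing the seed) until every fold contains both
# classes in its complement and itself; logs each redraw.
draw_folds_with_both_classes <- function(family_ids, y, k, seed,
                                         max_tries = 25) {
  for (tr in seq_len(max_tries)) {
    s <- (seed + tr - 1) %% 2147483647
    folds <- family_folds(family_ids, k, s)
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[folds == f])) == 2 &&
        length(unique(y[folds != f])) == 2, logical(1)))
    if (ok) {
      if (tr > 1) message("fold redraw: ", tr - 1,
                          " draw(s) left a fold with a single class")
      return(folds)
    }
  }
  stop("could not draw folds with both classes in every fold")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("Nested %d-fold CV: mean outer AUC %.3f (folds: %s)\n", x$k,
              mean(x$outer_auc), paste(sprintf("%.3f", x$outer_auc),
                                       collapse = ", ")))
  cat("Selected hyperparameters per fold:\n")
  print(cbind(fold = seq_len(x$k), x$selected), row.names = FALSE)
  invisible(x)
}

#' Normalized global factor importance
#'
#' Mean absolute Shapley value per factor over the explained instances,
#' normalized to sum to one across factors (the normalization constant also
#' scales interaction magnitudes, so importances and interaction values
#' share a unit).
#'
#' @param attributions a `"gbt_shap"` object or an n x p attribution
#'   matrix.
#' @return named numeric vector summing to 1.
#' @export
global_importance <- function(attributions) {
  phi <- if (inherits(attributions, "gbt_shap")) attributions$phi
         else as.matrix(attributions)
  if (nrow(phi) == 0) stop("empty attribution set")
  m <- colMeans(abs(phi))
  tot <- sum(m)
  if (tot == 0) return(m)
  m / tot
}

#' Cross-model median rank of each factor
#'
#' Ranks factors within each model by descending normalized importance
#' (ties broken alphabetically by factor name), then takes the median rank
#' across models; for an even number of models the lower of the two central
#' ranks is used, keeping ranks integral. Factors at or below the cutoff
#' are flagged as consistently highly ranked.
#'
#' @param importances list of named importance vectors (all sharing one
#'   factor registry), e.g. from [global_importance()] per model.
#' @param cutoff highly-ranked flag threshold, default 20.
#' @return data frame with `factor`, `median_rank`, `highly_ranked`, and
#'   the per-model rank matrix as attribute `"ranks"`.
#' @export
median_rank <- function(importances, cutoff = 20) {
  stopifnot(length(importances) >= 1)
  nm <- names(importances[[1]])
  for (imp in importances)
    if (!identical(sort(names(imp)), sort(nm)))
      stop("factor registries differ across models")
  ranks <- vapply(importances, function(imp) {
    imp <- imp[nm]
    ord <- order(-imp, nm)
    r <- integer(length(imp))
    r[ord] <- seq_along(ord)
    r
  }, integer(length(nm)))
  ranks <- matrix(ranks, nrow = length(nm), dimnames = list(nm, NULL))
  med <- apply(ranks, 1, lower_median)
  out <- data.frame(factor = nm, median_rank = med,
                    highly_ranked = med <= cutoff, row.names = NULL)
  out <- out[order(out$median_rank, out$factor), ]
  rownames(out) <- NULL
  attr(out, "ranks") <- ranks
  out
}

lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Effect-size bin of a normalized interaction value
#'
#' Bins absolute normalized values as small (< 0.1), moderate (< 0.3),
#' large (< 0.5) or very large (>= 0.5).
#' @param v numeric values.
#' @return character vector of bin labels.
#' @export
effect_size_bin <- function(v) {
  cut(abs(v), breaks = c(0, 0.1, 0.3, 0.5, Inf),
      labels = c("small", "moderate", "large", "very large"),
      right = FALSE, include.lowest = TRUE)
}

#' Sex-interaction report across models
#'
#' For each model, the pair interaction of every factor with the sex factor
#' is summarized as the mean absolute total pair attribution over the
#' explained instances, normalized by the same constant as the model's
#' global importances (so the sum of all attribution magnitudes per model
#' is 1). Values are aggregated across models by the median, and factors
#' whose aggregated value reaches `threshold` are reported with their
#' effect-size bin, the mean signed interaction in each sex group, and the
#' factor's main-effect importance for context.
#'
#' @param explained list of per-model explanations, each a list with
#'   elements `phi` (n x p attribution matrix), `pair` (n x p matrix of
#'   stored symmetric-half interaction entries against sex), and `sex`
#'   (0/1 per explained instance); [explain_models()] produces this.
#' @param sex_feature name of the sex factor, default `"sex"`.
#' @param threshold minimum normalized interaction value to report,
#'   default 0.1.
#' @return data frame with `factor`, `value`, `bin`, `mean_men`,
#'   `mean_women`, `main_importance`, sorted by decreasing value; zero rows
#'   when nothing reaches the threshold. The full per-factor table is kept
#'   as attribute `"all_factors"`.
#' @export
sex_interaction_report <- function(explained, sex_feature = "sex",
                                   threshold = 0.1) {
  stopifnot(length(explained) >= 1)
  nm <- colnames(explained[[1]]$phi)
  if (!sex_feature %in% nm) stop("`", sex_feature, "` not in the registry")
  per_model <- lapply(explained, function(e) {
    C <- sum(colMeans(abs(e$phi)))
    pair_total <- 2 * e$pair # stored symmetric halves
    list(value = colMeans(abs(pair_total)) / C,
         men = colMeans(pair_total[e$sex == 1, , drop = FALSE]),
         women = colMeans(pair_total[e$sex == 0, , drop = FALSE]),
         main = global_importance(e$phi))
  })
  agg <- function(field) apply(vapply(per_model, `[[`, numeric(length(nm)),
                                      field), 1, median)
  value <- agg("value")
  tab <- data.frame(factor = nm, value = value,
                    bin = effect_size_bin(value),
                    mean_men = agg("men"), mean_women = agg("women"),
                    main_importance = agg("main"), row.names = NULL)
  tab <- tab[tab$factor != sex_feature, ]
  tab <- tab[order(-tab$value, tab$factor), ]
  rownames(tab) <- NULL
  out <- tab[tab$value >= threshold, ]
  rownames(out) <- NULL
  attr(out, "all_factors") <- tab
  out
}

#' Explain the out-of-fold rows of nested-CV models
#'
#' For each outer-fold model, computes Shapley attributions and the
#' interaction entries against the sex factor on that fold's held-out test
#' rows (so every explanation is out-of-sample).
#'
#' @param cv a [nested_cv()] result.
#' @param x the feature matrix the CV was run on.
#' @param sex_feature name of the sex factor column in `x`.
#' @return list (one element per fold model) of lists with `phi`, `phi0`,
#'   `pair`, `sex`, `rows`; the input of [sex_interaction_report()] and,
#'   via [global_importance()], of [median_rank()].
#' @export
explain_models <- function(cv, x, sex_feature = "sex") {
  stopifnot(inherits(cv, "nested_cv"))
  x <- as_feature_matrix(x)
  lapply(seq_along(cv$models), function(i) {
    rows <- cv$test_rows[[i]]
    xi <- x[rows, , drop = FALSE]
    inter <- shapley_interactions(cv$models[[i]], xi, partner = sex_feature)
    list(phi = inter$attributions$phi, phi0 = inter$attributions$phi0,
         pair = inter$partner_row, sex = xi[, sex_feature], rows = rows)
  })
}

#' Pearson chi-square test statistic for a contingency table
#'
#' Plain Pearson statistic (no continuity correction) with expected counts
#' from the independence margins; used to reproduce printed descriptive
#' statistics from published count tables.
#'
#' @param table r x c matrix of non-negative counts with positive row and
#'   column sums.
#' @return list with `statistic` and `df` = (r-1)(c-1).
#' @examples
#' chi_square_contingency(rbind(c(81, 28), c(468, 627)))$statistic # 39.83
#' @export
chi_square_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column sums must be positive")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter))
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Equal-variance two-sample t computed from group sizes, means and SDs,
#' as used to verify printed group comparisons.
#'
#' @param n1,mean1,sd1 first group's size, mean and SD.
#' @param n2,mean2,sd2 second group's size, mean and SD.
#' @return list with `statistic` (|t|) and `df` = n1 + n2 - 2.
#' @examples
#' pooled_t_from_summary(109, 4.39, 2.37, 1090, 5.06, 2.14)$statistic # 3.08
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  t <- abs(mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(statistic = t, df = n1 + n2 - 2)
}
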