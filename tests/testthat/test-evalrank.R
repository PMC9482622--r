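test_that("outcome binarization is cumulative and gates dependence on use", {
  b <- binarize_outcomes(c(3, 0), c(0, 1))
  expect_equal(unlist(b[1, ]), c(use1plus = 1, use10plus = 1, use100plus = 1,
                                 use1000plus = 0, dependence = 0))
  expect_equal(unname(unlist(b[2, ])), rep(0L, 5)) # never-user forced clean

  # the reference full-sample distribution 550/324/144/78/108
  cats <- rep(0:4, c(550, 324, 144, 78, 108))
  bb <- binarize_outcomes(cats, rep(0, length(cats)))
  expect_equal(unname(colSums(bb[1:4])), c(654, 330, 186, 108))
  expect_error(binarize_outcomes(c(0, 5), c(0, 0)), "0..4")
})

test_that("family folds co-assign families and balance greedily", {
  folds <- family_folds(1:10, k = 5, seed = 1)
  expect_equal(unname(table(folds)), rep(2L, 5), ignore_attr = TRUE)

  fam <- c(rep(1, 3), 2:8)
  f2 <- family_folds(fam, k = 5, seed = 2)
  expect_length(unique(f2[fam == 1]), 1)

  set.seed(3)
  for (i in 1:10) {
    fam <- rep(seq_len(60), sample(1:5, 60, replace = TRUE))
    fk <- family_folds(fam, k = 5, seed = i)
    sizes <- table(fk)
    expect_lte(max(sizes) - min(sizes), max(table(fam)))
    # family disjointness across folds
    expect_true(all(tapply(fk, fam, function(z) length(unique(z))) == 1))
  }
  expect_identical(family_folds(fam, 5, 11), family_folds(fam, 5, 11))
  expect_error(family_folds(1:4, k = 5), "fewer families")
})

test_that("hyperparameter grids enumerate the printed sets", {
  g <- default_grid()
  expect_equal(nrow(g), 75)
  expect_setequal(unique(g$eta), c(0.01, 0.02, 0.05, 0.1, 0.2))
  expect_setequal(unique(g$max_depth), c(4, 6, 8, 10, 12))
  expect_setequal(unique(g$subsample), c(0.6, 0.8, 1))
  expect_false(any(duplicated(g)))
  r <- reduced_grid()
  expect_equal(nrow(r), 3)
  expect_true(all(r$eta %in% g$eta) && all(r$subsample %in% g$subsample))
})

test_that("nested CV returns k honest outer estimates with selected params", {
  set.seed(4)
  coh <- simulate_cohort(n = 240, seed = 31)
  x <- cohort_features(coh)
  y <- binarize_outcomes(coh$use_category, coh$dependence)$use1plus
  grid <- data.frame(eta = c(0.1, 0.2), max_depth = c(2L, 2L),
                     subsample = c(1, 1))
  cv <- nested_cv(x, y, coh$family_id, grid = grid, k = 5, seed = 5,
                  nrounds = 60)
  expect_length(cv$outer_auc, 5)
  expect_true(all(cv$outer_auc > 0 & cv$outer_auc < 1))
  expect_equal(nrow(cv$selected), 5)
  expect_true(all(cv$selected$eta %in% grid$eta))
  # outer test sets partition the cohort and respect families
  all_rows <- sort(unlist(cv$test_rows))
  expect_equal(all_rows, seq_len(nrow(x)))
  for (f in 1:5) {
    expect_equal(cv$test_rows[[f]], which(cv$folds == f))
    fams_test <- unique(coh$family_id[cv$folds == f])
    fams_train <- unique(coh$family_id[cv$folds != f])
    expect_length(intersect(fams_test, fams_train), 0)
  }
  # determinism
  cv2 <- nested_cv(x, y, coh$family_id, grid = grid, k = 5, seed = 5,
                   nrounds = 60)
  expect_identical(cv$outer_auc, cv2$outer_auc)
})

test_that("importance normalization and hand values behave", {
  phi <- rbind(c(0.3, -0.1), c(-0.3, 0.1), c(0.3, 0.1))
  colnames(phi) <- c("a", "b")
  gi <- global_importance(phi)
  expect_equal(unname(gi), c(0.75, 0.25))
  expect_equal(sum(gi), 1, tolerance = 1e-12)

  one <- matrix(c(0, 0.5, 0, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(global_importance(one)), c(1, 0))

  perm <- phi[, c("b", "a")]
  expect_equal(global_importance(perm), gi[c("b", "a")])
  expect_error(global_importance(phi[0, , drop = FALSE]), "empty")
})

test_that("median ranks aggregate with the lower-median convention", {
  imp <- function(v) stats::setNames(v, c("a", "b", "c"))
  # factor a ranked 1st in all models
  mr <- median_rank(list(imp(c(0.5, 0.3, 0.2)), imp(c(0.6, 0.2, 0.2)),
                         imp(c(0.7, 0.1, 0.2))), cutoff = 1)
  expect_equal(mr$median_rank[mr$factor == "a"], 1)
  expect_true(mr$highly_ranked[mr$factor == "a"])
  expect_false(any(mr$highly_ranked[mr$factor != "a"]))
  # tie in model 2: b vs c equal importance -> alphabetical
  ranks <- attr(mr, "ranks")
  expect_equal(unname(ranks[, 2]), c(1L, 2L, 3L))

  # ranks {4,4,6} -> 4 (via direct lower-median); even count -> lower
  expect_equal(shapboost:::lower_median(c(4, 4, 6)), 4)
  expect_equal(shapboost:::lower_median(c(2, 5)), 2)

  single <- median_rank(list(imp(c(0.2, 0.5, 0.3))))
  expect_equal(single$median_rank[single$factor == "b"], 1)

  expect_error(median_rank(list(imp(c(1, 0, 0)),
                                stats::setNames(1:3, c("a", "b", "z")))),
               "registries")
})

test_that("effect-size bins follow the documented cut points", {
  expect_equal(as.character(effect_size_bin(c(0.05, 0.27, -0.27, 0.3, 0.45,
                                              0.5, 0.7))),
               c("small", "moderate", "moderate", "large", "large",
                 "very large", "very large"))
})

test_that("the sex-interaction report thresholds and summarizes by group", {
  p <- 3
  nm <- c("sex", "f1", "f2")
  mk <- function(pair_f1) {
    phi <- matrix(rnorm(40 * p, sd = 0.1), 40, p, dimnames = list(NULL, nm))
    phi[, "f1"] <- rnorm(40, sd = 0.5)
    pair <- matrix(0, 40, p, dimnames = list(NULL, nm))
    sex <- rep(0:1, 20)
    pair[, "f1"] <- pair_f1 * ifelse(sex == 1, 1, -1)
    list(phi = phi, pair = pair, sex = sex)
  }
  set.seed(6)
  rep_on <- sex_interaction_report(list(mk(0.2), mk(0.25)))
  expect_true("f1" %in% rep_on$factor)
  expect_false("sex" %in% rep_on$factor)
  row <- rep_on[rep_on$factor == "f1", ]
  expect_gt(row$mean_men, 0)
  expect_lt(row$mean_women, 0)
  expect_true(row$bin %in% c("moderate", "large", "very large"))

  # additive models: empty table but full per-factor diagnostics retained
  rep_off <- sex_interaction_report(list(mk(0), mk(0)))
  expect_equal(nrow(rep_off), 0)
  expect_equal(nrow(attr(rep_off, "all_factors")), p - 1)
})

test_that("the Pearson chi-square matches an independent formula", {
  expect_equal(chi_square_contingency(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  set.seed(7)
  for (i in 1:25) {
    r <- sample(2:4, 1); cc <- sample(2:5, 1)
    tab <- matrix(rpois(r * cc, 20) + 1, r, cc)
    res <- chi_square_contingency(tab)
    expect_equal(res$statistic, oracle_chisq(tab), tolerance = 1e-10)
    expect_equal(res$df, (r - 1) * (cc - 1))
  }
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))), "sums")
})

test_that("pooled t from summaries matches hand cases", {
  expect_equal(pooled_t_from_summary(10, 5, 1, 12, 5, 1)$statistic, 0)
  res <- pooled_t_from_summary(109, 4.39, 2.37, 1090, 5.06, 2.14)
  expect_equal(res$df, 1197)
  sp <- sqrt((108 * 2.37^2 + 1089 * 2.14^2) / 1197)
  expect_equal(res$statistic, 0.67 / (sp * sqrt(1 / 109 + 1 / 1090)),
               tolerance = 1e-10)
  expect_error(pooled_t_from_summary(1, 0, 1, 5, 0, 1), "n1")
  expect_error(pooled_t_from_summary(5, 0, 0, 5, 0, 1), "sd1")
})

test_that("out-of-fold explanations cover exactly the test rows", {
  set.seed(8)
  coh <- simulate_cohort(n = 200, seed = 77)
  x <- cohort_features(coh)
  y <- binarize_outcomes(coh$use_category, coh$dependence)$use1plus
  grid <- data.frame(eta = 0.2, max_depth = 2L, subsample = 1)
  cv <- nested_cv(x, y, coh$family_id, grid = grid, k = 5, seed = 9,
                  nrounds = 40)
  expl <- explain_models(cv, x)
  expect_length(expl, 5)
  expect_equal(sort(unlist(lapply(expl, `[[`, "rows"))), seq_len(200))
  for (i in 1:5) {
    e <- expl[[i]]
    expect_equal(nrow(e$phi), length(cv$test_rows[[i]]))
    expect_equal(e$sex, x[cv$test_rows[[i]], "sex"], ignore_attr = TRUE)
    # local accuracy on out-of-fold rows
    marg <- predict(cv$models[[i]], x[e$rows, , drop = FALSE])
    expect_lt(max(abs(e$phi0 + rowSums(e$phi) - marg)), 1e-9)
  }
})
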