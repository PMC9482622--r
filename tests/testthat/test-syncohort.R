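test_that("family plans partition participants exactly and deterministically", {
  plan <- generate_families(10, mean_family_size = 1, seed = 1)
  expect_length(plan$sizes, 10)
  expect_true(all(plan$sizes == 1))

  plan2 <- generate_families(1204, mean_family_size = 2.1, seed = 7)
  expect_equal(sum(plan2$sizes), 1204)
  expect_length(plan2$family_id, 1204)
  # family count close to n / mean size
  expect_gt(length(plan2$sizes), 1204 / 2.1 * 0.75)
  expect_lt(length(plan2$sizes), 1204 / 2.1 * 1.35)
  expect_true(all(plan2$sizes >= 1 & plan2$sizes <= 5))

  expect_identical(plan2, generate_families(1204, mean_family_size = 2.1, seed = 7))
  expect_error(generate_families(0), "positive")
})

test_that("feature blocks carry the requested equicorrelation and sex split", {
  plan <- generate_families(1204, seed = 2)
  f0 <- generate_features(plan, c(environmental = 5, personality = 5),
                          block_correlation = 0, seed = 3)
  r0 <- cor(f0$X[, 1:5])
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)

  f5 <- generate_features(plan, c(environmental = 5, personality = 5),
                          block_correlation = 0.5, seed = 3)
  r5 <- cor(f5$X[, 1:5])
  expect_gt(mean(r5[upper.tri(r5)]), 0.4)
  expect_lt(mean(r5[upper.tri(r5)]), 0.6)
  # cross-domain features stay uncorrelated
  rx <- cor(f5$X[, 1:5], f5$X[, 6:10])
  expect_lt(mean(abs(rx)), 0.1)

  frac_female <- mean(f5$sex == 0)
  expect_gt(frac_female, 0.50)
  expect_lt(frac_female, 0.58)
  expect_error(generate_features(plan, c(a = 2), block_correlation = 1),
               "block_correlation")
})

test_that("outcome generator calibrates prevalence and respects the use gate", {
  prevs <- women <- numeric(20)
  for (s in 1:20) {
    coh <- simulate_cohort(n = 1204, seed = s)
    prevs[s] <- mean(coh$dependence)
    women[s] <- mean(coh$sex[coh$dependence == 1] == 0)
    expect_true(all(coh$use_category[coh$dependence == 1] >= 2))
    expect_true(all(coh$dependence[coh$use_category == 0] == 0))
  }
  expect_lt(abs(mean(prevs) - 109 / 1204), 0.015)
  # positive sex main effect: dependence cases male-skewed in every seed
  expect_true(all(women < 0.5))
})

test_that("ordinal thresholds reproduce the target use distribution", {
  coh <- simulate_cohort(n = 1204, seed = 4)
  counts <- as.integer(table(factor(coh$use_category, levels = 0:4)))
  expect_equal(counts, c(550, 324, 144, 78, 108), tolerance = 0,
               ignore_attr = TRUE)
})

test_that("a nonzero effect on an all-missing feature is rejected", {
  plan <- generate_families(50, seed = 1)
  f <- generate_features(plan, c(environmental = 2), seed = 1)
  f$X[, 1] <- NA
  spec <- effect_spec(beta = c(environmental_1 = 1))
  expect_error(generate_outcomes(f$X, f$sex, plan, spec, seed = 1),
               "all-missing")
  spec2 <- effect_spec(beta = c(nonexistent = 1))
  expect_error(generate_outcomes(f$X, f$sex, plan, spec2, seed = 1),
               "absent")
})

test_that("missingness injection hits the requested rates by mechanism", {
  X <- matrix(rnorm(1204 * 6), 1204, 6)
  expect_identical(inject_missingness(X, 0, seed = 1), X)
  Xm <- inject_missingness(X, 0.1, seed = 2)
  frac <- colMeans(is.na(Xm))
  expect_true(all(frac >= 0.08 & frac <= 0.12))

  y <- rbinom(1204, 1, 0.3)
  Xo <- inject_missingness(X, 0.05, mechanism = "outcome", y = y,
                           offset = 0.2, seed = 3)
  gap <- mean(is.na(Xo[y == 1, ])) - mean(is.na(Xo[y == 0, ]))
  expect_lt(abs(gap - 0.2), 0.03)
  expect_error(inject_missingness(X, 1), "rate")
})

test_that("family random effect induces within-family liability correlation", {
  set.seed(99)
  within <- between <- numeric(5)
  for (s in 1:5) {
    coh <- simulate_cohort(n = 1204, seed = 300 + s,
                           spec = effect_spec(sigma_f = 0.8))
    L <- attr(coh, "liability")
    fam <- coh$family_id
    Lc <- L - mean(L)
    pairs_w <- pairs_b <- 0
    sum_w <- 0
    for (f in unique(fam[duplicated(fam)])) {
      i <- which(fam == f)
      cp <- combn(i, 2)
      sum_w <- sum_w + sum(Lc[cp[1, ]] * Lc[cp[2, ]])
      pairs_w <- pairs_w + ncol(cp)
    }
    within[s] <- sum_w / pairs_w / var(L)
    i1 <- sample(length(L), 4000, replace = TRUE)
    i2 <- sample(length(L), 4000, replace = TRUE)
    keep <- fam[i1] != fam[i2]
    between[s] <- mean(Lc[i1[keep]] * Lc[i2[keep]]) / var(L)
  }
  expect_true(all(within > between))
  expect_gt(mean(within), 0.1)
})

test_that("connectome stacks are symmetric block matrices with unit diagonal", {
  stack <- generate_connectomes(4, 12, rep(1:3, each = 4), within_r = 0.6,
                                between_r = 0.1, subject_noise_sd = 0.05,
                                seed = 9)
  for (M in stack$matrices) {
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, 12))
    expect_true(all(abs(M[row(M) != col(M)]) < 1))
  }
  # block means match the construction
  M <- stack$matrices[[1]]
  same <- outer(stack$module, stack$module, "==") & row(M) != col(M)
  expect_lt(abs(mean(M[same]) - 0.6), 0.05)
  expect_lt(abs(mean(M[!same & row(M) != col(M)]) - 0.1), 0.05)

  # zero noise: all subjects identical
  s0 <- generate_connectomes(3, 8, subject_noise_sd = 0, seed = 1)
  expect_identical(s0$matrices[[1]], s0$matrices[[2]])

  # community recovery by thresholding the mean matrix
  mats <- generate_connectomes(10, 12, rep(1:2, each = 6), within_r = 0.6,
                               between_r = 0.1, seed = 5)
  avg <- Reduce(`+`, mats$matrices) / 10
  g <- igraph::graph_from_adjacency_matrix(avg > 0.35, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_true(all(tapply(comp$membership, mats$module,
                         function(z) length(unique(z))) == 1))

  expect_error(generate_connectomes(2, 3), "n_nodes")
  expect_error(generate_connectomes(2, 8, within_r = 0.1, between_r = 0.5),
               "between_r")
})

test_that("identical seeds reproduce a cohort bit-for-bit", {
  c1 <- simulate_cohort(n = 150, seed = 42)
  c2 <- simulate_cohort(n = 150, seed = 42)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(n = 150, seed = 43)
  expect_false(identical(c1, c3))
})

test_that("cohort and effect-spec round-trip through their text formats", {
  coh <- simulate_cohort(n = 80, seed = 6)
  path <- file.path(tempdir(), "cohort_rt.csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  strip <- function(d) {
    d <- as.data.frame(d)
    attributes(d) <- attributes(d)[c("names", "class", "row.names")]
    d
  }
  expect_equal(strip(back), strip(coh), tolerance = 1e-12)
  expect_identical(attr(coh, "domains"), attr(back, "domains"))

  spec <- default_effect_spec()
  sp <- file.path(tempdir(), "spec_rt.cfg")
  write_effect_spec(spec, sp)
  back_spec <- read_effect_spec(sp)
  expect_equal(back_spec$beta, spec$beta)
  expect_equal(back_spec$gamma, spec$gamma)
  expect_equal(back_spec$sigma_f, spec$sigma_f)

  stack <- generate_connectomes(2, 6, seed = 3)
  cd <- file.path(tempdir(), "conn_rt")
  write_connectomes(stack, cd)
  back_stack <- read_connectomes(cd)
  expect_equal(back_stack$matrices[[2]], stack$matrices[[2]],
               tolerance = 1e-12)
})
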