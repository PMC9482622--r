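#' Generate a family-block plan
#'
#' Draws family sizes from a shifted Poisson distribution (1 + Poisson with
#' mean `mean_family_size - 1`) truncated at `max_family_size`, until the
#' requested number of participants is reached; the last family is trimmed
#' so the totals match exactly. Family blocks are what the cross-validation
#' scheme keeps together, so every cohort carries one.
#'
#' @param n number of participants, at least 1.
#' @param mean_family_size mean family size, at least 1; 1 gives singleton
#'   families.
#' @param max_family_size truncation point for family sizes.
#' @param seed optional integer seed.
#' @return object of class `"family_plan"`: list with `family_id` (integer
#'   per participant) and `sizes` (participants per family).
#' @examples
#' plan <- generate_families(20, mean_family_size = 2, seed = 1)
#' table(plan$family_id)
#' @export
generate_families <- function(n, mean_family_size = 2, max_family_size = 5,
                              seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("`n` must be a positive participant count")
  n <- as.integer(n)
  stopifnot(mean_family_size >= 1, max_family_size >= 1)
  sizes <- with_seed(seed, {
    out <- integer(0)
    total <- 0L
    while (total < n) {
      draw <- 1L + min(rpois(1, mean_family_size - 1), max_family_size - 1L)
      draw <- min(draw, n - total)
      out <- c(out, draw)
      total <- total + draw
    }
    out
  })
  structure(list(family_id = rep(seq_along(sizes), sizes), sizes = sizes),
            class = "family_plan")
}

#' @export
print.family_plan <- function(x, ...) {
  cat(sprintf("Family plan: %d participants in %d families (sizes %s)\n",
              length(x$family_id), length(x$sizes),
              paste(names(table(x$sizes)), table(x$sizes), sep = "x",
                    collapse = ", ")))
  invisible(x)
}

#' Generate correlated multimodal features and sex
#'
#' Draws standard-normal features in named domains with within-domain
#' equicorrelation `block_correlation` (a shared per-participant domain
#' factor plus independent noise), and assigns binary sex (0 = woman,
#' 1 = man) with the configured female fraction.
#'
#' @param plan a [generate_families()] plan (fixes n).
#' @param p_per_domain named integer vector of feature counts per domain,
#'   e.g. `c(environmental = 5, personality = 5, ...)`; all counts >= 1.
#' @param block_correlation within-domain pairwise correlation in \[0, 1).
#' @param prop_female probability of sex = 0.
#' @param seed optional integer seed.
#' @return list with `X` (n x p matrix, columns `<domain>_<k>`), `domains`
#'   (domain label per column) and `sex` (0/1 per participant).
#' @export
generate_features <- function(plan,
                              p_per_domain = default_domain_counts(),
                              block_correlation = 0.3, prop_female = 0.54,
                              seed = NULL) {
  stopifnot(inherits(plan, "family_plan"), all(p_per_domain >= 1))
  if (block_correlation < 0 || block_correlation >= 1)
    stop("`block_correlation` must be in [0, 1)")
  stopifnot(prop_female > 0, prop_female < 1)
  n <- length(plan$family_id)
  doms <- names(p_per_domain)
  if (is.null(doms)) stop("`p_per_domain` must be a named vector")
  with_seed(seed, {
    cols <- list()
    labels <- character(0)
    for (d in doms) {
      pd <- p_per_domain[[d]]
      shared <- rnorm(n)
      Xd <- sqrt(block_correlation) * matrix(shared, n, pd) +
        sqrt(1 - block_correlation) * matrix(rnorm(n * pd), n, pd)
      colnames(Xd) <- paste0(d, "_", seq_len(pd))
      cols[[d]] <- Xd
      labels <- c(labels, rep(d, pd))
    }
    X <- do.call(cbind, cols)
    sex <- rbinom(n, 1, 1 - prop_female)
    list(X = X, domains = stats::setNames(labels, colnames(X)), sex = sex)
  })
}

#' Default scaled-down domain feature counts
#'
#' Small per-domain counts used throughout the package's simulations: large
#' enough to carry planted signal plus a clear majority of null features,
#' small enough that a full nested cross-validation is fast. Full-scale
#' counts can be passed explicitly.
#' @return named integer vector of feature counts.
#' @export
default_domain_counts <- function() {
  c(environmental = 5, personality = 5, mental_health = 5,
    neurocognitive = 5, brain_structural = 5)
}

#' Effect specification for the liability generator
#'
#' Parameters of the linear-Gaussian latent liability model that drives the
#' ordinal use outcome and the dependence diagnosis:
#' \deqn{L = X\beta + \mathrm{sex}\,(X\gamma) + \beta_s\,\mathrm{sex} +
#'   f_{\mathrm{family}} + \varepsilon,}
#' with family effect \eqn{f \sim N(0, \sigma_f^2)} shared within family and
#' residual \eqn{\varepsilon \sim N(0, \sigma_e^2)}. The ordinal use
#' category (0, 1+, 10+, 100+, 1000+ lifetime uses) is obtained by
#' thresholding L at `tau[1] < ... < tau[4]`; dependence requires both
#' exceeding `tau_dep` and a use category of at least 2 (10+ uses), so no
#' one is dependent without relevant use. When thresholds are `NULL` they
#' are calibrated per cohort: the tau's from the empirical liability
#' quantiles matching `use_probs`, and `tau_dep` by bisection to the target
#' `prevalence`.
#'
#' @param beta named numeric vector of per-feature main-effect liability
#'   weights (missing features get 0).
#' @param gamma named numeric vector of per-feature sex-interaction weights
#'   (act only when sex = 1).
#' @param beta_sex main-effect weight of sex itself.
#' @param sigma_f family random-effect SD, non-negative.
#' @param sigma_e residual SD, positive.
#' @param tau optional fixed ordinal thresholds (length 4, increasing).
#' @param tau_dep optional fixed dependence threshold.
#' @param prevalence target dependence prevalence for calibration.
#' @param use_probs target probabilities of the five use categories
#'   (summing to 1) for threshold calibration.
#' @return object of class `"effect_spec"`.
#' @export
effect_spec <- function(beta = numeric(0), gamma = numeric(0), beta_sex = 0,
                        sigma_f = 0.5, sigma_e = 1, tau = NULL,
                        tau_dep = NULL, prevalence = 109 / 1204,
                        use_probs = c(550, 324, 144, 78, 108) / 1204) {
  stopifnot(sigma_f >= 0, sigma_e > 0, prevalence > 0, prevalence < 1)
  if (!is.null(tau)) {
    stopifnot(length(tau) == 4)
    if (any(diff(tau) <= 0)) stop("`tau` must be strictly increasing")
  }
  if (length(beta) && is.null(names(beta))) stop("`beta` must be named")
  if (length(gamma) && is.null(names(gamma))) stop("`gamma` must be named")
  stopifnot(length(use_probs) == 5, abs(sum(use_probs) - 1) < 1e-8)
  structure(list(beta = beta, gamma = gamma, beta_sex = beta_sex,
                 sigma_f = sigma_f, sigma_e = sigma_e, tau = tau,
                 tau_dep = tau_dep, prevalence = prevalence,
                 use_probs = use_probs),
            class = "effect_spec")
}

#' Documented default planted-effect specification
#'
#' The package's reference study condition: three moderate main-effect
#' features (one environmental, one mental-health, one neurocognitive), one
#' personality feature with a large sex-interaction weight (its liability
#' effect exists only in men), and a positive sex main effect sized so that
#' dependence cases are strongly male-skewed; every other feature is null.
#'
#' @return an [effect_spec()].
#' @export
default_effect_spec <- function() {
  effect_spec(
    beta = c(environmental_1 = 0.6, mental_health_1 = 0.6,
             neurocognitive_1 = 0.6),
    gamma = c(personality_1 = 1.2),
    beta_sex = 0.6,
    sigma_f = 0.5, sigma_e = 1
  )
}

#' Generate ordinal use and dependence outcomes from a liability model
#'
#' @param X feature matrix (columns named as in the effect spec).
#' @param sex 0/1 vector.
#' @param plan a [generate_families()] plan.
#' @param spec an [effect_spec()].
#' @param seed optional integer seed.
#' @return list with `use_category` (0..4), `dependence` (0/1), the latent
#'   `liability`, and the realized thresholds `tau` / `tau_dep`.
#' @export
generate_outcomes <- function(X, sex, plan, spec = default_effect_spec(),
                              seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"), inherits(plan, "family_plan"))
  n <- nrow(X)
  stopifnot(length(sex) == n, length(plan$family_id) == n)
  eta <- linear_term(X, spec$beta) + sex * linear_term(X, spec$gamma) +
    spec$beta_sex * sex
  with_seed(seed, {
    fam_eff <- spec$sigma_f * rnorm(length(plan$sizes))
    L <- eta + fam_eff[plan$family_id] + spec$sigma_e * rnorm(n)
    tau <- spec$tau %||%
      unname(quantile(L, cumsum(spec$use_probs)[1:4], type = 1))
    use_category <- rowSums(outer(L, tau, ">"))
    tau_dep <- spec$tau_dep %||%
      calibrate_tau_dep(L, use_category, spec$prevalence)
    dependence <- as.integer(L > tau_dep & use_category >= 2)
    list(use_category = as.integer(use_category), dependence = dependence,
         liability = L, tau = tau, tau_dep = tau_dep)
  })
}

linear_term <- function(X, w) {
  if (!length(w)) return(numeric(nrow(X)))
  missing_cols <- setdiff(names(w), colnames(X))
  if (length(missing_cols))
    stop("effect refers to absent feature(s): ",
         paste(missing_cols, collapse = ", "))
  Xs <- X[, names(w), drop = FALSE]
  all_missing <- colSums(!is.na(Xs)) == 0
  if (any(all_missing & w != 0))
    stop("nonzero effect on an all-missing feature: ",
         paste(names(w)[all_missing & w != 0], collapse = ", "))
  Xs[is.na(Xs)] <- 0
  drop(Xs %*% w)
}

# Bisection on the realized prevalence of L > tau among those with use
# category >= 2; tolerance half a percentage point, at most 50 iterations.
calibrate_tau_dep <- function(L, use_category, target, tol = 0.005,
                              max_iter = 50) {
  eligible <- use_category >= 2
  lo <- min(L) - 1
  hi <- max(L) + 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    prev <- mean(L > mid & eligible)
    if (abs(prev - target) <= tol / 2) break
    if (prev > target) lo <- mid else hi <- mid
  }
  mid
}

#' Inject missing values into a feature matrix
#'
#' @param X feature matrix.
#' @param rate per-feature missingness probability in \[0, 1) (recycled
#'   across features).
#' @param mechanism `"MCAR"` for completely-at-random, or `"outcome"` to add
#'   `offset` to the rate for rows with `y == 1`.
#' @param y binary outcome, required for the `"outcome"` mechanism.
#' @param offset additional missingness probability for cases under the
#'   `"outcome"` mechanism.
#' @param seed optional integer seed.
#' @return `X` with `NA` entries injected.
#' @export
inject_missingness <- function(X, rate = 0.05, mechanism = c("MCAR", "outcome"),
                               y = NULL, offset = 0, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (any(rate < 0) || any(rate >= 1)) stop("`rate` must be in [0, 1)")
  rate <- rep_len(rate, ncol(X))
  if (all(rate == 0) && offset == 0) return(X)
  if (mechanism == "outcome") {
    if (is.null(y)) stop("`y` is required for outcome-dependent missingness")
    stopifnot(length(y) == nrow(X))
  }
  with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      pr <- rep(rate[j], nrow(X))
      if (mechanism == "outcome") pr <- pmin(pr + offset * (y == 1), 0.99)
      X[runif(nrow(X)) < pr, j] <- NA
    }
    X
  })
}

#' Generate per-subject block-structured connectivity matrices
#'
#' Each subject's matrix is a common modular template (entries `within_r`
#' inside a community, `between_r` across communities) plus independent
#' symmetric Gaussian subject noise, clipped to (-1, 1), with unit
#' diagonal.
#'
#' @param n_subjects number of subjects.
#' @param n_nodes number of nodes, at least 4.
#' @param module_assignment integer/factor community label per node;
#'   defaults to two equal communities.
#' @param within_r,between_r template correlations, `-1 < between_r <=
#'   within_r < 1`.
#' @param subject_noise_sd SD of the per-subject noise on the upper
#'   triangle.
#' @param seed optional integer seed.
#' @return object of class `"connectome_stack"`: list with `matrices` (list
#'   of symmetric matrices), `module` (node community labels).
#' @export
generate_connectomes <- function(n_subjects, n_nodes,
                                 module_assignment = NULL, within_r = 0.6,
                                 between_r = 0.1, subject_noise_sd = 0.05,
                                 seed = NULL) {
  stopifnot(n_subjects >= 1)
  if (n_nodes < 4) stop("`n_nodes` must be at least 4")
  if (!(between_r > -1 && between_r <= within_r && within_r < 1))
    stop("need -1 < between_r <= within_r < 1")
  module_assignment <- module_assignment %||%
    rep(1:2, length.out = n_nodes)
  stopifnot(length(module_assignment) == n_nodes)
  same <- outer(module_assignment, module_assignment, "==")
  template <- ifelse(same, within_r, between_r)
  diag(template) <- 1
  mats <- with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    M <- template
    if (subject_noise_sd > 0) {
      noise <- matrix(0, n_nodes, n_nodes)
      ut <- upper.tri(noise)
      noise[ut] <- rnorm(sum(ut), sd = subject_noise_sd)
      noise <- noise + t(noise)
      M <- M + noise
    }
    M[M >= 1] <- 0.999
    M[M <= -1] <- -0.999
    diag(M) <- 1
    dimnames(M) <- list(paste0("node_", seq_len(n_nodes)),
                        paste0("node_", seq_len(n_nodes)))
    M
  }))
  structure(list(matrices = mats, module = module_assignment),
            class = "connectome_stack")
}

#' @export
print.connectome_stack <- function(x, ...) {
  cat(sprintf("Connectome stack: %d subjects, %d nodes, %d communities\n",
              length(x$matrices), nrow(x$matrices[[1]]),
              length(unique(x$module))))
  invisible(x)
}

#' Simulate a complete cohort
#'
#' End-to-end cohort generator: family plan, correlated domain features and
#' sex, liability-driven ordinal use and dependence outcomes, and injected
#' missingness. This is the single object every downstream stage of the
#' package consumes.
#'
#' @param n participants.
#' @param mean_family_size,max_family_size see [generate_families()].
#' @param p_per_domain,block_correlation,prop_female see
#'   [generate_features()].
#' @param spec an [effect_spec()]; the default is the documented planted
#'   specification [default_effect_spec()].
#' @param missing_rate,missing_mechanism,missing_offset see
#'   [inject_missingness()] (outcome-dependent missingness keys on
#'   dependence).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return a data frame of class `"cohort"` with columns `participant_id`,
#'   `family_id`, `sex` (0 = woman, 1 = man), `use_category` (0..4 coding
#'   0/1+/10+/100+/1000+ lifetime uses), `dependence` (0/1) and the feature
#'   columns; attributes `domains`, `spec`, `liability`, `tau`, `tau_dep`.
#' @examples
#' coh <- simulate_cohort(n = 300, seed = 1)
#' mean(coh$dependence)
#' @export
simulate_cohort <- function(n = 1204, mean_family_size = 2,
                            max_family_size = 5,
                            p_per_domain = default_domain_counts(),
                            block_correlation = 0.3, prop_female = 0.54,
                            spec = default_effect_spec(),
                            missing_rate = 0.05,
                            missing_mechanism = "MCAR",
                            missing_offset = 0, seed = NULL) {
  seeds <- derive_seeds(seed, 4)
  plan <- generate_families(n, mean_family_size, max_family_size, seeds[[1]])
  feats <- generate_features(plan, p_per_domain, block_correlation,
                             prop_female, seeds[[2]])
  out <- generate_outcomes(feats$X, feats$sex, plan, spec, seeds[[3]])
  X <- inject_missingness(feats$X, missing_rate, missing_mechanism,
                          y = out$dependence, offset = missing_offset,
                          seed = seeds[[4]])
  cohort <- data.frame(participant_id = seq_len(n),
                       family_id = plan$family_id, sex = feats$sex,
                       use_category = out$use_category,
                       dependence = out$dependence)
  cohort <- cbind(cohort, as.data.frame(X))
  structure(cohort, domains = feats$domains, spec = spec,
            liability = out$liability, tau = out$tau, tau_dep = out$tau_dep,
            class = c("cohort", "data.frame"))
}

# Deterministic child seeds below 2^31 derived from one user seed.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list((as.double(seed) * 7919 + 104729 * seq_len(k)) %% 2147483647)
}

#' Feature columns of a cohort
#' @param cohort a [simulate_cohort()] cohort (or compatible data frame).
#' @param include_sex prepend the sex column as an ordinary feature (the
#'   analysis treats sex as a feature).
#' @return numeric feature matrix.
#' @export
cohort_features <- function(cohort, include_sex = TRUE) {
  meta <- c("participant_id", "family_id", "sex", "use_category", "dependence")
  X <- as.matrix(cohort[, setdiff(colnames(cohort), meta), drop = FALSE])
  if (include_sex) X <- cbind(sex = cohort$sex, X)
  X
}
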