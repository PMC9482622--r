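#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. The
#' defaults reproduce the package's reference simulation: a 1204-participant
#' family-structured cohort with the documented planted effects, all five
#' binary outcomes, and the reduced hyperparameter grid.
#'
#' @param n participants.
#' @param p_per_domain named feature counts per domain.
#' @param block_correlation,prop_female,mean_family_size,missing_rate cohort
#'   generator settings (see [simulate_cohort()]).
#' @param spec an [effect_spec()].
#' @param outcomes subset of `c("use1plus", "use10plus", "use100plus",
#'   "use1000plus", "dependence")`.
#' @param grid `"reduced"`, `"default"`, or a hyperparameter data frame.
#' @param k folds for both CV loops.
#' @param nrounds,early_stopping_rounds boosting limits.
#' @param seed master seed; every stage derives its stream from it.
#' @return a named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n = 1204, p_per_domain = default_domain_counts(),
                            block_correlation = 0.3, prop_female = 0.54,
                            mean_family_size = 2, missing_rate = 0.05,
                            spec = default_effect_spec(),
                            outcomes = c("use1plus", "use10plus", "use100plus",
                                         "use1000plus", "dependence"),
                            grid = "reduced", k = 5, nrounds = 300,
                            early_stopping_rounds = 30, seed = 1) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  structure(list(n = n, p_per_domain = p_per_domain,
                 block_correlation = block_correlation,
                 prop_female = prop_female,
                 mean_family_size = mean_family_size,
                 missing_rate = missing_rate, spec = spec,
                 outcomes = outcomes, grid = grid, k = k, nrounds = nrounds,
                 early_stopping_rounds = early_stopping_rounds, seed = seed),
            class = "pipeline_config")
}

resolve_grid <- function(grid) {
  if (is.data.frame(grid)) return(grid)
  switch(grid, reduced = reduced_grid(), default = default_grid(),
         stop("unknown grid `", grid, "`"))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, fits family-blocked nested cross-validation models
#' for each configured binary outcome, explains every outer-fold model on
#' its held-out rows, and aggregates: per-outcome AUC tables, cross-model
#' median ranks over all fitted models, and the sex-interaction report for
#' the clinically focal outcomes (dependence and 1000+ uses, when
#' configured). When `out_dir` is given, all artifacts are written as
#' delimited text plus a JSON run manifest from which the run can be
#' reproduced byte-identically with [run_from_manifest()].
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `cohort`, per-outcome `cv` results, `auc` table,
#'   `median_rank` table, `sex_report`, and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  grid <- resolve_grid(config$grid)
  cohort <- simulate_cohort(
    n = config$n, mean_family_size = config$mean_family_size,
    p_per_domain = config$p_per_domain,
    block_correlation = config$block_correlation,
    prop_female = config$prop_female, spec = config$spec,
    missing_rate = config$missing_rate, seed = config$seed)
  x <- cohort_features(cohort)
  labels <- binarize_outcomes(cohort$use_category, cohort$dependence)

  cv <- list()
  explained <- list()
  importances <- list()
  auc_rows <- list()
  for (oi in seq_along(config$outcomes)) {
    oc <- config$outcomes[oi]
    y <- labels[[oc]]
    cv_seed <- (config$seed * 37 + oi * 1009) %% 2147483647
    cv[[oc]] <- nested_cv(x, y, cohort$family_id, grid = grid, k = config$k,
                          seed = cv_seed, nrounds = config$nrounds,
                          early_stopping_rounds = config$early_stopping_rounds)
    explained[[oc]] <- explain_models(cv[[oc]], x)
    for (fi in seq_along(explained[[oc]]))
      importances[[paste(oc, fi, sep = "_fold")]] <-
        global_importance(explained[[oc]][[fi]]$phi)
    auc_rows[[oc]] <- data.frame(outcome = oc, fold = seq_len(config$k),
                                 auc = cv[[oc]]$outer_auc,
                                 cv[[oc]]$selected)
  }
  auc <- do.call(rbind, auc_rows)
  rownames(auc) <- NULL
  ranks <- median_rank(importances)
  focal <- intersect(c("dependence", "use1000plus"), config$outcomes)
  if (length(focal) == 0) focal <- config$outcomes
  sex_report <- sex_interaction_report(do.call(c, explained[focal]))

  manifest <- list(
    schema = "shapboost-run/1",
    package_version = as.character(utils::packageVersion("shapboost")),
    config = serialize_config(config),
    fold_plans = lapply(cv, `[[`, "folds"),
    selected = lapply(cv, function(z) z$selected),
    artifacts = if (is.null(out_dir)) NULL else
      c("cohort.csv", "auc.csv", "median_rank.csv", "sex_report.csv",
        "manifest.json")
  )
  result <- list(cohort = cohort, cv = cv, auc = auc, median_rank = ranks,
                 sex_report = sex_report, manifest = manifest)
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  spec <- unclass(cfg$spec)
  # named atomic vectors serialize as JSON arrays; lists keep their names
  spec$beta <- as.list(spec$beta)
  spec$gamma <- as.list(spec$gamma)
  cfg$spec <- spec
  cfg$p_per_domain <- as.list(cfg$p_per_domain)
  cfg$grid <- if (is.data.frame(cfg$grid)) list(custom = cfg$grid) else cfg$grid
  cfg
}

deserialize_config <- function(cfg) {
  spec <- cfg$spec
  cfg$spec <- effect_spec(beta = unlist(spec$beta), gamma = unlist(spec$gamma),
                          beta_sex = spec$beta_sex, sigma_f = spec$sigma_f,
                          sigma_e = spec$sigma_e,
                          tau = if (length(spec$tau)) unlist(spec$tau),
                          tau_dep = spec$tau_dep,
                          prevalence = spec$prevalence,
                          use_probs = unlist(spec$use_probs))
  if (is.list(cfg$grid) && !is.null(cfg$grid$custom))
    cfg$grid <- do.call(rbind, lapply(cfg$grid$custom, as.data.frame))
  cfg$p_per_domain <- unlist(cfg$p_per_domain)
  cfg$outcomes <- unlist(cfg$outcomes)
  do.call(pipeline_config, cfg[setdiff(names(cfg), character(0))])
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(out_dir, "cohort.csv"))
  write.csv(result$auc, file.path(out_dir, "auc.csv"), row.names = FALSE)
  write.csv(result$median_rank, file.path(out_dir, "median_rank.csv"),
            row.names = FALSE)
  write.csv(result$sex_report, file.path(out_dir, "sex_report.csv"),
            row.names = FALSE)
  writeLines(jsonlite::toJSON(result$manifest, digits = I(17),
                              auto_unbox = TRUE, null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Re-run a pipeline from its manifest
#'
#' Reads a run manifest written by [run_pipeline()] and re-executes the
#' pipeline with the recorded configuration; given the recorded seeds, the
#' outputs are bit-identical to the original run.
#'
#' @param manifest_path path to `manifest.json`.
#' @param out_dir optional output directory for the re-run's artifacts.
#' @return the [run_pipeline()] result.
#' @export
run_from_manifest <- function(manifest_path, out_dir = NULL) {
  manifest <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  if (!identical(manifest$schema, "shapboost-run/1"))
    stop("unrecognized manifest schema")
  run_pipeline(deserialize_config(manifest$config), out_dir = out_dir)
}

#' Generate the miniature fixture bundle
#'
#' Writes a deterministic miniature dataset used by the test suite: a
#' 120-participant cohort with the documented planted effects and injected
#' missingness, a 3-subject connectome stack, and a JSON file of summary
#' values recorded at generation time.
#'
#' @param dir output directory.
#' @param seed integer seed (the shipped fixtures use 20260901).
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(dir, seed = 20260901) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n = 120, mean_family_size = 2,
                            p_per_domain = c(environmental = 3,
                                             personality = 3,
                                             mental_health = 3,
                                             neurocognitive = 3),
                            missing_rate = 0.08, seed = seed)
  write_cohort(cohort, file.path(dir, "cohort.csv"))
  stack <- generate_connectomes(3, 12, rep(1:3, each = 4), seed = seed + 1)
  write_connectomes(stack, file.path(dir, "connectomes"))
  expected <- list(
    n = nrow(cohort),
    prevalence = mean(cohort$dependence),
    n_missing = sum(is.na(cohort_features(cohort, include_sex = FALSE))),
    use_counts = as.integer(table(factor(cohort$use_category, levels = 0:4)))
  )
  writeLines(jsonlite::toJSON(expected, digits = NA, auto_unbox = TRUE),
             file.path(dir, "expected.json"))
  invisible(dir)
}
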