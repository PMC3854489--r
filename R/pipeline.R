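#' Run configuration
#'
#' Validated key-value configuration tying the pipeline together. Defaults
#' reproduce the task's design constants; unknown keys are rejected.
#'
#' @param ... overrides for any of the documented keys: `family`,
#'   `n_subjects`, `n_trials`, `params` (see [cohort_spec()]), `rt_base`,
#'   `rt_effect`, `rt_sd`, `seed`, `n_restarts`, `hessian_step`, `alpha`,
#'   `n_perm`, `min_node`, `n_samples`, plus task constants `p_common`,
#'   `p_high`, `p_low`, `p_reset`, `break_after`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(family = "hier", n_subjects = 15L, n_trials = 270L,
                   params = "fixed", rt_base = 0.5, rt_effect = 0.3,
                   rt_sd = 0.1, seed = 1L, n_restarts = 10L,
                   hessian_step = 1e-4, alpha = 0.05, n_perm = 9999L,
                   min_node = 40L, n_samples = 1e5L,
                   p_common = 0.7, p_high = 0.7, p_low = 0.2,
                   p_reset = 1 / 7, break_after = 120L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, overrides)
  class(cfg) <- "run_config"
  cfg
}

config_task <- function(config) {
  task_config(p_common = config$p_common, p_high = config$p_high,
              p_low = config$p_low, p_reset = config$p_reset,
              n_trials = config$n_trials,
              break_after = config$break_after)
}

# short stable fingerprint of a configuration, for run logs
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_run <- function(what, config) {
  message(sprintf("[hierseq %s] %s: config %s, seed %d",
                  as.character(utils::packageVersion("hierseq")), what,
                  config_hash(config), config$seed))
}

#' Generate and write a synthetic cohort
#'
#' @param config a [run_config()].
#' @param out_dir directory for `sessions.csv` and `sessions.truth.json`.
#' @return list with the cohort and the written paths, invisibly.
#' @export
run_simulate <- function(config = run_config(), out_dir = ".") {
  log_run("simulate", config)
  spec <- cohort_spec(family = config$family, params = config$params,
                      n_subjects = config$n_subjects,
                      n_trials = config$n_trials, rt_base = config$rt_base,
                      rt_effect = config$rt_effect, rt_sd = config$rt_sd,
                      seed = config$seed)
  cohort <- generate_cohort(spec)
  csv <- file.path(out_dir, "sessions.csv")
  truth <- file.path(out_dir, "sessions.truth.json")
  write_sessions(cohort$sessions, csv)
  jsonlite::write_json(cohort$truth, truth, auto_unbox = TRUE, digits = 10)
  invisible(list(cohort = cohort, csv = csv, truth = truth))
}

#' Fit both model families to every subject
#'
#' Fits all 16 models (8 flat, 8 hierarchical) per subject and writes the
#' log-evidence matrix as CSV plus per-fit summaries as JSON.
#'
#' @param config a [run_config()].
#' @param data sessions (path to a CSV, a data.frame, or a list).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param specs model list override (default: both full families).
#' @return list with `evidence`, `pseudo_r2`, `fits`.
#' @export
run_fit <- function(config = run_config(), data, out_dir = NULL,
                    specs = c(build_flat_family(), build_hier_family())) {
  log_run("fit", config)
  sessions <- if (is.character(data)) read_sessions(data)
              else as_dataset(data)
  res <- fit_dataset(sessions, specs, n_restarts = config$n_restarts,
                     seed = config$seed, cfg = config_task(config))
  if (!is.null(out_dir)) {
    write.csv(res$evidence, file.path(out_dir, "evidence.csv"))
    summaries <- lapply(res$fits, function(sub)
      lapply(sub, function(f)
        list(model = f$spec$name, params = as.list(f$params),
             loglik = f$loglik, log_evidence = f$log_evidence,
             pseudo_r2 = pseudo_r2(f), seed = f$seed)))
    jsonlite::write_json(summaries, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  res
}

#' Compare fitted models and families
#'
#' Runs model-level BMS and the flat-vs-hierarchical family comparison on a
#' log-evidence matrix.
#'
#' @param evidence matrix or path to the CSV written by [run_fit()].
#' @param partition family per model column; default derives it from the
#'   model-name prefix.
#' @param config a [run_config()] (seed, sample count).
#' @param out_path optional JSON report path.
#' @return list with `bms` and `families`.
#' @export
run_compare <- function(evidence, partition = NULL,
                        config = run_config(), out_path = NULL) {
  log_run("compare", config)
  if (is.character(evidence))
    evidence <- as.matrix(read.csv(evidence, row.names = 1,
                                   check.names = FALSE))
  if (is.null(partition))
    partition <- sub("\\[.*", "", colnames(evidence))
  fam <- family_bms(evidence, partition, n_samples = config$n_samples,
                    seed = config$seed)
  report <- list(model_exceedance = as.list(fam$models$exceedance),
                 best_model_counts = as.list(fam$models$best_model_counts),
                 family_exceedance = as.list(fam$exceedance),
                 family_expected_freq = as.list(fam$expected_freq),
                 seed = config$seed)
  if (!is.null(out_path))
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = 10)
  list(bms = fam$models, families = fam, report = report)
}

#' Run the behavioral analysis battery
#'
#' Stay tables and regressions in all four modes, the RT contrast, and the
#' recursive partition of second-stage stays.
#'
#' @param data sessions (path, data.frame, or list).
#' @param config a [run_config()] (alpha, permutations, seed).
#' @param out_dir optional output directory for the JSON report and the
#'   tree text.
#' @return list of results.
#' @export
run_analyze <- function(data, config = run_config(), out_dir = NULL) {
  log_run("analyze", config)
  sessions <- if (is.character(data)) read_sessions(data)
              else as_dataset(data)
  if (length(sessions) == 0L) stopf("empty dataset")
  modes <- c("first_stage", "second_diff_machine",
             "second_same_vs_diff_same_a1", "second_same_vs_diff_diff_a1")
  tables <- lapply(modes, function(m) stay_table(sessions, m))
  regs <- lapply(modes, function(m) stay_regression(sessions, m))
  names(tables) <- names(regs) <- modes
  rts <- tryCatch(rt_contrast(sessions), warning = function(w) {
    message(conditionMessage(w)); NULL
  })
  have_rt <- any(vapply(sessions,
                        function(s) any(!is.na(s$rt2)), logical(1)))
  tree <- if (have_rt)
    partition_tree(sessions, alpha = config$alpha,
                   min_node = config$min_node, n_perm = config$n_perm,
                   seed = config$seed)
  else NULL
  if (!is.null(out_dir)) {
    report <- list(
      stay_tables = lapply(tables, function(t) t$cells),
      regressions = lapply(regs, function(r) r$coefficients),
      rt_contrast = if (!is.null(rts))
        list(rewarded = rts$rewarded[c("estimate", "se", "p")],
             unrewarded = rts$unrewarded[c("estimate", "se", "p")]),
      seed = config$seed)
    jsonlite::write_json(report, file.path(out_dir, "behavior.json"),
                         auto_unbox = TRUE, digits = 10)
    if (!is.null(tree))
      writeLines(format_partition(tree), file.path(out_dir, "tree.txt"))
  }
  list(stay_tables = tables, regressions = regs, rt_contrast = rts,
       tree = tree)
}

#' Parameter- and model-recovery harness
#'
#' Simulates cohorts from each family's full model, refits both families,
#' and reports whether the generating family wins the family comparison,
#' plus rank correlations between true and recovered parameters.
#'
#' @param config a [run_config()].
#' @param n_subjects,n_trials recovery cohort dimensions (defaults follow
#'   the config).
#' @param specs models to fit per family (defaults to each family's full
#'   model, which is sufficient for family-level recovery).
#' @return list with per-family recovery results.
#' @export
run_recover <- function(config = run_config(), n_subjects = config$n_subjects,
                        n_trials = config$n_trials,
                        specs = list(flat = build_flat_family()[[1]],
                                     hier = build_hier_family()[[1]])) {
  log_run("recover", config)
  out <- list()
  for (fam in c("flat", "hier")) {
    cs <- cohort_spec(family = fam, params = "prior",
                      n_subjects = n_subjects, n_trials = n_trials,
                      seed = config$seed)
    cohort <- generate_cohort(cs)
    fitres <- fit_dataset(cohort$sessions, unname(specs),
                          n_restarts = config$n_restarts,
                          seed = config$seed,
                          cfg = task_config(n_trials = n_trials))
    fb <- family_bms(fitres$evidence, names(specs),
                     n_samples = config$n_samples, seed = config$seed)
    out[[fam]] <- list(family_exceedance = fb$exceedance,
                       generating_wins =
                         names(which.max(fb$exceedance)) == fam,
                       evidence = fitres$evidence)
  }
  out
}
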