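# End-to-end orchestration: trial generation -> synthetic cohort ->
# preprocessing -> cross-validated model comparison -> accuracy-group
# analysis, with a deterministic run manifest.

#' Build a pipeline run configuration
#'
#' Every stochastic stage carries an explicit seed derived from
#' `rng_seed`; runs with identical configs are byte-reproducible.
#' Defaults are desk-scale (small fold/split counts); the full-scale
#' analysis uses 200 folds and 1000 random splits.
#'
#' @param experiment "exp1" or "exp2".
#' @param out_dir output directory for the stage artifacts.
#' @param n_participants synthetic cohort size.
#' @param orientation_group trial-list group (complex task).
#' @param variants character vector of variant names from
#'   [make_variant_lattice()], or a list of [variant_spec()] objects.
#' @param n_folds,test_size cross-validation settings (`test_size`
#'   defaults to 40% of the cohort, the complex-task split).
#' @param n_starts random starts per fit.
#' @param n_splits random splits for the group baseline.
#' @param artifact_rates named list with `timeout`, `wrong_start`,
#'   `wander` rates for the generator.
#' @param max_starts cap on optimizer runs per fit.
#' @param quadrature `c(n_hermite, n_legendre)` quadrature node counts.
#' @param control `nlminb` control list for all fits.
#' @param rng_seed master seed.
#' @return `run_config` list.
#' @export
run_config <- function(experiment = c("exp1", "exp2"), out_dir,
                       n_participants = 12L, orientation_group = "horizontal",
                       variants = NULL, n_folds = 5L, test_size = NULL,
                       n_starts = 2L, n_splits = 20L,
                       artifact_rates = list(timeout = 0.01,
                                             wrong_start = 0.01,
                                             wander = 0.01),
                       max_starts = 6L, quadrature = c(31L, 16L),
                       control = list(eval.max = 300, iter.max = 200,
                                      rel.tol = 1e-6),
                       rng_seed = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(rng_seed))
    stop("validation error: the run config requires an explicit seed",
         call. = FALSE)
  if (is.null(test_size)) test_size <- max(2L, round(0.4 * n_participants))
  if (is.null(variants)) {
    variants <- if (experiment == "exp1") c("equal_w_var", "diff_w_var")
                else c("baseline", "gd", "gd_proportional")
  }
  structure(list(experiment = experiment, out_dir = out_dir,
                 n_participants = as.integer(n_participants),
                 orientation_group = orientation_group, variants = variants,
                 n_folds = as.integer(n_folds),
                 test_size = as.integer(test_size),
                 n_starts = as.integer(n_starts),
                 n_splits = as.integer(n_splits),
                 artifact_rates = artifact_rates,
                 max_starts = as.integer(max_starts),
                 quadrature = as.integer(quadrature), control = control,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: trial-list generation, cohort simulation,
#' preprocessing (exclusions + standardization), Monte-Carlo
#' cross-validated model comparison, and the accuracy-group analysis with
#' its random-split baseline. Each stage writes its artifact under
#' `config$out_dir`; a manifest records inputs, seeds and output hashes.
#' A stage failure aborts with a stage-tagged error after writing a
#' partial manifest.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  manifest <- list(config = unclass(config), stages = list())
  say <- function(...) if (!quiet) message(...)
  finish_stage <- function(stage, fs) {
    files <<- c(files, fs)
    manifest$stages[[stage]] <<- fs
  }
  run_stage <- function(stage, expr) {
    say("[", stage, "]")
    tryCatch(expr, error = function(e) {
      manifest$status <- paste0("failed at stage: ", stage)
      jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
      stop("stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # 1. trials
  layouts <- run_stage("generate-trials", {
    ls <- if (config$experiment == "exp1") enumerate_base_trials("exp1")
          else c(enumerate_base_trials("exp2", config$orientation_group),
                 enumerate_subgoal_trials(config$orientation_group))
    write_trials(ls, pth("trials.csv"))
    ls
  })
  finish_stage("generate_trials", "trials.csv")

  # 2. synthetic cohort
  obs <- run_stage("simulate", {
    pc <- population_config(config$experiment, config$n_participants,
                            timeout_rate = config$artifact_rates$timeout,
                            wrong_start_rate = config$artifact_rates$wrong_start,
                            wander_rate = config$artifact_rates$wander,
                            rng_seed = config$rng_seed)
    o <- simulate_experiment(sample_population(pc), layouts, pc)
    utils::write.csv(o, pth("observations.csv"), row.names = FALSE)
    o
  })
  finish_stage("simulate", "observations.csv")

  # 3. preprocessing
  prep <- run_stage("preprocess", {
    p <- preprocess_observations(obs, layouts, config$experiment)
    utils::write.csv(p$data, pth("clean.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(p$report), pth("exclusion_report.json"),
                         auto_unbox = TRUE)
    p
  })
  finish_stage("preprocess", c("clean.csv", "exclusion_report.json"))

  # 4. cross-validated model comparison
  comparison <- run_stage("cv-compare", {
    lattice <- make_variant_lattice(config$experiment)
    variants <- if (is.character(config$variants)) lattice[config$variants]
                else config$variants
    data <- make_ddm_data(prep$data)
    folds <- make_folds(unique(data$participant_id), config$n_folds,
                        config$test_size, config$rng_seed + 10L)
    quad <- ddm_quadrature(config$quadrature[1], config$quadrature[2])
    tab <- cross_validate(data, variants, folds, n_starts = config$n_starts,
                          rng_seed = config$rng_seed + 11L, warm_start = TRUE,
                          max_starts = config$max_starts, quad = quad,
                          control = config$control)
    utils::write.csv(tab[, setdiff(names(tab), "params")], pth("folds.csv"),
                     row.names = FALSE)
    cmp <- compare_models(tab)
    jsonlite::write_json(list(winner = cmp$winner, rationale = cmp$rationale,
                              means = as.list(cmp$means),
                              n_folds = cmp$n_folds),
                         pth("comparison.json"), auto_unbox = TRUE)
    list(cmp = cmp, data = data,
         winner_spec = variants[[cmp$winner]])
  })
  finish_stage("cv_compare", c("folds.csv", "comparison.json"))

  # 5. accuracy groups + random-split baseline
  run_stage("groups", {
    groups <- median_split(participant_summaries(prep$data))
    quad <- ddm_quadrature(config$quadrature[1], config$quadrature[2])
    fits <- fit_accuracy_groups(comparison$data, groups,
                                comparison$winner_spec, mode = "full",
                                n_starts = config$n_starts,
                                max_starts = config$max_starts,
                                rng_seed = config$rng_seed + 12L,
                                quad = quad, control = config$control)
    observed <- weight_ratio(fits$high$params) - weight_ratio(fits$low$params)
    split <- random_split_baseline(
      comparison$data,
      group_sizes = c(sum(groups$accuracy_group == "high"),
                      sum(groups$accuracy_group == "low")),
      n_splits = config$n_splits, observed = observed,
      variant = comparison$winner_spec, n_starts = config$n_starts,
      rng_seed = config$rng_seed + 13L, quad = quad,
      control = config$control)
    jsonlite::write_json(unclass(split), pth("splits.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(groups, pth("groups.csv"), row.names = FALSE)
  })
  finish_stage("groups", c("splits.json", "groups.csv"))

  manifest$status <- "complete"
  manifest$hashes <- as.list(tools::md5sum(vapply(files, pth, character(1))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  say("pipeline complete: ", config$out_dir)
  invisible(manifest)
}
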