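# Synthetic cohorts with the statistical structure the analysis assumes:
# per-participant diffusion parameters drawn around the fitted population
# values, choices/RTs simulated from the forward diffusion process over
# the designed trial lists, and optional planted artifacts that trigger
# each exclusion rule.

#' Population configuration for synthetic cohorts
#'
#' Defaults center the per-participant diffusion parameters on the winning
#' fitted estimates of each experiment (myopic/future weight ratio 1.13 in
#' the simple task; in the complex task, subgoal-condition weights 1.27
#' and 1.04 arising from a 30% proportional decrease, goal weight 0.31),
#' with modest between-participant variability. Generated response times
#' live directly on the standardized scale, with the non-decision time
#' below the 0.5 floor; an affine per-participant map to seconds supports
#' end-to-end standardization tests.
#'
#' @param experiment "exp1" or "exp2".
#' @param n_participants cohort size.
#' @param means,sds named numeric vectors overriding individual parameter
#'   population means / SDs (names among t0, a, z, md, fd, sz, sd, gd, p).
#' @param timeout_rate,wrong_start_rate,wander_rate artifact rates in
#'   `[0, 1]` (at most one artifact is planted per trial).
#' @param rng_seed integer seed.
#' @return `population_config` list.
#' @export
population_config <- function(experiment = c("exp1", "exp2"),
                              n_participants = 40L, means = NULL, sds = NULL,
                              timeout_rate = 0, wrong_start_rate = 0,
                              wander_rate = 0, rng_seed = 1L) {
  experiment <- match.arg(experiment)
  m <- if (experiment == "exp1") {
    c(t0 = 0.35, a = 1.2, z = 0, md = 1.695, fd = 1.5, sz = 0.3, sd = 0.8,
      gd = 0, p = 1)
  } else {
    c(t0 = 0.35, a = 1.2, z = 0, md = 1.27 / 0.7, fd = 1.04 / 0.7, sz = 0.3,
      sd = 0.8, gd = 0.31, p = 0.7)
  }
  s <- c(t0 = 0.03, a = 0.1, z = 0, md = 0.15, fd = 0.15, sz = 0.05,
         sd = 0.1, gd = if (experiment == "exp1") 0 else 0.06,
         p = if (experiment == "exp1") 0 else 0.02)
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  stopifnot(all(s >= 0),
            all(c(timeout_rate, wrong_start_rate, wander_rate) >= 0),
            timeout_rate + wrong_start_rate + wander_rate <= 1)
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 means = m, sds = s, timeout_rate = timeout_rate,
                 wrong_start_rate = wrong_start_rate,
                 wander_rate = wander_rate, rng_seed = as.integer(rng_seed)),
            class = "population_config")
}

#' Draw per-participant diffusion parameters
#'
#' Truncated-normal draws (by rejection) respecting the parameter
#' invariants: positive bound, non-negative times and variabilities,
#' `|z| + sz/2 < a`, positive proportional multiplier. Reproducible under
#' the config seed.
#'
#' @param config a [population_config()].
#' @return data frame, one row per participant, with the parameter columns
#'   and the per-participant seconds map (`sec_intercept`, `sec_slope`).
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  m <- config$means; s <- config$sds
  ok <- function(th) {
    th[["a"]] > 0.1 && th[["t0"]] >= 0 && th[["sz"]] >= 0 && th[["sd"]] >= 0 &&
      th[["md"]] > 0 && th[["fd"]] > 0 && th[["p"]] > 0 &&
      abs(th[["z"]]) + th[["sz"]] / 2 < th[["a"]]
  }
  if (!ok(m))
    stop("config error: population means violate the parameter invariants",
         call. = FALSE)
  withr::with_seed(config$rng_seed, {
    rows <- lapply(seq_len(config$n_participants), function(i) {
      for (attempt in 1:1000) {
        th <- stats::rnorm(length(m), m, s)
        names(th) <- names(m)
        if (ok(th)) break
        if (attempt == 1000)
          stop("config error: truncation region infeasible", call. = FALSE)
      }
      c(participant_id = NA, as.list(th),
        sec_intercept = stats::rnorm(1, 0.3, 0.05),
        sec_slope = max(0.3, stats::rnorm(1, 0.8, 0.1)))
    })
    df <- do.call(rbind, lapply(rows, as.data.frame))
    df$participant_id <- sprintf("P%03d", seq_len(nrow(df)))
    df
  })
}

# Per-layout constants needed repeatedly during simulation.
layout_sim_info <- function(layouts) {
  lapply(layouts, function(lay) {
    adv <- compute_advantages(lay)
    m <- adv[["myopic"]]; f <- adv[["future"]]
    can <- canonicalize(lay)
    goal_dir <- if (lay$condition == "subgoal") {
      if (can$goal_end == "upper") 1L else -1L
    } else 0L
    list(layout = lay, m = m, f = f, goal_dir = goal_dir,
         trial_type = classify_trial(adv),
         lens = main_candidate_lengths(lay),
         actions_up = shortest_actions(lay, "upper"),
         actions_down = shortest_actions(lay, "lower"))
  })
}

#' Simulate a synthetic cohort over a trial list
#'
#' One observation per participant x trial, in the observation CSV schema
#' consumed by preprocessing (displayed-frame action strings, raw seconds),
#' plus generator ground truth: the standardized-scale RT, the diffusion
#' choice coding, the goal side indicator, and the planted-artifact label.
#' The drift on each trial combines the signed advantages with the
#' participant's weights (scaled by `p`, plus the goal weight, in the
#' subgoal condition). Filler layouts are not simulated.
#'
#' @param population data frame from [sample_population()].
#' @param layouts list of [trial_layout()] objects (base and/or subgoal).
#' @param config a [population_config()] (artifact rates and seed).
#' @param dt,max_t forward-simulation settings.
#' @return observation data frame.
#' @export
simulate_experiment <- function(population, layouts, config, dt = 1e-3,
                                max_t = 30) {
  keep <- vapply(layouts, function(l) l$condition != "filler", logical(1))
  info <- layout_sim_info(layouts[keep])
  n_tr <- length(info)
  withr::with_seed(config$rng_seed + 1L, {
    out <- list()
    for (i in seq_len(nrow(population))) {
      pp <- population[i, ]
      drift <- vapply(info, function(tr) {
        if (tr$layout$condition == "subgoal")
          pp$p * (pp$md * tr$m + pp$fd * tr$f) + pp$gd * tr$goal_dir
        else pp$md * tr$m + pp$fd * tr$f
      }, numeric(1))
      sim <- ddm_simulate_cpp(drift, pp$t0, pp$a, pp$z, pp$sz, pp$sd, dt, max_t)
      u <- stats::runif(n_tr)
      rows <- lapply(seq_len(n_tr), function(j) {
        tr <- info[[j]]
        choice_up <- if (sim$choice[j] != 0L) sim$choice[j]
                     else if (drift[j] >= 0) 1L else -1L
        route <- if (choice_up == 1L) "up" else "down"
        actions <- if (route == "up") tr$actions_up else tr$actions_down
        rt_std <- sim$rt[j]
        rt_raw <- pp$sec_intercept + pp$sec_slope * rt_std
        artifact <- "none"
        if (u[j] < config$timeout_rate) {
          artifact <- "timeout"
          rt_raw <- 61 + stats::runif(1, 0, 29)
        } else if (u[j] < config$timeout_rate + config$wrong_start_rate) {
          artifact <- "wrong_start"
          actions <- c("left", "right", actions)
        } else if (u[j] < config$timeout_rate + config$wrong_start_rate +
                   config$wander_rate) {
          artifact <- "wander"
          k <- ceiling((max(tr$lens) + 5 - length(actions)) / 2)
          inv <- c(up = "down", down = "up", left = "right", right = "left")
          pad <- rep(c(inv[[actions[1]]], actions[1]), max(k, 1L))
          actions <- c(actions[1], pad, actions[-1])
        }
        lay <- tr$layout
        disp <- display_direction(actions, lay$orientation, lay$mirrored)
        m <- tr$m
        ia <- m != 0 && tr$f != 0 && sign(m) != sign(tr$f)
        data.frame(participant_id = pp$participant_id,
                   trial_id = lay$trial_id, condition = lay$condition,
                   orientation = lay$orientation, mirrored = lay$mirrored,
                   myopic_adv = m, future_adv = tr$f,
                   trial_type = tr$trial_type, goal_end = lay$goal_end,
                   first_move = disp[1], actions = paste(disp, collapse = ";"),
                   rt_raw = rt_raw, rt_std = rt_std,
                   chose_myopic = if (ia) choice_up * sign(m) else NA_integer_,
                   goal_sign = if (ia) tr$goal_dir * sign(m) else 0L,
                   planted_artifact = artifact)
      })
      out[[i]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
}

ia_layouts <- function(experiment, orientation_group = "horizontal") {
  is_ia <- function(lay) {
    adv <- compute_advantages(lay)
    adv[["myopic"]] != 0 && adv[["future"]] != 0 &&
      sign(adv[["myopic"]]) != sign(adv[["future"]])
  }
  layouts <- if (experiment == "exp1") {
    enumerate_base_trials("exp1")
  } else {
    c(enumerate_base_trials("exp2", orientation_group),
      enumerate_subgoal_trials(orientation_group))
  }
  Filter(is_ia, layouts)
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic cohort over the experiment's incongruent-advantage
#' trial list from a population centered on the winning fitted values,
#' fits the generating variant to the pooled generator-scale data, and
#' reports per-parameter recovery plus the derived quantities (weight
#' ratio, goal weight, proportional weight decrease).
#'
#' @param config a [population_config()].
#' @param variant a [variant_spec()]; defaults to the experiment's winning
#'   variant (different weights with variabilities; plus goal weight and
#'   proportional change for the complex task).
#' @param n_starts random starts for the fit.
#' @param orientation_group trial-list group for the complex task.
#' @param quad,control fitting settings.
#' @return list with `truth` (population means), `fit`, `params`,
#'   `weight_ratio`, `gd`, `proportional_decrease`, `recovery` (bias
#'   table), and `n_trials`.
#' @export
recovery_experiment <- function(config, variant = NULL, n_starts = 5L,
                                orientation_group = "horizontal",
                                quad = ddm_quadrature(),
                                control = list(eval.max = 500, iter.max = 300)) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(variant)) {
    variant <- if (config$experiment == "exp1")
      variant_spec("diff_w_var") else
      variant_spec("gd_proportional", subgoal_mode = "gd_proportional")
  }
  layouts <- ia_layouts(config$experiment, orientation_group)
  pop <- sample_population(config)
  obs <- simulate_experiment(pop, layouts, config)
  data <- make_ddm_data(obs)
  fit <- fit_variant(data, variant, n_starts = n_starts,
                     rng_seed = config$rng_seed + 2L, quad = quad,
                     control = control)
  est <- fit$params
  truth <- config$means
  common <- intersect(names(est), names(truth))
  recovery <- data.frame(parameter = common, true = truth[common],
                         estimate = est[common],
                         bias = est[common] - truth[common])
  list(truth = truth, fit = fit, params = est,
       weight_ratio = weight_ratio(est),
       gd = if ("gd" %in% names(est)) est[["gd"]] else NA_real_,
       proportional_decrease = if ("p" %in% names(est))
         proportional_decrease(est) else NA_real_,
       recovery = recovery, n_trials = nrow(data),
       n_participants = config$n_participants)
}

#' One model-selection recovery replicate
#'
#' Generates a cohort from `config`, cross-validates the given variants
#' over shared folds, and returns the comparison report with the selected
#' winner.
#'
#' @param config a [population_config()] describing the generating
#'   population.
#' @param variants candidate [variant_spec()] list.
#' @param n_folds,test_size Monte-Carlo cross-validation settings.
#' @param n_starts random starts per fold fit (0 = warm start only).
#' @param warm_start,warm_n_starts,max_starts see [cross_validate()].
#' @param orientation_group trial-list group for the complex task.
#' @param quad,control fitting settings (defaults are the desk-scale
#'   reduced quadrature and loosened optimizer tolerances; see the
#'   methods vignette).
#' @return [compare_models()] report with the fold table attached.
#' @export
selection_experiment <- function(config, variants, n_folds = 20L,
                                 test_size = NULL, n_starts = 0L,
                                 warm_start = TRUE, warm_n_starts = 3L,
                                 max_starts = 1L,
                                 orientation_group = "horizontal",
                                 quad = ddm_quadrature(15L, 8L),
                                 control = list(eval.max = 250, iter.max = 150,
                                                rel.tol = 1e-6)) {
  layouts <- ia_layouts(config$experiment, orientation_group)
  pop <- sample_population(config)
  obs <- simulate_experiment(pop, layouts, config)
  data <- make_ddm_data(obs)
  if (is.null(test_size))
    test_size <- max(2L, round(0.4 * config$n_participants))
  folds <- make_folds(unique(data$participant_id), n_folds, test_size,
                      config$rng_seed + 3L)
  tab <- cross_validate(data, variants, folds, n_starts = n_starts,
                        rng_seed = config$rng_seed + 4L,
                        warm_start = warm_start,
                        warm_n_starts = warm_n_starts,
                        max_starts = max_starts, quad = quad,
                        control = control)
  rep <- compare_models(tab)
  rep$fold_table <- tab
  rep
}
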