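# Accuracy-group fits and the random-split permutation baseline for
# between-group parameter differences.

#' Ratio of the myopic to the future drift weight
#'
#' Scale-invariant summary of weighting balance; 1 is the optimal, equal
#' weighting.
#'
#' @param params named parameter vector or [ddm_params()] with `md`, `fd`.
#' @return `md / fd`.
#' @export
weight_ratio <- function(params) {
  md <- params[["md"]]
  fd <- if ("fd" %in% names(params)) params[["fd"]] else md
  if (fd == 0) stop("undefined-ratio: fd is zero", call. = FALSE)
  md / fd
}

#' Percentage decrease of the advantage weights in the subgoal condition
#'
#' For the proportional weight-change variant, returns `100 * (1 - p)`.
#'
#' @param params named parameter vector with a `p` element.
#' @return percentage decrease.
#' @export
proportional_decrease <- function(params) {
  100 * (1 - params[["p"]])
}

#' Fit a model variant separately to the accuracy groups
#'
#' In "full" mode (used for the difference statistics) each group's model
#' is trained on the pooled trials of all its participants. In "cv" mode
#' the group analysis mirrors the cohort cross-validation with
#' within-group test resampling.
#'
#' @param data fitting data frame from [make_ddm_data()].
#' @param groups data frame with `participant_id` and `accuracy_group`
#'   columns (from [median_split()]).
#' @param variant a [variant_spec()].
#' @param mode "full" or "cv".
#' @param n_folds,test_sizes cv-mode settings; `test_sizes` is a named
#'   list/vector with elements `high` and `low`.
#' @param n_starts,max_starts,rng_seed,quad,control passed to the fitting
#'   routines.
#' @return list with one element per group: a [fit_variant()] result
#'   ("full" mode) or a [cross_validate()] fold table ("cv" mode).
#' @export
fit_accuracy_groups <- function(data, groups, variant,
                                mode = c("full", "cv"), n_folds = 20L,
                                test_sizes = NULL, n_starts = 10L,
                                max_starts = 30L, rng_seed = 1L,
                                quad = ddm_quadrature(),
                                control = list(eval.max = 500, iter.max = 300)) {
  mode <- match.arg(mode)
  out <- list()
  for (grp in c("high", "low")) {
    ids <- groups$participant_id[groups$accuracy_group == grp]
    d <- data[data$participant_id %in% ids, ]
    if (mode == "full") {
      out[[grp]] <- fit_variant(d, variant, n_starts = n_starts,
                                rng_seed = rng_seed + match(grp, c("high", "low")),
                                max_starts = max_starts,
                                quad = quad, control = control)
    } else {
      ts <- test_sizes[[grp]]
      if (is.null(ts) || ts >= length(ids))
        stop("config error: test size missing or too large for group ", grp,
             call. = FALSE)
      folds <- make_folds(ids, n_folds, ts,
                          rng_seed + 100L * match(grp, c("high", "low")))
      out[[grp]] <- cross_validate(d, list(variant), folds,
                                   n_starts = n_starts, rng_seed = rng_seed,
                                   quad = quad, control = control)
    }
  }
  out
}

#' Random-split baseline distribution for a group-difference statistic
#'
#' Repeatedly reassigns participants at random into two groups matched in
#' size to the observed accuracy groups, fits the model to the full pooled
#' data of each random group, and records the difference of a parameter
#' statistic (group 1 minus group 2, sizes matched to high/low). Returns
#' the baseline distribution, its percentile 95% CI, and the count of
#' splits more extreme than the observed difference (one-sided, more
#' negative, matching how these baselines are reported; set `alternative`
#' for the two-sided count).
#'
#' @param data fitting data frame from [make_ddm_data()].
#' @param group_sizes integer vector `c(high_size, low_size)`; must sum to
#'   the cohort size.
#' @param n_splits number of random splits.
#' @param observed observed statistic difference (high minus low) to
#'   compare against the baseline.
#' @param variant a [variant_spec()]; ignored when `stat_fun` bypasses
#'   fitting.
#' @param stat_fun function mapping one group's fitting data frame to a
#'   scalar statistic. The default fits `variant` to the group (a single
#'   reduced-start fit per group per split) and returns the myopic/future
#'   weight ratio.
#' @param statistic_name label stored in the result.
#' @param n_starts random starts per group fit inside each split.
#' @param rng_seed master seed; per-split seeds fan out deterministically.
#' @param alternative "less" (more negative is more extreme) or
#'   "two_sided".
#' @param quad,control fitting settings.
#' @return `split_statistic` list: `name`, `observed`, `baseline`, `ci95`,
#'   `n_more_extreme`, `tail_proportion`, `n_splits`.
#' @export
random_split_baseline <- function(data, group_sizes, n_splits, observed,
                                  variant = NULL, stat_fun = NULL,
                                  statistic_name = "weight_ratio_difference",
                                  n_starts = 2L, rng_seed = 1L,
                                  alternative = c("less", "two_sided"),
                                  quad = ddm_quadrature(),
                                  control = list(eval.max = 500, iter.max = 300)) {
  alternative <- match.arg(alternative)
  ids <- unique(data$participant_id)
  if (sum(group_sizes) != length(ids))
    stop("group sizes must sum to the cohort size", call. = FALSE)
  if (is.null(stat_fun)) {
    if (is.null(variant)) stop("need a variant or a stat_fun", call. = FALSE)
    stat_fun <- function(d, seed) {
      fit_variant(d, variant, n_starts = n_starts, rng_seed = seed,
                  max_starts = max(n_starts, 5L), quad = quad,
                  control = control)$params
    }
    stat_of <- function(d, seed) weight_ratio(stat_fun(d, seed))
  } else {
    stat_of <- function(d, seed) stat_fun(d)
  }
  split_seeds <- withr::with_seed(rng_seed,
                                  sample.int(.Machine$integer.max - 1L, n_splits))
  baseline <- vapply(seq_len(n_splits), function(s) {
    g1 <- withr::with_seed(split_seeds[s], sample(ids, group_sizes[1]))
    d1 <- data[data$participant_id %in% g1, ]
    d2 <- data[!data$participant_id %in% g1, ]
    stat_of(d1, split_seeds[s]) - stat_of(d2, split_seeds[s] + 1L)
  }, numeric(1))
  n_extreme <- switch(alternative,
                      less = sum(baseline < observed),
                      two_sided = sum(abs(baseline) > abs(observed)))
  structure(list(name = statistic_name, observed = observed,
                 baseline = baseline,
                 ci95 = unname(stats::quantile(baseline, c(0.025, 0.975))),
                 n_more_extreme = n_extreme,
                 tail_proportion = n_extreme / n_splits,
                 n_splits = n_splits),
            class = "split_statistic")
}

#' Joint tail probability of independent random-split events
#'
#' Product of the one-sided tail proportions observed in independent
#' random-split baselines.
#'
#' @param proportions numeric vector of tail proportions in `[0, 1]`.
#' @return their product.
#' @export
joint_tail_probability <- function(proportions) {
  stopifnot(all(proportions >= 0 & proportions <= 1))
  prod(proportions)
}
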