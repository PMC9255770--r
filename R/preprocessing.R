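# Observation tables: one row per trial with participant_id, trial_id,
# condition, orientation, mirrored, myopic_adv, future_adv, goal_end,
# first_move, actions (";"-separated, displayed frame), rt_raw (seconds).

#' Standardize raw response times within a participant
#'
#' z-scores the raw first-move response times (sample-SD, n-1 divisor)
#' and shifts the distribution so that its minimum is exactly 0.5. The
#' transform is affine, hence rank-preserving.
#'
#' @param rts_raw numeric vector of one participant's response times.
#' @return standardized response times, `min(out) == 0.5`.
#' @export
standardize_rt <- function(rts_raw) {
  if (length(rts_raw) < 2L)
    stop("degenerate-participant: need at least two trials", call. = FALSE)
  s <- stats::sd(rts_raw)
  if (!is.finite(s) || s == 0)
    stop("degenerate-participant: zero response-time variance", call. = FALSE)
  z <- (rts_raw - mean(rts_raw)) / s
  z - min(z) + 0.5
}

#' Classify the initial route of an executed path
#'
#' Determines whether the path committed to the upper or lower route
#' around the start-proximal wall. A trial is `ill_identified` when the
#' first move is equivalent to going left in the canonical left-to-right
#' frame, when the first vertical move contradicts the side on which the
#' path eventually clears the start-proximal wall, or when the path never
#' clears that wall.
#'
#' @param actions character vector of canonical-frame moves.
#' @param layout a [trial_layout()].
#' @return "upper", "lower" or "ill_identified".
#' @export
classify_initial_route <- function(actions, layout) {
  if (length(actions) == 0L)
    stop("empty-trial: no actions", call. = FALSE)
  if (actions[1] == "left") return("ill_identified")
  lay <- canonicalize(layout)
  cols <- vapply(lay$maze$walls, function(w) w$column, integer(1))
  w1 <- lay$maze$walls[[which.min(cols)]]
  walk <- walk_actions(lay, actions)
  crossed <- which(walk$cells[, 2L] > w1$column)
  if (length(crossed) == 0L) return("ill_identified")
  cross_idx <- crossed[1L]
  side <- if (walk$cells[cross_idx, 1L] < w1$center_row) "upper" else "lower"
  vertical <- which(actions %in% c("up", "down"))
  vertical <- vertical[vertical < cross_idx]   # moves before clearing the wall
  if (length(vertical) > 0L) {
    committed <- if (actions[vertical[1L]] == "up") "upper" else "lower"
    if (committed != side) return("ill_identified")
  }
  side
}

#' Apply the trial-level exclusion rules
#'
#' Removes trials whose first move took longer than one minute
#' (`timeout`), trials whose executed path was five or more steps longer
#' than the longer of the two main route candidates (`path_too_long`;
#' steps counted under the experiment's collision-penalty rule), and
#' trials with ill-identified initial route (`ill_identified`). Reasons
#' are assigned with that precedence. The operation is idempotent and
#' partitions the input: kept + excluded = input.
#'
#' @param obs observation data frame (see the package overview for the
#'   schema); a `route` column is computed when absent.
#' @param layouts list of [trial_layout()] objects covering `obs$trial_id`.
#' @param experiment "exp1" (collision steps penalized) or "exp2" (free).
#' @return list with `kept`, `excluded` (input rows plus `route`,
#'   `excluded`, `reason` columns) and `report` (named counts per reason).
#' @export
apply_exclusions <- function(obs, layouts, experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  penalty <- if (experiment == "exp1") "penalized" else "free"
  lay_by_id <- stats::setNames(layouts,
                               vapply(layouts, function(l) l$trial_id,
                                      character(1)))
  n <- nrow(obs)
  route <- character(n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    lay <- lay_by_id[[obs$trial_id[i]]]
    if (is.null(lay)) stop("unknown trial_id: ", obs$trial_id[i], call. = FALSE)
    acts <- canonical_direction(strsplit(obs$actions[i], ";")[[1]],
                                lay$orientation, lay$mirrored)
    route[i] <- classify_initial_route(acts, lay)
    if (obs$rt_raw[i] > 60) {
      reason[i] <- "timeout"
    } else {
      longer <- max(main_candidate_lengths(lay))
      executed <- path_length(lay, acts, penalty)
      if (executed >= longer + 5) {
        reason[i] <- "path_too_long"
      } else if (route[i] == "ill_identified") {
        reason[i] <- "ill_identified"
      }
    }
  }
  obs$route <- route
  obs$excluded <- !is.na(reason)
  obs$reason <- reason
  report <- c(timeout = sum(reason == "timeout", na.rm = TRUE),
              path_too_long = sum(reason == "path_too_long", na.rm = TRUE),
              ill_identified = sum(reason == "ill_identified", na.rm = TRUE))
  list(kept = obs[!obs$excluded, , drop = FALSE],
       excluded = obs[obs$excluded, , drop = FALSE],
       report = report)
}

#' Code a route choice for the diffusion model
#'
#' On incongruent-advantage trials with an identified route, +1 marks the
#' choice satisfying the myopic advantage (the upper decision bound) and
#' -1 the choice satisfying the future advantage.
#'
#' @param myopic_adv,future_adv signed advantages of the trial.
#' @param route "upper" or "lower" (canonical frame).
#' @return +1 or -1.
#' @export
code_choice_for_ddm <- function(myopic_adv, future_adv, route) {
  if (route == "ill_identified")
    stop("not-codable: ill-identified route", call. = FALSE)
  if (myopic_adv == 0 || future_adv == 0 ||
      sign(myopic_adv) == sign(future_adv))
    stop("not-codable: choice coding is defined for IA trials only",
         call. = FALSE)
  chose_upper <- route == "upper"
  myopic_up <- myopic_adv > 0
  if (chose_upper == myopic_up) 1L else -1L
}

#' Capped probit transform of a choice-accuracy proportion
#'
#' Inverse-normal transform, clamped to `[-3, 3]`; proportions of exactly
#' 0 or 1 map to the caps.
#'
#' @param accuracy proportion(s) in `[0, 1]`.
#' @return probit score(s) in `[-3, 3]`.
#' @export
probit_accuracy <- function(accuracy) {
  stopifnot(all(accuracy >= 0 & accuracy <= 1))
  pmin(3, pmax(-3, stats::qnorm(accuracy)))
}

#' Preprocess an observation table
#'
#' Runs the full trial-level pipeline: route classification and exclusion
#' rules, per-participant response-time standardization (computed over each
#' participant's non-excluded trials across analyzed conditions), diffusion
#' choice coding on IA trials, and optimality flags.
#'
#' @inheritParams apply_exclusions
#' @return list with `data` (kept trials plus `rt_std`, `chose_myopic`,
#'   `optimal`, `goal_sign` columns), `excluded`, and `report`.
#' @export
preprocess_observations <- function(obs, layouts,
                                    experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  ex <- apply_exclusions(obs, layouts, experiment)
  kept <- ex$kept
  kept$rt_std <- NA_real_
  for (pid in unique(kept$participant_id)) {
    idx <- kept$participant_id == pid
    kept$rt_std[idx] <- standardize_rt(kept$rt_raw[idx])
  }
  lay_by_id <- stats::setNames(layouts,
                               vapply(layouts, function(l) l$trial_id,
                                      character(1)))
  n <- nrow(kept)
  kept$chose_myopic <- NA_integer_
  kept$optimal <- NA
  kept$unique_optimal <- NA
  kept$goal_sign <- 0L
  for (i in seq_len(n)) {
    lay <- lay_by_id[[kept$trial_id[i]]]
    opt <- optimal_initial_directions(lay)
    chosen <- if (kept$route[i] == "upper") "up" else "down"
    kept$optimal[i] <- chosen %in% opt
    kept$unique_optimal[i] <- length(opt) == 1L
    m <- kept$myopic_adv[i]; f <- kept$future_adv[i]
    ia <- m != 0 && f != 0 && sign(m) != sign(f)
    if (ia) {
      kept$chose_myopic[i] <- code_choice_for_ddm(m, f, kept$route[i])
      if (kept$condition[i] == "subgoal") {
        ge <- canonicalize(lay)$goal_end
        kept$goal_sign[i] <- (if (ge == "upper") 1L else -1L) * sign(m)
      }
    }
  }
  list(data = kept, excluded = ex$excluded, report = ex$report)
}

#' Per-participant accuracy and response-time summaries
#'
#' Accuracy is the proportion of optimal first moves over trials with a
#' unique optimal initial direction; the probit score is its capped
#' inverse-normal transform.
#'
#' @param data preprocessed kept-trial data frame (from
#'   [preprocess_observations()]).
#' @return data frame with one row per participant.
#' @export
participant_summaries <- function(data) {
  pids <- unique(data$participant_id)
  rows <- lapply(pids, function(pid) {
    d <- data[data$participant_id == pid, ]
    du <- d[d$unique_optimal, ]
    acc <- mean(du$optimal)
    data.frame(participant_id = pid, accuracy = acc,
               probit_score = probit_accuracy(acc),
               median_rt_std = stats::median(d$rt_std),
               n_trials = nrow(d))
  })
  do.call(rbind, rows)
}

#' Median split of participants by choice accuracy
#'
#' Participants strictly above the group median accuracy form the high
#' group; participants at or below the median (including exact ties) form
#' the low group.
#'
#' @param summaries output of [participant_summaries()].
#' @return `summaries` with an `accuracy_group` factor column.
#' @export
median_split <- function(summaries) {
  if (nrow(summaries) < 2L)
    stop("median split needs at least two participants", call. = FALSE)
  med <- stats::median(summaries$accuracy)
  summaries$accuracy_group <- factor(ifelse(summaries$accuracy > med,
                                            "high", "low"),
                                     levels = c("high", "low"))
  summaries
}
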