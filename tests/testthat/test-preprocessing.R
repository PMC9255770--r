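test_that("response-time standardization shifts the z-scores to a 0.5 minimum", {
  # hand-computed: mean 2, sample SD 1 -> z = (-1, 0, 1) -> shift by 1.5
  expect_equal(standardize_rt(c(1, 2, 3)), c(0.5, 1.5, 2.5))
  set.seed(4)
  for (i in 1:5) {
    x <- rlnorm(30, 0, 0.4)
    out <- standardize_rt(x)
    expect_equal(min(out), 0.5)
    expect_equal(order(out), order(x))          # affine, rank-preserving
    expect_equal(diff(range(out)), diff(range(x)) / sd(x))
  }
  expect_error(standardize_rt(c(2, 2, 2)), "degenerate-participant")
  expect_error(standardize_rt(2), "degenerate-participant")
})

test_that("initial-route classification flags backward and contradictory starts", {
  lay <- base_layout(2, -1)
  up_path <- mazeddm:::shortest_actions(lay, "upper")
  down_path <- mazeddm:::shortest_actions(lay, "lower")
  expect_equal(classify_initial_route(up_path, lay), "upper")
  expect_equal(classify_initial_route(down_path, lay), "lower")
  # first move equivalent to going left in the canonical frame
  expect_equal(classify_initial_route(c("left", "right", up_path), lay),
               "ill_identified")
  # initial down move followed by an upper-route traversal
  expect_equal(classify_initial_route(c("down", "up", up_path), lay),
               "ill_identified")
  expect_error(classify_initial_route(character(0), lay), "empty-trial")
})

test_that("exclusion rules remove timeouts, wandering paths and unidentified routes", {
  lay <- base_layout(2, -1)
  up_path <- mazeddm:::shortest_actions(lay, "upper")
  mk <- function(actions, rt) data.frame(
    participant_id = "P1", trial_id = lay$trial_id,
    condition = "base", myopic_adv = 2, future_adv = -1,
    actions = paste(actions, collapse = ";"), rt_raw = rt)
  longer <- max(main_candidate_lengths(lay))
  wander <- c(up_path[1], rep(c("down", "up"), 6), up_path[-1])
  stopifnot(length(wander) >= longer + 5)
  obs <- rbind(mk(up_path, 1.2),                 # kept
               mk(up_path, 61),                  # timeout
               mk(wander, 2.0),                  # too long
               mk(c("left", "right", up_path), 1.5))  # ill-identified
  res <- apply_exclusions(obs, list(lay), "exp1")
  expect_equal(unname(res$report),
               c(1L, 1L, 1L))
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(obs))
  expect_equal(res$kept$route, "upper")
  # idempotent on the kept table
  res2 <- apply_exclusions(res$kept, list(lay), "exp1")
  expect_equal(nrow(res2$kept), nrow(res$kept))
  expect_equal(sum(res2$report), 0L)
  # boundary: exactly five extra steps is excluded, four is kept
  pad4 <- c(up_path[1], rep(c("down", "up"),
                            (longer + 4 - length(up_path)) %/% 2), up_path[-1])
  expect_lt(length(pad4), longer + 5)
  expect_equal(sum(apply_exclusions(mk(pad4, 1), list(lay), "exp1")$report), 0L)
})

test_that("diffusion choice coding marks the myopic-satisfying route as +1", {
  expect_equal(code_choice_for_ddm(2, -1, "upper"), 1L)
  expect_equal(code_choice_for_ddm(1, -2, "lower"), -1L)
  expect_equal(code_choice_for_ddm(-2, 1, "lower"), 1L)  # mirrored trial
  expect_error(code_choice_for_ddm(1, 1, "upper"), "not-codable")
  expect_error(code_choice_for_ddm(2, 0, "upper"), "not-codable")
  expect_error(code_choice_for_ddm(2, -1, "ill_identified"), "not-codable")
})

test_that("probit accuracy scores are capped inverse-normal transforms", {
  expect_equal(probit_accuracy(0.5), 0)
  expect_equal(probit_accuracy(1), 3)
  expect_equal(probit_accuracy(0), -3)
  expect_equal(probit_accuracy(0.9772), 2, tolerance = 1e-3)
  p <- seq(0, 1, by = 0.05)
  out <- probit_accuracy(p)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= -3 & out <= 3))
})

test_that("median split sends above-median participants to the high group", {
  s <- data.frame(participant_id = paste0("P", 1:4),
                  accuracy = c(0.6, 0.8, 0.9, 1.0))
  g <- median_split(s)
  expect_equal(as.character(g$accuracy_group), c("low", "low", "high", "high"))
  # ties at the median go low
  s2 <- data.frame(participant_id = paste0("P", 1:3),
                   accuracy = c(0.7, 0.7, 0.9))
  expect_equal(as.character(median_split(s2)$accuracy_group),
               c("low", "low", "high"))
  # a 95-participant cohort without median ties splits 47 / 48: the group
  # above the 48th order statistic
  acc <- seq(0.5, 1.0, length.out = 95)
  s3 <- data.frame(participant_id = paste0("P", 1:95), accuracy = acc)
  tallies <- table(median_split(s3)$accuracy_group)
  expect_equal(unname(tallies[["high"]]), 47L)
  expect_equal(unname(tallies[["low"]]), 48L)
})

test_that("preprocessing yields per-participant 0.5 RT minima and coded IA trials", {
  coh <- tiny_cohort(3, "exp2", seed = 12)
  pp <- preprocess_observations(coh$obs, coh$layouts, "exp2")
  mins <- tapply(pp$data$rt_std, pp$data$participant_id, min)
  expect_true(all(abs(mins - 0.5) < 1e-12))
  ia <- !is.na(pp$data$chose_myopic)
  expect_true(all(pp$data$trial_type[ia] %in% c("IA", "IA-m", "IA-f")))
  expect_true(all(pp$data$goal_sign[ia & pp$data$condition == "subgoal"]
                  %in% c(-1, 1)))
  expect_true(all(pp$data$goal_sign[pp$data$condition == "base"] == 0))
  sm <- participant_summaries(pp$data)
  expect_equal(nrow(sm), 3L)
  expect_true(all(sm$accuracy >= 0 & sm$accuracy <= 1))
  # unique-optimal trials only: NT and cancelling IA pairs never count
  expect_true(all(pp$data$unique_optimal ==
                    (pp$data$myopic_adv + pp$data$future_adv != 0)))
})
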