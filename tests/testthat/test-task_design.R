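test_that("advantages are signed offsets from the wall centers", {
  # worked example: start offset +2, goal offset -2
  lay <- base_layout(2, -2)
  expect_equal(compute_advantages(lay), c(myopic = 2, future = -2))
  # zero offsets
  expect_equal(compute_advantages(base_layout(0, 0)),
               c(myopic = 0, future = 0))
  # arbitrary designed offsets
  expect_equal(compute_advantages(base_layout(3, -1)),
               c(myopic = 3, future = -1))
  # subgoal layouts anchor the future advantage at the bottleneck opening
  expect_equal(compute_advantages(subgoal_layout(1, -2)),
               c(myopic = 1, future = -2))
})

test_that("canonicalize is the identity on canonical layouts and undoes presentation", {
  lay <- base_layout(2, -1)
  expect_identical(canonicalize(lay), lay)

  # orientation round trip: displayed cells of a TB trial map back to the
  # canonical cells under the inverse point transform
  tb <- base_layout(2, -1, orientation = "TB")
  disp <- displayed_cells(tb)
  back <- mazeddm:::unorient_point(disp$start, "TB", 11L, 11L)
  expect_equal(back, canonicalize(tb)$start)
  expect_equal(mazeddm:::unorient_point(disp$goal, "TB", 11L, 11L),
               canonicalize(tb)$goal)

  # mirroring negates both advantage components
  mir <- base_layout(2, -1, mirrored = TRUE)
  can <- canonicalize(mir)
  expect_false(can$mirrored)
  expect_equal(compute_advantages(mir), c(myopic = -2, future = 1))
  expect_equal(compute_advantages(can), c(myopic = -2, future = 1))

  # direction transforms invert each other for every orientation x mirror
  for (o in c("LR", "RL", "TB", "BT"))
    for (mr in c(FALSE, TRUE))
      expect_equal(canonical_direction(
        display_direction(c("up", "down", "left", "right"), o, mr), o, mr),
        c("up", "down", "left", "right"))

  bad <- base_layout(1, 0)
  bad$maze$walls[[1]]$center_row <- 20L
  expect_error(canonicalize(bad), "invalid-geometry")
})

test_that("trial-type classification matches the designed taxonomy", {
  tab <- advantage_table()
  for (i in seq_len(nrow(tab)))
    expect_equal(classify_trial(c(tab$myopic[i], tab$future[i])),
                 tab$label[i])
  # mirrors stay in the same class
  for (i in seq_len(nrow(tab)))
    expect_equal(classify_trial(-c(tab$myopic[i], tab$future[i])),
                 tab$label[i])
  expect_equal(classify_trial(c(1, -1)), "IA")
  expect_equal(classify_trial(c(1, -3)), "IA-f")
})

test_that("route-length difference equals twice the summed advantage (BFS oracle)", {
  skip_if_not_installed("igraph")
  # independent oracle: grid graph in igraph, route-side constraint imposed
  # by deleting the cells on the wrong side of each wall column
  oracle_len <- function(lay, side) {
    lay <- canonicalize(lay)
    blocked <- mazeddm:::route_blocked(lay, side)
    nr <- nrow(blocked); nc <- ncol(blocked)
    id <- function(r, c) r * nc + c + 1L
    edges <- c()
    for (r in 0:(nr - 1)) for (c in 0:(nc - 1)) {
      if (blocked[r + 1, c + 1]) next
      if (c + 1 < nc && !blocked[r + 1, c + 2])
        edges <- c(edges, id(r, c), id(r, c + 1))
      if (r + 1 < nr && !blocked[r + 2, c + 1])
        edges <- c(edges, id(r, c), id(r + 1, c))
    }
    g <- igraph::make_graph(edges, n = nr * nc, directed = FALSE)
    igraph::distances(g, id(lay$start[1], lay$start[2]),
                      id(lay$goal[1], lay$goal[2]))[1, 1]
  }
  layouts <- enumerate_base_trials("exp1")
  idx <- seq(1, length(layouts), by = 7)  # sample across the design
  for (lay in layouts[idx]) {
    adv <- compute_advantages(lay)
    lens <- main_candidate_lengths(lay)
    expect_equal(lens[["lower"]] - lens[["upper"]],
                 2 * (adv[["myopic"]] + adv[["future"]]))
    expect_equal(lens[["upper"]], oracle_len(lay, "upper"))
    expect_equal(lens[["lower"]], oracle_len(lay, "lower"))
  }
})

test_that("optimal initial directions follow the shorter route, ties returned whole", {
  expect_equal(optimal_initial_directions(base_layout(2, 0)), "up")
  expect_setequal(optimal_initial_directions(base_layout(1, -1)),
                  c("up", "down"))
  expect_setequal(optimal_initial_directions(base_layout(2, -2)),
                  c("up", "down"))
  expect_setequal(optimal_initial_directions(base_layout(0, 0)),
                  c("up", "down"))
  expect_equal(optimal_initial_directions(base_layout(-2, 1, "exp1")), "down")
  # invariant: both directions exactly when the advantages cancel
  for (lay in enumerate_base_trials("exp1")) {
    adv <- compute_advantages(lay)
    dirs <- optimal_initial_directions(lay)
    if (adv[["myopic"]] + adv[["future"]] == 0) {
      expect_setequal(dirs, c("up", "down"))
    } else {
      expect_length(dirs, 1L)
    }
  }
})

test_that("path length counts collisions per the experiment's penalty rule", {
  lay <- base_layout(0, 0)
  straight <- c("right", "right", "right", "right")
  expect_equal(path_length(lay, straight, "penalized"), 4L)
  # start sits at (5, 1); the second and third right-moves hit the wall
  # at column 3, so only two moves are effective
  expect_equal(path_length(lay, c("right", "right", "right", "up"),
                           "penalized"), 4L)
  expect_equal(path_length(lay, c("right", "right", "right", "up"),
                           "free"), 2L)
  # unbounded simple-task grid: walking off the canvas is an error
  expect_error(path_length(lay, rep("left", 3), "penalized"),
               "out-of-bounds")
  # bounded complex-task grid treats the boundary as a wall
  lay2 <- base_layout(0, 0, experiment = "exp2")
  expect_equal(path_length(lay2, rep("left", 3), "free"), 1L)
  expect_error(path_length(lay, character(0)), "empty-trial")
})

test_that("base-trial enumeration produces the designed counts", {
  b1 <- enumerate_base_trials("exp1")
  expect_length(b1, 92L)
  b2h <- enumerate_base_trials("exp2", "horizontal")
  b2v <- enumerate_base_trials("exp2", "vertical")
  expect_length(b2h, 46L)
  expect_length(b2v, 46L)
  # 23 distinct signed advantage pairs (12 designed + 11 mirrored)
  advs <- unique(t(sapply(b1, compute_advantages)))
  expect_equal(nrow(advs), 23L)
  # trial ids are unique
  df <- trials_to_df(b1)
  expect_equal(anyDuplicated(df$trial_id), 0L)
})

test_that("subgoal enumeration balances goal ends over advantage pairs", {
  sg <- enumerate_subgoal_trials("horizontal")
  expect_length(sg, 92L)
  df <- trials_to_df(sg)
  expect_true(all(df$condition == "subgoal"))
  expect_true(all(df$goal_end %in% c("upper", "lower")))
  tallies <- table(paste(df$myopic_adv, df$future_adv, df$orientation),
                   df$goal_end)
  expect_true(all(tallies == 1L))
})

test_that("filler sampling respects the design constraints and the seed", {
  expect_length(enumerate_filler_trials(0, 1), 0L)
  fills <- enumerate_filler_trials(40, 11)
  expect_length(fills, 40L)
  for (lay in fills) {
    for (w in lay$maze$walls) {
      rows <- mazeddm:::wall_rows(w)
      expect_true(min(rows) >= 1 && max(rows) <= 9)
      expect_true(w$length %in% c(3, 5, 7))
    }
    lens <- sapply(lay$maze$walls, function(w) w$length)
    ctrs <- sapply(lay$maze$walls, function(w) w$center_row)
    expect_false(all(lens == 7) && all(ctrs == 5))  # never a base duplicate
    expect_lt(lay$start[2], 3)
    expect_gt(lay$goal[2], 7)
  }
  expect_identical(trials_to_df(enumerate_filler_trials(10, 99)),
                   trials_to_df(enumerate_filler_trials(10, 99)))
})

test_that("trial tables round-trip through CSV", {
  layouts <- c(enumerate_base_trials("exp2", "horizontal")[1:6],
               enumerate_subgoal_trials("horizontal")[1:6])
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(layouts, path)
  back <- read_trials(path)
  expect_identical(trials_to_df(back), trials_to_df(layouts))
  expect_equal(compute_advantages(back[[8]]), compute_advantages(layouts[[8]]))
})
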