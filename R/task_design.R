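# Canonical frame: 0-based (row, col), left-to-right travel, up = decreasing
# row. All geometry is stored in the canonical frame of the *designed*
# (unmirrored) layout; `mirrored` and `orientation` record presentation.

.DIRS <- list(up = c(-1L, 0L), down = c(1L, 0L),
              left = c(0L, -1L), right = c(0L, 1L))

#' Default canonical maze geometry
#'
#' Parametric geometry of the designed trials: an 11-row grid with the
#' start in column 1, two length-7 internal walls in columns 3 and 7
#' centered on row 5, and the goal in column 9 (base trials). Subgoal
#' layouts extend the grid to 13 columns, with a bottleneck wall in column
#' 10 whose single opening sits at the former goal position and the final
#' goal in column 12 at the chosen end of the goal column. Advantage
#' offsets are applied along rows. Override fields via a JSON config with
#' [geometry_from_json()].
#'
#' @return named list of geometry constants.
#' @export
default_geometry <- function() {
  list(n_rows = 11L, n_cols = 11L, start_col = 1L,
       wall_cols = c(3L, 7L), wall_length = 7L, center_row = 5L,
       goal_col = 9L, subgoal_n_cols = 13L, bottleneck_col = 10L,
       final_goal_col = 12L)
}

#' Read a geometry override from a JSON config
#'
#' @param path JSON file with any subset of the fields of
#'   [default_geometry()].
#' @return full geometry list with overrides applied.
#' @export
geometry_from_json <- function(path) {
  geo <- default_geometry()
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(ov)) geo[[nm]] <- ov[[nm]]
  geo
}

#' Internal wall specification
#'
#' A vertical wall segment in the canonical frame. Length must be odd and
#' one of 3, 5 or 7, and the wall may never occupy the top or bottom grid
#' row (those rows carry the upper and lower main paths).
#'
#' @param column grid column of the wall.
#' @param center_row grid row of the wall's center.
#' @param length odd wall length in cells (3, 5 or 7).
#' @return `wall_spec` object.
#' @export
wall_spec <- function(column, center_row, length) {
  if (!length %in% c(3L, 5L, 7L))
    stop("wall length must be 3, 5 or 7", call. = FALSE)
  structure(list(column = as.integer(column),
                 center_row = as.integer(center_row),
                 length = as.integer(length)),
            class = "wall_spec")
}

wall_rows <- function(wall) {
  half <- (wall$length - 1L) %/% 2L
  (wall$center_row - half):(wall$center_row + half)
}

#' Grid maze container
#'
#' @param n_rows,n_cols grid dimensions (11 rows; 11 or 13 columns).
#' @param walls list of [wall_spec()] objects (two internal walls for the
#'   designed trials).
#' @param bounded whether boundary walls surround the canvas (so stepping
#'   off the grid is a collision rather than an error).
#' @param bottleneck optional `list(column, open_row)`: a full-height wall
#'   with a single opening, used by subgoal layouts.
#' @return `grid_maze` object.
#' @export
grid_maze <- function(n_rows = 11L, n_cols = 11L, walls = list(),
                      bounded = FALSE, bottleneck = NULL) {
  stopifnot(n_rows == 11L, n_cols %in% c(11L, 13L))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 walls = walls, bounded = bounded, bottleneck = bottleneck),
            class = "grid_maze")
}

#' Full description of one maze trial
#'
#' @param maze a [grid_maze()].
#' @param start,goal `c(row, col)` cells in the canonical frame of the
#'   designed layout.
#' @param subgoal bottleneck opening cell (subgoal condition only).
#' @param orientation presented orientation: "LR", "RL", "TB" or "BT".
#' @param mirrored whether the presented trial is the vertical mirror of
#'   the stored geometry.
#' @param condition "base", "subgoal" or "filler".
#' @param goal_end "upper", "lower" (subgoal condition) or "none".
#' @param experiment "exp1" or "exp2".
#' @param trial_id optional identifier.
#' @return `trial_layout` object.
#' @export
trial_layout <- function(maze, start, goal, subgoal = NULL,
                         orientation = "LR", mirrored = FALSE,
                         condition = c("base", "subgoal", "filler"),
                         goal_end = "none", experiment = "exp1",
                         trial_id = NULL) {
  condition <- match.arg(condition)
  orientation <- match.arg(orientation, c("LR", "RL", "TB", "BT"))
  if (condition == "subgoal" && (is.null(subgoal) || goal_end == "none"))
    stop("subgoal layouts need a subgoal cell and a goal end", call. = FALSE)
  if (condition != "subgoal" && (!is.null(subgoal) || goal_end != "none"))
    stop("subgoal cell / goal end only valid in the subgoal condition",
         call. = FALSE)
  lay <- structure(list(maze = maze, start = as.integer(start),
                        goal = as.integer(goal),
                        subgoal = if (is.null(subgoal)) NULL else as.integer(subgoal),
                        orientation = orientation, mirrored = isTRUE(mirrored),
                        condition = condition, goal_end = goal_end,
                        experiment = experiment, trial_id = trial_id),
                   class = "trial_layout")
  validate_layout(lay)
  lay
}

validate_layout <- function(layout) {
  maze <- layout$maze
  in_grid <- function(cell)
    cell[1] >= 0 && cell[1] < maze$n_rows && cell[2] >= 0 && cell[2] < maze$n_cols
  for (w in maze$walls) {
    rows <- wall_rows(w)
    if (w$column < 0 || w$column >= maze$n_cols ||
        min(rows) < 1L || max(rows) > maze$n_rows - 2L)
      stop("invalid-geometry: wall outside grid or blocking a boundary path",
           call. = FALSE)
  }
  if (!in_grid(layout$start) || !in_grid(layout$goal))
    stop("invalid-geometry: start or goal outside grid", call. = FALSE)
  blocked <- blocked_cells(layout)
  if (blocked[layout$start[1] + 1L, layout$start[2] + 1L] ||
      blocked[layout$goal[1] + 1L, layout$goal[2] + 1L])
    stop("invalid-geometry: start or goal inside a wall", call. = FALSE)
  invisible(layout)
}

#' Logical matrix of blocked cells (canonical frame)
#'
#' @param layout a [trial_layout()].
#' @return `n_rows x n_cols` logical matrix (TRUE = wall cell).
#' @export
blocked_cells <- function(layout) {
  maze <- layout$maze
  blocked <- matrix(FALSE, maze$n_rows, maze$n_cols)
  for (w in maze$walls) blocked[wall_rows(w) + 1L, w$column + 1L] <- TRUE
  if (!is.null(maze$bottleneck)) {
    bn <- maze$bottleneck
    blocked[, bn$column + 1L] <- TRUE
    blocked[bn$open_row + 1L, bn$column + 1L] <- FALSE
  }
  blocked
}

mirror_geometry <- function(layout) {
  nr <- layout$maze$n_rows
  flip <- function(cell) c(nr - 1L - cell[1], cell[2])
  layout$start <- flip(layout$start)
  layout$goal <- flip(layout$goal)
  if (!is.null(layout$subgoal)) layout$subgoal <- flip(layout$subgoal)
  layout$maze$walls <- lapply(layout$maze$walls, function(w) {
    w$center_row <- nr - 1L - w$center_row
    w
  })
  if (!is.null(layout$maze$bottleneck))
    layout$maze$bottleneck$open_row <- nr - 1L - layout$maze$bottleneck$open_row
  if (layout$goal_end != "none")
    layout$goal_end <- if (layout$goal_end == "upper") "lower" else "upper"
  layout
}

#' Reduce a layout to the canonical left-to-right, unmirrored frame
#'
#' Undoes the presentation orientation (a metadata transform: geometry is
#' stored canonically) and bakes a vertical mirror into the geometry, so
#' that a mirrored layout becomes an unmirrored layout whose advantage
#' offsets have flipped sign. Path structure and advantages of the
#' presented trial are preserved.
#'
#' @param layout a [trial_layout()].
#' @return equivalent canonical `trial_layout` (`orientation = "LR"`,
#'   `mirrored = FALSE`).
#' @export
canonicalize <- function(layout) {
  stopifnot(inherits(layout, "trial_layout"))
  validate_layout(layout)
  if (layout$mirrored) {
    layout <- mirror_geometry(layout)
    layout$mirrored <- FALSE
  }
  layout$orientation <- "LR"
  layout
}

# ---- presentation transforms -------------------------------------------

orient_point <- function(cell, orientation, n_rows, n_cols) {
  r <- cell[1]; c <- cell[2]
  switch(orientation,
         LR = c(r, c),
         RL = c(r, n_cols - 1L - c),
         TB = c(c, n_rows - 1L - r),
         BT = c(n_cols - 1L - c, r))
}

unorient_point <- function(cell, orientation, n_rows, n_cols) {
  # inverse of orient_point; n_rows/n_cols are the canonical dims
  r <- cell[1]; c <- cell[2]
  switch(orientation,
         LR = c(r, c),
         RL = c(r, n_cols - 1L - c),
         TB = c(n_rows - 1L - c, r),
         BT = c(c, n_cols - 1L - r))
}

#' Map a canonical direction to its on-screen equivalent
#'
#' Applies the vertical mirror (if any) and the orientation transform to a
#' movement direction, giving the key a participant would press for that
#' canonical move. [canonical_direction()] is the inverse.
#'
#' @param dir character vector of canonical directions ("up", "down",
#'   "left", "right").
#' @param orientation presented orientation.
#' @param mirrored whether the trial is vertically mirrored.
#' @return character vector of displayed directions.
#' @export
display_direction <- function(dir, orientation = "LR", mirrored = FALSE) {
  vapply(dir, function(d) {
    v <- .DIRS[[d]]
    if (mirrored) v <- c(-v[1], v[2])
    v <- switch(orientation,
                LR = v, RL = c(v[1], -v[2]),
                TB = c(v[2], -v[1]), BT = c(-v[2], v[1]))
    names(.DIRS)[vapply(.DIRS, function(u) all(u == v), logical(1))]
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname display_direction
#' @export
canonical_direction <- function(dir, orientation = "LR", mirrored = FALSE) {
  vapply(dir, function(d) {
    v <- .DIRS[[d]]
    v <- switch(orientation,
                LR = v, RL = c(v[1], -v[2]),
                TB = c(-v[2], v[1]), BT = c(v[2], -v[1]))
    if (mirrored) v <- c(-v[1], v[2])
    names(.DIRS)[vapply(.DIRS, function(u) all(u == v), logical(1))]
  }, character(1), USE.NAMES = FALSE)
}

#' On-screen cell coordinates of a layout
#'
#' Applies the mirror and orientation transforms to the stored canonical
#' geometry, returning the displayed positions of the start, goal, subgoal
#' and every wall cell, together with the displayed grid dimensions.
#'
#' @param layout a [trial_layout()].
#' @return list with `dims`, `start`, `goal`, `subgoal`, and a two-column
#'   matrix `blocked` of displayed wall cells.
#' @export
displayed_cells <- function(layout) {
  maze <- layout$maze
  lay <- layout
  if (lay$mirrored) lay <- mirror_geometry(lay)
  o <- lay$orientation
  op <- function(cell) orient_point(cell, o, maze$n_rows, maze$n_cols)
  blocked <- which(blocked_cells(lay), arr.ind = TRUE) - 1L
  bl <- t(apply(blocked, 1L, function(rc) op(c(rc[1], rc[2]))))
  dims <- if (o %in% c("TB", "BT")) c(maze$n_cols, maze$n_rows)
          else c(maze$n_rows, maze$n_cols)
  list(dims = dims, start = op(lay$start), goal = op(lay$goal),
       subgoal = if (is.null(lay$subgoal)) NULL else op(lay$subgoal),
       blocked = bl)
}

# ---- advantages ---------------------------------------------------------

#' Myopic and future path advantages of a layout
#'
#' Signed row offsets (positive toward the upper route in the canonical
#' frame) of the start relative to the center of the start-proximal wall
#' and of the goal (base trials) or bottleneck opening (subgoal trials)
#' relative to the center of the goal-proximal wall. Mirrored layouts are
#' canonicalized first, so mirroring negates both components.
#'
#' @param layout a [trial_layout()].
#' @return named integer vector `c(myopic = , future = )`.
#' @export
compute_advantages <- function(layout) {
  lay <- canonicalize(layout)
  if (length(lay$maze$walls) < 2L)
    stop("invalid-geometry: need a start-proximal and a goal-proximal wall",
         call. = FALSE)
  cols <- vapply(lay$maze$walls, function(w) w$column, integer(1))
  w_start <- lay$maze$walls[[which.min(cols)]]
  w_goal <- lay$maze$walls[[which.max(cols)]]
  anchor <- if (lay$condition == "subgoal") lay$subgoal else lay$goal
  c(myopic = w_start$center_row - lay$start[1],
    future = w_goal$center_row - anchor[1])
}

#' Classify an advantage pair into its trial-type label
#'
#' NT when both components are zero; SA when exactly one is zero (suffix
#' names the nonzero one); CA when both share a sign; IA when signs
#' oppose, with -m / -f marking the larger magnitude and no suffix on
#' equal magnitudes.
#'
#' @param adv advantage pair `c(myopic, future)`.
#' @return label string: one of NT, SA-m, SA-f, CA, IA, IA-m, IA-f.
#' @export
classify_trial <- function(adv) {
  m <- adv[[1]]; f <- adv[[2]]
  if (m == 0 && f == 0) return("NT")
  if (f == 0) return("SA-m")
  if (m == 0) return("SA-f")
  if (sign(m) == sign(f)) return("CA")
  if (abs(m) > abs(f)) return("IA-m")
  if (abs(m) < abs(f)) return("IA-f")
  "IA"
}

#' Total path-length difference implied by an advantage pair
#'
#' The two main route candidates differ in length by twice the summed
#' advantage; this returns the magnitude `2 * |myopic + future|` (the sign,
#' i.e. which route is shorter, is carried by the optimal direction).
#'
#' @param adv advantage pair `c(myopic, future)`.
#' @return nonnegative integer path-length difference.
#' @export
overall_advantage <- function(adv) {
  2L * abs(adv[[1]] + adv[[2]])
}

# ---- movement and paths -------------------------------------------------

# Walk an action sequence from the start; returns visited cells and step
# counts under both penalty rules.
walk_actions <- function(layout, actions) {
  if (length(actions) == 0L) stop("empty-trial: no actions", call. = FALSE)
  lay <- canonicalize(layout)
  maze <- lay$maze
  blocked <- blocked_cells(lay)
  cell <- lay$start
  cells <- matrix(NA_integer_, length(actions) + 1L, 2L)
  cells[1L, ] <- cell
  moved <- logical(length(actions))
  for (i in seq_along(actions)) {
    v <- .DIRS[[actions[[i]]]]
    tgt <- cell + v
    inside <- tgt[1] >= 0 && tgt[1] < maze$n_rows &&
              tgt[2] >= 0 && tgt[2] < maze$n_cols
    if (!inside) {
      if (!maze$bounded)
        stop("out-of-bounds: action leaves an unbounded grid", call. = FALSE)
      moved[i] <- FALSE               # boundary wall collision
    } else if (blocked[tgt[1] + 1L, tgt[2] + 1L]) {
      moved[i] <- FALSE               # internal wall collision
    } else {
      cell <- tgt
      moved[i] <- TRUE
    }
    cells[i + 1L, ] <- cell
  }
  list(cells = cells, moved = moved, final = cell)
}

#' Step count of an executed action sequence
#'
#' In `penalized` mode (simple-task rules) a step into a wall increases the
#' step count without moving; in `free` mode (complex-task rules) wall
#' collisions neither move nor count.
#'
#' @param layout a [trial_layout()].
#' @param actions character vector of canonical-frame moves.
#' @param penalty_mode "penalized" or "free".
#' @return integer step count.
#' @export
path_length <- function(layout, actions,
                        penalty_mode = c("penalized", "free")) {
  penalty_mode <- match.arg(penalty_mode)
  walk <- walk_actions(layout, actions)
  if (penalty_mode == "penalized") length(actions) else sum(walk$moved)
}

# BFS distance from `from` to every cell; -1 where unreachable.
bfs_distances <- function(blocked, from) {
  nr <- nrow(blocked); nc <- ncol(blocked)
  dist <- matrix(-1L, nr, nc)
  qi <- integer(nr * nc); qr <- integer(nr * nc)
  head <- 1L; tail <- 1L
  qi[1L] <- from[1]; qr[1L] <- from[2]
  dist[from[1] + 1L, from[2] + 1L] <- 0L
  while (head <= tail) {
    r <- qi[head]; c <- qr[head]; head <- head + 1L
    d <- dist[r + 1L, c + 1L]
    for (v in .DIRS) {
      r2 <- r + v[1]; c2 <- c + v[2]
      if (r2 >= 0L && r2 < nr && c2 >= 0L && c2 < nc &&
          !blocked[r2 + 1L, c2 + 1L] && dist[r2 + 1L, c2 + 1L] < 0L) {
        dist[r2 + 1L, c2 + 1L] <- d + 1L
        tail <- tail + 1L
        qi[tail] <- r2; qr[tail] <- c2
      }
    }
  }
  dist
}

# Blocked matrix constraining passage of every internal wall to one side
# (the bottleneck wall keeps its single opening and is not constrained).
route_blocked <- function(lay, side) {
  blocked <- blocked_cells(lay)
  for (w in lay$maze$walls) {
    rows <- wall_rows(w)
    shut <- if (side == "upper") (max(rows) + 1L):(lay$maze$n_rows - 1L)
            else 0L:(min(rows) - 1L)
    blocked[shut + 1L, w$column + 1L] <- TRUE
  }
  blocked
}

#' Lengths of the two main route candidates
#'
#' Shortest collision-free path length from the start to the goal for the
#' upper route (clearing every internal wall above) and the lower route
#' (clearing every internal wall below), by breadth-first search in the
#' canonical frame. Subgoal layouts route through the bottleneck
#' automatically.
#'
#' @param layout a [trial_layout()].
#' @return named numeric vector `c(upper = , lower = )` (Inf if a route is
#'   impossible).
#' @export
main_candidate_lengths <- function(layout) {
  lay <- canonicalize(layout)
  len_route <- function(side) {
    dist <- bfs_distances(route_blocked(lay, side), lay$goal)
    d <- dist[lay$start[1] + 1L, lay$start[2] + 1L]
    if (d < 0L) Inf else d
  }
  c(upper = len_route("upper"), lower = len_route("lower"))
}

#' Optimal initial direction(s) of a layout
#'
#' Direction(s) whose best continuation reaches the goal (through the
#' bottleneck when present) in the minimum number of steps; both are
#' returned on ties.
#'
#' @param layout a [trial_layout()].
#' @return nonempty subset of `c("up", "down")`.
#' @export
optimal_initial_directions <- function(layout) {
  lens <- main_candidate_lengths(layout)
  if (all(!is.finite(lens)))
    stop("invalid-geometry: goal unreachable from start", call. = FALSE)
  names(lens)[lens == min(lens)] |>
    (\(x) ifelse(x == "upper", "up", "down"))()
}

# Shortest action sequence from start to goal committed to one main route
# (clearing the internal walls on that side); deterministic tie-breaking.
shortest_actions <- function(layout, route = c("upper", "lower")) {
  route <- match.arg(route)
  lay <- canonicalize(layout)
  blocked <- route_blocked(lay, route)
  dist <- bfs_distances(blocked, lay$goal)
  cell <- lay$start
  if (dist[cell[1] + 1L, cell[2] + 1L] < 0L)
    stop("invalid-geometry: goal unreachable on the ", route, " route",
         call. = FALSE)
  # prefer the committing vertical move so the route is identifiable from
  # the action sequence
  order_dirs <- if (route == "upper") c("up", "right", "left", "down")
                else c("down", "right", "left", "up")
  actions <- character(0)
  while (!all(cell == lay$goal)) {
    d <- dist[cell[1] + 1L, cell[2] + 1L]
    for (nm in order_dirs) {
      tgt <- cell + .DIRS[[nm]]
      if (tgt[1] >= 0 && tgt[1] < lay$maze$n_rows &&
          tgt[2] >= 0 && tgt[2] < lay$maze$n_cols &&
          !blocked[tgt[1] + 1L, tgt[2] + 1L] &&
          dist[tgt[1] + 1L, tgt[2] + 1L] == d - 1L) {
        cell <- tgt
        actions <- c(actions, nm)
        break
      }
    }
  }
  actions
}

# ---- designed trial sets ------------------------------------------------

#' The twelve designed advantage pairings
#'
#' @return data frame with columns `label`, `myopic`, `future`.
#' @export
advantage_table <- function() {
  data.frame(
    label = c("NT", "SA-m", "SA-m", "SA-f", "SA-f", "CA",
              "IA", "IA", "IA-m", "IA-m", "IA-f", "IA-f"),
    myopic = c(0L, 2L, 1L, 0L, 0L, 1L, 1L, 2L, 2L, 3L, 1L, 1L),
    future = c(0L, 0L, 0L, 2L, 1L, 1L, -1L, -2L, -1L, -1L, -2L, -3L))
}

make_base_layout <- function(m, f, experiment = "exp1", orientation = "LR",
                             mirrored = FALSE, geometry = default_geometry()) {
  g <- geometry
  maze <- grid_maze(g$n_rows, g$n_cols,
                    walls = list(wall_spec(g$wall_cols[1], g$center_row, g$wall_length),
                                 wall_spec(g$wall_cols[2], g$center_row, g$wall_length)),
                    bounded = experiment == "exp2")
  trial_layout(maze,
               start = c(g$center_row - m, g$start_col),
               goal = c(g$center_row - f, g$goal_col),
               orientation = orientation, mirrored = mirrored,
               condition = "base", experiment = experiment,
               trial_id = sprintf("%s_base_%d_%d_%s%s", experiment, m, f,
                                  orientation, if (mirrored) "_mir" else ""))
}

make_subgoal_layout <- function(m, f, goal_end = c("upper", "lower"),
                                orientation = "LR", mirrored = FALSE,
                                geometry = default_geometry()) {
  g <- geometry
  goal_end <- match.arg(goal_end)
  maze <- grid_maze(g$n_rows, g$subgoal_n_cols,
                    walls = list(wall_spec(g$wall_cols[1], g$center_row, g$wall_length),
                                 wall_spec(g$wall_cols[2], g$center_row, g$wall_length)),
                    bounded = TRUE,
                    bottleneck = list(column = g$bottleneck_col,
                                      open_row = g$center_row - f))
  goal_row <- if (goal_end == "upper") 0L else g$n_rows - 1L
  trial_layout(maze,
               start = c(g$center_row - m, g$start_col),
               goal = c(goal_row, g$final_goal_col),
               subgoal = c(g$center_row - f, g$bottleneck_col),
               orientation = orientation, mirrored = mirrored,
               condition = "subgoal", goal_end = goal_end,
               experiment = "exp2",
               trial_id = sprintf("exp2_subgoal_%d_%d_%s_%s%s", m, f, goal_end,
                                  orientation, if (mirrored) "_mir" else ""))
}

#' Enumerate the designed base trials
#'
#' Every advantage pairing of [advantage_table()] is instantiated, each
#' mirrored vertically except the neutral (NT) layout, and the resulting 23
#' signed layouts are expanded over orientations: all four for the simple
#' task (92 trials), or the two orientations of one group for the complex
#' task (46 trials).
#'
#' @param experiment "exp1" or "exp2".
#' @param orientation_group "horizontal" (LR, RL) or "vertical" (TB, BT);
#'   required for exp2.
#' @param geometry geometry constants, see [default_geometry()].
#' @return list of [trial_layout()] objects.
#' @export
enumerate_base_trials <- function(experiment = c("exp1", "exp2"),
                                  orientation_group = NULL,
                                  geometry = default_geometry()) {
  experiment <- match.arg(experiment)
  orientations <- if (experiment == "exp1") c("LR", "RL", "TB", "BT")
  else {
    if (is.null(orientation_group))
      stop("exp2 needs an orientation group", call. = FALSE)
    switch(match.arg(orientation_group, c("horizontal", "vertical")),
           horizontal = c("LR", "RL"), vertical = c("TB", "BT"))
  }
  tab <- advantage_table()
  out <- list()
  for (i in seq_len(nrow(tab))) {
    mirrors <- if (tab$myopic[i] == 0L && tab$future[i] == 0L) FALSE
               else c(FALSE, TRUE)
    for (mir in mirrors)
      for (o in orientations)
        out[[length(out) + 1L]] <-
          make_base_layout(tab$myopic[i], tab$future[i], experiment, o, mir,
                           geometry)
  }
  out
}

#' Enumerate the designed subgoal trials
#'
#' The 23 signed advantage layouts (12 designed, 11 mirrored) each appear
#' in the two orientations of the group and with the final goal at both
#' ends of the goal column: 92 trials.
#'
#' @inheritParams enumerate_base_trials
#' @return list of [trial_layout()] objects.
#' @export
enumerate_subgoal_trials <- function(orientation_group = c("horizontal", "vertical"),
                                     geometry = default_geometry()) {
  orientations <- switch(match.arg(orientation_group),
                         horizontal = c("LR", "RL"), vertical = c("TB", "BT"))
  tab <- advantage_table()
  out <- list()
  for (i in seq_len(nrow(tab))) {
    mirrors <- if (tab$myopic[i] == 0L && tab$future[i] == 0L) FALSE
               else c(FALSE, TRUE)
    for (mir in mirrors)
      for (o in orientations)
        for (ge in c("upper", "lower"))
          out[[length(out) + 1L]] <-
            make_subgoal_layout(tab$myopic[i], tab$future[i], ge, o, mir,
                                geometry)
  }
  out
}

#' Sample filler trials
#'
#' Fillers randomize orientation, the length of each internal wall (3, 5
#' or 7, uniform), wall vertical shifts (uniform over positions that never
#' block the top or bottom path), and start/goal cells (uniform left of the
#' start-proximal wall / right of the goal-proximal wall). Two length-7
#' walls are never both centered, so no filler duplicates a designed base
#' layout. Reproducible under `rng_seed`.
#'
#' @param n number of fillers.
#' @param rng_seed integer seed.
#' @param geometry geometry constants.
#' @return list of [trial_layout()] objects.
#' @export
enumerate_filler_trials <- function(n, rng_seed,
                                    geometry = default_geometry()) {
  stopifnot(n >= 0)
  if (n == 0L) return(list())
  g <- geometry
  withr::with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        lens <- sample(c(3L, 5L, 7L), 2L, replace = TRUE)
        centers <- vapply(lens, function(L) {
          half <- (L - 1L) %/% 2L
          sample((1L + half):(g$n_rows - 2L - half), 1L)
        }, integer(1))
        if (!(all(lens == 7L) && all(centers == g$center_row))) break
      }
      orientation <- sample(c("LR", "RL", "TB", "BT"), 1L)
      start <- c(sample(0:(g$n_rows - 1L), 1L),
                 sample(0:(g$wall_cols[1] - 1L), 1L))
      goal <- c(sample(0:(g$n_rows - 1L), 1L),
                sample((g$wall_cols[2] + 1L):(g$n_cols - 1L), 1L))
      maze <- grid_maze(g$n_rows, g$n_cols,
                        walls = list(wall_spec(g$wall_cols[1], centers[1], lens[1]),
                                     wall_spec(g$wall_cols[2], centers[2], lens[2])))
      trial_layout(maze, start, goal, orientation = orientation,
                   condition = "filler", experiment = "exp1",
                   trial_id = sprintf("exp1_filler_%03d", i))
    })
  })
}

# ---- serialization ------------------------------------------------------

layout_geometry_json <- function(layout) {
  maze <- layout$maze
  jsonlite::toJSON(list(
    n_rows = maze$n_rows, n_cols = maze$n_cols, bounded = maze$bounded,
    walls = lapply(maze$walls, function(w) unclass(w)),
    bottleneck = maze$bottleneck,
    start = layout$start, goal = layout$goal, subgoal = layout$subgoal),
    auto_unbox = TRUE)
}

#' Tabulate a trial list
#'
#' One row per trial with identifiers, presentation metadata, signed
#' advantages, the trial-type label, and a JSON-encoded geometry column
#' from which the layout can be rebuilt.
#'
#' @param layouts list of [trial_layout()] objects.
#' @return data frame.
#' @export
trials_to_df <- function(layouts) {
  rows <- lapply(seq_along(layouts), function(i) {
    lay <- layouts[[i]]
    adv <- compute_advantages(lay)
    data.frame(trial_id = if (is.null(lay$trial_id)) sprintf("trial_%03d", i)
                          else lay$trial_id,
               experiment = lay$experiment, condition = lay$condition,
               orientation = lay$orientation, mirrored = lay$mirrored,
               myopic_adv = adv[["myopic"]], future_adv = adv[["future"]],
               trial_type = classify_trial(adv),
               goal_end = lay$goal_end,
               geometry = as.character(layout_geometry_json(lay)))
  })
  do.call(rbind, rows)
}

#' Write / read trial tables as CSV
#'
#' @param layouts list of [trial_layout()] objects.
#' @param path CSV file path.
#' @return `read_trials` returns the reconstructed list of layouts (the
#'   tabular form is available via [trials_to_df()]).
#' @export
write_trials <- function(layouts, path) {
  utils::write.csv(trials_to_df(layouts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    geo <- jsonlite::fromJSON(df$geometry[i])
    drop_empty <- function(x) if (length(x) == 0L) NULL else x
    maze <- grid_maze(geo$n_rows, geo$n_cols,
                      walls = lapply(seq_len(nrow(geo$walls)), function(k)
                        wall_spec(geo$walls$column[k], geo$walls$center_row[k],
                                  geo$walls$length[k])),
                      bounded = geo$bounded,
                      bottleneck = drop_empty(geo$bottleneck))
    trial_layout(maze, geo$start, geo$goal,
                 subgoal = drop_empty(geo$subgoal),
                 orientation = df$orientation[i], mirrored = df$mirrored[i],
                 condition = df$condition[i], goal_end = df$goal_end[i],
                 experiment = df$experiment[i], trial_id = df$trial_id[i])
  })
}
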