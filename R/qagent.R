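# Epsilon-greedy tabular baseline on a discretized arena.  The value function
# is assumed converged: V(s) = -(shortest-path distance to the goal cell) on
# an 8-connected grid.  The agent takes the value-greedy neighbor with
# probability 1 - epsilon and a uniformly random neighbor otherwise.  With a
# goal fixed at the old target, a greedy agent retraces the old path and
# never discovers a switched target.

#' Discretize an arena into a grid for the Q baseline
#'
#' @param arena an [arena_spec()].
#' @param cell_cm grid cell size, cm.
#' @return list with grid dimensions, cell size and the port cell.
#' @export
arena_grid <- function(arena = arena_spec(), cell_cm = 3) {
  nx <- floor(arena$width / cell_cm)
  ny <- floor(arena$height / cell_cm)
  x0 <- arena$port_xy[1] - arena$width / 2
  y0 <- arena$port_xy[2]
  port_cell <- c(
    pmin(nx, pmax(1, ceiling((arena$port_xy[1] - x0) / cell_cm + 1e-9))),
    pmin(ny, pmax(1, ceiling((arena$port_xy[2] - y0) / cell_cm + 1e-9)))
  )
  list(nx = nx, ny = ny, cell_cm = cell_cm, x0 = x0, y0 = y0,
       port_cell = port_cell)
}

cell_of_point <- function(grid, xy) {
  c(pmin(grid$nx, pmax(1, ceiling((xy[1] - grid$x0) / grid$cell_cm))),
    pmin(grid$ny, pmax(1, ceiling((xy[2] - grid$y0) / grid$cell_cm))))
}

# Shortest-path distance on an open 8-connected grid is the Chebyshev
# distance to the goal.
grid_value <- function(grid, goal_cell) {
  gx <- matrix(rep(seq_len(grid$nx), grid$ny), grid$nx, grid$ny)
  gy <- matrix(rep(seq_len(grid$ny), each = grid$nx), grid$nx, grid$ny)
  -pmax(abs(gx - goal_cell[1]), abs(gy - goal_cell[2]))
}

#' Run the epsilon-greedy Q baseline
#'
#' @param grid an [arena_grid()].
#' @param goal_xy goal position in cm (e.g. the pre-switch target center).
#' @param epsilon exploration probability in `[0, 1]` (1 = random walk).
#' @param n_trajectories number of trajectories to simulate.
#' @param start_xy start position in cm (default the port).
#' @param step_cap maximum steps per trajectory.
#' @param seed integer seed.
#' @return list of trajectories; each a data.frame with `x`, `y` (cm),
#'   `greedy` (logical per step) and an attribute `reached_goal`.
#' @export
run_q_baseline <- function(grid, goal_xy, epsilon, n_trajectories = 1L,
                           start_xy = NULL, step_cap = 500L, seed = 1L) {
  check_number(epsilon, "epsilon", lower = 0, upper = 1)
  if (grid$nx < 2 || grid$ny < 2) {
    fl_stop("grid too small", "configuration_error")
  }
  set.seed(as.integer(seed))
  goal_cell <- cell_of_point(grid, goal_xy)
  start_cell <- if (is.null(start_xy)) grid$port_cell
                else cell_of_point(grid, start_xy)
  V <- grid_value(grid, goal_cell)
  moves <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                 dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  out <- vector("list", n_trajectories)
  for (k in seq_len(n_trajectories)) {
    pos <- start_cell
    path <- matrix(NA_integer_, step_cap + 1L, 2L)
    greedy <- logical(step_cap)
    path[1, ] <- pos
    steps <- 0L
    while (steps < step_cap && !(pos[1] == goal_cell[1] && pos[2] == goal_cell[2])) {
      cand <- cbind(pos[1] + moves[, 1], pos[2] + moves[, 2])
      ok <- cand[, 1] >= 1 & cand[, 1] <= grid$nx &
            cand[, 2] >= 1 & cand[, 2] <= grid$ny
      cand <- cand[ok, , drop = FALSE]
      vals <- V[cbind(cand[, 1], cand[, 2])]
      best <- which(vals == max(vals))
      g <- stats::runif(1) >= epsilon
      pick <- if (g) {
        best[sample.int(length(best), 1L)]
      } else {
        sample.int(nrow(cand), 1L)
      }
      steps <- steps + 1L
      greedy[steps] <- vals[pick] == max(vals)
      pos <- cand[pick, ]
      path[steps + 1L, ] <- pos
    }
    path <- path[seq_len(steps + 1L), , drop = FALSE]
    traj <- data.frame(
      x = grid$x0 + (path[, 1] - 0.5) * grid$cell_cm,
      y = grid$y0 + (path[, 2] - 0.5) * grid$cell_cm,
      greedy = c(greedy[seq_len(steps)], NA)
    )
    attr(traj, "reached_goal") <-
      pos[1] == goal_cell[1] && pos[2] == goal_cell[2]
    out[[k]] <- traj
  }
  out
}
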