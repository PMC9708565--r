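# Simulated task environments: free-foraging arena (STF) and head-fixed
# joystick (NTF).  Geometry and reward rules only; trial timing constants are
# carried on the spec objects and consumed by the session loop.

#' Axis-aligned rectangle
#'
#' @param xmin,xmax,ymin,ymax rectangle edges (cm).
#' @return named numeric vector of class `fl_rect`.
#' @export
rect <- function(xmin, xmax, ymin, ymax) {
  if (!(xmin < xmax && ymin < ymax)) {
    fl_stop("rectangle edges must satisfy xmin < xmax and ymin < ymax",
            "invalid_input")
  }
  structure(c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "fl_rect")
}

point_in_rect <- function(x, y, r) {
  x >= r[["xmin"]] & x <= r[["xmax"]] & y >= r[["ymin"]] & y <= r[["ymax"]]
}

rects_overlap <- function(a, b) {
  a[["xmin"]] <= b[["xmax"]] && b[["xmin"]] <= a[["xmax"]] &&
    a[["ymin"]] <= b[["ymax"]] && b[["ymin"]] <= a[["ymax"]]
}

#' Spatial target foraging (STF) arena specification
#'
#' Defines the 75 cm x 75 cm open arena with the reward port at the origin and
#' the y axis pointing into the arena.  The collection area is a 20 x 14 cm
#' rectangle around the port; the two unmarked 18 x 14 cm target areas are
#' centered ~34 cm (target 1) and ~52 cm (target 2) from the port.  Reward is
#' triggered by entering the active target rectangle anywhere along a
#' trajectory; the next trial arms 2 s after re-entry into the collection area.
#'
#' @param width,height arena dimensions, cm.
#' @param port_xy reward port position; the coordinate origin by convention.
#' @param collection_rect collection area rectangle ([rect()]).
#' @param target_rects named list of target rectangles keyed by target id.
#' @param trial_rearm_delay seconds between collection-area entry and the next
#'   trial becoming available.
#' @return object of class `fl_arena_spec`.
#' @export
arena_spec <- function(width = 75, height = 75,
                       port_xy = c(0, 0),
                       collection_rect = rect(-10, 10, 0, 14),
                       target_rects = list(
                         "1" = rect(-9, 9, 27, 41),
                         "2" = rect(-9, 9, 45, 59)
                       ),
                       trial_rearm_delay = 2) {
  check_number(width, "width", lower = 1)
  check_number(height, "height", lower = 1)
  check_number(trial_rearm_delay, "trial_rearm_delay", lower = 0)
  if (length(port_xy) != 2L || !all(is.finite(port_xy))) {
    fl_stop("`port_xy` must be a finite 2-vector", "invalid_input")
  }
  if (!inherits(collection_rect, "fl_rect")) {
    fl_stop("`collection_rect` must be built with rect()", "invalid_input")
  }
  if (length(target_rects) < 1L || is.null(names(target_rects))) {
    fl_stop("`target_rects` must be a named list of rect()s", "invalid_input")
  }
  bounds <- rect(port_xy[1] - width / 2, port_xy[1] + width / 2,
                 port_xy[2], port_xy[2] + height)
  for (id in names(target_rects)) {
    r <- target_rects[[id]]
    if (!inherits(r, "fl_rect")) {
      fl_stop(sprintf("target %s is not a rect()", id), "invalid_input")
    }
    inside <- r[["xmin"]] >= bounds[["xmin"]] && r[["xmax"]] <= bounds[["xmax"]] &&
      r[["ymin"]] >= bounds[["ymin"]] && r[["ymax"]] <= bounds[["ymax"]]
    if (!inside) {
      fl_stop(sprintf("target %s does not lie fully inside the arena", id),
              "invalid_input")
    }
    if (rects_overlap(r, collection_rect)) {
      fl_stop(sprintf("target %s overlaps the collection area", id),
              "invalid_input")
    }
  }
  structure(list(width = width, height = height, port_xy = port_xy,
                 collection_rect = collection_rect,
                 target_rects = target_rects,
                 trial_rearm_delay = trial_rearm_delay),
            class = "fl_arena_spec")
}

#' Non-navigational target foraging (NTF) joystick specification
#'
#' Radial target bands in joystick displacement (mm).  A trial is rewarded
#' when displacement stays inside the active band contiguously for at least
#' `occupancy_required` seconds (~100 ms in the task); reward is delivered
#' `reward_delay` seconds after the qualifying crossing and followed by an
#' `iti`-second inter-trial interval.
#'
#' The default bands (block 1 at 4-6 mm, block 2 at 8-10 mm) put the two
#' targets on the order of 10 mm from the joystick rest position and are
#' configurable.
#'
#' @param target_bands named list of `c(d_lo, d_hi)` radial intervals, mm.
#' @param occupancy_required contiguous occupancy needed for reward, seconds.
#' @param reward_delay delay from threshold crossing to reward, seconds.
#' @param iti inter-trial interval, seconds.
#' @param trials_per_block default block length.
#' @return object of class `fl_joystick_spec`.
#' @export
joystick_spec <- function(target_bands = list("1" = c(4, 6), "2" = c(8, 10)),
                          occupancy_required = 0.1,
                          reward_delay = 1.0,
                          iti = 3.3,
                          trials_per_block = 40) {
  check_number(occupancy_required, "occupancy_required", lower = 0)
  check_number(reward_delay, "reward_delay", lower = 0)
  check_number(iti, "iti", lower = 0)
  check_number(trials_per_block, "trials_per_block", lower = 1)
  if (length(target_bands) < 1L || is.null(names(target_bands))) {
    fl_stop("`target_bands` must be a named list", "invalid_input")
  }
  for (id in names(target_bands)) {
    b <- target_bands[[id]]
    if (length(b) != 2L || !all(is.finite(b)) || !(0 < b[1] && b[1] < b[2])) {
      fl_stop(sprintf("band %s must satisfy 0 < d_lo < d_hi", id),
              "invalid_input")
    }
  }
  structure(list(target_bands = target_bands,
                 occupancy_required = occupancy_required,
                 reward_delay = reward_delay, iti = iti,
                 trials_per_block = trials_per_block),
            class = "fl_joystick_spec")
}

#' Block schedule
#'
#' Ordered target blocks; the default is the STF session structure of two
#' 80-trial blocks (near target then far target).
#'
#' @param target_id vector of target ids (character or coercible).
#' @param n_trials trials per block, positive integers.
#' @return data.frame of class `fl_block_schedule` with a `switch_index`
#'   attribute (trial index of the first trial of each block after the first).
#' @export
block_schedule <- function(target_id = c("1", "2"), n_trials = c(80, 80)) {
  if (length(target_id) != length(n_trials) || length(target_id) < 1L) {
    fl_stop("`target_id` and `n_trials` must be equal-length, non-empty",
            "invalid_input")
  }
  if (any(n_trials < 1) || any(n_trials != round(n_trials))) {
    fl_stop("`n_trials` must be positive integers", "invalid_input")
  }
  sched <- data.frame(target_id = as.character(target_id),
                      n_trials = as.integer(n_trials))
  class(sched) <- c("fl_block_schedule", "data.frame")
  attr(sched, "switch_index") <- utils::head(cumsum(sched$n_trials), -1) + 1L
  sched
}

# Map trial index -> block row index.
block_of_trial <- function(schedule, i) {
  findInterval(i, cumsum(schedule$n_trials), left.open = TRUE) + 1L
}

new_trial_outcome <- function(rewarded, intercept_time = NA_real_,
                              reward_time = NA_real_, returned_home = NA) {
  structure(list(rewarded = rewarded, intercept_time = intercept_time,
                 reward_time = reward_time, returned_home = returned_home),
            class = "fl_trial_outcome")
}

#' Evaluate an STF trajectory against the arena reward rule
#'
#' A trial is rewarded if any sample of the trajectory falls inside the active
#' target rectangle (closed boundaries); interception time is the first such
#' sample.  `returned_home` records whether a sample at or after interception
#' (or any sample, for unrewarded trials) lies in the collection area.
#'
#' @param traj position series: data.frame with columns `t`, `x`, `y` (cm).
#' @param arena an [arena_spec()].
#' @param active_target target id (name in `arena$target_rects`).
#' @return an `fl_trial_outcome` list.
#' @export
evaluate_stf_trajectory <- function(traj, arena, active_target) {
  if (is.null(traj) || nrow(traj) == 0L) {
    fl_stop("empty trajectory", "invalid_input")
  }
  active_target <- as.character(active_target)
  if (!active_target %in% names(arena$target_rects)) {
    fl_stop(sprintf("unknown target id '%s'", active_target), "key_error")
  }
  tr <- arena$target_rects[[active_target]]
  hit <- point_in_rect(traj$x, traj$y, tr)
  rewarded <- any(hit)
  idx0 <- if (rewarded) which(hit)[1] else 1L
  home <- point_in_rect(traj$x[idx0:nrow(traj)], traj$y[idx0:nrow(traj)],
                        arena$collection_rect)
  new_trial_outcome(
    rewarded = rewarded,
    intercept_time = if (rewarded) traj$t[which(hit)[1]] else NA_real_,
    reward_time = if (rewarded) traj$t[which(hit)[1]] else NA_real_,
    returned_home = any(home)
  )
}

#' Evaluate an NTF trajectory against the joystick band rule
#'
#' Rewarded iff the radial displacement stays inside the active band
#' contiguously for at least `occupancy_required` seconds; reward is delivered
#' `reward_delay` seconds after the occupancy requirement is met.
#'
#' @param traj position series: data.frame with columns `t`, `x`, `y` (mm).
#' @param spec a [joystick_spec()].
#' @param block block id (name in `spec$target_bands`).
#' @return an `fl_trial_outcome` list.
#' @export
evaluate_ntf_trajectory <- function(traj, spec, block) {
  if (is.null(traj) || nrow(traj) == 0L) {
    fl_stop("empty trajectory", "invalid_input")
  }
  block <- as.character(block)
  if (!block %in% names(spec$target_bands)) {
    fl_stop(sprintf("unknown block id '%s'", block), "key_error")
  }
  if (nrow(traj) < 2L) {
    fl_stop("trajectory too short to establish a sample interval",
            "invalid_input")
  }
  dt <- traj$t[2] - traj$t[1]
  if (spec$occupancy_required < dt) {
    fl_stop("occupancy_required is shorter than the sample interval",
            "configuration_error")
  }
  band <- spec$target_bands[[block]]
  r <- sqrt(traj$x^2 + traj$y^2)
  inside <- r >= band[1] & r <= band[2]
  need <- ceiling(spec$occupancy_required / dt)
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= need)
  if (length(ok) == 0L) {
    return(new_trial_outcome(rewarded = FALSE))
  }
  qualify_idx <- starts[ok[1]] + need - 1L
  qt <- traj$t[qualify_idx]
  new_trial_outcome(rewarded = TRUE, intercept_time = qt,
                    reward_time = qt + spec$reward_delay,
                    returned_home = NA)
}
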