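# Full simulated session: per trial, sample policy parameters, generate and
# integrate the trajectory, evaluate it against the environment, update the
# smoothed reward rate and apply the MeSH update plus any perturbation.
# The trial loop works on bare vectors (no intermediate containers) so that
# grid-search fitting can afford thousands of sessions.

#' Run a simulated foraging session
#'
#' @param env an [arena_spec()] (STF) or [joystick_spec()] (NTF).
#' @param schedule a [block_schedule()]; for STF, `target_id` names target
#'   rectangles; for NTF, joystick band ids.
#' @param policy0 initial [policy_state()].
#' @param shape a [trajectory_shape()].
#' @param noise a [noise_spec()].
#' @param mesh an [mesh_params()].
#' @param pert an [perturbation_spec()].
#' @param seed integer seed; identical inputs and seed give an identical
#'   result.
#' @param freeze_omega if TRUE the heading-offset mean is not updated
#'   (default for NTF, where only amplitude adapts).
#' @param init_spec optional [initiation_spec()]; when given, a per-trial
#'   initiation latency is sampled (NTF).
#' @param init_window initiation window per trial, seconds.
#' @param store_trajectories keep full position series per trial.
#' @return object of class `fl_sim_result`: element `trials` is a data.frame
#'   with one row per trial (sampled parameters, amplitude, outcome flags,
#'   latency), `policy_history` has `n_trials + 1` rows, plus the config
#'   snapshot and seed.
#' @export
run_session <- function(env, schedule, policy0, shape,
                        noise = noise_spec(), mesh = mesh_params(),
                        pert = perturbation_spec("none"),
                        seed = 1L,
                        freeze_omega = inherits(env, "fl_joystick_spec"),
                        init_spec = NULL, init_window = 12,
                        store_trajectories = FALSE) {
  if (nrow(schedule) == 0L) fl_stop("empty schedule", "invalid_input")
  is_ntf <- inherits(env, "fl_joystick_spec")
  if (!is_ntf && !inherits(env, "fl_arena_spec")) {
    fl_stop("`env` must be an arena_spec() or joystick_spec()", "invalid_input")
  }
  set.seed(as.integer(seed))

  n_trials <- sum(schedule$n_trials)
  block_id <- rep(seq_len(nrow(schedule)), schedule$n_trials)
  target_id <- schedule$target_id[block_id]

  dt <- shape$dt
  t_grid <- shape_times(shape)
  n_pts <- length(t_grid)
  base_heading <- -pi + 2 * pi * t_grid / shape$duration
  bumps <- speed_template(shape)
  w <- round(noise$smoothing_window / dt)
  origin <- if (is_ntf) c(0, 0) else env$port_xy

  if (is_ntf) {
    need_occ <- ceiling(env$occupancy_required / dt)
    if (env$occupancy_required < dt) {
      fl_stop("occupancy_required is shorter than the sample interval",
              "configuration_error")
    }
  } else {
    rects <- env$target_rects
    crect <- env$collection_rect
  }

  policy <- policy0
  upsilon <- 0
  a_v <- om_v <- amp_v <- ups_v <- it_v <- lat_v <- numeric(n_trials)
  rew_v <- pert_v <- logical(n_trials)
  hist_A <- numeric(n_trials + 1); hist_O <- numeric(n_trials + 1)
  hist_A[1] <- policy$A; hist_O[1] <- policy$Omega
  trajs <- if (store_trajectories) vector("list", n_trials) else NULL

  for (i in seq_len(n_trials)) {
    a_i <- max(0, stats::rnorm(1, policy$A, policy$sigma_a))
    omega_i <- stats::rnorm(1, policy$Omega, policy$sigma_omega)
    heading <- base_heading + omega_i +
      smoothed_noise(n_pts, noise$amplitude[1], w)
    speed <- bumps * a_i + smoothed_noise(n_pts, noise$amplitude[2], w)
    x <- origin[1] + c(0, cumsum((speed * cos(heading) * dt)[-n_pts]))
    y <- origin[2] + c(0, cumsum((speed * sin(heading) * dt)[-n_pts]))

    if (is_ntf) {
      band <- env$target_bands[[target_id[i]]]
      r2 <- (x - origin[1])^2 + (y - origin[2])^2
      inside <- r2 >= band[1]^2 & r2 <= band[2]^2
      runs <- rle(inside)
      ends <- cumsum(runs$lengths)
      ok <- which(runs$values & runs$lengths >= need_occ)
      rewarded <- length(ok) > 0L
      it_v[i] <- if (rewarded) {
        t_grid[ends[ok[1]] - runs$lengths[ok[1]] + need_occ]
      } else NA_real_
    } else {
      tr <- rects[[target_id[i]]]
      hit <- x >= tr[[1L]] & x <= tr[[2L]] & y >= tr[[3L]] & y <= tr[[4L]]
      rewarded <- any(hit)
      it_v[i] <- if (rewarded) t_grid[which.max(hit)] else NA_real_
    }

    masked <- i %in% pert$trial_mask
    effective_rewarded <- rewarded &&
      !(masked && pert$variant == "reward_not_detected")
    upsilon_prev <- upsilon
    upsilon <- (1 - mesh$lambda) * upsilon_prev +
      mesh$lambda * as.numeric(effective_rewarded)
    after <- mesh_update(policy, a_i, omega_i, upsilon, mesh)
    if (masked && pert$variant != "none") {
      after <- apply_perturbation(policy, after, pert, i,
                                  context = list(a_i = a_i,
                                                 omega_i = omega_i,
                                                 upsilon_prev = upsilon_prev,
                                                 mesh = mesh))
    }
    if (freeze_omega) after$Omega <- policy$Omega

    if (!is.null(init_spec)) {
      lat_v[i] <- sample_initiation_time(init_spec, init_window)$latency
    } else {
      lat_v[i] <- NA_real_
    }

    amp_v[i] <- sqrt(max((x - origin[1])^2 + (y - origin[2])^2))
    a_v[i] <- a_i; om_v[i] <- omega_i
    rew_v[i] <- rewarded; pert_v[i] <- masked; ups_v[i] <- upsilon
    if (store_trajectories) trajs[[i]] <- position_series(t_grid, x, y)

    policy <- after
    hist_A[i + 1] <- policy$A; hist_O[i + 1] <- policy$Omega
  }

  structure(list(
    trials = data.frame(
      index = seq_len(n_trials), block = block_id, target = target_id,
      a = a_v, omega = om_v, max_amplitude = amp_v, rewarded = rew_v,
      perturbed = pert_v, upsilon = ups_v, intercept_time = it_v,
      initiation_latency = lat_v
    ),
    schedule = schedule,
    policy_history = data.frame(A = hist_A, Omega = hist_O),
    trajectories = trajs,
    config = list(env = env, policy0 = policy0, shape = shape, noise = noise,
                  mesh = mesh, pert = pert, freeze_omega = freeze_omega),
    seed = as.integer(seed)
  ), class = "fl_sim_result")
}

#' Per-trial attempt statistics of a simulated session
#'
#' Converts a simulation result into the attempt-table form the behavioral
#' analyses consume (one row per trial with amplitude, heading, reward and
#' laser flags, plus the policy scaling parameter that governed the trial).
#'
#' @param sim an `fl_sim_result`.
#' @return data.frame with columns `max_amplitude`, `initial_heading`,
#'   `scaling`, `rewarded`, `laser`, `block`.
#' @export
sim_attempts <- function(sim) {
  stopifnot(inherits(sim, "fl_sim_result"))
  data.frame(
    max_amplitude = sim$trials$max_amplitude,
    initial_heading = sim$trials$omega,
    scaling = utils::head(sim$policy_history$A, -1),
    rewarded = sim$trials$rewarded,
    laser = sim$trials$perturbed,
    block = sim$trials$block
  )
}
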