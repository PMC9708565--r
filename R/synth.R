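# Synthetic sessions with known ground truth: behavioral traces driven by
# the learning agent, and aligned ROI activity with Gaussian place fields,
# heavy-tailed activation propensity and injected synchronous population
# events whose timing is retrospective (after trajectory completion, arena
# task) or prospective (before movement initiation, joystick task).

#' Synthetic-session configuration
#'
#' @param task `"stf"` or `"ntf"`.
#' @param schedule a [block_schedule()].
#' @param policy,mesh,shape,noise agent configuration (defaults appropriate
#'   for the task).
#' @param pert an [perturbation_spec()].
#' @param n_rois number of ROIs in the neural session.
#' @param pf_sigma place-field width, cm.
#' @param peak_hz median place-field peak transient rate, Hz; per-ROI peaks
#'   are log-normal around it.
#' @param log_sigma s.d. of log peak rates (heavy tail).
#' @param background_hz spatially untuned background transient rate, Hz.
#' @param spe_rate overall SPE rate, Hz.
#' @param spe_timing `"retrospective"` (within 2 s after trajectory stop),
#'   `"prospective"` (within 2 s before movement onset) or `"uniform"`.
#' @param spe_window width of the eligible SPE window, seconds.
#' @param spe_participation fraction of ROIs recruited per SPE.
#' @param n_ensembles number of recurring SPE ensembles.
#' @param frame_rate imaging frame rate, Hz (10 or 17).
#' @param calcium_tau dF/F exponential decay constant, seconds.
#' @param dff_noise_sd dF/F additive noise s.d.
#' @param seed integer seed.
#' @return list of class `fl_synth_config`.
#' @export
synth_config <- function(task = c("stf", "ntf"),
                         schedule = NULL,
                         policy = NULL, mesh = mesh_params(),
                         shape = NULL, noise = noise_spec(),
                         pert = perturbation_spec("none"),
                         n_rois = 100, pf_sigma = 6, peak_hz = 3,
                         log_sigma = 1, background_hz = 0.1,
                         spe_rate = 0.5,
                         spe_timing = c("retrospective", "prospective",
                                        "uniform"),
                         spe_window = 2, spe_participation = 0.2,
                         n_ensembles = 3,
                         frame_rate = 10, calcium_tau = 0.5,
                         dff_noise_sd = 0.1, seed = 1L) {
  task <- match.arg(task)
  spe_timing <- match.arg(spe_timing)
  if (is.null(shape)) shape <- if (task == "stf") stf_shape() else ntf_shape()
  if (is.null(policy)) {
    policy <- if (task == "stf") default_stf_policy(shape)
              else default_ntf_policy(shape)
  }
  if (is.null(schedule)) {
    schedule <- if (task == "stf") block_schedule()
                else block_schedule(c("1", "2"), c(40, 40))
  }
  if (task == "ntf" && spe_timing == "retrospective") {
    fl_stop("retrospective SPE timing is an arena-task regime",
            "configuration_error")
  }
  check_number(spe_rate, "spe_rate", lower = 1e-9)
  check_number(spe_participation, "spe_participation", lower = 0, upper = 1)
  structure(list(task = task, schedule = schedule, policy = policy,
                 mesh = mesh, shape = shape, noise = noise, pert = pert,
                 n_rois = n_rois, pf_sigma = pf_sigma, peak_hz = peak_hz,
                 log_sigma = log_sigma, background_hz = background_hz,
                 spe_rate = spe_rate, spe_timing = spe_timing,
                 spe_window = spe_window,
                 spe_participation = spe_participation,
                 n_ensembles = n_ensembles, frame_rate = frame_rate,
                 calcium_tau = calcium_tau, dff_noise_sd = dff_noise_sd,
                 seed = as.integer(seed)),
            class = "fl_synth_config")
}

#' Generate a synthetic behavioral session
#'
#' Runs the learning agent through the task and lays the per-trial
#' trajectories out on a continuous session clock with inter-trial rest at
#' the port (2-s re-arm plus a random extra for the arena task; 3.3-s ITI
#' plus the sampled initiation latency for the joystick task).  Reward and
#' laser flags are placed on the trace at the appropriate times.
#'
#' @param cfg an [synth_config()].
#' @param env environment override (defaults per task).
#' @param init_spec optional [initiation_spec()] for NTF initiation
#'   latencies.
#' @return list with `trace` (data.frame `t`, `x`, `y`, `reward_flag`,
#'   `laser_flag`, `block_id`), `events` (one row per trial), `sim` (the
#'   `fl_sim_result`) and `truth` (per-trial ground truth).
#' @export
synth_behavior_session <- function(cfg, env = NULL, init_spec = NULL) {
  if (!inherits(cfg, "fl_synth_config")) {
    fl_stop("`cfg` must be a synth_config()", "configuration_error")
  }
  is_ntf <- cfg$task == "ntf"
  if (is.null(env)) env <- if (is_ntf) joystick_spec() else arena_spec()
  sim <- run_session(env, cfg$schedule, cfg$policy, cfg$shape,
                     noise = cfg$noise, mesh = cfg$mesh, pert = cfg$pert,
                     seed = cfg$seed, init_spec = init_spec,
                     store_trajectories = TRUE)
  dt <- cfg$shape$dt
  set.seed(cfg$seed + 7L)
  n_tr <- nrow(sim$trials)
  rest_dur <- if (is_ntf) {
    lat <- sim$trials$initiation_latency
    lat[is.na(lat)] <- 3
    env$iti + lat
  } else {
    env$trial_rearm_delay + stats::runif(n_tr, 0, 2)
  }
  pieces <- vector("list", n_tr)
  ev <- sim$trials
  t0 <- 0
  t_start <- t_stop <- t_intercept <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    traj <- sim$trajectories[[i]]
    n_mv <- nrow(traj)
    n_rest <- max(2L, round(rest_dur[i] / dt))
    rest_xy <- cbind(stats::rnorm(n_rest, 0, 0.02),
                     stats::rnorm(n_rest, 0, 0.02))
    piece <- data.frame(
      t = t0 + seq(0, by = dt, length.out = n_mv + n_rest),
      x = c(traj$x, traj$x[n_mv] * 0 + rest_xy[, 1]),
      y = c(traj$y, traj$y[n_mv] * 0 + rest_xy[, 2]),
      reward_flag = 0, laser_flag = 0,
      block_id = ev$block[i]
    )
    if (ev$rewarded[i]) {
      ri <- min(n_mv + n_rest, 1L + round(ev$intercept_time[i] / dt))
      piece$reward_flag[ri] <- 1
    }
    if (ev$perturbed[i]) {
      piece$laser_flag[(n_mv + 1L):min(n_mv + n_rest,
                                       n_mv + round(1 / dt))] <- 1
    }
    t_start[i] <- t0
    t_stop[i] <- t0 + (n_mv - 1L) * dt
    t_intercept[i] <- if (ev$rewarded[i]) t0 + ev$intercept_time[i] else NA
    t0 <- t0 + (n_mv + n_rest) * dt
    pieces[[i]] <- piece
  }
  trace <- do.call(rbind, pieces)
  events <- data.frame(
    trial = ev$index, block = ev$block, target = ev$target,
    t_start = t_start, t_stop = t_stop, t_intercept = t_intercept,
    rewarded = ev$rewarded, laser = ev$perturbed
  )
  list(trace = trace, events = events, sim = sim,
       truth = list(a = ev$a, omega = ev$omega, rewarded = ev$rewarded,
                    policy_history = sim$policy_history,
                    movement_onsets = t_start, movement_stops = t_stop))
}

#' Smooth open-field exploration trace
#'
#' Ornstein-Uhlenbeck velocity process reflected at the arena walls;
#' produces the arena coverage needed for place-map and decoder positive
#' controls (the task's stereotyped loops do not tile the arena).
#'
#' @param duration seconds.
#' @param dt sample interval, seconds.
#' @param arena an [arena_spec()].
#' @param mean_speed approximate running speed, cm/s.
#' @param seed integer seed.
#' @return data.frame with `t`, `x`, `y`.
#' @export
synth_open_field_trace <- function(duration = 600, dt = 0.1,
                                   arena = arena_spec(), mean_speed = 12,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  n <- round(duration / dt)
  th <- 0.1                       # velocity relaxation per step
  sig <- mean_speed * sqrt(2 * th - th^2) / sqrt(pi / 2) * sqrt(dt / dt)
  vx <- vy <- numeric(n)
  x <- y <- numeric(n)
  xlim <- c(arena$port_xy[1] - arena$width / 2,
            arena$port_xy[1] + arena$width / 2)
  ylim <- c(arena$port_xy[2], arena$port_xy[2] + arena$height)
  x[1] <- mean(xlim); y[1] <- mean(ylim)
  for (k in 2:n) {
    vx[k] <- vx[k - 1] * (1 - th) + stats::rnorm(1, 0, sig)
    vy[k] <- vy[k - 1] * (1 - th) + stats::rnorm(1, 0, sig)
    x[k] <- x[k - 1] + vx[k] * dt
    y[k] <- y[k - 1] + vy[k] * dt
    if (x[k] < xlim[1]) { x[k] <- 2 * xlim[1] - x[k]; vx[k] <- -vx[k] }
    if (x[k] > xlim[2]) { x[k] <- 2 * xlim[2] - x[k]; vx[k] <- -vx[k] }
    if (y[k] < ylim[1]) { y[k] <- 2 * ylim[1] - y[k]; vy[k] <- -vy[k] }
    if (y[k] > ylim[2]) { y[k] <- 2 * ylim[2] - y[k]; vy[k] <- -vy[k] }
  }
  data.frame(t = seq(0, by = dt, length.out = n), x = x, y = y)
}

#' Generate a synthetic neural session aligned to a behavior trace
#'
#' ROI spike trains are inhomogeneous Poisson draws from Gaussian place
#' fields (plus an untuned background) with log-normal peak rates; SPEs are
#' injected at the configured overall rate inside the eligible timing
#' windows (after trajectory stops, before movement onsets, or uniformly),
#' each recruiting one of a small set of recurring ensembles.  dF/F is the
#' spike train convolved with an exponential calcium kernel plus Gaussian
#' noise.
#'
#' @param trace data.frame `t`, `x`, `y` (any sampling; resampled to the
#'   imaging frame rate).
#' @param cfg an [synth_config()].
#' @param events optional per-trial events table (from
#'   [synth_behavior_session()]); required for retrospective/prospective SPE
#'   timing.
#' @param place_cells if FALSE, ROIs have only background rate (negative
#'   control for tuning-dependent analyses).
#' @return list with `roi` (RoiMatrix: `dff`, `spikes`, `frame_times`,
#'   `frame_xy`, `frame_rate`) and `truth` (field centers, peak rates, SPE
#'   frames, ensembles, per-event ensemble ids).
#' @export
synth_neural_session <- function(trace, cfg, events = NULL,
                                 place_cells = TRUE) {
  set.seed(cfg$seed + 101L)
  fr <- cfg$frame_rate
  ft <- seq(min(trace$t), max(trace$t), by = 1 / fr)
  fx <- stats::approx(trace$t, trace$x, xout = ft)$y
  fy <- stats::approx(trace$t, trace$y, xout = ft)$y
  n_fr <- length(ft); n_roi <- cfg$n_rois
  arena <- arena_spec()
  centers <- cbind(stats::runif(n_roi, -arena$width / 2, arena$width / 2),
                   stats::runif(n_roi, 0, arena$height))
  peaks <- exp(stats::rnorm(n_roi, log(cfg$peak_hz), cfg$log_sigma))
  rates <- matrix(cfg$background_hz, n_roi, n_fr)
  if (place_cells) {
    for (j in seq_len(n_roi)) {
      d2 <- (fx - centers[j, 1])^2 + (fy - centers[j, 2])^2
      rates[j, ] <- rates[j, ] + peaks[j] * exp(-d2 / (2 * cfg$pf_sigma^2))
    }
  }
  spikes <- matrix(stats::rpois(n_roi * n_fr, rates / fr), n_roi, n_fr)

  # recurring SPE ensembles
  n_part <- max(1L, round(cfg$spe_participation * n_roi))
  ensembles <- lapply(seq_len(cfg$n_ensembles),
                      function(e) sample(n_roi, n_part))
  # eligible windows on the session clock
  windows <- if (cfg$spe_timing == "uniform" || is.null(events)) {
    cbind(min(ft), max(ft))
  } else if (cfg$spe_timing == "retrospective") {
    cbind(events$t_stop, events$t_stop + cfg$spe_window)
  } else {
    cbind(pmax(0, events$t_start - cfg$spe_window), events$t_start)
  }
  total_t <- max(ft) - min(ft)
  win_t <- sum(windows[, 2] - windows[, 1])
  n_spe <- stats::rpois(1, cfg$spe_rate * total_t)
  # sample event times in the eligible windows, enforcing >= 0.4 s
  # separation so injected events stay individually resolvable; top up
  # until the target count is reached (or the windows saturate)
  spe_times <- numeric(0)
  for (it in 1:20) {
    need <- n_spe - length(spe_times)
    if (need <= 0L) break
    w_pick <- sample(nrow(windows), need, replace = TRUE,
                     prob = windows[, 2] - windows[, 1])
    cand <- stats::runif(need, windows[w_pick, 1], windows[w_pick, 2])
    spe_times <- sort(c(spe_times, cand))
    keep <- c(TRUE, diff(spe_times) > 0.4)
    spe_times <- spe_times[keep]
  }
  spe_times <- spe_times[spe_times >= min(ft) & spe_times <= max(ft)]
  spe_frames <- pmax(1L, pmin(n_fr - 1L,
                              round((spe_times - min(ft)) * fr) + 1L))
  ens_id <- if (length(spe_frames)) {
    sample(cfg$n_ensembles, length(spe_frames), replace = TRUE)
  } else integer(0)
  for (k in seq_along(spe_frames)) {
    rois <- ensembles[[ens_id[k]]]
    jitter <- sample(0:1, length(rois), replace = TRUE)
    idx <- cbind(rois, spe_frames[k] + jitter)
    spikes[idx] <- spikes[idx] + 1L
  }

  # calcium kernel: single-exponential decay
  klen <- ceiling(5 * cfg$calcium_tau * fr)
  kern <- exp(-(0:klen) / (cfg$calcium_tau * fr))
  dff <- t(apply(spikes, 1, function(s) {
    stats::convolve(s, rev(kern), type = "open")[seq_along(s)]
  }))
  dff <- dff + matrix(stats::rnorm(n_roi * n_fr, 0, cfg$dff_noise_sd),
                      n_roi, n_fr)

  list(
    roi = list(dff = dff, spikes = spikes, frame_times = ft,
               frame_xy = cbind(x = fx, y = fy), frame_rate = fr),
    truth = list(centers = centers, peaks = peaks,
                 spe_times = spe_times, spe_frames = spe_frames,
                 ensembles = ensembles, ensemble_id = ens_id,
                 window_time = win_t)
  )
}

#' Synthetic movement-locked sequence activity
#'
#' ROI x frame activity in which each ROI fires at a fixed latency from
#' trial onset (a sequence), for peri-movement sorting and reliability
#' checks.  Latencies are evenly spread over the trial unless given.
#'
#' @param n_roi number of ROIs.
#' @param n_trials number of trials.
#' @param trial_len frames per trial.
#' @param gap_len inter-trial frames (silent).
#' @param width temporal tuning width, frames.
#' @param noise_sd additive noise s.d. (signal peak is 1).
#' @param latencies optional per-ROI peak latency, frames.
#' @param seed integer seed.
#' @return list with `activity` (ROI x frame), `trial_starts`, `trial_len`,
#'   `latencies`.
#' @export
synth_trial_sequence <- function(n_roi = 50, n_trials = 20, trial_len = 50,
                                 gap_len = 20, width = 3, noise_sd = 0.1,
                                 latencies = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(latencies)) {
    latencies <- round(seq(2, trial_len - 2, length.out = n_roi))
  }
  frames_per_trial <- trial_len + gap_len
  n_fr <- n_trials * frames_per_trial
  act <- matrix(0, n_roi, n_fr)
  trial_starts <- (seq_len(n_trials) - 1L) * frames_per_trial + 1L
  tt <- seq_len(trial_len)
  for (j in seq_len(n_roi)) {
    prof <- exp(-(tt - latencies[j])^2 / (2 * width^2))
    for (s in trial_starts) act[j, s + tt - 1L] <- prof
  }
  act <- act + matrix(stats::rnorm(n_roi * n_fr, 0, noise_sd), n_roi, n_fr)
  list(activity = act, trial_starts = trial_starts, trial_len = trial_len,
       latencies = latencies)
}

#' Bin population activity and positions for decoding
#'
#' Sums spike counts and averages positions over consecutive frame bins,
#' assigning each bin to a trial id for fold construction.
#'
#' @param spikes ROI x frame matrix.
#' @param xy frame x 2 position matrix.
#' @param bin_frames frames per bin.
#' @return list with `F` (bin x ROI), `K` (bin x 2), `trial_id` (bin index
#'   groups of ~`bins_per_trial`), and `bin_frames`.
#' @param bins_per_trial bins grouped into one pseudo-trial.
#' @export
bin_population <- function(spikes, xy, bin_frames = 5, bins_per_trial = 10) {
  n_fr <- ncol(spikes)
  n_bin <- floor(n_fr / bin_frames)
  idx <- rep(seq_len(n_bin), each = bin_frames)
  Fm <- rowsum(t(spikes[, seq_len(n_bin * bin_frames), drop = FALSE]), idx)
  Km <- rowsum(xy[seq_len(n_bin * bin_frames), , drop = FALSE], idx) /
    bin_frames
  list(F = Fm, K = Km,
       trial_id = (seq_len(n_bin) - 1L) %/% bins_per_trial + 1L,
       bin_frames = bin_frames)
}
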