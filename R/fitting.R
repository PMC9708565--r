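# Grid-search fitting of the agent's forward learning rate and trajectory
# variance to switch-aligned behavioral summaries.

#' Switch-aligned amplitude summary
#'
#' Per-offset mean and s.e.m. of maximum trajectory amplitude across
#' sessions, aligned so offset 0 is the first trial of the post-switch
#' block.
#'
#' @param sessions list of attempt data.frames (column `max_amplitude`),
#'   one per session, in trial order.
#' @param switch_index trial index of the first post-switch trial (scalar or
#'   per-session vector).
#' @param window `c(pre, post)`: trials before/after the switch to include
#'   (offsets `-pre .. post`, offset 0 = first post-switch trial).
#' @return object of class `fl_switch_curve`: data.frame with
#'   `trial_offset`, `mean_amplitude`, `sem`, `prob_correct` (per-offset
#'   interception probability; NaN when the attempt tables carry no
#'   `rewarded` flag) and `n_sessions`.
#' @export
switch_aligned_summary <- function(sessions, switch_index,
                                   window = c(10, 40)) {
  if (!length(sessions)) fl_stop("no sessions", "invalid_input")
  switch_index <- rep(as.integer(switch_index), length.out = length(sessions))
  offsets <- seq(-window[1], window[2])
  vals <- matrix(NA_real_, length(sessions), length(offsets))
  truncated <- FALSE
  for (s in seq_along(sessions)) {
    amp <- sessions[[s]]$max_amplitude
    idx <- switch_index[s] + offsets
    ok <- idx >= 1 & idx <= length(amp)
    if (!all(ok)) truncated <- TRUE
    vals[s, ok] <- amp[idx[ok]]
  }
  if (truncated) warning("window exceeds some sessions; truncated")
  rewarded <- matrix(NA, length(sessions), length(offsets))
  for (s in seq_along(sessions)) {
    if (!"rewarded" %in% names(sessions[[s]])) next
    rw <- sessions[[s]]$rewarded
    idx <- switch_index[s] + offsets
    ok <- idx >= 1 & idx <= length(rw)
    rewarded[s, ok] <- rw[idx[ok]]
  }
  n_eff <- colSums(!is.na(vals))
  sems <- apply(vals, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_eff, 1))
  sems[n_eff < 2] <- 0
  curve <- data.frame(
    trial_offset = offsets,
    mean_amplitude = colMeans(vals, na.rm = TRUE),
    sem = sems,
    prob_correct = rowMeans(t(rewarded), na.rm = TRUE),
    n_sessions = n_eff
  )
  class(curve) <- c("fl_switch_curve", "data.frame")
  curve
}

#' Default fitting grid
#'
#' 5 x 5 grid over the forward learning rate and the per-trial gain
#' sampling s.d. (as a fraction of the default gain A0).
#'
#' @param alpha learning-rate values.
#' @param sigma_frac gain-s.d. values as fractions of A0.
#' @return data.frame with columns `alpha`, `sigma_frac`.
#' @export
fit_grid <- function(alpha = c(0.05, 0.1, 0.2, 0.4, 0.8),
                     sigma_frac = c(0.05, 0.1, 0.15, 0.2, 0.3)) {
  expand.grid(alpha = alpha, sigma_frac = sigma_frac)
}

# Simulate n_sims sessions at one parameter pair and return the
# switch-aligned curve.
simulate_switch_curve <- function(alpha, sigma_frac, n_sims, seed,
                                  env, schedule, shape, noise, mesh_base,
                                  policy_base, window) {
  mesh <- mesh_params(alpha = alpha, beta = mesh_base$beta,
                      lambda = mesh_base$lambda)
  pol <- policy_base
  pol$sigma_a <- sigma_frac * pol$A0
  sw <- attr(schedule, "switch_index")[1]
  sessions <- lapply(seq_len(n_sims), function(s) {
    sim_attempts(run_session(env, schedule, pol, shape, noise = noise,
                             mesh = mesh, seed = seed + s))
  })
  suppressWarnings(switch_aligned_summary(sessions, sw, window))
}

#' Grid-search fit of learning rate and trajectory variance
#'
#' For every `(alpha, sigma_a)` pair on the grid, simulates `n_sims`
#' two-block sessions, computes the switch-aligned curves and scores them
#' against the observed curves over the window.  The default loss fits the
#' mean-amplitude and interception-probability curves jointly, each term a
#' mean squared error normalized by the observed curve's variance; the
#' amplitude-only MSE (optionally s.e.m.-weighted) is available via
#' `loss`.  The two curves identify different parameter combinations - the
#' amplitude trajectory mainly constrains the product of learning rate and
#' exploration s.d., while the hit-rate level pins the s.d. itself - so the
#' joint loss resolves the (alpha, sigma) trade-off.  Ties break toward
#' smaller alpha, then smaller sigma.
#'
#' @param observed an `fl_switch_curve` (the target).
#' @param env an [arena_spec()] or [joystick_spec()].
#' @param schedule a [block_schedule()] with one switch.
#' @param shape,noise,policy_base,mesh_base simulation configuration; the
#'   grid overrides `alpha` and `sigma_a`.
#' @param grid data.frame from [fit_grid()].
#' @param n_sims simulated sessions per pair.
#' @param seed integer seed.
#' @param loss `"joint"` (amplitude + interception probability),
#'   `"amplitude"`, or `"amplitude_weighted"` (s.e.m.-weighted).
#' @return object of class `fl_fit_result`: `grid` with a `loss` column,
#'   `best` (row of the grid), `n_sims`, `seed`.
#' @export
grid_search_fit <- function(observed, env, schedule,
                            shape = stf_shape(), noise = noise_spec(),
                            policy_base = default_stf_policy(shape),
                            mesh_base = mesh_params(),
                            grid = fit_grid(), n_sims = 10, seed = 1L,
                            loss = c("joint", "amplitude",
                                     "amplitude_weighted")) {
  loss_kind <- match.arg(loss)
  if (!nrow(grid)) fl_stop("empty grid", "invalid_input")
  if (!all(is.finite(observed$mean_amplitude))) {
    fl_stop("observed curve must be finite", "invalid_input")
  }
  window <- c(-min(observed$trial_offset), max(observed$trial_offset))
  loss <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    # common random numbers across grid cells: every pair sees the same
    # session seeds, so loss differences between neighbors are not washed
    # out by independent simulation noise
    cur <- simulate_switch_curve(grid$alpha[g], grid$sigma_frac[g], n_sims,
                                 seed = seed,
                                 env, schedule, shape, noise, mesh_base,
                                 policy_base, window)
    err <- cur$mean_amplitude - observed$mean_amplitude
    loss[g] <- switch(loss_kind,
      joint = {
        errp <- cur$prob_correct - observed$prob_correct
        mean(err^2, na.rm = TRUE) /
          max(stats::var(observed$mean_amplitude), 1e-12) +
          mean(errp^2, na.rm = TRUE) /
          max(stats::var(observed$prob_correct, na.rm = TRUE), 1e-12)
      },
      amplitude = mean(err^2, na.rm = TRUE),
      amplitude_weighted = {
        wts <- 1 / pmax(observed$sem, 1e-6)^2
        mean(wts * err^2, na.rm = TRUE)
      })
  }
  if (all(!is.finite(loss))) fl_stop("all losses non-finite", "fit_error")
  grid$loss <- loss
  ord <- order(loss, grid$alpha, grid$sigma_frac)
  structure(list(grid = grid, best = grid[ord[1], , drop = FALSE],
                 n_sims = n_sims, seed = as.integer(seed)),
            class = "fl_fit_result")
}
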