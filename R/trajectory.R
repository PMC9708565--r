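# Generative trajectory model: a trial's movement is produced by a heading
# series (linear sweep across (-pi, pi] plus a per-trial offset) and a speed
# series (one or two Gaussian bumps scaled by a per-trial gain), both
# perturbed by smoothed Gaussian noise, then path-integrated.

#' Trajectory shape parameters
#'
#' `tau` holds one (joystick) or two (arena) Gaussian speed-peak times; with
#' two peaks and a full heading sweep the integrated path is an out-and-back
#' loop.  Defaults resolve the bump width comfortably (`dt << sigma`).
#'
#' @param tau Gaussian peak time(s), seconds, inside `(0, duration)`.
#' @param sigma Gaussian width, seconds.
#' @param duration trial movement duration, seconds.
#' @param dt sample interval, seconds.
#' @return object of class `fl_trajectory_shape`.
#' @export
trajectory_shape <- function(tau, sigma, duration, dt = 0.01) {
  check_number(sigma, "sigma", lower = 1e-12)
  check_number(duration, "duration", lower = 1e-12)
  check_number(dt, "dt", lower = 1e-12)
  if (length(tau) < 1L || length(tau) > 2L || any(!is.finite(tau)) ||
      any(tau <= 0 | tau >= duration)) {
    fl_stop("`tau` must be 1 or 2 peak times inside (0, duration)",
            "invalid_input")
  }
  if (dt > sigma / 5) {
    fl_stop("`dt` must be small relative to `sigma`", "invalid_input")
  }
  structure(list(tau = as.numeric(tau), sigma = sigma, duration = duration,
                 dt = dt),
            class = "fl_trajectory_shape")
}

#' @rdname trajectory_shape
#' @export
stf_shape <- function(duration = 4, dt = 0.01, sigma = 0.5,
                      tau = c(0.25, 0.75) * duration) {
  trajectory_shape(tau = tau, sigma = sigma, duration = duration, dt = dt)
}

#' @rdname trajectory_shape
#' @export
ntf_shape <- function(duration = 1.5, dt = 0.01, sigma = 0.15, tau = 0.4 * duration) {
  trajectory_shape(tau = tau, sigma = sigma, duration = duration, dt = dt)
}

#' Smoothed-noise specification
#'
#' White Gaussian noise smoothed with a moving-average window; smoothing
#' preserves the zero mean.  `amplitude` is the pre-smoothing standard
#' deviation, one value per channel (heading rad, speed units/s) or a single
#' value used for both.
#'
#' @param amplitude noise s.d. per channel (length 1 or 2: heading, speed).
#' @param smoothing_window moving-average window, seconds.
#' @return object of class `fl_noise_spec`.
#' @export
noise_spec <- function(amplitude = c(0.15, 2), smoothing_window = 0.15) {
  if (!length(amplitude) %in% c(1L, 2L) || any(!is.finite(amplitude)) ||
      any(amplitude < 0)) {
    fl_stop("`amplitude` must be 1 or 2 non-negative numbers", "invalid_input")
  }
  check_number(smoothing_window, "smoothing_window", lower = 0)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, 2L)
  structure(list(amplitude = as.numeric(amplitude),
                 smoothing_window = smoothing_window),
            class = "fl_noise_spec")
}

#' @rdname noise_spec
#' @export
zero_noise <- function() noise_spec(amplitude = c(0, 0))

shape_times <- function(shape) {
  seq(0, shape$duration, by = shape$dt)
}

# Unit-gain speed template: sum of unnormalized Gaussian bumps.
speed_template <- function(shape) {
  t <- shape_times(shape)
  g <- 0
  for (tj in shape$tau) g <- g + exp(-(t - tj)^2 / (2 * shape$sigma^2))
  g
}

#' Generate a heading series
#'
#' Noiseless headings sweep linearly from `-pi` to `pi` over the trial,
#' offset by the sampled per-trial heading `omega_i`; smoothed zero-mean
#' noise is added on top.
#'
#' @param shape a [trajectory_shape()].
#' @param omega_i per-trial heading offset, radians.
#' @param noise a [noise_spec()].
#' @return numeric heading series (radians) over `seq(0, duration, dt)`.
#' @export
generate_heading <- function(shape, omega_i, noise = zero_noise()) {
  if (!inherits(shape, "fl_trajectory_shape")) {
    fl_stop("`shape` must be a trajectory_shape()", "invalid_input")
  }
  check_number(omega_i, "omega_i")
  t <- shape_times(shape)
  base <- -pi + 2 * pi * t / shape$duration
  w <- round(noise$smoothing_window / shape$dt)
  base + omega_i + smoothed_noise(length(t), noise$amplitude[1], w)
}

#' Generate a speed series
#'
#' Noiseless speeds equal the Gaussian bump template scaled by the per-trial
#' gain `a_i` (linear in `a_i`); smoothed zero-mean noise is added on top.
#'
#' @param shape a [trajectory_shape()].
#' @param a_i per-trial speed gain (peak speed of one bump, units/s).
#' @param noise a [noise_spec()].
#' @return numeric speed series over `seq(0, duration, dt)`.
#' @export
generate_speed <- function(shape, a_i, noise = zero_noise()) {
  if (!inherits(shape, "fl_trajectory_shape")) {
    fl_stop("`shape` must be a trajectory_shape()", "invalid_input")
  }
  check_number(a_i, "a_i", lower = 0)
  g <- speed_template(shape) * a_i
  w <- round(noise$smoothing_window / shape$dt)
  g + smoothed_noise(length(g), noise$amplitude[2], w)
}

#' Path-integrate heading and speed series into a position series
#'
#' `position[k+1] = position[k] + speed[k] * (cos(heading[k]), sin(heading[k])) * dt`
#' with `position[1] = origin`.
#'
#' @param heading heading series, radians.
#' @param speed speed series, units/s; same length as `heading`.
#' @param origin 2-vector start position.
#' @param dt sample interval, seconds.
#' @return data.frame with columns `t`, `x`, `y`.
#' @export
integrate_trajectory <- function(heading, speed, origin = c(0, 0), dt) {
  n <- length(heading)
  if (length(speed) != n) {
    fl_stop("`heading` and `speed` must have equal length", "invalid_input")
  }
  if (n == 0L) fl_stop("empty series", "invalid_input")
  check_number(dt, "dt", lower = 1e-12)
  dx <- speed * cos(heading) * dt
  dy <- speed * sin(heading) * dt
  position_series(
    t = seq(0, by = dt, length.out = n),
    x = origin[1] + c(0, cumsum(dx[-n])),
    y = origin[2] + c(0, cumsum(dy[-n]))
  )
}

#' Noiseless gain-to-amplitude map
#'
#' Maximum radial excursion from the origin of the noiseless unit-gain
#' trajectory; excursion is proportional to the gain, so this constant maps a
#' speed gain to the trajectory amplitude in position units.
#'
#' @param shape a [trajectory_shape()].
#' @return scalar amplitude per unit gain.
#' @export
amplitude_gain <- function(shape) {
  h <- generate_heading(shape, 0, zero_noise())
  s <- generate_speed(shape, 1, zero_noise())
  traj <- integrate_trajectory(h, s, c(0, 0), shape$dt)
  max(sqrt(traj$x^2 + traj$y^2))
}
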