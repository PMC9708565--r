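# Hazard-gated model of self-initiated movement.  Ungated latencies follow a
# Gaussian latency density g(mean, sd) by construction: the per-step
# initiation probability is the hazard H(t) = g(t) / (1 - G(t)) times dt, so
# inverting the hazard reproduces g.  When the SPE gate is active, initiation
# additionally requires that at least one synchronous population event has
# occurred since the start of the trial window (latched gate); optogenetic
# inactivation thins SPEs inside laser windows and can add a rebound SPE at
# laser offset.

#' Movement-initiation model specification
#'
#' @param hazard_mean,hazard_sd mean and s.d. (seconds) of the Gaussian
#'   latency density the hazard is built from.
#' @param spe_gate logical; must an SPE precede initiation?
#' @param spe_rate rate (Hz) of the exponential inter-SPE interval sampler.
#' @param spe_intervals optional numeric vector of empirical inter-SPE
#'   intervals (seconds) sampled with replacement instead of the exponential.
#' @param laser_windows list of `c(onset, offset)` second pairs, or NULL.
#' @param laser_spe_factor multiplier on SPE probability inside laser windows.
#' @param rebound_prob probability of a rebound SPE at each laser offset.
#' @param dt hazard time step, seconds.
#' @return object of class `fl_initiation_spec`.
#' @export
initiation_spec <- function(hazard_mean = 3, hazard_sd = 0.48,
                            spe_gate = TRUE, spe_rate = 0.5,
                            spe_intervals = NULL,
                            laser_windows = NULL,
                            laser_spe_factor = 0.25,
                            rebound_prob = 0.9,
                            dt = 0.002) {
  check_number(hazard_mean, "hazard_mean", lower = 0)
  if (!is.numeric(hazard_sd) || length(hazard_sd) != 1L ||
      !is.finite(hazard_sd) || hazard_sd <= 0) {
    fl_stop("`hazard_sd` must be positive", "invalid_input")
  }
  check_flag(spe_gate, "spe_gate")
  check_number(spe_rate, "spe_rate", lower = 1e-9)
  check_number(laser_spe_factor, "laser_spe_factor", lower = 0, upper = 1)
  check_number(rebound_prob, "rebound_prob", lower = 0, upper = 1)
  check_number(dt, "dt", lower = 1e-9)
  if (!is.null(spe_intervals) &&
      (!is.numeric(spe_intervals) || any(spe_intervals <= 0))) {
    fl_stop("`spe_intervals` must be positive intervals", "invalid_input")
  }
  if (!is.null(laser_windows)) {
    for (w in laser_windows) {
      if (length(w) != 2L || w[1] > w[2]) {
        fl_stop("laser windows must be c(onset, offset) with onset <= offset",
                "invalid_input")
      }
    }
  }
  structure(list(hazard_mean = hazard_mean, hazard_sd = hazard_sd,
                 spe_gate = spe_gate, spe_rate = spe_rate,
                 spe_intervals = spe_intervals,
                 laser_windows = laser_windows,
                 laser_spe_factor = laser_spe_factor,
                 rebound_prob = rebound_prob, dt = dt),
            class = "fl_initiation_spec")
}

# Draw one trial's SPE times on [0, window]: renewal process from the
# interval sampler, thinned inside laser windows, plus rebound events at
# laser offsets.
draw_spe_times <- function(spec, trial_window) {
  draw_int <- if (is.null(spec$spe_intervals)) {
    function(n) stats::rexp(n, rate = spec$spe_rate)
  } else {
    function(n) {
      spec$spe_intervals[sample.int(length(spec$spe_intervals), n,
                                    replace = TRUE)]
    }
  }
  mean_int <- if (is.null(spec$spe_intervals)) 1 / spec$spe_rate
              else mean(spec$spe_intervals)
  n_guess <- ceiling(trial_window / mean_int + 8 * sqrt(trial_window / mean_int) + 8)
  times <- cumsum(draw_int(n_guess))
  while (times[length(times)] <= trial_window) {   # top up (rare)
    times <- c(times, times[length(times)] + cumsum(draw_int(n_guess)))
  }
  times <- times[times <= trial_window]
  if (!is.null(spec$laser_windows)) {
    keep <- rep(TRUE, length(times))
    for (w in spec$laser_windows) {
      in_w <- times >= w[1] & times <= w[2]
      keep[in_w] <- keep[in_w] & stats::runif(sum(in_w)) < spec$laser_spe_factor
    }
    times <- times[keep]
    for (w in spec$laser_windows) {
      if (w[2] <= trial_window && stats::runif(1) < spec$rebound_prob) {
        times <- c(times, w[2])
      }
    }
    times <- sort(times)
  }
  times
}

# Vectorized core: n latencies from the discrete-step hazard scheme.  The
# per-step success probabilities p_k = H(t_k) dt define a survival curve
# S_k = prod(1 - p_j); sampling the first success by inverse transform is
# distributionally identical to checking u_k < p_k step by step.  With the
# latched gate, steps before the first SPE have zero probability, i.e. the
# conditional survival is S_k / S_(gate-1).
sample_initiation_core <- function(spec, trial_window, n) {
  if (trial_window <= 0) {
    fl_stop("`trial_window` must be positive", "invalid_input")
  }
  dt <- spec$dt
  tk <- seq(dt / 2, trial_window, by = dt)          # step midpoints
  K <- length(tk)
  H <- stats::dnorm(tk, spec$hazard_mean, spec$hazard_sd) /
    pmax(1 - stats::pnorm(tk, spec$hazard_mean, spec$hazard_sd), 1e-300)
  p <- pmin(H * dt, 1)
  S <- cumprod(1 - p)
  latencies <- rep(NA_real_, n)
  spe_list <- vector("list", n)
  revS <- rev(S)
  for (i in seq_len(n)) {
    spe <- if (spec$spe_gate) draw_spe_times(spec, trial_window) else numeric(0)
    spe_list[[i]] <- spe
    if (spec$spe_gate) {
      if (length(spe) == 0L) next                  # gate never opens
      kg <- findInterval(spe[1], tk - dt / 2, left.open = FALSE)
      kg <- max(1L, kg)
    } else {
      kg <- 1L
    }
    s_before <- if (kg > 1L) S[kg - 1L] else 1
    target <- s_before * (1 - stats::runif(1))
    # smallest k >= kg with S[k] <= target (S decreasing).  The global
    # first crossing can precede the gate when the hazard saturates
    # (S hits 0) before the first SPE; conditionally on the gate the first
    # eligible step is kg itself, so clamp.
    m <- findInterval(target, revS)                # how many S values <= target
    if (m < 1L) next                               # survived the window
    k <- max(K - m + 1L, kg)
    latencies[i] <- (k - 1L) * dt + stats::runif(1) * dt
  }
  list(latency = latencies, spe_times = spe_list)
}

#' Sample a self-initiated movement time
#'
#' Draws SPE times from the interval sampler (thinned inside laser windows,
#' with a possible rebound event at each laser offset), then samples the
#' initiation time from the Gaussian-latency hazard, gated - if `spe_gate` -
#' on at least one SPE having occurred since the window start.  Returns
#' `NA` latency when no initiation happens within the window.
#'
#' @param spec an [initiation_spec()].
#' @param trial_window available time for initiation, seconds.
#' @param n number of independent trials to draw.
#' @return for `n = 1` a list with `latency` (scalar, `NA` if none) and
#'   `spe_times`; for `n > 1` a list with vector `latency` and list
#'   `spe_times`.
#' @export
sample_initiation_time <- function(spec, trial_window, n = 1L) {
  if (!inherits(spec, "fl_initiation_spec")) {
    fl_stop("`spec` must be initiation_spec()", "invalid_input")
  }
  out <- sample_initiation_core(spec, trial_window, n)
  if (n == 1L) {
    list(latency = out$latency[1], spe_times = out$spe_times[[1]])
  } else {
    out
  }
}
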