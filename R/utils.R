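# Internal helpers: classed errors, angle arithmetic, smoothed noise.

fl_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "foragerl_error", "error", "condition")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         class = "invalid_input") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fl_stop(sprintf("`%s` must be a single finite number", name), class)
  }
  if (x < lower || x > upper) {
    fl_stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                    format(lower), format(upper), format(x)), class)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    fl_stop(sprintf("`%s` must be TRUE or FALSE", name), "invalid_input")
  }
  invisible(x)
}

#' Wrap an angle to (-pi, pi]
#'
#' @param theta angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(theta) {
  w <- atan2(sin(theta), cos(theta))
  # atan2 maps pi to pi and -pi to pi only up to sign of the zero sine term;
  # force the half-open convention so that wrap_angle(-pi) == pi.
  w[w == -pi] <- pi
  w
}

# Signed circular difference a - b in (-pi, pi].
circ_diff <- function(a, b) wrap_angle(a - b)

# Zero-mean Gaussian noise smoothed with a moving-average window.  Circular
# convolution keeps the series length and the zero-mean property exactly.
# (cumsum-based running mean on the circularly padded series: identical to a
# centered circular moving average, but cheap enough for the session loop.)
smoothed_noise <- function(n, amplitude, window_frames) {
  if (amplitude <= 0) return(numeric(n))
  eps <- stats::rnorm(n, 0, amplitude)
  w <- max(1L, as.integer(window_frames))
  if (w > 1L) {
    lh <- w %/% 2L
    rh <- w - lh - 1L
    pad <- c(eps[(n - lh + 1L):n], eps, eps[1:max(1L, rh)][seq_len(rh)])
    cs <- c(0, cumsum(pad))
    eps <- (cs[(w + 1L):(w + n)] - cs[1:n]) / w
  }
  eps
}

# Position series container used across the simulation and behavior modules:
# a data.frame with columns t, x, y.
position_series <- function(t, x, y) {
  data.frame(t = t, x = x, y = y)
}
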