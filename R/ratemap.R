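# Occupancy-normalized place maps, response reliability and peri-movement
# sorting of ROI activity.

#' Occupancy-normalized place-field rate map
#'
#' Restricts to movement periods (speed >= `speed_min`), bins the arena into
#' `bin` x `bin` cm cells, masks bins visited fewer than `min_visits` times,
#' divides transient counts by occupancy seconds, smooths with a Gaussian
#' filter (`smooth_sigma` cm) and normalizes by the maximum.
#'
#' @param spike_frames frames at which the ROI emitted transients (event
#'   onsets).
#' @param trace data.frame `t`, `x`, `y` aligned to the imaging frames (one
#'   row per frame).
#' @param arena an [arena_spec()] (defines the binning extent).
#' @param bin bin side, cm.
#' @param speed_min movement threshold, cm/s.
#' @param min_visits minimum entries into a bin for it to count.
#' @param smooth_sigma Gaussian smoothing s.d., cm.
#' @return object of class `fl_rate_map`: `rate` (x-bin x y-bin matrix,
#'   max-normalized, NA where masked), `occupancy_s`, `event_count`,
#'   `visits`, `bin_centers_x/y`, `peak_xy`.
#' @export
compute_rate_map <- function(spike_frames, trace, arena = arena_spec(),
                             bin = 4, speed_min = 1, min_visits = 5,
                             smooth_sigma = 4) {
  n <- nrow(trace)
  dt <- stats::median(diff(trace$t))
  speed <- c(0, sqrt(diff(trace$x)^2 + diff(trace$y)^2) / diff(trace$t))
  moving <- speed >= speed_min
  if (!any(moving)) fl_stop("no movement periods", "invalid_input")
  xe <- seq(arena$port_xy[1] - arena$width / 2,
            arena$port_xy[1] + arena$width / 2 + bin, by = bin)
  ye <- seq(arena$port_xy[2], arena$port_xy[2] + arena$height + bin, by = bin)
  bx <- findInterval(trace$x, xe, rightmost.closed = TRUE)
  by <- findInterval(trace$y, ye, rightmost.closed = TRUE)
  bx <- pmin(pmax(bx, 1L), length(xe) - 1L)
  by <- pmin(pmax(by, 1L), length(ye) - 1L)
  nbx <- length(xe) - 1L; nby <- length(ye) - 1L
  cell <- (by - 1L) * nbx + bx
  occ <- ev <- vis <- matrix(0, nbx, nby)
  mcell <- cell[moving]
  occ_tab <- tabulate(mcell, nbins = nbx * nby) * dt
  occ[] <- occ_tab
  # visits: entries into a bin during movement (run-length starts)
  entry <- mcell[c(TRUE, diff(mcell) != 0)]
  vis[] <- tabulate(entry, nbins = nbx * nby)
  sf <- spike_frames[spike_frames >= 1 & spike_frames <= n]
  sf <- sf[moving[sf]]
  ev[] <- tabulate(cell[sf], nbins = nbx * nby)
  mask <- vis >= min_visits & occ > 0
  rate <- ev / occ
  rate[!mask] <- NA
  rate_s <- gauss_smooth_2d(rate, sigma_bins = smooth_sigma / bin)
  if (all(is.na(rate_s)) || max(rate_s, na.rm = TRUE) <= 0) {
    norm <- rate_s
  } else {
    norm <- rate_s / max(rate_s, na.rm = TRUE)
  }
  pk <- which(norm == suppressWarnings(max(norm, na.rm = TRUE)),
              arr.ind = TRUE)
  cx <- (xe[-length(xe)] + xe[-1]) / 2
  cy <- (ye[-length(ye)] + ye[-1]) / 2
  peak_xy <- if (nrow(pk)) c(cx[pk[1, 1]], cy[pk[1, 2]]) else c(NA, NA)
  structure(list(rate = norm, occupancy_s = occ, event_count = ev,
                 visits = vis, bin_centers_x = cx, bin_centers_y = cy,
                 peak_xy = peak_xy),
            class = "fl_rate_map")
}

# NA-aware 2-D Gaussian smoothing (normalized convolution: missing bins get
# zero weight, so masked regions neither leak nor shrink the field).
gauss_smooth_2d <- function(m, sigma_bins) {
  if (sigma_bins <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_bins))
  g <- stats::dnorm(-half:half, sd = sigma_bins)
  k <- outer(g, g)
  nx <- nrow(m); ny <- ncol(m)
  w <- !is.na(m)
  v <- m; v[!w] <- 0
  num <- matrix(0, nx, ny); den <- matrix(0, nx, ny)
  for (dx in -half:half) for (dy in -half:half) {
    kk <- k[dx + half + 1L, dy + half + 1L]
    sx <- max(1, 1 - dx):min(nx, nx - dx)
    sy <- max(1, 1 - dy):min(ny, ny - dy)
    num[sx, sy] <- num[sx, sy] + kk * v[sx + dx, sy + dy]
    den[sx, sy] <- den[sx, sy] + kk * w[sx + dx, sy + dy]
  }
  out <- num / den
  out[!w] <- NA
  out
}

#' Trial-to-trial response reliability
#'
#' Reliability at trial time tau is the mean pairwise Pearson correlation,
#' across trials, of the population activity vectors in a +/- `half_window`
#' second window centered at tau.  Bounded in [-1, 1]; windows where the
#' activity is constant in one of the trials yield NA with a warning.
#'
#' @param activity ROI x frame matrix.
#' @param trial_starts start frame of each trial (equal-length windows).
#' @param trial_len trial window length, frames.
#' @param frame_rate Hz.
#' @param half_window seconds.
#' @return numeric reliability series of length `trial_len`.
#' @export
response_reliability <- function(activity, trial_starts, trial_len,
                                 frame_rate, half_window = 0.25) {
  n_tr <- length(trial_starts)
  if (n_tr < 5L) fl_stop("need >= 5 trials", "invalid_input")
  hw <- max(1L, round(half_window * frame_rate))
  n_fr <- ncol(activity)
  out <- rep(NA_real_, trial_len)
  any_const <- FALSE
  for (tau in seq_len(trial_len)) {
    offs <- max(1L - 0L, tau - hw):min(trial_len, tau + hw)
    vecs <- vapply(trial_starts, function(s) {
      fr <- s + offs - 1L
      fr <- fr[fr >= 1 & fr <= n_fr]
      as.vector(activity[, fr, drop = FALSE])
    }, numeric(nrow(activity) * length(offs)))
    sds <- apply(vecs, 2, stats::sd)
    if (any(sds == 0)) { any_const <- TRUE; next }
    cc <- stats::cor(vecs)
    out[tau] <- mean(cc[lower.tri(cc)])
  }
  if (any_const) warning("constant activity in some windows; reliability NA there")
  out
}

#' Peri-movement sorting of ROIs
#'
#' `crossval`: ROIs are sorted by the time of their peak trial-averaged
#' response in a random half of trials; the returned order indexes the
#' held-out half (whose mean image is also returned).  `hierarchical`: ROIs
#' are split at the median of session-average activity and each group is
#' sorted by latency to peak from movement onset (ties, including the
#' all-equal case, fall back to a pure latency sort).
#'
#' @param activity ROI x frame matrix.
#' @param trial_starts start frame of each trial window.
#' @param trial_len window length, frames.
#' @param mode `"crossval"` or `"hierarchical"`.
#' @param seed integer seed for the random half split.
#' @return list with `order` (ROI indices), and for crossval mode
#'   `heldout_mean` (ROI x time, rows in returned order) and
#'   `heldout_peak_latency` (frames, in returned order).
#' @export
pmth_sort <- function(activity, trial_starts, trial_len,
                      mode = c("crossval", "hierarchical"), seed = 1L) {
  mode <- match.arg(mode)
  n_roi <- nrow(activity)
  if (n_roi == 1L) return(list(order = 1L))
  trial_mean <- function(starts) {
    acc <- matrix(0, n_roi, trial_len)
    for (s in starts) acc <- acc + activity[, s:(s + trial_len - 1L)]
    acc / length(starts)
  }
  if (mode == "crossval") {
    if (length(trial_starts) < 4L) fl_stop("need >= 4 trials", "invalid_input")
    set.seed(as.integer(seed))
    half <- sample(seq_along(trial_starts), floor(length(trial_starts) / 2))
    m_train <- trial_mean(trial_starts[half])
    m_test <- trial_mean(trial_starts[-half])
    ord <- order(apply(m_train, 1, which.max))
    list(order = ord,
         heldout_mean = m_test[ord, , drop = FALSE],
         heldout_peak_latency = apply(m_test[ord, , drop = FALSE], 1,
                                      which.max))
  } else {
    m <- trial_mean(trial_starts)
    avg <- rowMeans(m)
    med <- stats::median(avg)
    grp <- avg > med
    # tie rule: with (numerically) equal activity fall back to a pure
    # latency sort
    if (all(grp) || all(!grp) ||
        diff(range(avg)) < 1e-8 * max(1, abs(med))) {
      grp <- rep(FALSE, n_roi)
    }
    lat <- apply(m, 1, which.max)
    list(order = order(!grp, lat))
  }
}
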