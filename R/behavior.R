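# Behavioral analysis pipeline: trace preprocessing, attempt segmentation,
# performance, prior-trial-conditioned learning deltas and the bootstrap
# PETH comparison used for NTF inactivation catch trials.

#' Preprocess a position trace
#'
#' Single-sample tracking jumps larger than `jump_threshold` are replaced by
#' linear interpolation, then both coordinates are smoothed with a
#' Savitzky-Golay filter (3rd order, 11 points).  A 3rd-order filter
#' reproduces cubic trends exactly, so genuine kinematics pass through
#' unchanged away from the series edges.
#'
#' @param raw data.frame with columns `t`, `x`, `y`; >= 11 samples, uniform
#'   sampling.
#' @param jump_threshold displacement (same units as `x`/`y`) flagged as a
#'   tracking error.
#' @return the cleaned, smoothed trace (same shape as input).
#' @export
preprocess_trace <- function(raw, jump_threshold = 20) {
  if (nrow(raw) < 11L) fl_stop("need at least 11 samples", "invalid_input")
  check_number(jump_threshold, "jump_threshold", lower = 1e-9)
  x <- raw$x; y <- raw$y; n <- length(x)
  step <- sqrt(diff(x)^2 + diff(y)^2)
  # a tracking error jumps away and back within one sample
  bad <- which(step[-(n - 1L)] > jump_threshold & step[-1L] > jump_threshold) + 1L
  if (length(bad) > 0.2 * n) {
    fl_stop("more than 20% of samples flagged as tracking errors",
            "quality_error")
  }
  if (length(bad) > 0L) {
    ok <- setdiff(seq_len(n), bad)
    x[bad] <- stats::approx(raw$t[ok], x[ok], xout = raw$t[bad], rule = 2)$y
    y[bad] <- stats::approx(raw$t[ok], y[ok], xout = raw$t[bad], rule = 2)$y
  }
  out <- raw
  out$x <- signal::sgolayfilt(x, p = 3, n = 11)
  out$y <- signal::sgolayfilt(y, p = 3, n = 11)
  out
}

#' Extract foraging attempts from a position trace
#'
#' Attempts are maximal contiguous excursions from the port whose peak radial
#' distance reaches `amp_threshold` (10 cm in the arena task) and whose span
#' is at least `min_duration` (1 s).  Boundaries extend with hysteresis to
#' the first/last sample above 10% of the threshold around each
#' supra-threshold run.  `max_amplitude` is computed over the first ~500 ms
#' of the attempt, the initial ballistic phase; `initial_heading` is the
#' angle of the displacement vector at the 500-ms mark, measured clockwise
#' from the +y axis.
#'
#' @param trace preprocessed data.frame with `t`, `x`, `y` centered on the
#'   port/rest position; optional columns `reward_flag`, `laser_flag`.
#' @param amp_threshold radial detection threshold (cm or mm).
#' @param min_duration minimum attempt span, seconds.
#' @param amp_window window after attempt start over which the maximum
#'   amplitude is taken, seconds.
#' @return data.frame of attempts: `start_idx`, `stop_idx`, `t_start`,
#'   `t_stop`, `max_amplitude`, `initial_heading`, `path_length`,
#'   `rewarded`, `laser`.
#' @export
extract_attempts <- function(trace, amp_threshold = 10, min_duration = 1,
                             amp_window = 0.5) {
  check_number(amp_threshold, "amp_threshold", lower = 1e-9)
  check_number(min_duration, "min_duration", lower = 0)
  n <- nrow(trace)
  empty <- data.frame(start_idx = integer(0), stop_idx = integer(0),
                      t_start = numeric(0), t_stop = numeric(0),
                      max_amplitude = numeric(0), initial_heading = numeric(0),
                      path_length = numeric(0), rewarded = logical(0),
                      laser = logical(0))
  if (n < 2L) return(empty)
  r <- sqrt(trace$x^2 + trace$y^2)
  supra <- r >= amp_threshold
  if (!any(supra)) return(empty)
  lo <- r > 0.1 * amp_threshold
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- cbind(starts[runs$values], ends[runs$values])
  # hysteresis: grow each run while above 10% of threshold
  for (k in seq_len(nrow(seg))) {
    i <- seg[k, 1]
    while (i > 1L && lo[i - 1L]) i <- i - 1L
    j <- seg[k, 2]
    while (j < n && lo[j + 1L]) j <- j + 1L
    seg[k, ] <- c(i, j)
  }
  # merge overlapping extended segments
  keep <- list()
  cur <- seg[1, ]
  for (k in seq_len(nrow(seg))[-1]) {
    if (seg[k, 1] <= cur[2]) cur[2] <- max(cur[2], seg[k, 2])
    else { keep[[length(keep) + 1L]] <- cur; cur <- seg[k, ] }
  }
  keep[[length(keep) + 1L]] <- cur
  seg <- do.call(rbind, keep)

  dt <- trace$t[2] - trace$t[1]
  out <- lapply(seq_len(nrow(seg)), function(k) {
    i <- seg[k, 1]; j <- seg[k, 2]
    if (trace$t[j] - trace$t[i] < min_duration) return(NULL)
    wnd <- i:min(j, i + max(1L, round(amp_window / dt)))
    i500 <- min(j, i + max(1L, round(amp_window / dt)))
    data.frame(
      start_idx = i, stop_idx = j,
      t_start = trace$t[i], t_stop = trace$t[j],
      max_amplitude = max(r[wnd]),
      initial_heading = atan2(trace$x[i500] - trace$x[i],
                              trace$y[i500] - trace$y[i]),
      path_length = sum(sqrt(diff(trace$x[i:j])^2 + diff(trace$y[i:j])^2)),
      rewarded = if ("reward_flag" %in% names(trace))
        any(trace$reward_flag[i:j] > 0) else NA,
      laser = if ("laser_flag" %in% names(trace))
        any(trace$laser_flag[i:j] > 0) else NA
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Interception performance
#'
#' Probability of correctly intercepting the target given that a foraging
#' attempt was initiated.
#'
#' @param attempts data.frame with logical column `rewarded`.
#' @return scalar probability.
#' @export
performance <- function(attempts) {
  if (is.null(attempts) || nrow(attempts) == 0L) {
    fl_stop("performance is undefined with zero attempts", "invalid_input")
  }
  mean(attempts$rewarded)
}

#' Prior-trial-conditioned learning deltas
#'
#' For each attempt i the change in a per-attempt statistic relative to
#' attempt i-1 is conditioned on the type of attempt i-1: unrewarded,
#' rewarded, or rewarded + laser inactivation.  Session-wise means of the
#' signed and absolute deltas are computed per condition; the omnibus
#' Kruskal-Wallis test compares the three conditions across session means of
#' the absolute delta (the magnitude of the trial-to-trial policy change),
#' with Holm-corrected pairwise Wilcoxon rank-sum comparisons.
#'
#' @param sessions list of attempt data.frames (columns `max_amplitude`,
#'   `initial_heading`, `rewarded`, `laser`; simulated sessions additionally
#'   carry `scaling`, the policy speed-scaling parameter governing each
#'   trial).
#' @param statistic which per-attempt statistic to difference
#'   (`"max_amplitude"`, `"initial_heading"`, or `"scaling"` for simulated
#'   sessions).
#' @return object of class `fl_delta_table`: `session_means` (long
#'   data.frame), `condition_means`, `counts`, `kruskal` (statistic, df, p),
#'   `pairwise_p` (Holm-corrected matrix).
#' @export
conditional_deltas <- function(sessions, statistic = "max_amplitude") {
  if (!statistic %in% names(sessions[[1]])) {
    fl_stop(sprintf("statistic '%s' is not a column of the attempt tables",
                    statistic), "invalid_input")
  }
  conds <- c("unrewarded", "rewarded", "rewarded_laser")
  rows <- list()
  for (s in seq_along(sessions)) {
    at <- sessions[[s]]
    if (nrow(at) < 2L) next
    v <- at[[statistic]]
    d <- if (statistic == "initial_heading") {
      circ_diff(v[-1], v[-length(v)])
    } else {
      diff(v)
    }
    prior_rew <- at$rewarded[-nrow(at)]
    prior_las <- at$laser[-nrow(at)]
    cls <- ifelse(!prior_rew, "unrewarded",
                  ifelse(prior_las, "rewarded_laser", "rewarded"))
    for (cond in conds) {
      sel <- cls == cond
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, condition = cond, n = sum(sel),
        mean_delta = mean(d[sel]), mean_abs_delta = mean(abs(d[sel])))
    }
  }
  sm <- do.call(rbind, rows)
  if (is.null(sm) || !nrow(sm)) {
    fl_stop("no session has enough attempts for deltas", "invalid_input")
  }
  present <- conds[conds %in% unique(sm$condition)]
  if (length(present) < length(conds)) {
    warning(sprintf("condition(s) absent in all sessions: %s; test degrades to %d groups",
                    paste(setdiff(conds, present), collapse = ", "),
                    length(present)))
  }
  sm$condition <- factor(sm$condition, levels = present)
  if (stats::var(sm$mean_abs_delta) == 0) {
    # fully tied data: no evidence of any condition difference
    kw <- list(statistic = 0, parameter = length(present) - 1, p.value = 1)
  } else {
    kw <- stats::kruskal.test(mean_abs_delta ~ condition, data = sm)
  }
  pw <- NULL
  if (length(present) > 1L) {
    pwt <- stats::pairwise.wilcox.test(sm$mean_abs_delta, sm$condition,
                                       p.adjust.method = "holm",
                                       exact = FALSE)$p.value
    # expose as a full symmetric matrix over all present conditions
    pw <- matrix(NA_real_, length(present), length(present),
                 dimnames = list(present, present))
    for (a in rownames(pwt)) for (b in colnames(pwt)) {
      if (!is.na(pwt[a, b])) pw[a, b] <- pw[b, a] <- pwt[a, b]
    }
  }
  structure(list(
    statistic = statistic,
    session_means = sm,
    condition_means = tapply(sm$mean_abs_delta, sm$condition, mean),
    condition_means_signed = tapply(sm$mean_delta, sm$condition, mean),
    counts = tapply(sm$n, sm$condition, sum),
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p.value = kw$p.value),
    pairwise_p = pw
  ), class = "fl_delta_table")
}

#' Bootstrap PETH comparison of catch and control trials
#'
#' Movement events are aligned to a trigger (e.g. reward delivery) and binned
#' over the following `window` seconds.  `k` = the number of catch trials;
#' each bootstrap iteration resamples `k` catch and `k` control trials with
#' replacement and computes both PETHs; percentile confidence bands come from
#' `n_boot` iterations.  Significant spans are maximal runs of at least
#' `min_span` seconds in which the two 95% bands do not overlap.
#'
#' @param movement_times sorted vector of movement onset times, seconds.
#' @param align_events vector of alignment event times, seconds.
#' @param catch_mask logical per event: TRUE for inactivation catch trials.
#' @param window PETH window after each event, seconds.
#' @param n_boot bootstrap iterations (>= 100).
#' @param bin_width PETH bin width, seconds.
#' @param min_span minimum significant span, seconds.
#' @param ci confidence level of the percentile bands.
#' @return object of class `fl_peth_result`: bin centers, mean and CI curves
#'   for catch and control (rates, events/s), and `significant_spans`.
#' @export
peth_bootstrap <- function(movement_times, align_events, catch_mask,
                           window = 12, n_boot = 1000, bin_width = 0.1,
                           min_span = 0.2, ci = 0.95) {
  if (n_boot < 100) fl_stop("n_boot must be >= 100", "configuration_error")
  if (length(align_events) != length(catch_mask)) {
    fl_stop("`align_events` and `catch_mask` must have equal length",
            "invalid_input")
  }
  k <- sum(catch_mask)
  if (k < 5) fl_stop("need at least 5 catch trials", "invalid_input")
  edges <- seq(0, window, by = bin_width)
  nb <- length(edges) - 1L
  # per-trial binned movement counts
  counts <- t(vapply(align_events, function(ev) {
    rel <- movement_times - ev
    rel <- rel[rel > 0 & rel <= window]
    if (!length(rel)) return(numeric(nb))
    tabulate(pmin(nb, ceiling(rel / bin_width)), nbins = nb)
  }, numeric(nb)))
  catch_rows <- which(catch_mask)
  ctrl_rows <- which(!catch_mask)
  boot_catch <- matrix(NA_real_, n_boot, nb)
  boot_ctrl <- matrix(NA_real_, n_boot, nb)
  for (b in seq_len(n_boot)) {
    boot_catch[b, ] <- colMeans(counts[sample(catch_rows, k, replace = TRUE), ,
                                       drop = FALSE])
    boot_ctrl[b, ] <- colMeans(counts[sample(ctrl_rows, k, replace = TRUE), ,
                                      drop = FALSE])
  }
  qs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  ci_catch <- apply(boot_catch, 2, stats::quantile, probs = qs) / bin_width
  ci_ctrl <- apply(boot_ctrl, 2, stats::quantile, probs = qs) / bin_width
  disjoint <- ci_catch[2, ] < ci_ctrl[1, ] | ci_ctrl[2, ] < ci_catch[1, ]
  need <- ceiling(min_span / bin_width)
  runs <- rle(disjoint)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= need)
  spans <- if (length(ok)) {
    cbind(t_on = edges[starts[ok]], t_off = edges[ends[ok] + 1L])
  } else {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("t_on", "t_off")))
  }
  structure(list(
    bin_centers = edges[-1] - bin_width / 2,
    mean_catch = colMeans(boot_catch) / bin_width,
    mean_ctrl = colMeans(boot_ctrl) / bin_width,
    ci_catch = ci_catch, ci_ctrl = ci_ctrl,
    significant_spans = spans,
    k = k, n_boot = n_boot
  ), class = "fl_peth_result")
}
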