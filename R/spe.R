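# Synchronous population events (SPEs): near-simultaneous activation of a
# large fraction of the imaged population (~15% of ROIs within ~200 ms), the
# imaging proxy for ripple-associated reactivation.  Detection slides a
# window over the deconvolved raster, counts distinct active ROIs and keeps
# local maxima of the active fraction.

#' Detect synchronous population events in a spike raster
#'
#' @param spikes ROI x frame matrix of inferred event counts.
#' @param frame_rate Hz.
#' @param window sliding-window length, seconds (~200 ms).
#' @param fraction minimum fraction of all imaged ROIs active in a window.
#' @param immobility_mask optional logical per frame; windows are only
#'   evaluated where TRUE.
#' @return data.frame of events: `onset_frame` (window start), `peak_frame`,
#'   `fraction_active`, plus the binary participation matrix as attribute
#'   `"participation"` (event x ROI).
#' @export
detect_spes <- function(spikes, frame_rate, window = 0.2, fraction = 0.15,
                        immobility_mask = NULL) {
  if (!is.matrix(spikes)) fl_stop("`spikes` must be a matrix", "invalid_input")
  n_roi <- nrow(spikes); n_fr <- ncol(spikes)
  if (n_roi < 20L) fl_stop("need at least 20 ROIs", "invalid_input")
  w <- floor(window * frame_rate)
  if (w < 1L) {
    fl_stop("window is shorter than one frame", "configuration_error")
  }
  active <- spikes > 0
  # distinct active ROIs per window via running any() over w frames
  cs <- cbind(0, t(apply(active, 1, cumsum)))
  n_win <- n_fr - w + 1L
  idx <- seq_len(n_win)
  in_win <- (cs[, idx + w] - cs[, idx]) > 0      # ROI x window
  frac <- colSums(in_win) / n_roi
  if (!is.null(immobility_mask)) {
    wm <- vapply(idx, function(i) all(immobility_mask[i:(i + w - 1L)]),
                 logical(1))
    frac[!wm] <- 0
  }
  cand <- which(frac >= fraction)
  events <- list()
  # non-maximum suppression: keep local maxima separated by >= one window
  remaining <- cand
  while (length(remaining)) {
    best <- remaining[which.max(frac[remaining])]
    events[[length(events) + 1L]] <- best
    remaining <- remaining[abs(remaining - best) >= w]
  }
  if (!length(events)) {
    out <- data.frame(onset_frame = integer(0), peak_frame = integer(0),
                      fraction_active = numeric(0))
    attr(out, "participation") <- matrix(FALSE, 0, n_roi)
    return(out)
  }
  onsets <- sort(unlist(events))
  part <- t(vapply(onsets, function(i) in_win[, i], logical(n_roi)))
  # peak frame: frame with the most active ROIs inside the window
  peaks <- vapply(onsets, function(i) {
    i - 1L + which.max(colSums(active[, i:(i + w - 1L), drop = FALSE]))
  }, integer(1))
  out <- data.frame(onset_frame = onsets, peak_frame = peaks,
                    fraction_active = frac[onsets])
  attr(out, "participation") <- part
  out
}

#' Cluster SPEs by their participating-ROI vectors
#'
#' k-means (20 restarts) on the binary participation vectors for each k in
#' `k_range`; the returned `k_star` maximizes the mean silhouette width on
#' Euclidean distance.
#'
#' @param participation event x ROI binary (or numeric) matrix.
#' @param k_range candidate cluster counts.
#' @param seed integer seed (k-means restarts are stochastic).
#' @return list with `labels` (at `k_star`), `k_star`, `silhouette`
#'   (mean width per k) and `all_labels`.
#' @export
cluster_spes <- function(participation, k_range = 2:8, seed = 1L) {
  X <- as.matrix(participation) * 1
  k_max <- max(k_range)
  if (nrow(X) < k_max + 1L) {
    fl_stop("too few events to cluster", "invalid_input")
  }
  if (all(stats::dist(X[!duplicated(X), , drop = FALSE]) == 0) ||
      nrow(unique(X)) < 2L) {
    fl_stop("degenerate input: all participation vectors identical",
            "invalid_input")
  }
  set.seed(as.integer(seed))
  sil <- numeric(length(k_range))
  labs <- vector("list", length(k_range))
  d <- stats::dist(X)
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    km <- stats::kmeans(X, centers = k, nstart = 20, iter.max = 50)
    labs[[j]] <- km$cluster
    sw <- cluster::silhouette(km$cluster, d)
    sil[j] <- mean(sw[, "sil_width"])
  }
  j_star <- which.max(sil)
  list(labels = labs[[j_star]], k_star = k_range[j_star],
       silhouette = stats::setNames(sil, k_range), all_labels = labs)
}

#' Loadings of SPEs on the leading event-triggered principal component
#'
#' Takes +/- `half_window` seconds of dF/F around each event, concatenates
#' all event windows into one frames x ROI matrix, computes principal
#' components, and projects each event's mean population vector onto the
#' leading component ("the SPE component").  Sign convention: the ROI with
#' the largest-magnitude weight has a positive weight, making loadings
#' reproducible across runs.
#'
#' @param dff ROI x frame matrix of dF/F.
#' @param event_frames vector of event frames (e.g. `peak_frame`).
#' @param frame_rate Hz.
#' @param half_window seconds on each side of the event.
#' @return list with `loadings` (per event), `weights` (per ROI) and the
#'   fraction of variance explained by the leading component.
#' @export
spe_pc_loadings <- function(dff, event_frames, frame_rate,
                            half_window = 0.25) {
  if (length(event_frames) < 3L) fl_stop("need >= 3 events", "invalid_input")
  hw <- max(1L, round(half_window * frame_rate))
  n_fr <- ncol(dff)
  if (2L * hw + 1L > n_fr) {
    warning("window longer than recording; truncating")
  }
  wins <- lapply(event_frames, function(f) {
    i0 <- max(1L, f - hw); i1 <- min(n_fr, f + hw)
    t(dff[, i0:i1, drop = FALSE])                # frames x ROI
  })
  X <- do.call(rbind, wins)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  wvec <- pc$rotation[, 1]
  if (wvec[which.max(abs(wvec))] < 0) wvec <- -wvec
  mu <- colMeans(X)
  loadings <- vapply(wins, function(wmat) {
    mean((wmat - rep(mu, each = nrow(wmat))) %*% wvec)
  }, numeric(1))
  var_frac <- pc$sdev[1]^2 / sum(pc$sdev^2)
  list(loadings = loadings, weights = wvec, var_explained = var_frac)
}

#' Correlate SPE loadings with a per-event behavioral covariate
#'
#' @param loadings per-event loadings on the SPE component.
#' @param covariate per-event behavioral value (return angle, block id,
#'   speed gain, ...).
#' @return list with Pearson `r` and two-sided `p`.
#' @export
correlate_loading_with_covariate <- function(loadings, covariate) {
  if (length(loadings) != length(covariate) || length(loadings) < 5L) {
    fl_stop("inputs must be equal length >= 5", "invalid_input")
  }
  if (stats::sd(loadings) == 0 || stats::sd(covariate) == 0) {
    fl_stop("zero variance input; correlation undefined", "invalid_input")
  }
  ct <- stats::cor.test(loadings, covariate, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
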