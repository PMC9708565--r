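# Readers and writers for the documented on-disk schemas.
#
# Session CSV: one row per sample with columns t, x, y, reward_flag,
# laser_flag, block_id.
#
# ROI matrix: a directory holding dff.csv and spikes.csv (ROI x frame,
# no headers), frame_times.csv (one column t, optional x, y) and meta.yaml
# (frame_rate and provenance).  Plain-text by design so sessions diff and
# version cleanly.

SESSION_COLUMNS <- c("t", "x", "y", "reward_flag", "laser_flag", "block_id")

#' Write / read a behavioral session CSV
#'
#' @param trace data.frame with the session columns (`t`, `x`, `y`,
#'   `reward_flag`, `laser_flag`, `block_id`).
#' @param path file path.
#' @return `load_session` returns the validated data.frame.
#' @export
write_session <- function(trace, path) {
  missing <- setdiff(SESSION_COLUMNS, names(trace))
  if (length(missing)) {
    fl_stop(paste("missing required column(s):",
                  paste(missing, collapse = ", ")), "schema_error")
  }
  utils::write.csv(trace[SESSION_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
load_session <- function(path) {
  if (!file.exists(path)) fl_stop(paste("no such file:", path), "io_error")
  df <- utils::read.csv(path)
  missing <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing)) {
    fl_stop(paste("missing required column(s):",
                  paste(missing, collapse = ", ")), "schema_error")
  }
  if (any(!is.finite(df$t)) || any(diff(df$t) <= 0)) {
    fl_stop("column t must be finite and strictly increasing", "data_error")
  }
  df
}

#' Write / read a ROI matrix directory
#'
#' @param roi list with `dff`, `spikes` (ROI x frame matrices),
#'   `frame_times`, `frame_rate`, optional `frame_xy`.
#' @param dir directory path (created if needed).
#' @return `load_roi_matrix` returns the validated list.
#' @export
write_roi_matrix <- function(roi, dir) {
  if (!all(dim(roi$dff) == dim(roi$spikes))) {
    fl_stop("dff and spikes must have congruent shapes", "data_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(roi$dff, file.path(dir, "dff.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(roi$spikes, file.path(dir, "spikes.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  ftab <- data.frame(t = roi$frame_times)
  if (!is.null(roi$frame_xy)) {
    ftab$x <- roi$frame_xy[, 1]; ftab$y <- roi$frame_xy[, 2]
  }
  utils::write.csv(ftab, file.path(dir, "frame_times.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(frame_rate = roi$frame_rate,
                        n_rois = nrow(roi$dff),
                        n_frames = ncol(roi$dff)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_roi_matrix
#' @export
load_roi_matrix <- function(dir) {
  need <- c("dff.csv", "spikes.csv", "frame_times.csv", "meta.yaml")
  have <- file.exists(file.path(dir, need))
  if (!all(have)) {
    fl_stop(paste("missing file(s):", paste(need[!have], collapse = ", ")),
            "schema_error")
  }
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  dff <- as.matrix(utils::read.csv(file.path(dir, "dff.csv"),
                                   header = FALSE))
  spikes <- as.matrix(utils::read.csv(file.path(dir, "spikes.csv"),
                                      header = FALSE))
  dimnames(dff) <- dimnames(spikes) <- NULL
  if (!all(dim(dff) == dim(spikes))) {
    fl_stop("dff and spikes shapes mismatch", "data_error")
  }
  ftab <- utils::read.csv(file.path(dir, "frame_times.csv"))
  if (nrow(ftab) != ncol(dff)) {
    fl_stop("frame_times length does not match frame count", "data_error")
  }
  if (any(diff(ftab$t) <= 0)) {
    fl_stop("frame times must be strictly increasing", "data_error")
  }
  out <- list(dff = dff, spikes = spikes, frame_times = ftab$t,
              frame_rate = meta$frame_rate)
  if (all(c("x", "y") %in% names(ftab))) {
    out$frame_xy <- cbind(x = ftab$x, y = ftab$y)
  }
  out
}

#' Read / write a run configuration as YAML
#'
#' A run configuration is a named list of per-stage parameter blocks plus a
#' `seed`; every analysis driver records it alongside its outputs.
#'
#' @param config named list.
#' @param path YAML file path.
#' @return `load_run_config` returns the list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) fl_stop(paste("no such file:", path), "io_error")
  yaml::read_yaml(path)
}

#' Write a JSON run manifest next to an artifact
#'
#' Records inputs, parameters, seed and a digest of the configuration so a
#' run can be reproduced from the manifest alone.
#'
#' @param path manifest path (`.json`).
#' @param inputs character vector of input paths/identifiers.
#' @param params named list of parameters.
#' @param seed integer seed used.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, inputs = character(0), params = list(),
                           seed = NA_integer_) {
  manifest <- list(
    inputs = inputs, params = params, seed = seed,
    config_hash = config_hash(params),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# Order-independent digest of a parameter list (no external digest
# dependency: serialize deterministically and hash with a small FNV-1a).
config_hash <- function(params) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      paste0("{", paste(names(x), vapply(x, canon, ""), sep = ":",
                        collapse = ","), "}")
    } else {
      paste(format(x, digits = 15), collapse = ",")
    }
  }
  s <- utf8ToInt(canon(params))
  h <- 5381
  for (b in s) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
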