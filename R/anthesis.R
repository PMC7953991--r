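## Anthesis quantification: per-frame width profiles are assembled into a
## time x spike-position surface anchored at the tip (position 0), outlier
## cells are removed, and flowering onset position, spread directions and
## duration are extracted from the swelling of the surface above its
## pre-flowering baseline.

#' Assemble per-frame width profiles into an anthesis surface
#'
#' Profiles are tip-anchored (position 0 = tip) because the profiled length
#' varies frame to frame (the detected topmost branch point moves with
#' occlusion); rows are padded with invalid cells beyond each frame's
#' profiled length, and the surface width is the maximum profile length.
#'
#' @param profiles list of `width_profile` objects (empty/`NULL` entries are
#'   allowed and yield all-invalid rows).
#' @param frames 0-based frame indices parallel to `profiles`.
#' @param timestamps optional POSIXct/character timestamps parallel to
#'   `profiles`.
#' @param frames_per_day frames per capture day, used to express durations
#'   in days (default 72, the 10-minute cadence over a 12 h window).
#' @return object of class `anthesis_surface`: `widths` (T x P matrix),
#'   `valid` (logical T x P), `frames`, `timestamps`, `frames_per_day`.
#'   Rows are ordered by frame.
#' @export
align_profiles <- function(profiles, frames = seq_along(profiles) - 1L,
                           timestamps = NULL, frames_per_day = 72L) {
  if (length(profiles) < 2L) stopf("need profiles from at least 2 frames")
  sizes <- vapply(profiles, function(p) if (is.null(p) || nrow(p) == 0L) 0L
                  else as.integer(floor(max(p$position))) + 1L, 0L)
  if (all(sizes == 0L)) stopf("all profiles are empty")
  ord <- order(frames)
  profiles <- profiles[ord]; frames <- frames[ord]; sizes <- sizes[ord]
  if (!is.null(timestamps)) timestamps <- timestamps[ord]
  P <- max(sizes)
  T_ <- length(profiles)
  widths <- matrix(NA_real_, T_, P)
  valid <- matrix(FALSE, T_, P)
  for (i in seq_len(T_)) {
    p <- profiles[[i]]
    if (is.null(p) || nrow(p) == 0L) next
    len <- sizes[i]
    xout <- 0:(len - 1L)
    w <- if (nrow(p) == 1L) rep(p$width, length(xout))
         else stats::approx(p$position, p$width, xout = xout, rule = 2)$y
    widths[i, seq_len(len)] <- w
    valid[i, seq_len(len)] <- TRUE
  }
  structure(list(widths = widths, valid = valid, frames = frames,
                 timestamps = timestamps,
                 frames_per_day = as.integer(frames_per_day)),
            class = "anthesis_surface")
}

#' Remove outlier cells from an anthesis surface
#'
#' Cells whose width deviates from the column's running median by more than
#' `z_cutoff` robust deviations (MAD, floored at half a pixel for lattice
#' noise) are marked invalid. Only temporally isolated excursions are
#' removed: a cell that agrees with one of its temporal neighbours (the edge
#' of a genuine flowering step) is retained. The valid-cell count never
#' increases; the operation is idempotent.
#'
#' @param surface an `anthesis_surface`.
#' @param window running-median window in frames (odd; default 9).
#' @param z_cutoff robust-deviation cutoff (default 3.5).
#' @return the cleaned surface.
#' @export
remove_outliers <- function(surface, window = 9L, z_cutoff = 3.5) {
  stopifnot(inherits(surface, "anthesis_surface"))
  if (window %% 2L == 0L) window <- window + 1L
  for (j in seq_len(ncol(surface$widths))) {
    vi <- which(surface$valid[, j])
    if (length(vi) < 5L) next
    v <- surface$widths[vi, j]
    k <- min(window, length(v) - (1 - length(v) %% 2L))
    rm_ <- stats::runmed(v, k)
    resid <- v - rm_
    s <- max(stats::mad(resid), 0.5)
    n <- length(v)
    dprev <- c(Inf, abs(diff(v)))
    dnext <- c(abs(diff(v)), Inf)
    out <- abs(resid) > z_cutoff * s & dprev > z_cutoff * s & dnext > z_cutoff * s
    if (any(out)) surface$valid[vi[out], j] <- FALSE
  }
  surface
}

#' Quantify flowering onset, spread and duration from a surface
#'
#' The pre-flowering baseline width of each spike position is the median
#' over the first `baseline_frames` frames. A cell is flowering when its
#' width exceeds baseline + `swell_threshold` times the estimated swelling
#' amplitude (the 95th-percentile excess over baseline across the surface).
#' Onset is the first flowering frame and the median flowering position in
#' it; duration is the time between the first and last frames with any
#' flowering column, in capture days; spread directions report whether the
#' flowering column set expands toward the tip (upward) and/or the base
#' (downward) after onset.
#'
#' @param surface an `anthesis_surface` (outliers ideally removed first).
#' @param baseline_frames number of leading frames taken as pre-flowering
#'   baseline (must precede any swelling).
#' @param swell_threshold fraction of the estimated amplitude a width must
#'   exceed baseline by (default 0.5).
#' @param min_amplitude smallest credible swelling amplitude in pixels; if
#'   the estimate falls below it, no flowering is reported (default 2).
#' @param direction_margin pixels of extent beyond the onset position needed
#'   to call a spread direction (default 8).
#' @return object of class `flowering_summary`.
#' @export
summarize_flowering <- function(surface, baseline_frames = 36L,
                                swell_threshold = 0.5, min_amplitude = 2,
                                direction_margin = 8) {
  stopifnot(inherits(surface, "anthesis_surface"))
  W <- surface$widths; V <- surface$valid
  T_ <- nrow(W); P <- ncol(W)
  if (baseline_frames >= T_) stopf("baseline_frames must leave frames to analyze")
  base_rows <- seq_len(baseline_frames)
  baseline <- vapply(seq_len(P), function(j) {
    v <- W[base_rows, j][V[base_rows, j]]
    if (length(v)) stats::median(v) else NA_real_
  }, 0)
  excess <- sweep(W, 2L, baseline, "-")
  excess[!V] <- NA
  excess[, is.na(baseline)] <- NA
  amp <- stats::quantile(excess, 0.95, na.rm = TRUE, names = FALSE)
  no_flower <- structure(list(detected = FALSE, onset_frame = NA_integer_,
                              onset_time = NULL, onset_position_px = NA_real_,
                              onset_fraction = NA_real_, end_frame = NA_integer_,
                              end_time = NULL, duration_days = 0,
                              directions = character(0),
                              amplitude_est = amp, threshold = NA_real_,
                              baseline_frames = baseline_frames),
                         class = "flowering_summary")
  if (!is.finite(amp) || amp < min_amplitude) return(no_flower)
  thr <- swell_threshold * amp
  flowering <- !is.na(excess) & excess > thr
  rows <- which(rowSums(flowering) > 0L)
  if (!length(rows)) return(no_flower)
  t0 <- rows[1L]; t1 <- rows[length(rows)]
  cols0 <- which(flowering[t0, ])
  onset_px <- stats::median(cols0) - 1
  cols_all <- which(colSums(flowering[rows, , drop = FALSE]) > 0L)
  dirs <- character(0)
  if (onset_px - (min(cols_all) - 1) >= direction_margin) dirs <- c(dirs, "upward")
  if ((max(cols_all) - 1) - onset_px >= direction_margin) dirs <- c(dirs, "downward")
  duration_days <- (surface$frames[t1] - surface$frames[t0]) / surface$frames_per_day
  structure(list(detected = TRUE,
                 onset_frame = surface$frames[t0],
                 onset_time = if (!is.null(surface$timestamps)) surface$timestamps[t0] else NULL,
                 onset_position_px = onset_px,
                 onset_fraction = onset_px / (P - 1),
                 end_frame = surface$frames[t1],
                 end_time = if (!is.null(surface$timestamps)) surface$timestamps[t1] else NULL,
                 duration_days = duration_days,
                 directions = dirs,
                 amplitude_est = amp, threshold = thr,
                 baseline_frames = baseline_frames),
            class = "flowering_summary")
}

#' @export
print.flowering_summary <- function(x, ...) {
  if (!x$detected) {
    cat("No flowering detected.\n")
  } else {
    cat(sprintf("Flowering onset at %.0f px from the tip (fraction %.2f of the profiled spike)\n",
                x$onset_position_px, x$onset_fraction))
    cat(sprintf("  frames %d..%d, duration %.2f capture days; spread: %s\n",
                x$onset_frame, x$end_frame, x$duration_days,
                if (length(x$directions)) paste(x$directions, collapse = " + ") else "none"))
    cat(sprintf("  estimated amplitude %.1f px (threshold %.1f px over baseline)\n",
                x$amplitude_est, x$threshold))
  }
  invisible(x)
}

#' Write an anthesis surface to CSV
#'
#' Rows are frames (with `frame_index` and optional `timestamp` columns),
#' columns the positions from the tip; invalid cells are empty.
#'
#' @param surface an `anthesis_surface`.
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  W <- surface$widths
  W[!surface$valid] <- NA
  df <- data.frame(frame_index = surface$frames)
  if (!is.null(surface$timestamps)) df$timestamp <- as.character(surface$timestamps)
  colnames(W) <- sprintf("pos%04d", seq_len(ncol(W)) - 1L)
  utils::write.csv(cbind(df, W), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a flowering summary as JSON
#' @param summary a `flowering_summary`.
#' @param path output JSON path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       null = "null", POSIXt = "ISO8601")
  invisible(path)
}
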