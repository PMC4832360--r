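#' Region of interest for tracking
#'
#' A square window around one object (bacterial chain or pillar tip).
#'
#' @param center_px numeric 2-vector `(row, col)`, possibly fractional.
#' @param half_size_px window half-width in px (>= 4); the template is
#'   `(2 * half_size_px + 1)` px square.
#' @param object_id label carried into the trajectory.
#' @return an object of class `roi`.
#' @export
roi <- function(center_px, half_size_px = 16L, object_id = "obj1") {
  if (length(center_px) != 2L || !all(is.finite(center_px)))
    stop("center_px: must be finite (row, col)")
  if (half_size_px < 4L) stop("half_size_px: must be >= 4")
  structure(list(center_px = as.numeric(center_px),
                 half_size_px = as.integer(half_size_px),
                 object_id = as.character(object_id)),
            class = "roi")
}

#' Tracking options
#'
#' @param search_radius_px maximum displacement searched per frame, px.
#'   The default 10 px covers ~700 nm/s motion at 10 Hz and 100 nm/px
#'   with ample margin.
#' @param template `"fixed"` keeps the frame-0 window as template;
#'   `"running"` blends each newly tracked window in with weight `alpha`,
#'   tolerating slow appearance change (e.g. chain rotation at kinks).
#' @param alpha running-average weight in (0, 1].
#' @param min_quality minimum acceptable peak correlation; below it a
#'   frame counts as "lost".
#' @param max_lost number of consecutive lost frames tolerated before the
#'   trajectory is truncated (with a warning).
#' @param refresh_quality when the peak correlation falls below this, the
#'   object's appearance has changed abruptly (e.g. a chain rotated at a
#'   kink) and the template no longer matches: the tracker re-localizes
#'   the object by the rotation-invariant thresholded intensity centroid
#'   of the search window and re-acquires the template there. Set to 0 to
#'   disable re-acquisition.
#' @return an object of class `track_options`.
#' @export
track_options <- function(search_radius_px = 10L,
                          template = c("fixed", "running"), alpha = 0.1,
                          min_quality = 0.2, max_lost = 5L,
                          refresh_quality = 0.5) {
  template <- match.arg(template)
  if (search_radius_px < 1L) stop("search_radius_px: must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha: must be in (0, 1]")
  if (min_quality < -1 || min_quality > 1) stop("min_quality: must be in [-1, 1]")
  if (refresh_quality < 0 || refresh_quality > 1)
    stop("refresh_quality: must be in [0, 1]")
  structure(list(search_radius_px = as.integer(search_radius_px),
                 template = template, alpha = alpha,
                 min_quality = min_quality, max_lost = as.integer(max_lost),
                 refresh_quality = refresh_quality),
            class = "track_options")
}

#' Construct a trajectory
#'
#' Time-ordered sub-pixel positions of one tracked object in physical
#' units. Normally produced by [track_roi()]; the constructor is exported
#' so externally measured positions can enter the motility and force
#' statistics.
#'
#' @param frame integer frame indices (1-based, consecutive).
#' @param x_nm,y_nm positions in nm.
#' @param frame_rate_hz acquisition rate, Hz.
#' @param pixel_size_nm spatial calibration, nm/px.
#' @param object_id label.
#' @param quality per-sample peak-correlation score in `[-1, 1]`.
#' @return an object of class `trajectory` (a data frame with columns
#'   frame, t_s, x_nm, y_nm, quality).
#' @export
trajectory <- function(frame, x_nm, y_nm, frame_rate_hz, pixel_size_nm = NA,
                       object_id = "obj1", quality = rep(1, length(frame))) {
  n <- length(frame)
  if (length(x_nm) != n || length(y_nm) != n || length(quality) != n)
    stop("frame, x_nm, y_nm, quality must have equal length")
  if (!all(is.finite(x_nm)) || !all(is.finite(y_nm)))
    stop("positions must be finite")
  t_s <- (frame - 1) / frame_rate_hz
  if (n > 1L && any(diff(t_s) <= 0)) stop("times must be strictly increasing")
  out <- data.frame(frame = as.integer(frame), t_s = t_s,
                    x_nm = x_nm, y_nm = y_nm, quality = quality)
  attr(out, "object_id") <- object_id
  attr(out, "frame_rate_hz") <- frame_rate_hz
  attr(out, "pixel_size_nm") <- pixel_size_nm
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': %d samples @ %.3g Hz, mean quality %.3f\n",
              attr(x, "object_id"), nrow(x), attr(x, "frame_rate_hz"),
              mean(x$quality)))
  cat(sprintf("  net displacement %.0f nm, path length %.0f nm\n",
              sqrt(diff(range(x$x_nm))^2 + diff(range(x$y_nm))^2),
              sum(sqrt(diff(x$x_nm)^2 + diff(x$y_nm)^2))))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  graphics::plot(x$x_nm / 1000, x$y_nm / 1000, type = "l", asp = 1,
                 xlab = expression(x ~ (mu * m)), ylab = expression(y ~ (mu * m)),
                 main = attr(x, "object_id"), ...)
  graphics::points(x$x_nm[1] / 1000, x$y_nm[1] / 1000, pch = 16)
  invisible(x)
}

#' Track one region of interest through a movie
#'
#' Sub-pixel cross-correlation tracking. The template is the ROI window
#' from frame 1 (optionally running-average updated); for each later
#' frame the normalized cross-correlation against a search window centred
#' on the previous position is computed, the integer argmax is refined to
#' sub-pixel precision by separable quadratic fits through the 3x3
#' correlation neighbourhood of the peak, and the position is reported in
#' nm. Registering every frame against the template (rather than the
#' previous frame) keeps localization errors from accumulating as a
#' random walk; per-step displacements are differences of successive
#' positions.
#'
#' The trajectory is truncated, with a warning, when the correlation peak
#' stays below `min_quality` for more than `max_lost` consecutive frames
#' or when the search window can no longer fit inside the frame.
#'
#' @param movie a [movie_stack()].
#' @param roi an [roi()], valid in frame 1.
#' @param options a [track_options()].
#' @return a [trajectory()] with per-sample quality scores.
#' @export
track_roi <- function(movie, roi, options = track_options()) {
  stopifnot(inherits(movie, "movie_stack"), inherits(roi, "roi"),
            inherits(options, "track_options"))
  d <- dim(movie$frames)
  nt <- d[3]
  h <- roi$half_size_px
  R <- options$search_radius_px
  c0 <- round(roi$center_px)
  if (c0[1] - h < 1 || c0[1] + h > d[1] || c0[2] - h < 1 || c0[2] + h > d[2])
    stop("roi: window not fully inside frame 1")
  template <- matrix(as.double(movie$frames[(c0[1] - h):(c0[1] + h),
                                            (c0[2] - h):(c0[2] + h), 1]),
                     2 * h + 1, 2 * h + 1)
  offset0 <- roi$center_px - c0

  pos <- matrix(NA_real_, nt, 2)
  qual <- numeric(nt)
  pos[1, ] <- roi$center_px
  qual[1] <- 1
  lost <- 0L
  kept <- nt
  for (t in 2:nt) {
    ci <- round(pos[t - 1L, ] - offset0)
    lo <- c(1L + h + R, 1L + h + R)
    hi <- c(d[1] - h - R, d[2] - h - R)
    if (any(hi < lo)) stop("frame too small for this window + search radius")
    ci_cl <- pmin(pmax(ci, lo), hi)
    if (any(abs(ci_cl - ci) > R)) {
      warning(sprintf("roi '%s' drifted out of frame; trajectory truncated at frame %d",
                      roi$object_id, t - 1L))
      kept <- t - 1L
      break
    }
    S <- matrix(as.double(movie$frames[(ci_cl[1] - h - R):(ci_cl[1] + h + R),
                                       (ci_cl[2] - h - R):(ci_cl[2] + h + R), t]),
                2 * (h + R) + 1, 2 * (h + R) + 1)
    cc <- ncc_map(template, S)
    pk <- ncc_peak(cc)
    sub <- ncc_subpixel(cc, pk[1], pk[2])
    disp <- c(pk[1], pk[2]) - (R + 1L)            # integer shift from window centre
    pos[t, ] <- ci_cl + disp + sub + offset0
    qual[t] <- pk[3]
    refreshed <- FALSE
    if (pk[3] < options$refresh_quality) {
      # appearance changed abruptly (e.g. chain rotated at a kink): the
      # template no longer matches, so re-localize by the rotation-
      # invariant intensity centroid of the search window and re-acquire
      # the template there
      thr <- stats::median(S) + 3 * stats::mad(S)
      w <- pmax(S - thr, 0)
      tot <- sum(w)
      if (tot > 0) {
        rr <- (ci_cl[1] - h - R):(ci_cl[1] + h + R)
        cs <- (ci_cl[2] - h - R):(ci_cl[2] + h + R)
        pos[t, ] <- c(sum(rr * rowSums(w)), sum(cs * colSums(w))) / tot
        cn <- round(pos[t, ])
        cn <- pmin(pmax(cn, c(1L + h, 1L + h)), c(d[1] - h, d[2] - h))
        template <- matrix(as.double(movie$frames[(cn[1] - h):(cn[1] + h),
                                                  (cn[2] - h):(cn[2] + h), t]),
                           2 * h + 1, 2 * h + 1)
        offset0 <- c(0, 0)   # anchor is now the centroid itself
        refreshed <- TRUE
      }
    }
    if (pk[3] < options$min_quality) {
      lost <- lost + 1L
      if (lost > options$max_lost) {
        warning(sprintf(
          "roi '%s': correlation below %.2f for %d consecutive frames; truncated at frame %d",
          roi$object_id, options$min_quality, lost, t))
        kept <- t
        break
      }
    } else {
      lost <- 0L
    }
    if (options$template == "running" && !refreshed) {
      cn <- round(pos[t, ] - offset0)
      cn <- pmin(pmax(cn, c(1L + h, 1L + h)), c(d[1] - h, d[2] - h))
      win <- matrix(as.double(movie$frames[(cn[1] - h):(cn[1] + h),
                                           (cn[2] - h):(cn[2] + h), t]),
                    2 * h + 1, 2 * h + 1)
      template <- (1 - options$alpha) * template + options$alpha * win
    }
  }
  keep <- seq_len(kept)
  xy <- px_to_nm(pos[keep, , drop = FALSE], movie$pixel_size_nm)
  trajectory(frame = keep, x_nm = xy[, 1], y_nm = xy[, 2],
             frame_rate_hz = movie$frame_rate_hz,
             pixel_size_nm = movie$pixel_size_nm,
             object_id = roi$object_id, quality = qual[keep])
}

#' Track many regions of interest
#'
#' Applies [track_roi()] independently to each ROI, preserving order.
#' Per-ROI truncation warnings propagate without aborting the others.
#'
#' @param movie a [movie_stack()].
#' @param rois list of [roi()] objects.
#' @param options a [track_options()].
#' @return list of trajectories, named by object id.
#' @export
track_many <- function(movie, rois, options = track_options()) {
  out <- lapply(rois, function(r) track_roi(movie, r, options))
  names(out) <- vapply(rois, function(r) r$object_id, character(1))
  out
}

#' Write trajectories to CSV
#'
#' Columns: object_id, frame, t_s, x_nm, y_nm, quality (units in names).
#'
#' @param trajs a `trajectory` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr)
    cbind(object_id = attr(tr, "object_id"), as.data.frame(tr)))
  write_csv_precise(do.call(rbind, rows), path)
}

#' Read trajectories written by [write_trajectories()]
#'
#' @param path CSV path.
#' @param frame_rate_hz,pixel_size_nm calibration to attach.
#' @return list of `trajectory` objects, one per object_id.
#' @export
read_trajectories <- function(path, frame_rate_hz, pixel_size_nm = NA) {
  df <- utils::read.csv(path)
  lapply(split(df, df$object_id), function(g)
    trajectory(frame = g$frame, x_nm = g$x_nm, y_nm = g$y_nm,
               frame_rate_hz = frame_rate_hz, pixel_size_nm = pixel_size_nm,
               object_id = g$object_id[1], quality = g$quality))
}
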