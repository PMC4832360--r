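#' Detect a micro-pillar grid in a reference frame
#'
#' Local-maxima detection above an automatic robust threshold, centroid
#' refinement by intensity moments, and a fit of
#' the detected spots to an axis-aligned lattice. Returns the spot
#' positions indexed by lattice row and column.
#'
#' @param frame_img numeric matrix (typically the first movie frame).
#' @param expected_pitch_um expected centre-to-centre spacing; used for
#'   maxima merging, lattice clustering and the residual check.
#' @param pixel_size_nm spatial calibration, nm/px.
#' @param grid_shape optional (rows, cols); if given, the detected count
#'   must match.
#' @param refine_half_px half-width of the centroid-refinement window.
#'
#' @details Detection runs on a 3x3 box-smoothed copy of the frame, with
#'   the threshold 6 robust SDs (MAD-based) above the median, so
#'   single-pixel noise spikes cannot seed spurious maxima; candidates
#'   whose integrated background-subtracted mass falls below 20% of the
#'   brightest spot's are discarded for the same reason. At least 4
#'   genuine spots are required.
#' @return a `pillar_grid` data frame: row, col, x_nm, y_nm; attributes
#'   `pitch_um` (estimated) and `pixel_size_nm`.
#' @export
detect_pillars <- function(frame_img, expected_pitch_um, pixel_size_nm,
                           grid_shape = NULL, refine_half_px = 6L) {
  stopifnot(is.matrix(frame_img))
  pitch_px <- expected_pitch_um * 1000 / pixel_size_nm
  nr <- nrow(frame_img); nc <- ncol(frame_img)
  img <- frame_img
  # detect on a 3x3 box-smoothed copy: read noise shrinks ~3x while the
  # (multi-pixel) tip spots barely attenuate. The cut sits 6 robust SDs
  # above the median: a 3-sigma cut would admit ~0.1% of pure-noise
  # pixels, i.e. tens of false maxima on a 256 x 256 frame
  sm <- box3(img)
  thr <- stats::median(sm) + 6 * stats::mad(sm)
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  ismax <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & core >= sm[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no pillars found")
  peaks <- cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
  # merge maxima closer than half a pitch, keeping the brightest
  bright <- sm[peaks]
  ord <- order(bright, decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (nrow(kept) == 0L ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) > (pitch_px / 2)^2)
      kept <- rbind(kept, p)
  }
  # centroid refinement with local background subtraction; integrated
  # spot mass separates real tips from residual noise spikes
  w <- refine_half_px
  refined <- t(apply(kept, 1, function(p) {
    r0 <- max(1L, p[1] - w); r1 <- min(nr, p[1] + w)
    c0 <- max(1L, p[2] - w); c1 <- min(nc, p[2] + w)
    win <- img[r0:r1, c0:c1, drop = FALSE]
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    ww <- pmax(win - stats::median(border), 0)
    tot <- sum(ww)
    if (tot <= 0) return(c(p[1], p[2], 0))
    c(sum((r0:r1) * rowSums(ww)) / tot, sum((c0:c1) * colSums(ww)) / tot, tot)
  }))
  mass <- refined[, 3]
  keep_mass <- mass >= 0.2 * max(mass)
  centers <- refined[keep_mass, 1:2, drop = FALSE]
  if (nrow(centers) < 4L)
    stop("no pillars found (fewer than 4 spots on the frame)")
  # axis-aligned lattice: cluster row and column coordinates
  cluster_1d <- function(v) {
    o <- order(v)
    vs <- v[o]
    grp <- cumsum(c(1, diff(vs) > pitch_px / 2))
    lab <- integer(length(v)); lab[o] <- grp
    centers <- tapply(v, lab, mean)
    list(label = lab, centers = centers)
  }
  rcl <- cluster_1d(centers[, 1])
  ccl <- cluster_1d(centers[, 2])
  resid_px <- sqrt((centers[, 1] - rcl$centers[rcl$label])^2 +
                     (centers[, 2] - ccl$centers[ccl$label])^2)
  if (max(resid_px) > pitch_px / 4)
    stop("lattice residual too large (", round(max(resid_px), 2), " px)")
  if (!is.null(grid_shape)) {
    if (nrow(centers) < prod(grid_shape))
      stop("fewer pillars (", nrow(centers), ") than expected grid (",
           prod(grid_shape), ")")
    if (length(rcl$centers) != grid_shape[1] || length(ccl$centers) != grid_shape[2])
      stop("detected lattice does not match expected grid shape")
  }
  xy <- px_to_nm(centers, pixel_size_nm)
  est_pitch <- mean(c(diff(sort(rcl$centers)), diff(sort(ccl$centers)))) *
    pixel_size_nm / 1000
  out <- data.frame(row = rcl$label, col = ccl$label,
                    x_nm = xy[, 1], y_nm = xy[, 2])
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  attr(out, "pitch_um") <- if (is.finite(est_pitch)) est_pitch else expected_pitch_um
  attr(out, "pixel_size_nm") <- pixel_size_nm
  class(out) <- c("pillar_grid", "data.frame")
  out
}

#' @export
print.pillar_grid <- function(x, ...) {
  cat(sprintf("pillar_grid: %d pillars (%d rows x %d cols), pitch %.2f um\n",
              nrow(x), max(x$row), max(x$col), attr(x, "pitch_um")))
  invisible(x)
}

#' Convert tip positions to deflections and forces
#'
#' `delta_t = position_t - rest`; the force magnitude follows the linear
#' spring calibration, `F_t = k * ||delta_t||`, with k in pN/um and
#' deflection converted from nm (so a 1.0 um deflection at the calibrated
#' stiffness of 240 pN/um converts to exactly 240 pN).
#'
#' @param positions a [trajectory()] or data frame with `x_nm`, `y_nm`
#'   (and optionally `frame`).
#' @param rest numeric 2-vector, rest position `(x_nm, y_nm)`.
#' @param k_pN_per_um spring constant, pN/um (> 0).
#' @param frame_rate_hz temporal calibration; taken from the trajectory
#'   when available.
#' @param pillar_index optional (row, col) label.
#' @return a `deflection_series` data frame: frame, t_s, dx_nm, dy_nm,
#'   force_pN; attributes `k_pN_per_um`, `pillar_index`.
#' @export
deflection_to_force <- function(positions, rest, k_pN_per_um,
                                frame_rate_hz = NULL, pillar_index = NULL) {
  if (k_pN_per_um <= 0) stop("k_pN_per_um: must be > 0")
  if (inherits(positions, "trajectory") && is.null(frame_rate_hz))
    frame_rate_hz <- attr(positions, "frame_rate_hz")
  df <- as.data.frame(positions)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop("positions: need columns x_nm, y_nm")
  if (!all(is.finite(df$x_nm)) || !all(is.finite(df$y_nm)))
    stop("positions: non-finite values")
  if (length(rest) != 2L || !all(is.finite(rest)))
    stop("rest: must be finite (x_nm, y_nm)")
  frame <- if ("frame" %in% names(df)) df$frame else seq_len(nrow(df))
  dx <- df$x_nm - rest[1]
  dy <- df$y_nm - rest[2]
  out <- data.frame(frame = frame,
                    t_s = if (!is.null(frame_rate_hz)) (frame - 1) / frame_rate_hz
                          else NA_real_,
                    dx_nm = dx, dy_nm = dy,
                    force_pN = k_pN_per_um * sqrt(dx^2 + dy^2) / 1000)
  attr(out, "k_pN_per_um") <- k_pN_per_um
  attr(out, "pillar_index") <- pillar_index
  attr(out, "frame_rate_hz") <- frame_rate_hz
  class(out) <- c("deflection_series", "data.frame")
  out
}

#' Segment pull events from a force series
#'
#' Maximal runs of frames with `F >= threshold` lasting at least
#' `min_duration_frames` become events; runs separated by fewer than
#' `min_gap_frames` sub-threshold frames are merged into one event. The
#' default threshold is `max(25, 5 * sigma_hat)` pN, where `sigma_hat` is
#' the MAD-based noise SD of the force baseline: the 25 pN floor equals
#' one histogram bin of the assay being emulated (sub-bin pulls are
#' unresolvable in that presentation), and the 5-sigma rule keeps the
#' false-event rate negligible on noise-only movies.
#'
#' @param series a `deflection_series` (or bare numeric force vector).
#' @param threshold_pN detection threshold; `NULL` for the default above.
#' @param min_duration_frames minimum event length, frames.
#' @param min_gap_frames runs separated by at least this many
#'   sub-threshold frames count as distinct events.
#' @param frame_rate_hz needed only when `series` is a bare vector.
#' @return a `pull_events` data frame: start_frame, end_frame,
#'   peak_force_pN, mean_force_pN, duration_s (plus pillar_row/col when
#'   the series carries a pillar index); attribute `threshold_pN`.
#' @export
segment_pulls <- function(series, threshold_pN = NULL,
                          min_duration_frames = 3L, min_gap_frames = 2L,
                          frame_rate_hz = NULL) {
  if (is.numeric(series) && is.null(dim(series))) {
    force <- series
    frames <- seq_along(force)
    pid <- NULL
    if (is.null(frame_rate_hz)) frame_rate_hz <- 10
  } else {
    stopifnot(inherits(series, "deflection_series"))
    force <- series$force_pN
    frames <- series$frame
    pid <- attr(series, "pillar_index")
    if (is.null(frame_rate_hz)) frame_rate_hz <- attr(series, "frame_rate_hz")
    if (is.null(frame_rate_hz)) frame_rate_hz <- 10
  }
  if (length(force) == 0L) stop("empty series")
  if (is.null(threshold_pN)) {
    sigma <- stats::mad(force, center = stats::median(force))
    threshold_pN <- max(25, 5 * sigma)
  }
  if (threshold_pN <= 0) stop("threshold_pN: must be > 0")
  above <- force >= threshold_pN
  # merge gaps shorter than min_gap_frames
  r <- rle(above)
  if (length(r$values) > 2L) {
    interior <- which(!r$values & r$lengths < min_gap_frames)
    interior <- interior[interior > 1L & interior < length(r$values)]
    r$values[interior] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration_frames
  evs <- lapply(which(keep), function(i) {
    sl <- starts[i]:ends[i]
    data.frame(start_frame = frames[starts[i]], end_frame = frames[ends[i]],
               peak_force_pN = max(force[sl]),
               mean_force_pN = mean(force[sl]),
               duration_s = length(sl) / frame_rate_hz)
  })
  out <- if (length(evs)) do.call(rbind, evs) else
    data.frame(start_frame = integer(0), end_frame = integer(0),
               peak_force_pN = numeric(0), mean_force_pN = numeric(0),
               duration_s = numeric(0))
  if (!is.null(pid)) {
    out$pillar_row <- if (nrow(out)) pid[1] else integer(0)
    out$pillar_col <- if (nrow(out)) pid[2] else integer(0)
  }
  attr(out, "threshold_pN") <- threshold_pN
  class(out) <- c("pull_events", "data.frame")
  out
}

#' Summarize pull forces across events
#'
#' Pools the per-event force statistic (the event peak by default; the
#' event mean is available since "the force of a transient pull" is
#' ambiguous between the two) across pillars and replicates and reports
#' n, mean, SD, SE and a fixed-width histogram with left-closed
#' right-open bins anchored at 0, in 25 pN intervals by default.
#'
#' @param events a `pull_events` or a list of them.
#' @param bin_width_pN histogram bin width, pN.
#' @param statistic `"peak"` or `"mean"` force per event.
#' @return a `summary_stats`.
#' @export
summarize_forces <- function(events, bin_width_pN = 25,
                             statistic = c("peak", "mean")) {
  statistic <- match.arg(statistic)
  if (inherits(events, "pull_events")) events <- list(events)
  values <- unlist(lapply(events, function(e) {
    stopifnot(inherits(e, "pull_events"))
    if (statistic == "peak") e$peak_force_pN else e$mean_force_pN
  }), use.names = FALSE)
  if (length(values) == 0L) stop("no pull events to summarize")
  new_summary_stats(values, bin_width_pN, "pN")
}

# 3x3 box mean with replicated borders
box3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + pad[dr + 1:nr, dc + 1:nc]
  out / 9
}
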