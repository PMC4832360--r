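#' Auto-detect a chain ROI in the first frame
#'
#' Intensity centroid of the above-threshold pixels (image median plus 3
#' robust SDs) of frame 1 — the "brightest blob" fallback when no ROI is
#' supplied.
#'
#' @param movie a [movie_stack()].
#' @param half_size_px window half-width for the returned ROI.
#' @return an [roi()].
#' @export
auto_detect_roi <- function(movie, half_size_px = 24L) {
  img <- get_frame(movie, 1L)
  thr <- stats::median(img) + 3 * stats::mad(img)
  idx <- which(img > thr, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no object found above background in frame 1")
  w <- img[idx] - thr
  ctr <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  d <- dim(img)
  ctr <- pmin(pmax(ctr, 1 + half_size_px), d[1:2] - half_size_px)
  roi(ctr, half_size_px, "chain1")
}

write_json_file <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")

#' Run the chain-motility pipeline
#'
#' Movie in, motility statistics out: track the chain, compute
#' instantaneous velocities and their pooled summary (100 nm/s bins),
#' estimate per-frame poses, and derive the axis-relative directionality
#' report. With `out_dir` set, writes `trajectory.csv`, `velocities.csv`,
#' `histogram.csv`, `summary.json`, `directionality.json` and a resolved
#' copy of the full configuration (`run_config.json`), so a run is
#' reproducible from its outputs alone.
#'
#' @param input a [movie_stack()] or path to a TIFF written by
#'   [write_movie()].
#' @param out_dir optional output directory (created if needed).
#' @param chain_roi an [roi()]; auto-detected when `NULL`.
#' @param options tracking options; the default fixed template with
#'   quality-gated re-acquisition tolerates chain rotation at kinks.
#' @param bin_width_nm_s velocity histogram bin width.
#' @param pose_half_size_px pose window half-width.
#' @param ... passed to [directionality()].
#' @return a `motility_analysis`: list(trajectory, velocities, summary,
#'   poses, directionality).
#' @export
run_motility_pipeline <- function(input, out_dir = NULL, chain_roi = NULL,
                                  options = track_options(),
                                  bin_width_nm_s = 100,
                                  pose_half_size_px = 24L, ...) {
  movie <- if (inherits(input, "movie_stack")) input else read_movie(input)
  if (is.null(chain_roi)) chain_roi <- auto_detect_roi(movie, pose_half_size_px)
  traj <- track_roi(movie, chain_roi, options)
  vel <- instantaneous_velocities(traj)
  summ <- pool_and_summarize(vel, bin_width_nm_s)
  poses <- estimate_poses(movie, traj, pose_half_size_px)
  direc <- tryCatch(directionality(traj, poses, ...),
                    error = function(e) structure(
                      list(degenerate = TRUE, reason = conditionMessage(e)),
                      class = "directionality_report"))
  res <- structure(list(trajectory = traj, velocities = vel, summary = summ,
                        poses = poses, directionality = direc),
                   class = "motility_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectories(traj, file.path(out_dir, "trajectory.csv"))
    write_csv_precise(data.frame(step = seq_along(vel$values),
                                 v_nm_s = vel$values),
                      file.path(out_dir, "velocities.csv"))
    utils::write.csv(summ$histogram, file.path(out_dir, "histogram.csv"),
                     row.names = FALSE)
    write_json_file(summ[c("n", "mean", "sd", "se", "bin_width", "unit")],
                    file.path(out_dir, "summary.json"))
    dj <- unclass(direc)
    dj$angles_deg <- NULL
    write_json_file(dj, file.path(out_dir, "directionality.json"))
    cfg <- list(pipeline = "motility",
                roi = unclass(chain_roi), tracking = unclass(options),
                bin_width_nm_s = bin_width_nm_s,
                pose_half_size_px = pose_half_size_px,
                pixel_size_nm = movie$pixel_size_nm,
                frame_rate_hz = movie$frame_rate_hz)
    write_json_file(cfg, file.path(out_dir, "run_config.json"))
  }
  res
}

#' @export
print.motility_analysis <- function(x, ...) {
  cat("motility_analysis\n")
  print(x$summary)
  if (!isTRUE(x$directionality$degenerate)) print(x$directionality)
  else cat("  directionality: degenerate (", x$directionality$reason, ")\n")
  invisible(x)
}

#' Run the micro-pillar force pipeline
#'
#' Movie in, force statistics out: detect the pillar grid in frame 1,
#' track every tip, take each pillar's rest position as its per-frame
#' median tracked position (robust to transient pulls up to a 50% duty
#' cycle), convert deflections to forces through the spring calibration,
#' segment pull events, and summarize peak forces in 25 pN bins. With
#' `out_dir` set, writes `deflections.csv`, `events.csv`,
#' `histogram.csv`, `summary.json` and `run_config.json`.
#'
#' @param input a [movie_stack()] or TIFF path.
#' @param k_pN_per_um spring constant (default the calibrated 240 pN/um).
#' @param expected_pitch_um pillar spacing for grid detection.
#' @param out_dir optional output directory.
#' @param options tracking options; pillar tips move little per frame, so
#'   the default search radius is small and the template fixed.
#' @param tip_half_size_px tip tracking window half-width.
#' @param threshold_pN event threshold; `NULL` for the adaptive default
#'   of [segment_pulls()].
#' @param bin_width_pN force histogram bin width.
#' @param statistic per-event statistic pooled into the distribution.
#' @param grid_shape optional expected (rows, cols) for detection checks.
#' @return a `force_analysis`: list(grid, trajectories, deflections,
#'   events, summary).
#' @export
run_force_pipeline <- function(input, k_pN_per_um = 240, expected_pitch_um = 3,
                               out_dir = NULL,
                               options = track_options(search_radius_px = 5L),
                               tip_half_size_px = 8L, threshold_pN = NULL,
                               bin_width_pN = 25,
                               statistic = c("peak", "mean"),
                               grid_shape = NULL) {
  statistic <- match.arg(statistic)
  movie <- if (inherits(input, "movie_stack")) input else read_movie(input)
  px <- movie$pixel_size_nm
  grid <- detect_pillars(get_frame(movie, 1L), expected_pitch_um, px,
                         grid_shape = grid_shape)
  rois <- lapply(seq_len(nrow(grid)), function(i)
    roi(c(grid$y_nm[i] / px + 1, grid$x_nm[i] / px + 1), tip_half_size_px,
        sprintf("p%02d_%02d", grid$row[i], grid$col[i])))
  trajs <- track_many(movie, rois, options)
  series <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    rest <- c(stats::median(tr$x_nm), stats::median(tr$y_nm))
    deflection_to_force(tr, rest, k_pN_per_um,
                        pillar_index = c(grid$row[i], grid$col[i]))
  })
  events <- lapply(series, segment_pulls, threshold_pN = threshold_pN)
  all_events <- do.call(rbind, lapply(events, as.data.frame))
  class(all_events) <- c("pull_events", "data.frame")
  summ <- if (nrow(all_events)) summarize_forces(all_events, bin_width_pN,
                                                 statistic) else NULL
  res <- structure(list(grid = grid, trajectories = trajs,
                        deflections = series, events = all_events,
                        summary = summ, k_pN_per_um = k_pN_per_um),
                   class = "force_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    defl <- do.call(rbind, lapply(series, function(s) {
      pid <- attr(s, "pillar_index")
      cbind(pillar_row = pid[1], pillar_col = pid[2], as.data.frame(s))
    }))
    write_csv_precise(defl, file.path(out_dir, "deflections.csv"))
    write_csv_precise(as.data.frame(all_events), file.path(out_dir, "events.csv"))
    if (!is.null(summ)) {
      utils::write.csv(summ$histogram, file.path(out_dir, "histogram.csv"),
                       row.names = FALSE)
      write_json_file(summ[c("n", "mean", "sd", "se", "bin_width", "unit")],
                      file.path(out_dir, "summary.json"))
    } else {
      write_json_file(list(n = 0), file.path(out_dir, "summary.json"))
    }
    cfg <- list(pipeline = "force", k_pN_per_um = k_pN_per_um,
                expected_pitch_um = expected_pitch_um,
                tracking = unclass(options),
                tip_half_size_px = tip_half_size_px,
                threshold_pN = if (is.null(threshold_pN)) "auto" else threshold_pN,
                bin_width_pN = bin_width_pN, statistic = statistic,
                pixel_size_nm = px, frame_rate_hz = movie$frame_rate_hz)
    write_json_file(cfg, file.path(out_dir, "run_config.json"))
  }
  res
}

#' @export
print.force_analysis <- function(x, ...) {
  cat(sprintf("force_analysis: %d pillars, k = %g pN/um, %d pull events\n",
              nrow(x$grid), x$k_pN_per_um, nrow(x$events)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
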