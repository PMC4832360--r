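#' Ground truth of a simulated movie
#'
#' Container returned by the simulators: `poses` (one record per frame
#' per object: frame, object_id, x_nm, y_nm, angle_deg), `events`
#' (scripted pull table), `pillars` (rest positions), `deflections`
#' (per-frame deflection vectors and forces) and `changes` (kink /
#' reversal times for chain movies). Written to disk as plain CSV files
#' plus a JSON header so read-back is lossless.
#'
#' @name ground_truth
NULL

new_ground_truth <- function(kind, poses,
                             events = NULL, pillars = NULL,
                             deflections = NULL, changes = NULL,
                             meta = list()) {
  if (is.null(events))
    events <- data.frame(pillar_row = integer(0), pillar_col = integer(0),
                         t_start_s = numeric(0), t_end_s = numeric(0),
                         peak_force_pN = numeric(0), direction_deg = numeric(0),
                         profile = character(0))
  structure(list(kind = kind, poses = poses, events = events,
                 pillars = pillars, deflections = deflections,
                 changes = changes, meta = meta),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth (%s): %d pose records, %d objects, %d events\n",
              x$kind, nrow(x$poses), length(unique(x$poses$object_id)),
              nrow(x$events)))
  invisible(x)
}

# full-precision CSV so numeric round trips are bit-exact
write_csv_precise <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, file, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Write ground truth to disk
#'
#' Writes `<prefix>_poses.csv`, `<prefix>_events.csv`, optionally
#' `<prefix>_deflections.csv`, and a JSON header `<prefix>.json` holding
#' the kind, metadata, pillar rest positions and change log. Numeric
#' columns are written at full precision, so [read_ground_truth()]
#' reproduces the object exactly.
#'
#' @param truth a `ground_truth`.
#' @param prefix path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_ground_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  write_csv_precise(truth$poses, paste0(prefix, "_poses.csv"))
  write_csv_precise(truth$events, paste0(prefix, "_events.csv"))
  if (!is.null(truth$deflections))
    write_csv_precise(truth$deflections, paste0(prefix, "_deflections.csv"))
  header <- list(kind = truth$kind, meta = truth$meta,
                 pillars = truth$pillars, changes = truth$changes,
                 has_deflections = !is.null(truth$deflections))
  jsonlite::write_json(header, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param prefix the path prefix used when writing.
#' @return a `ground_truth` object equal to the one written.
#' @export
read_ground_truth <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  poses <- utils::read.csv(paste0(prefix, "_poses.csv"))
  events <- utils::read.csv(paste0(prefix, "_events.csv"),
                            colClasses = c(profile = "character"))
  defl <- NULL
  if (isTRUE(header$has_deflections))
    defl <- utils::read.csv(paste0(prefix, "_deflections.csv"))
  pil <- header$pillars
  if (!is.null(pil) && length(pil)) pil <- as.data.frame(pil) else pil <- NULL
  chg <- header$changes
  if (!is.null(chg) && length(chg)) chg <- as.data.frame(chg) else chg <- NULL
  meta <- header$meta
  new_ground_truth(kind = header$kind, poses = poses, events = events,
                   pillars = pil, deflections = defl, changes = chg,
                   meta = meta)
}

#' Build a trajectory object from ground-truth poses
#'
#' Convenience for testing downstream statistics against exact positions,
#' bypassing the tracker.
#'
#' @param truth a `ground_truth` from a chain simulation.
#' @param object_id which object to extract.
#' @return a `trajectory`.
#' @export
truth_trajectory <- function(truth, object_id = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$poses
  if (is.null(object_id)) object_id <- p$object_id[1]
  p <- p[p$object_id == object_id, , drop = FALSE]
  f <- truth$meta$frame_rate_hz
  trajectory(frame = p$frame, x_nm = p$x_nm, y_nm = p$y_nm,
             frame_rate_hz = f, pixel_size_nm = truth$meta$pixel_size_nm,
             object_id = object_id, quality = rep(1, nrow(p)))
}

#' Build a pose table from ground truth
#'
#' @param truth a `ground_truth` from a chain simulation.
#' @param object_id which object to extract.
#' @return a `chain_poses` data frame (frame, x_nm, y_nm, angle_deg,
#'   axis_ratio, degenerate) usable by [directionality()].
#' @export
truth_poses <- function(truth, object_id = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$poses
  if (is.null(object_id)) object_id <- p$object_id[1]
  p <- p[p$object_id == object_id, , drop = FALSE]
  out <- data.frame(frame = p$frame, x_nm = p$x_nm, y_nm = p$y_nm,
                    angle_deg = p$angle_deg, axis_ratio = Inf,
                    degenerate = FALSE)
  class(out) <- c("chain_poses", "data.frame")
  out
}
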