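#' Instantaneous velocities of a trajectory
#'
#' The per-step speed `v_i = ||r_(i+1) - r_i|| * frame_rate_hz` for every
#' consecutive frame pair, with no smoothing: at 10 Hz this is the
#' "instantaneous velocity" that gets pooled across chains and replicates
#' downstream. Raw frame-to-frame speeds are noise-inflated when the
#' localization error approaches the step length; see the package
#' vignette for the size of that bias.
#'
#' @param traj a [trajectory()] with >= 2 samples and a uniform time step.
#' @return an object of class `velocity_samples`: list with `values`
#'   (nm/s, one per frame pair), `object_id`, `frame_rate_hz`.
#' @export
instantaneous_velocities <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2L) stop("trajectory has fewer than 2 samples")
  dts <- diff(traj$t_s)
  if (max(dts) - min(dts) > 1e-9 * mean(dts))
    stop("non-uniform timestamps")
  f <- attr(traj, "frame_rate_hz")
  v <- sqrt(diff(traj$x_nm)^2 + diff(traj$y_nm)^2) * f
  structure(list(values = v, object_id = attr(traj, "object_id"),
                 frame_rate_hz = f),
            class = "velocity_samples")
}

#' @export
print.velocity_samples <- function(x, ...) {
  cat(sprintf("velocity_samples '%s': n = %d, mean %.1f nm/s\n",
              x$object_id, length(x$values), mean(x$values)))
  invisible(x)
}

# shared summary machinery for velocity (nm/s) and force (pN) samples
new_summary_stats <- function(values, bin_width, unit) {
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1L) stats::sd(values) else 0
  nb <- floor(max(values) / bin_width) + 1L
  breaks <- seq(0, nb * bin_width, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, right = FALSE,
                           plot = FALSE)$counts
  structure(list(n = n, mean = m, sd = s, se = s / sqrt(n),
                 bin_width = bin_width, unit = unit,
                 histogram = data.frame(bin_left = breaks[-length(breaks)],
                                        bin_right = breaks[-1],
                                        count = counts)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats (%s): n = %d, mean = %.4g, sd = %.4g, se = %.4g\n",
              x$unit, x$n, x$mean, x$sd, x$se))
  cat(sprintf("  histogram: %d bins of width %g (%s), counts sum to %d\n",
              nrow(x$histogram), x$bin_width, x$unit, sum(x$histogram$count)))
  invisible(x)
}

#' @export
plot.summary_stats <- function(x, ...) {
  graphics::barplot(x$histogram$count,
                    names.arg = x$histogram$bin_left, space = 0,
                    xlab = paste0("bin left edge (", x$unit, ")"),
                    ylab = "count", ...)
  invisible(x)
}

#' Pool velocity samples and summarize their distribution
#'
#' Pools all per-step speeds across chains and replicates (step-level
#' pooling, so `n` counts frame pairs, not chains) and reports n, mean,
#' SD, SE = SD/sqrt(n), and a fixed-width histogram with left-closed
#' right-open bins anchored at 0 (`[0, w), [w, 2w), ...`), matching the
#' 100 nm/s presentation of measured velocity distributions.
#'
#' @param samples a `velocity_samples` or a list of them.
#' @param bin_width_nm_s histogram bin width, nm/s.
#' @return a `summary_stats`.
#' @export
pool_and_summarize <- function(samples, bin_width_nm_s = 100) {
  if (inherits(samples, "velocity_samples")) samples <- list(samples)
  values <- unlist(lapply(samples, function(s) {
    stopifnot(inherits(s, "velocity_samples"))
    s$values
  }), use.names = FALSE)
  if (length(values) == 0L) stop("empty velocity pool")
  new_summary_stats(values, bin_width_nm_s, "nm_s")
}

#' Estimate the pose of a chain in one frame
#'
#' Centroid = intensity-weighted mean after local background subtraction;
#' long-axis angle = direction of the principal eigenvector of the
#' intensity second-moment (covariance) tensor, reported in `[0, 180)`
#' (the axis is undirected). Windows whose eigenvalue ratio falls below
#' `min_axis_ratio` carry no usable axis (isotropic blob) and are flagged
#' degenerate.
#'
#' @param frame_img numeric matrix (one movie frame).
#' @param roi an [roi()] locating the chain.
#' @param pixel_size_nm spatial calibration.
#' @param min_axis_ratio isotropy guard on the eigenvalue ratio.
#' @return a `chain_pose`: list(x_nm, y_nm, angle_deg, axis_ratio,
#'   degenerate).
#' @export
estimate_pose <- function(frame_img, roi, pixel_size_nm,
                          min_axis_ratio = 1.2) {
  stopifnot(is.matrix(frame_img), inherits(roi, "roi"))
  h <- roi$half_size_px
  c0 <- round(roi$center_px)
  r0 <- max(1L, c0[1] - h); r1 <- min(nrow(frame_img), c0[1] + h)
  cc0 <- max(1L, c0[2] - h); cc1 <- min(ncol(frame_img), c0[2] + h)
  win <- frame_img[r0:r1, cc0:cc1, drop = FALSE]
  border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
  w <- pmax(win - stats::median(border), 0)
  tot <- sum(w)
  degenerate_pose <- function(x, y, ratio) {
    structure(list(x_nm = x, y_nm = y, angle_deg = NA_real_,
                   axis_ratio = ratio, degenerate = TRUE),
              class = "chain_pose")
  }
  if (tot <= 0)
    return(degenerate_pose(NA_real_, NA_real_, 1))
  rows <- r0:r1; cols <- cc0:cc1
  mr <- sum(rows * rowSums(w)) / tot
  mc <- sum(cols * colSums(w)) / tot
  dr <- rows - mr; dc <- cols - mc
  mrr <- sum(dr^2 * rowSums(w)) / tot
  mcc <- sum(dc^2 * colSums(w)) / tot
  mrc <- sum(w * outer(dr, dc)) / tot
  ev <- eigen(matrix(c(mcc, mrc, mrc, mrr), 2, 2), symmetric = TRUE)
  ratio <- ev$values[1] / max(ev$values[2], 1e-12)
  xy <- px_to_nm(cbind(mr, mc), pixel_size_nm)
  if (ratio < min_axis_ratio)
    return(degenerate_pose(xy[1], xy[2], ratio))
  v <- ev$vectors[, 1]   # components (x, y) since tensor is in (col, row)
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  structure(list(x_nm = xy[1], y_nm = xy[2], angle_deg = ang,
                 axis_ratio = ratio, degenerate = FALSE),
            class = "chain_pose")
}

#' Estimate poses along a tracked trajectory
#'
#' Runs [estimate_pose()] on every frame of a movie, centring the window
#' on the tracked position, and returns one pose record per trajectory
#' sample.
#'
#' @param movie a [movie_stack()].
#' @param traj the chain's [trajectory()].
#' @param half_size_px pose window half-width; should cover the whole
#'   chain (default 24 px covers a 4-cell, ~4 um chain at 100 nm/px).
#' @param min_axis_ratio isotropy guard, see [estimate_pose()].
#' @return a `chain_poses` data frame: frame, x_nm, y_nm, angle_deg,
#'   axis_ratio, degenerate.
#' @export
estimate_poses <- function(movie, traj, half_size_px = 24L,
                           min_axis_ratio = 1.2) {
  stopifnot(inherits(movie, "movie_stack"), inherits(traj, "trajectory"))
  px <- movie$pixel_size_nm
  out <- lapply(seq_len(nrow(traj)), function(i) {
    ctr <- c(traj$y_nm[i] / px + 1, traj$x_nm[i] / px + 1)
    p <- estimate_pose(get_frame(movie, traj$frame[i]),
                       roi(ctr, half_size_px, attr(traj, "object_id")),
                       px, min_axis_ratio)
    data.frame(frame = traj$frame[i], x_nm = p$x_nm, y_nm = p$y_nm,
               angle_deg = p$angle_deg, axis_ratio = p$axis_ratio,
               degenerate = p$degenerate)
  })
  out <- do.call(rbind, out)
  class(out) <- c("chain_poses", "data.frame")
  out
}

#' Time-averaged mean-squared displacement
#'
#' `MSD(tau) = mean_i ||r_(i+tau) - r_i||^2` over all frame pairs at each
#' lag.
#'
#' @param traj a [trajectory()].
#' @param max_lag_frames largest lag; default a quarter of the trajectory
#'   (capping the fit range limits estimator variance at large lags).
#' @return data frame with columns lag_s, msd_nm2.
#' @export
msd <- function(traj, max_lag_frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (is.null(max_lag_frames)) max_lag_frames <- max(3L, floor((n - 1) / 4))
  max_lag_frames <- min(max_lag_frames, n - 1L)
  f <- attr(traj, "frame_rate_hz")
  lags <- seq_len(max_lag_frames)
  vals <- vapply(lags, function(L) {
    i <- seq_len(n - L)
    mean((traj$x_nm[i + L] - traj$x_nm[i])^2 +
           (traj$y_nm[i + L] - traj$y_nm[i])^2)
  }, numeric(1))
  data.frame(lag_s = lags / f, msd_nm2 = vals)
}

# log-log least-squares slope of MSD(tau); ~1 diffusive, ~2 ballistic
msd_exponent <- function(traj, max_lag_frames = NULL) {
  m <- msd(traj, max_lag_frames)
  m <- m[m$msd_nm2 > 0, , drop = FALSE]
  if (nrow(m) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(log(msd_nm2) ~ log(lag_s), data = m))[2])
}

#' Axis-relative directionality of a chain trajectory
#'
#' Classifies every step by its acute angle to the chain's long axis
#' (folded to `[0, 90]` degrees since the axis is undirected): "parallel"
#' if the angle is at most `parallel_max_deg`, "perpendicular" if at
#' least `perpendicular_min_deg`. Steps shorter than `noise_floor_nm` and
#' steps whose pose is degenerate are excluded from the angle statistics.
#'
#' Reversals are sign changes of the displacement projected on the
#' dominant motion axis (the principal direction of the step vectors —
#' the parallel component for train-like motion, the perpendicular one
#' for crabwise motion), counted only when the new sign persists for at
#' least `min_persist_frames` steps. The MSD exponent comes from a
#' log-log least-squares fit over lags up to a quarter of the duration.
#'
#' @param traj a [trajectory()].
#' @param poses a `chain_poses` table aligned frame-by-frame with `traj`
#'   (from [estimate_poses()] or [truth_poses()]).
#' @param parallel_max_deg,perpendicular_min_deg classification
#'   thresholds, degrees.
#' @param noise_floor_nm minimum step length entering angle statistics.
#' @param min_persist_frames persistence required to count a reversal.
#' @return a `directionality_report`: list(fraction_parallel,
#'   fraction_perpendicular, n_reversals, msd_exponent, n_steps_used,
#'   angles_deg).
#' @export
directionality <- function(traj, poses, parallel_max_deg = 30,
                           perpendicular_min_deg = 60, noise_floor_nm = 20,
                           min_persist_frames = 3L) {
  stopifnot(inherits(traj, "trajectory"))
  poses <- as.data.frame(poses)
  if (nrow(poses) != nrow(traj))
    stop("poses must align frame-by-frame with the trajectory")
  if (all(poses$degenerate)) stop("all poses degenerate; no usable axis")
  dx <- diff(traj$x_nm); dy <- diff(traj$y_nm)
  len <- sqrt(dx^2 + dy^2)
  ax <- poses$angle_deg[-nrow(poses)]          # axis at the step's start frame
  usable <- len > noise_floor_nm & !poses$degenerate[-nrow(poses)]
  if (sum(usable) < 10L) stop("fewer than 10 usable steps")
  step_ang <- atan2(dy[usable], dx[usable]) * 180 / pi
  rel <- abs((step_ang - ax[usable] + 90) %% 180 - 90)  # acute angle in [0, 90]
  frac_par <- mean(rel <= parallel_max_deg)
  frac_perp <- mean(rel >= perpendicular_min_deg)

  # dominant motion axis from the principal direction of the usable steps
  sv <- cbind(dx[usable], dy[usable])
  ev <- eigen(crossprod(sv), symmetric = TRUE)
  u <- ev$vectors[, 1]
  proj <- sv %*% u
  r <- rle(sign(proj[abs(proj) > 0]))
  good <- r$lengths >= min_persist_frames
  sgns <- r$values[good]
  if (length(sgns) > 1L) sgns <- sgns[c(TRUE, diff(sgns) != 0)]
  n_rev <- max(0L, length(sgns) - 1L)

  structure(list(fraction_parallel = frac_par,
                 fraction_perpendicular = frac_perp,
                 n_reversals = n_rev,
                 msd_exponent = msd_exponent(traj),
                 n_steps_used = sum(usable),
                 angles_deg = rel),
            class = "directionality_report")
}

#' @export
print.directionality_report <- function(x, ...) {
  cat(sprintf(paste0("directionality: %.1f%% parallel, %.1f%% perpendicular",
                     " (n = %d steps)\n"),
              100 * x$fraction_parallel, 100 * x$fraction_perpendicular,
              x$n_steps_used))
  cat(sprintf("  reversals: %d; MSD exponent alpha = %.2f\n",
              x$n_reversals, x$msd_exponent))
  invisible(x)
}
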