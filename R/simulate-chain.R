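#' Simulate the ground-truth path of one bacterial chain
#'
#' Generates centroid positions and long-axis angles for a chain moving
#' under one of the four motility models, without rendering any images.
#' This is the cheap path used by Monte-Carlo checks of the motion
#' statistics; [simulate_chain_movie()] renders the same paths.
#'
#' Motion models (time step `dt = 1 / frame_rate_hz`):
#' * `train`: per-step displacement along the current chain axis with
#'   speed drawn from `Normal(speed_nm_s, speed_sd_nm_s)` clipped at 0;
#'   at Poisson(`kink_rate_hz`) times the axis turns abruptly by a
#'   uniform `[30, 90]` degree kink of random sign (the chain axis and
#'   the motion axis coincide).
#' * `crabwise`: the chain axis is fixed; displacement is perpendicular
#'   to it, with the sign of the perpendicular direction flipping at
#'   Poisson(`reversal_rate_hz`) times.
#' * `brownian`: per-coordinate displacements `Normal(0, sqrt(2 D dt))`;
#'   the chain axis stays fixed (rotational diffusion is not modelled).
#' * `static`: no motion.
#'
#' Positions are clipped (with a warning) so the whole rendered chain
#' stays inside the frame.
#'
#' @param config a [chain_config()].
#' @param geometry a [movie_geometry()].
#' @return a `ground_truth` object (see [simulate_chain_movie()]).
#' @export
simulate_chain_path <- function(config, geometry = movie_geometry()) {
  stopifnot(inherits(config, "chain_config"), inherits(geometry, "movie_geometry"))
  withr::with_seed(config$seed, chain_path_impl(config, geometry))
}

chain_path_impl <- function(config, geometry) {
  f <- geometry$frame_rate_hz
  nt <- round(config$duration_s * f) + 1L
  if (nt < 2L) stop("duration_s: movie must span at least 2 frames")
  dt <- 1 / f
  px <- geometry$pixel_size_nm
  width_nm <- (geometry$shape[2] - 1) * px
  height_nm <- (geometry$shape[1] - 1) * px
  start <- c(width_nm / 2, height_nm / 2)
  theta0 <- stats::runif(1, 0, 360)

  steps <- matrix(0, nt - 1L, 2)      # (dx, dy) nm per frame interval
  axis_deg <- rep(theta0, nt)         # directed axis angle per frame
  changes <- data.frame(t_s = numeric(0), type = character(0), value = numeric(0))

  if (config$mode == "train") {
    speeds <- pmax(stats::rnorm(nt - 1L, config$speed_nm_s, config$speed_sd_nm_s), 0)
    kink_t <- poisson_times(config$kink_rate_hz, config$duration_s)
    if (length(kink_t)) {
      dirs <- sample(c(-1, 1), length(kink_t), replace = TRUE)
      mags <- stats::runif(length(kink_t), 30, 90)
      changes <- data.frame(t_s = kink_t, type = "kink", value = dirs * mags)
    }
    th <- theta0
    ki <- 1L
    for (i in seq_len(nt - 1L)) {
      t_now <- (i - 1L) * dt
      while (ki <= nrow(changes) && changes$t_s[ki] <= t_now) {
        th <- th + changes$value[ki]
        ki <- ki + 1L
      }
      axis_deg[i] <- th
      steps[i, ] <- speeds[i] * dt * c(cospi(th / 180), sinpi(th / 180))
    }
    axis_deg[nt] <- th
  } else if (config$mode == "crabwise") {
    speeds <- pmax(stats::rnorm(nt - 1L, config$speed_nm_s, config$speed_sd_nm_s), 0)
    rev_t <- poisson_times(config$reversal_rate_hz, config$duration_s)
    if (length(rev_t))
      changes <- data.frame(t_s = rev_t, type = "reversal", value = NA_real_)
    perp <- theta0 + 90
    sgn <- 1
    ri <- 1L
    for (i in seq_len(nt - 1L)) {
      t_now <- (i - 1L) * dt
      while (ri <= nrow(changes) && changes$t_s[ri] <= t_now) {
        sgn <- -sgn
        if (is.na(changes$value[ri])) changes$value[ri] <- sgn
        ri <- ri + 1L
      }
      steps[i, ] <- sgn * speeds[i] * dt * c(cospi(perp / 180), sinpi(perp / 180))
    }
  } else if (config$mode == "brownian") {
    d_nm2 <- config$diffusion_um2_s * 1e6
    steps[] <- stats::rnorm(2L * (nt - 1L), 0, sqrt(2 * d_nm2 * dt))
  } # static: zero steps

  pos <- matrix(0, nt, 2)
  pos[1, ] <- start
  if (nt > 1L) {
    pos[, 1] <- start[1] + c(0, cumsum(steps[, 1]))
    pos[, 2] <- start[2] + c(0, cumsum(steps[, 2]))
  }

  # keep the whole chain (plus 3 sigma of blur) inside the frame
  half_span <- (config$n_cells - 1L) * config$cell_radius_nm
  margin <- half_span + 3 * config$noise$psf_sigma_nm
  lo <- margin; hix <- width_nm - margin; hiy <- height_nm - margin
  if (hix <= lo || hiy <= lo) stop("geometry: frame too small for this chain")
  clipped <- pos[, 1] < lo | pos[, 1] > hix | pos[, 2] < lo | pos[, 2] > hiy
  if (any(clipped)) {
    warning("chain positions clipped to the frame in ", sum(clipped), " frame(s)")
    pos[, 1] <- pmin(pmax(pos[, 1], lo), hix)
    pos[, 2] <- pmin(pmax(pos[, 2], lo), hiy)
  }

  poses <- data.frame(frame = seq_len(nt), object_id = "chain1",
                      x_nm = pos[, 1], y_nm = pos[, 2],
                      angle_deg = axis_deg %% 180)
  new_ground_truth(kind = "chain", poses = poses, changes = changes,
                   meta = list(mode = config$mode, n_cells = config$n_cells,
                               speed_nm_s = config$speed_nm_s,
                               duration_s = config$duration_s,
                               frame_rate_hz = f, pixel_size_nm = px,
                               seed = config$seed,
                               axis_deg_directed = axis_deg))
}

poisson_times <- function(rate_hz, duration_s) {
  if (rate_hz <= 0) return(numeric(0))
  # draw a generous fixed-length batch so stream length is data-independent
  n_max <- max(10L, ceiling(4 * rate_hz * duration_s + 20))
  tt <- cumsum(stats::rexp(n_max, rate_hz))
  tt[tt < duration_s]
}

#' Simulate a time-lapse movie of one bacterial chain
#'
#' Renders the path from [simulate_chain_path()] as `n_cells` Gaussian
#' blobs spaced `2 * cell_radius_nm` along the chain axis, on a constant
#' background with additive Gaussian read noise, and returns the movie
#' together with its exact ground truth. Identical `(config, geometry)`
#' (the seed lives in the config) give bit-identical output.
#'
#' @param config a [chain_config()].
#' @param geometry a [movie_geometry()].
#' @return list with elements `movie` (a [movie_stack()]) and `truth`
#'   (a `ground_truth`: per-frame centroid and axis angle, plus the log
#'   of kink / reversal times).
#' @export
simulate_chain_movie <- function(config, geometry = movie_geometry()) {
  stopifnot(inherits(config, "chain_config"), inherits(geometry, "movie_geometry"))
  withr::with_seed(config$seed, {
    truth <- chain_path_impl(config, geometry)
    nt <- nrow(truth$poses)
    px <- geometry$pixel_size_nm
    sigma_px <- config$noise$psf_sigma_nm / px
    frames <- array(0L, dim = c(geometry$shape[1], geometry$shape[2], nt))
    axis_dir <- truth$meta$axis_deg_directed
    offsets <- (seq_len(config$n_cells) - (config$n_cells + 1) / 2) *
      2 * config$cell_radius_nm
    for (i in seq_len(nt)) {
      th <- axis_dir[i]
      u <- c(cospi(th / 180), sinpi(th / 180))
      centers_nm <- cbind(truth$poses$x_nm[i] + offsets * u[1],
                          truth$poses$y_nm[i] + offsets * u[2])
      frames[, , i] <- render_frame(geometry$shape, nm_to_px(centers_nm, px),
                                    sigma_px, config$noise$amplitude,
                                    config$noise$background_level,
                                    config$noise$gaussian_sd)
    }
    movie <- movie_stack(frames, px, geometry$frame_rate_hz)
    list(movie = movie, truth = truth)
  })
}
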