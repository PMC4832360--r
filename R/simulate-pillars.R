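#' Simulate a micro-pillar force-sensor movie
#'
#' Renders a regular grid of pillar tips as Gaussian spots. Each scripted
#' pull event applies a time-dependent force `F(t)` to one pillar; the tip
#' is displaced through the linear spring, `delta(t) = F(t) / k`, along
#' the event's azimuth, and overlapping events on one pillar sum their
#' force vectors. Ground truth logs the rest positions, the per-frame
#' deflection vectors with their force magnitudes, and the scripted event
#' table. Identical config (seed included) gives bit-identical output.
#'
#' @param config a [pillar_config()].
#' @param geometry a [movie_geometry()]; the grid is centred in the frame.
#' @return list with elements `movie` and `truth` (`ground_truth` with
#'   `pillars`, `poses` = per-frame tip positions, `deflections`, `events`).
#' @export
simulate_pillar_movie <- function(config, geometry = movie_geometry()) {
  stopifnot(inherits(config, "pillar_config"), inherits(geometry, "movie_geometry"))
  f <- geometry$frame_rate_hz
  nt <- round(config$duration_s * f) + 1L
  if (nt < 2L) stop("duration_s: movie must span at least 2 frames")
  px <- geometry$pixel_size_nm
  gr <- config$grid_shape[1]; gc <- config$grid_shape[2]
  pitch_nm <- config$pitch_um * 1000
  width_nm <- (geometry$shape[2] - 1) * px
  height_nm <- (geometry$shape[1] - 1) * px

  rows <- rep(seq_len(gr), each = gc)
  cols <- rep(seq_len(gc), times = gr)
  rest_x <- width_nm / 2 + (cols - (gc + 1) / 2) * pitch_nm
  rest_y <- height_nm / 2 + (rows - (gr + 1) / 2) * pitch_nm
  marg <- 3 * config$noise$psf_sigma_nm
  if (any(rest_x < marg | rest_x > width_nm - marg |
          rest_y < marg | rest_y > height_nm - marg))
    stop("geometry: pillar grid does not fit inside the frame")
  pillars <- data.frame(row = rows, col = cols, x_nm = rest_x, y_nm = rest_y)

  times <- (seq_len(nt) - 1L) / f
  # per-frame force vector per pillar
  fx <- matrix(0, nt, gr * gc)
  fy <- matrix(0, nt, gr * gc)
  for (e in config$events) {
    idx <- (e$pillar[1] - 1L) * gc + e$pillar[2]
    ft <- pull_profile(times, e)
    fx[, idx] <- fx[, idx] + ft * cospi(e$direction_deg / 180)
    fy[, idx] <- fy[, idx] + ft * sinpi(e$direction_deg / 180)
  }
  # linear spring: deflection (nm) = force (pN) / k (pN/um) * 1000
  dx <- fx / config$k_pN_per_um * 1000
  dy <- fy / config$k_pN_per_um * 1000

  sigma_px <- config$noise$psf_sigma_nm / px
  frames <- array(0L, dim = c(geometry$shape[1], geometry$shape[2], nt))
  movie <- withr::with_seed(config$seed, {
    for (i in seq_len(nt)) {
      centers_nm <- cbind(rest_x + dx[i, ], rest_y + dy[i, ])
      frames[, , i] <- render_frame(geometry$shape, nm_to_px(centers_nm, px),
                                    sigma_px, config$noise$amplitude,
                                    config$noise$background_level,
                                    config$noise$gaussian_sd)
    }
    movie_stack(frames, px, f)
  })

  ids <- sprintf("p%02d_%02d", rows, cols)
  poses <- data.frame(
    frame = rep(seq_len(nt), times = gr * gc),
    object_id = rep(ids, each = nt),
    x_nm = as.vector(sweep(dx, 2, rest_x, `+`)),
    y_nm = as.vector(sweep(dy, 2, rest_y, `+`)),
    angle_deg = NA_real_)
  deflections <- data.frame(
    frame = rep(seq_len(nt), times = gr * gc),
    pillar_row = rep(rows, each = nt),
    pillar_col = rep(cols, each = nt),
    dx_nm = as.vector(dx), dy_nm = as.vector(dy),
    force_pN = config$k_pN_per_um * sqrt(as.vector(dx)^2 + as.vector(dy)^2) / 1000)
  events <- if (length(config$events)) do.call(rbind, lapply(config$events, function(e)
    data.frame(pillar_row = e$pillar[1], pillar_col = e$pillar[2],
               t_start_s = e$t_start_s, t_end_s = e$t_end_s,
               peak_force_pN = e$peak_force_pN,
               direction_deg = e$direction_deg, profile = e$profile)))
  else data.frame(pillar_row = integer(0), pillar_col = integer(0),
                  t_start_s = numeric(0), t_end_s = numeric(0),
                  peak_force_pN = numeric(0), direction_deg = numeric(0),
                  profile = character(0))

  truth <- new_ground_truth(kind = "pillar", poses = poses, events = events,
                            pillars = pillars, deflections = deflections,
                            meta = list(grid_shape = config$grid_shape,
                                        pitch_um = config$pitch_um,
                                        k_pN_per_um = config$k_pN_per_um,
                                        duration_s = config$duration_s,
                                        frame_rate_hz = f, pixel_size_nm = px,
                                        seed = config$seed))
  list(movie = movie, truth = truth)
}

# force magnitude over time for one scripted pull
pull_profile <- function(times, e) {
  dur <- e$t_end_s - e$t_start_s
  rel <- (times - e$t_start_s) / dur
  ft <- numeric(length(times))
  inside <- rel >= 0 & rel <= 1
  r <- rel[inside]
  ft[inside] <- if (e$profile == "triangular") {
    e$peak_force_pN * (1 - abs(2 * r - 1))
  } else {
    # ramp-hold-release: quarter up, half hold, quarter down
    e$peak_force_pN * pmin(1, pmin(r / 0.25, (1 - r) / 0.25))
  }
  ft
}
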