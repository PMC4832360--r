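#' Imaging noise model
#'
#' Additive camera model used by both simulators: constant background
#' offset, Gaussian read noise, and an isotropic Gaussian point-spread
#' scale that sets the rendered blob width. Defaults give a peak
#' signal-to-noise ratio of about 20 (cell amplitude 100 counts over
#' background 100, read noise SD 5) -- generous but nontrivial.
#'
#' @param background_level background intensity offset (counts, >= 0).
#' @param gaussian_sd additive read-noise SD (counts, >= 0); 0 disables noise.
#' @param psf_sigma_nm Gaussian blur scale in nm (>= 0).
#' @param amplitude peak intensity of one rendered object above background.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(background_level = 100, gaussian_sd = 5,
                         psf_sigma_nm = 250, amplitude = 100) {
  for (nm in c("background_level", "gaussian_sd", "psf_sigma_nm", "amplitude")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(nm, ": must be a single finite number >= 0")
  }
  structure(list(background_level = background_level, gaussian_sd = gaussian_sd,
                 psf_sigma_nm = psf_sigma_nm, amplitude = amplitude),
            class = "noise_config")
}

#' Movie geometry: frame size and calibration
#'
#' Defaults (256 x 256 px, 100 nm/px, 10 Hz) match the acquisition rate
#' of the motility assays being emulated; the frame size is a compromise
#' chosen for fast simulation. Recovery experiments on fast, long
#' trajectories should pass a larger frame so the chain never reaches
#' the border (a 30 s run at ~700 nm/s covers ~21 um).
#'
#' @param shape integer 2-vector, frame rows and cols in px.
#' @param pixel_size_nm nm per pixel (> 0).
#' @param frame_rate_hz frames per second (> 0).
#' @return an object of class `movie_geometry`.
#' @export
movie_geometry <- function(shape = c(256L, 256L), pixel_size_nm = 100,
                           frame_rate_hz = 10) {
  if (length(shape) != 2L || any(shape < 32))
    stop("shape: must be two frame dimensions >= 32 px")
  if (pixel_size_nm <= 0) stop("pixel_size_nm: must be > 0")
  if (frame_rate_hz <= 0) stop("frame_rate_hz: must be > 0")
  structure(list(shape = as.integer(shape), pixel_size_nm = pixel_size_nm,
                 frame_rate_hz = frame_rate_hz),
            class = "movie_geometry")
}

#' Configuration of a simulated bacterial chain
#'
#' Describes one chain of cocci and its motion model. Four models cover
#' the observed phenotypes: `"train"` -- directed motion parallel to the
#' chain's long axis with occasional abrupt kinks (wild type); `"crabwise"`
#' -- motion perpendicular to the long axis with stochastic reversals of
#' gear; `"brownian"` -- pure thermal diffusion (retraction-motor mutant);
#' `"static"` -- no motion. Only the parameters relevant to `mode` are
#' consumed; the rest are ignored.
#'
#' @param mode one of `"train"`, `"brownian"`, `"crabwise"`, `"static"`.
#' @param n_cells number of cocci in the chain (>= 1).
#' @param cell_radius_nm coccus radius in nm; centres are spaced
#'   `2 * cell_radius_nm` along the chain axis.
#' @param speed_nm_s ground-truth mean speed (train/crabwise), nm/s.
#' @param speed_sd_nm_s per-step speed spread (SD of the per-frame speed
#'   draw, clipped at 0), nm/s.
#' @param kink_rate_hz Poisson rate of abrupt axis changes (train mode), Hz.
#' @param reversal_rate_hz Poisson rate of gear reversals (crabwise mode), Hz.
#' @param diffusion_um2_s diffusion coefficient (brownian mode), um^2/s.
#' @param duration_s movie length in seconds (> 0).
#' @param noise a [noise_config()].
#' @param seed integer seed; mandatory, all modes draw from one stream.
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(mode = c("train", "brownian", "crabwise", "static"),
                         n_cells = 4L, cell_radius_nm = 500,
                         speed_nm_s = 694, speed_sd_nm_s = 150,
                         kink_rate_hz = 0.05, reversal_rate_hz = 0.2,
                         diffusion_um2_s = 0.05, duration_s = 30,
                         noise = noise_config(), seed) {
  mode <- match.arg(mode)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed: a single integer seed is mandatory")
  if (n_cells < 1L) stop("n_cells: must be >= 1")
  if (duration_s <= 0) stop("duration_s: must be > 0")
  for (nm in c("cell_radius_nm", "speed_nm_s", "speed_sd_nm_s", "kink_rate_hz",
               "reversal_rate_hz", "diffusion_um2_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(nm, ": must be a single finite number >= 0")
  }
  stopifnot(inherits(noise, "noise_config"))
  structure(list(mode = mode, n_cells = as.integer(n_cells),
                 cell_radius_nm = cell_radius_nm, speed_nm_s = speed_nm_s,
                 speed_sd_nm_s = speed_sd_nm_s, kink_rate_hz = kink_rate_hz,
                 reversal_rate_hz = reversal_rate_hz,
                 diffusion_um2_s = diffusion_um2_s, duration_s = duration_s,
                 noise = noise, seed = as.integer(seed)),
            class = "chain_config")
}

#' One scripted pull event on a micro-pillar
#'
#' A transient tension episode applied to a single pillar. The force
#' profile rises from 0 to `peak_force_pN` and back within
#' `[t_start_s, t_end_s]`: `"ramp-hold-release"` ramps up over the first
#' quarter of the window, holds the peak over the middle half, and
#' releases over the last quarter; `"triangular"` peaks at the midpoint.
#' The pillar tip is displaced through the linear spring:
#' `deflection = force / k`, along `direction_deg`.
#'
#' @param pillar integer 2-vector `(row, col)` indexing the pillar grid.
#' @param t_start_s,t_end_s event window, `0 <= t_start_s < t_end_s`.
#' @param peak_force_pN maximum tension, pN (>= 0).
#' @param direction_deg pull azimuth, degrees from +x towards +y.
#' @param profile `"ramp-hold-release"` or `"triangular"`.
#' @return an object of class `scripted_pull`.
#' @export
scripted_pull <- function(pillar, t_start_s, t_end_s, peak_force_pN,
                          direction_deg = 0,
                          profile = c("ramp-hold-release", "triangular")) {
  profile <- match.arg(profile)
  if (length(pillar) != 2L || any(pillar < 1))
    stop("pillar: must be (row, col) with both >= 1")
  if (t_start_s < 0 || t_start_s >= t_end_s)
    stop("t_start_s/t_end_s: need 0 <= t_start_s < t_end_s")
  if (peak_force_pN < 0) stop("peak_force_pN: must be >= 0")
  structure(list(pillar = as.integer(pillar), t_start_s = t_start_s,
                 t_end_s = t_end_s, peak_force_pN = peak_force_pN,
                 direction_deg = direction_deg, profile = profile),
            class = "scripted_pull")
}

#' Configuration of a simulated micro-pillar force-sensor array
#'
#' A regular grid of flexible pillars whose tips behave as linear springs
#' of stiffness `k_pN_per_um` (default 240, the calibrated value of the
#' polyacrylamide pillars being emulated). Scripted pull events displace
#' tips by `force / k`; overlapping events on one pillar sum their force
#' vectors.
#'
#' @param grid_shape integer 2-vector, pillar rows x cols.
#' @param pitch_um centre-to-centre pillar spacing, um. Must satisfy
#'   `pitch_um * 1000 > 6 * noise$psf_sigma_nm` so tip spots stay separable.
#' @param k_pN_per_um spring constant, pN per um of tip deflection (> 0).
#' @param events list of [scripted_pull()] events.
#' @param noise a [noise_config()].
#' @param duration_s movie length, s (> 0).
#' @param seed integer seed (mandatory).
#' @return an object of class `pillar_config`.
#' @export
pillar_config <- function(grid_shape = c(8L, 8L), pitch_um = 3,
                          k_pN_per_um = 240, events = list(),
                          noise = noise_config(), duration_s = 30, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed: a single integer seed is mandatory")
  if (length(grid_shape) != 2L || any(grid_shape < 1))
    stop("grid_shape: must be (rows, cols) with both >= 1")
  if (k_pN_per_um <= 0) stop("k_pN_per_um: must be > 0")
  if (duration_s <= 0) stop("duration_s: must be > 0")
  stopifnot(inherits(noise, "noise_config"))
  if (pitch_um * 1000 <= 6 * noise$psf_sigma_nm)
    stop("pitch_um: tip spots would overlap (need pitch_um * 1000 > 6 * psf_sigma_nm)")
  events <- lapply(events, function(e) {
    if (!inherits(e, "scripted_pull")) stop("events: must be scripted_pull objects")
    if (any(e$pillar > grid_shape)) stop("events: unknown pillar index ",
                                         paste(e$pillar, collapse = ","))
    if (e$t_end_s > duration_s) stop("events: event window outside movie duration")
    e
  })
  structure(list(grid_shape = as.integer(grid_shape), pitch_um = pitch_um,
                 k_pN_per_um = k_pN_per_um, events = events, noise = noise,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "pillar_config")
}

#' Draw a random schedule of scripted pull events
#'
#' Generates `n_events` non-overlapping pull events spread over a pillar
#' grid with peak forces from a floor-shifted exponential distribution:
#' `peak = min_peak_pN + Exponential(mean_peak_pN - min_peak_pN)`. The
#' floor (default 30 pN, just above the 25 pN histogram-bin resolution of
#' the assay being emulated) keeps every scripted event resolvable by the
#' detection threshold; the exponential tail reproduces the right-skewed
#' shape of measured pull-force distributions. With
#' `exact_mean = TRUE` (default) the exponential part is rescaled so the
#' sample mean of the peaks equals `mean_peak_pN` exactly, which makes
#' parameter-recovery experiments independent of sampling scatter.
#'
#' @param grid_shape pillar grid (rows, cols).
#' @param duration_s movie duration the events must fit into.
#' @param n_events number of events (>= 1).
#' @param mean_peak_pN target mean peak force, pN.
#' @param min_peak_pN force floor, pN (< `mean_peak_pN`).
#' @param event_duration_s duration of each event, s.
#' @param gap_s minimum gap between events on one pillar, s.
#' @param seed integer seed.
#' @param exact_mean rescale draws so the sample mean is exact.
#' @return list of [scripted_pull()] events.
#' @export
random_pull_events <- function(grid_shape, duration_s, n_events,
                               mean_peak_pN = 69.9, min_peak_pN = 30,
                               event_duration_s = 2, gap_s = 1, seed,
                               exact_mean = TRUE) {
  if (missing(seed)) stop("seed: mandatory for random event generation")
  if (n_events < 1) stop("n_events: must be >= 1")
  if (min_peak_pN >= mean_peak_pN) stop("min_peak_pN: must be < mean_peak_pN")
  n_pillars <- prod(grid_shape)
  slots_per_pillar <- floor((duration_s - gap_s) / (event_duration_s + gap_s))
  if (n_events > n_pillars * slots_per_pillar)
    stop("n_events: schedule does not fit (", n_pillars * slots_per_pillar,
         " slots available)")
  withr::with_seed(as.integer(seed), {
    e <- stats::rexp(n_events)
    scale <- if (exact_mean) (mean_peak_pN - min_peak_pN) / mean(e) else
      (mean_peak_pN - min_peak_pN)
    peaks <- min_peak_pN + e * scale
    dirs <- stats::runif(n_events, 0, 360)
    lapply(seq_len(n_events), function(i) {
      p <- (i - 1L) %% n_pillars
      slot <- (i - 1L) %/% n_pillars
      t0 <- gap_s + slot * (event_duration_s + gap_s)
      scripted_pull(pillar = c(p %/% grid_shape[2] + 1L, p %% grid_shape[2] + 1L),
                    t_start_s = t0, t_end_s = t0 + event_duration_s,
                    peak_force_pN = peaks[i], direction_deg = dirs[i])
    })
  })
}
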