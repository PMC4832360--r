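test_that("pillar detection localizes a clean grid to 0.05 px", {
  cfg <- pillar_config(grid_shape = c(8L, 8L), pitch_um = 3,
                       noise = noise_off(), duration_s = 0.2, seed = 1)
  sim <- simulate_pillar_movie(cfg, geom_small(256))
  grid <- detect_pillars(get_frame(sim$movie, 1), 3, 100, grid_shape = c(8, 8))
  expect_equal(nrow(grid), 64L)
  truth <- sim$truth$pillars
  m <- merge(grid, truth, by = c("row", "col"), suffixes = c("", "_true"))
  expect_equal(nrow(m), 64L)
  err_px <- sqrt((m$x_nm - m$x_nm_true)^2 + (m$y_nm - m$y_nm_true)^2) / 100
  expect_lt(max(err_px), 0.05)
  expect_equal(attr(grid, "pitch_um"), 3, tolerance = 0.01)
})

test_that("pillar detection fails loudly on an empty frame", {
  withr::with_seed(2, {
    empty <- matrix(as.integer(round(100 + stats::rnorm(160 * 160, 0, 5))), 160, 160)
  })
  expect_error(detect_pillars(empty, 3, 100), "no pillars")
})

test_that("median rest position is robust to an event at the reference frame", {
  ev <- list(scripted_pull(c(1, 1), 0, 6, 200, direction_deg = 45))
  cfg <- pillar_config(grid_shape = c(2L, 2L), pitch_um = 4, events = ev,
                       duration_s = 20, seed = 5)
  sim <- simulate_pillar_movie(cfg, geom_small(256))
  res <- run_force_pipeline(sim$movie, expected_pitch_um = 4,
                            grid_shape = c(2, 2))
  tr <- res$trajectories[["p01_01"]]
  rest_est <- c(stats::median(tr$x_nm), stats::median(tr$y_nm))
  truth_rest <- sim$truth$pillars[sim$truth$pillars$row == 1 &
                                    sim$truth$pillars$col == 1, ]
  err_px <- sqrt((rest_est[1] - truth_rest$x_nm)^2 +
                   (rest_est[2] - truth_rest$y_nm)^2) / 100
  expect_lt(err_px, 0.2)
})

test_that("deflection converts to force through the spring calibration", {
  # 1.0 um at 240 pN/um -> 240 pN exactly
  pos <- data.frame(x_nm = c(0, 1000), y_nm = c(0, 0))
  ds <- deflection_to_force(pos, rest = c(0, 0), k_pN_per_um = 240)
  expect_equal(ds$force_pN, c(0, 240), tolerance = 1e-12)
  # 2.5 um -> 600 pN; direction does not matter
  pos2 <- data.frame(x_nm = 2500 * cospi(0.3), y_nm = 2500 * sinpi(0.3))
  expect_equal(deflection_to_force(pos2, c(0, 0), 240)$force_pN, 600,
               tolerance = 1e-9)
  expect_error(deflection_to_force(data.frame(x_nm = NA, y_nm = 0), c(0, 0), 240),
               "finite")
  expect_error(deflection_to_force(pos, c(0, 0), 0), "k_pN_per_um")
})

test_that("pull segmentation finds square pulses and separates events", {
  f <- c(rep(0, 10), rep(100, 10), rep(0, 10))
  ev <- segment_pulls(f, threshold_pN = 25)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$peak_force_pN, 100)
  expect_equal(ev$mean_force_pN, 100)
  expect_equal(ev$start_frame, 11L)
  expect_equal(ev$duration_s, 1)

  two <- c(rep(0, 5), rep(80, 8), rep(0, 5), rep(120, 8), rep(0, 5))
  ev2 <- segment_pulls(two, threshold_pN = 25)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$peak_force_pN, c(80, 120))

  # a single sub-threshold frame does not split an event
  dip <- c(rep(0, 5), rep(80, 5), 10, rep(80, 5), rep(0, 5))
  expect_equal(nrow(segment_pulls(dip, threshold_pN = 25)), 1L)
  # ...but two sub-threshold frames do
  gap2 <- c(rep(0, 5), rep(80, 5), 10, 10, rep(80, 5), rep(0, 5))
  expect_equal(nrow(segment_pulls(gap2, threshold_pN = 25)), 2L)

  # events shorter than min_duration_frames are dropped
  blip <- c(rep(0, 10), 100, 100, rep(0, 10))
  expect_equal(nrow(segment_pulls(blip, threshold_pN = 25)), 0L)
  expect_error(segment_pulls(numeric(0)), "empty")
})

test_that("noise-only force series yield almost no false events", {
  false_events <- vapply(seq_len(100), function(s) {
    withr::with_seed(6000 + s, {
      f <- abs(stats::rnorm(1e4, 0, 5))
    })
    nrow(segment_pulls(f, threshold_pN = 25))
  }, numeric(1))
  expect_lte(mean(false_events), 0.1)
})

test_that("force summaries pool peaks into 25 pN bins", {
  mk_events <- function(peaks) {
    structure(data.frame(start_frame = seq_along(peaks),
                         end_frame = seq_along(peaks) + 3L,
                         peak_force_pN = peaks, mean_force_pN = peaks * 0.8,
                         duration_s = rep(0.4, length(peaks))),
              class = c("pull_events", "data.frame"))
  }
  s <- summarize_forces(mk_events(c(50, 100)))
  expect_equal(s$n, 2L)
  expect_equal(s$mean, 75)
  s240 <- summarize_forces(mk_events(240))
  hit <- s240$histogram[s240$histogram$count > 0, ]
  expect_equal(hit$bin_left, 225)
  expect_equal(hit$bin_right, 250)
  # mean statistic switch
  expect_equal(summarize_forces(mk_events(c(50, 100)), statistic = "mean")$mean, 60)
  expect_error(summarize_forces(mk_events(numeric(0))), "no pull events")
  # exponential-sample recovery within 3 SE
  withr::with_seed(77, { peaks <- 30 + stats::rexp(200, 1 / 40) })
  s_exp <- summarize_forces(mk_events(peaks))
  expect_lt(abs(s_exp$mean - 70), 3 * s_exp$se)
})

test_that("doubling scripted forces doubles recovered peaks (end-to-end)", {
  mk <- function(scale) {
    ev <- list(scripted_pull(c(1, 1), 1, 4, 80 * scale, direction_deg = 20),
               scripted_pull(c(2, 2), 5, 8, 120 * scale, direction_deg = 200))
    cfg <- pillar_config(grid_shape = c(2L, 2L), pitch_um = 4, events = ev,
                         duration_s = 10, seed = 9)
    sim <- simulate_pillar_movie(cfg, geom_small(256))
    res <- run_force_pipeline(sim$movie, expected_pitch_um = 4,
                              grid_shape = c(2, 2))
    res$events[order(res$events$start_frame), "peak_force_pN"]
  }
  p1 <- mk(1)
  p2 <- mk(2)
  expect_equal(length(p1), 2L)
  expect_equal(length(p2), 2L)
  expect_equal(p2 / p1, c(2, 2), tolerance = 0.02)
})

test_that("the spring constant propagates linearly with no hidden state", {
  ev <- list(scripted_pull(c(1, 2), 1, 4, 100))
  cfg <- pillar_config(grid_shape = c(2L, 2L), pitch_um = 4, events = ev,
                       duration_s = 6, seed = 12)
  sim <- simulate_pillar_movie(cfg, geom_small(256))
  r1 <- run_force_pipeline(sim$movie, k_pN_per_um = 240, expected_pitch_um = 4,
                           threshold_pN = 25)
  r2 <- run_force_pipeline(sim$movie, k_pN_per_um = 480, expected_pitch_um = 4,
                           threshold_pN = 50)
  f1 <- do.call(rbind, r1$deflections)$force_pN
  f2 <- do.call(rbind, r2$deflections)$force_pN
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  expect_equal(r2$events$peak_force_pN, 2 * r1$events$peak_force_pN,
               tolerance = 1e-12)
})

test_that("zero-event movies produce zero events at default threshold", {
  n_ev <- vapply(1:10, function(s) {
    cfg <- pillar_config(grid_shape = c(2L, 2L), pitch_um = 4,
                         duration_s = 10, seed = 7000 + s)
    sim <- simulate_pillar_movie(cfg, geom_small(192))
    nrow(run_force_pipeline(sim$movie, expected_pitch_um = 4)$events)
  }, numeric(1))
  expect_gte(mean(n_ev == 0), 0.95)
})

test_that("a noise-free scripted event is recovered within the tracking bound", {
  ev <- list(scripted_pull(c(1, 1), 1, 5, 150, direction_deg = 225))
  cfg <- pillar_config(grid_shape = c(2L, 2L), pitch_um = 4, events = ev,
                       noise = noise_off(), duration_s = 8, seed = 3)
  sim <- simulate_pillar_movie(cfg, geom_small(256))
  res <- run_force_pipeline(sim$movie, expected_pitch_um = 4)
  expect_equal(nrow(res$events), 1L)
  # k * (0.1 px * pixel size) = 240 * 0.01 um = 2.4 pN error budget
  expect_lt(abs(res$events$peak_force_pN - 150), 2.4)
})
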