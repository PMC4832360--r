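test_that("static chains give identical frames and zero ground-truth motion", {
  cfg <- chain_config("static", duration_s = 2, seed = 5)
  sim <- simulate_chain_movie(cfg, geom_small())
  nt <- n_frames(sim$movie)
  expect_equal(nt, 21L)
  # without read noise all frames are bit-identical
  cfg0 <- chain_config("static", duration_s = 2, noise = noise_off(), seed = 5)
  sim0 <- simulate_chain_movie(cfg0, geom_small())
  for (i in 2:n_frames(sim0$movie))
    expect_identical(get_frame(sim0$movie, i), get_frame(sim0$movie, 1))
  expect_equal(diff(sim$truth$poses$x_nm), rep(0, nt - 1))
  expect_equal(diff(sim$truth$poses$y_nm), rep(0, nt - 1))
})

test_that("constant-speed train path integrates to speed times duration", {
  cfg <- chain_config("train", speed_nm_s = 694, speed_sd_nm_s = 0,
                      kink_rate_hz = 0, duration_s = 30, seed = 2)
  tr <- simulate_chain_path(cfg, movie_geometry(c(512L, 512L)))
  p <- tr$poses
  steps <- cbind(diff(p$x_nm), diff(p$y_nm))
  lens <- sqrt(rowSums(steps^2))
  expect_equal(sum(lens), 694 * 30, tolerance = 1e-10)
  expect_equal(lens, rep(69.4, 300), tolerance = 1e-10)
  # every displacement parallel to the logged axis
  ang <- atan2(steps[, 2], steps[, 1]) * 180 / pi
  rel <- abs((ang - p$angle_deg[-nrow(p)] + 90) %% 180 - 90)
  expect_lt(max(rel), 1e-9)
})

test_that("crabwise steps are perpendicular to the axis and flip only at logged reversals", {
  cfg <- chain_config("crabwise", speed_nm_s = 457, speed_sd_nm_s = 0,
                      reversal_rate_hz = 0.2, duration_s = 30, seed = 9)
  tr <- simulate_chain_path(cfg, movie_geometry(c(384L, 384L)))
  p <- tr$poses
  steps <- cbind(diff(p$x_nm), diff(p$y_nm))
  ang <- atan2(steps[, 2], steps[, 1]) * 180 / pi
  rel <- abs((ang - p$angle_deg[-nrow(p)] + 90) %% 180 - 90)
  expect_lt(max(abs(rel - 90)), 1e-9)
  # sign changes happen exactly at logged reversal times
  axis <- p$angle_deg[1]
  u_perp <- c(cospi((axis + 90) / 180), sinpi((axis + 90) / 180))
  proj <- steps %*% u_perp
  flips <- which(diff(sign(proj)) != 0)      # step index before each flip
  logged <- tr$changes$t_s[tr$changes$type == "reversal"]
  f <- 10
  expect_equal(length(flips), length(logged))
  # flip between steps i and i+1 means a reversal in ((i-1)/f, i/f]
  expect_true(all(logged > (flips - 1) / f & logged <= flips / f))
})

test_that("brownian steps have the diffusive mean and variance", {
  d_um2 <- 0.05
  nseeds <- 120
  all_steps <- do.call(rbind, lapply(seq_len(nseeds), function(s) {
    cfg <- chain_config("brownian", diffusion_um2_s = d_um2, duration_s = 5,
                        seed = 1000 + s)
    p <- simulate_chain_path(cfg, geom_small(256))$poses
    cbind(diff(p$x_nm), diff(p$y_nm))
  }))
  dt <- 0.1
  expected_var <- 2 * d_um2 * 1e6 * dt        # nm^2 per coordinate
  n <- nrow(all_steps)
  se_mean <- sqrt(expected_var / n)
  expect_lt(abs(mean(all_steps[, 1])), 3 * se_mean)
  expect_lt(abs(mean(all_steps[, 2])), 3 * se_mean)
  se_var <- expected_var * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(all_steps[, 1]) - expected_var), 3 * se_var)
  expect_lt(abs(stats::var(all_steps[, 2]) - expected_var), 3 * se_var)
})

test_that("empirical MSD slope of brownian paths recovers 4*D", {
  d_um2 <- 0.05
  msd1 <- vapply(seq_len(200), function(s) {
    cfg <- chain_config("brownian", diffusion_um2_s = d_um2, duration_s = 30,
                        seed = 2000 + s)
    tr <- truth_trajectory(simulate_chain_path(cfg, geom_small(256)))
    m <- msd(tr, max_lag_frames = 5)
    stats::coef(stats::lm(msd_nm2 ~ lag_s - 1, data = m))[1]
  }, numeric(1))
  slope <- mean(msd1)                          # nm^2 / s
  expect_equal(slope, 4 * d_um2 * 1e6, tolerance = 0.1)
})

test_that("simulation is bit-reproducible from (config, seed)", {
  cfg <- chain_config("train", duration_s = 2, seed = 77)
  a <- simulate_chain_movie(cfg, geom_small())
  b <- simulate_chain_movie(cfg, geom_small())
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$poses, b$truth$poses)
  cfg2 <- chain_config("train", duration_s = 2, seed = 78)
  c2 <- simulate_chain_movie(cfg2, geom_small())
  expect_false(identical(a$movie$frames, c2$movie$frames))

  pcfg <- pillar_config(grid_shape = c(2L, 2L), duration_s = 2, seed = 3,
                        events = list(scripted_pull(c(1, 1), 0.5, 1.5, 100)))
  pa <- simulate_pillar_movie(pcfg, geom_small())
  pb <- simulate_pillar_movie(pcfg, geom_small())
  expect_identical(pa$movie$frames, pb$movie$frames)
  expect_identical(pa$truth$deflections, pb$truth$deflections)
})

test_that("pillar movies obey the linear spring exactly", {
  # no events: every tip stays at its grid node
  cfg0 <- pillar_config(grid_shape = c(3L, 3L), duration_s = 2,
                        noise = noise_off(), seed = 1)
  sim0 <- simulate_pillar_movie(cfg0, geom_small())
  expect_true(all(sim0$truth$deflections$dx_nm == 0))
  expect_true(all(sim0$truth$deflections$force_pN == 0))
  for (i in 2:n_frames(sim0$movie))
    expect_identical(get_frame(sim0$movie, i), get_frame(sim0$movie, 1))

  # 240 pN at k = 240 pN/um deflects exactly 1.000 um at the hold
  mk <- function(peak) pillar_config(
    grid_shape = c(2L, 2L), pitch_um = 6, k_pN_per_um = 240,
    events = list(scripted_pull(c(1, 1), 1, 3, peak)),
    noise = noise_off(), duration_s = 4, seed = 1)
  s240 <- simulate_pillar_movie(mk(240), geom_small(256))
  d <- s240$truth$deflections
  d11 <- d[d$pillar_row == 1 & d$pillar_col == 1, ]
  expect_equal(max(sqrt(d11$dx_nm^2 + d11$dy_nm^2)), 1000, tolerance = 1e-12)
  expect_equal(max(d11$force_pN), 240, tolerance = 1e-12)

  # 700 pN -> 2.9167 um, linearity forces the value
  s700 <- simulate_pillar_movie(mk(700), geom_small(256))
  d7 <- s700$truth$deflections
  d7 <- d7[d7$pillar_row == 1 & d7$pillar_col == 1, ]
  expect_equal(max(sqrt(d7$dx_nm^2 + d7$dy_nm^2)), 700 / 240 * 1000,
               tolerance = 1e-9)
})

test_that("overlapping events on one pillar sum their forces", {
  ev <- list(scripted_pull(c(1, 1), 0.5, 2.5, 100, direction_deg = 0),
             scripted_pull(c(1, 1), 0.5, 2.5, 50, direction_deg = 0))
  cfg <- pillar_config(grid_shape = c(1L, 2L), pitch_um = 6, events = ev,
                       noise = noise_off(), duration_s = 3, seed = 1)
  sim <- simulate_pillar_movie(cfg, geom_small(256))
  d <- sim$truth$deflections
  d11 <- d[d$pillar_row == 1 & d$pillar_col == 1, ]
  expect_equal(max(d11$force_pN), 150, tolerance = 1e-9)
})

test_that("rendered spot centroids match ground truth to 0.05 px", {
  cfg <- pillar_config(grid_shape = c(2L, 2L), pitch_um = 4,
                       events = list(scripted_pull(c(2, 2), 0.3, 1.7, 150,
                                                   direction_deg = 30)),
                       noise = noise_off(), duration_s = 2, seed = 1)
  sim <- simulate_pillar_movie(cfg, geom_small(256))
  px <- sim$movie$pixel_size_nm
  # brute-force intensity moments around each true tip position
  for (fr in c(1L, 8L, 11L)) {
    img <- get_frame(sim$movie, fr)
    p <- sim$truth$poses[sim$truth$poses$frame == fr, ]
    for (i in seq_len(nrow(p))) {
      r0 <- round(p$y_nm[i] / px + 1); c0 <- round(p$x_nm[i] / px + 1)
      rows <- (r0 - 10):(r0 + 10); cols <- (c0 - 10):(c0 + 10)
      w <- img[rows, cols] - 100
      w[w < 0] <- 0
      cr <- sum(rows * rowSums(w)) / sum(w)
      cc <- sum(cols * colSums(w)) / sum(w)
      expect_lt(abs(cr - (p$y_nm[i] / px + 1)), 0.05)
      expect_lt(abs(cc - (p$x_nm[i] / px + 1)), 0.05)
    }
  }
})

test_that("configs reject invalid inputs with the offending field named", {
  expect_error(chain_config("train", n_cells = 0, seed = 1), "n_cells")
  expect_error(chain_config("train", duration_s = 0, seed = 1), "duration_s")
  expect_error(chain_config("train", duration_s = 30), "seed")
  expect_error(chain_config("train", speed_nm_s = -5, seed = 1), "speed_nm_s")
  expect_error(simulate_chain_movie(
    chain_config("static", duration_s = 0.05, seed = 1), geom_small()),
    "2 frames")
  expect_error(pillar_config(grid_shape = c(2, 2), duration_s = 5, seed = 1,
                             events = list(scripted_pull(c(3, 1), 0, 1, 10))),
               "pillar index")
  expect_error(pillar_config(grid_shape = c(2, 2), duration_s = 5, seed = 1,
                             events = list(scripted_pull(c(1, 1), 0, 9, 10))),
               "outside movie duration")
  expect_error(scripted_pull(c(1, 1), 2, 1, 10), "t_start")
  expect_error(pillar_config(grid_shape = c(2, 2), pitch_um = 0.5,
                             duration_s = 5, seed = 1), "overlap")
})

test_that("ground truth round-trips losslessly through CSV + JSON", {
  tmp <- withr::local_tempdir()
  # chain truth with 301 pose records
  cfg <- chain_config("train", duration_s = 30, seed = 4)
  tr <- simulate_chain_path(cfg, movie_geometry(c(512L, 512L)))
  prefix <- file.path(tmp, "chain")
  write_ground_truth(tr, prefix)
  back <- read_ground_truth(prefix)
  expect_equal(nrow(back$poses), 301L)
  expect_identical(back$poses$x_nm, tr$poses$x_nm)
  expect_identical(back$poses$angle_deg, tr$poses$angle_deg)

  # pillar truth: 3 scripted events survive bit-exactly
  ev <- random_pull_events(c(2, 2), 20, 3, seed = 8)
  pcfg <- pillar_config(grid_shape = c(2L, 2L), events = ev, duration_s = 20,
                        seed = 8)
  sim <- simulate_pillar_movie(pcfg, geom_small(256))
  prefix2 <- file.path(tmp, "pillars")
  write_ground_truth(sim$truth, prefix2)
  back2 <- read_ground_truth(prefix2)
  expect_equal(nrow(back2$events), 3L)
  expect_identical(back2$events$peak_force_pN, sim$truth$events$peak_force_pN)
  expect_identical(back2$deflections$dx_nm, sim$truth$deflections$dx_nm)

  # empty truth: zero records, still a valid file pair
  cfg0 <- chain_config("static", duration_s = 0.2, seed = 1)
  tr0 <- simulate_chain_path(cfg0, geom_small())
  prefix3 <- file.path(tmp, "static")
  write_ground_truth(tr0, prefix3)
  expect_equal(nrow(read_ground_truth(prefix3)$events), 0L)
})

test_that("random pull events respect the schedule, floor and exact mean", {
  ev <- random_pull_events(c(8, 8), 50, 96, mean_peak_pN = 69.9,
                           min_peak_pN = 30, seed = 11)
  peaks <- vapply(ev, function(e) e$peak_force_pN, numeric(1))
  expect_equal(mean(peaks), 69.9, tolerance = 1e-12)
  expect_true(all(peaks >= 30))
  expect_equal(length(ev), 96L)
  # no two events overlap on the same pillar
  by_pillar <- split(ev, vapply(ev, function(e) paste(e$pillar, collapse = "_"),
                                character(1)))
  for (g in by_pillar) {
    if (length(g) < 2) next
    t0 <- sort(vapply(g, function(e) e$t_start_s, numeric(1)))
    t1 <- sort(vapply(g, function(e) e$t_end_s, numeric(1)))
    expect_true(all(t0[-1] >= t1[-length(t1)]))
  }
  expect_error(random_pull_events(c(2, 2), 10, 500, seed = 1), "schedule")
})
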