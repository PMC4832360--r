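# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; nothing is read from disk.

geom_small <- function(side = 160L, ...) movie_geometry(c(side, side), ...)

noise_off <- function(...) noise_config(gaussian_sd = 0, ...)

# Brute-force normalized cross-correlation: the O(n^4) reference the fast
# FFT/integral-image implementation is checked against.
brute_ncc <- function(template, search) {
  m <- nrow(template); M <- nrow(search); K <- M - m + 1L
  tz <- template - mean(template)
  out <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    w <- search[k:(k + m - 1L), l:(l + m - 1L)]
    wz <- w - mean(w)
    den <- sqrt(sum(tz^2) * sum(wz^2))
    out[k, l] <- if (den < 1e-12) 0 else sum(tz * wz) / den
  }
  out
}

# Frequency-domain sub-pixel shift of a periodic image (band-limited
# interpolation): the oracle for fractional-shift tracking.
fft_shift_image <- function(img, d_row, d_col) {
  nr <- nrow(img); nc <- ncol(img)
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] / nc
  ph <- exp(-2i * pi * (outer(fr * d_row, rep(1, nc)) +
                          outer(rep(1, nr), fc * d_col)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

# Smooth random texture with strong low-frequency content, suitable for
# sub-pixel registration tests.
smooth_texture <- function(n, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(stats::rnorm(n * n), n, n)
    k <- stats::dnorm(seq(-6, 6, length.out = 13))
    k <- outer(k, k)
    # simple FFT blur
    kp <- matrix(0, n, n)
    kp[1:13, 1:13] <- k / sum(k)
    Re(stats::fft(stats::fft(img) * stats::fft(kp), inverse = TRUE)) / (n * n)
  })
}

# movie_stack from a list of plain matrices (scaled to a 16-bit-ish range)
movie_from_matrices <- function(mats, pixel_size_nm = 100, frame_rate_hz = 10) {
  mats <- lapply(mats, function(m) {
    m <- m - min(m)
    if (max(m) > 0) m <- m / max(m)
    round(100 + 400 * m)
  })
  frames <- array(0L, dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  for (i in seq_along(mats)) frames[, , i] <- mats[[i]]
  movie_stack(frames, pixel_size_nm, frame_rate_hz)
}

# trajectory built straight from step vectors
traj_from_steps <- function(dx, dy, frame_rate_hz = 10, start = c(0, 0)) {
  trajectory(frame = seq_len(length(dx) + 1L),
             x_nm = start[1] + c(0, cumsum(dx)),
             y_nm = start[2] + c(0, cumsum(dy)),
             frame_rate_hz = frame_rate_hz)
}
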