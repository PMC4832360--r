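# Frame rendering: objects are isotropic Gaussian blobs on a dark
# background (phase-contrast polarity inverted), which preserves sub-pixel
# centroid information while staying cheap. Blobs are evaluated only on a
# +/- 5 sigma local window.

# centers_px: n x 2 matrix of (row, col), possibly fractional
render_frame <- function(shape, centers_px, sigma_px, amplitude,
                         background, noise_sd) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(background, nr, nc)
  w <- max(2L, ceiling(5 * sigma_px))
  if (!is.null(centers_px) && nrow(centers_px) > 0) {
    for (b in seq_len(nrow(centers_px))) {
      cr <- centers_px[b, 1]; cc <- centers_px[b, 2]
      r0 <- max(1L, floor(cr) - w); r1 <- min(nr, ceiling(cr) + w)
      c0 <- max(1L, floor(cc) - w); c1 <- min(nc, ceiling(cc) + w)
      if (r0 > r1 || c0 > c1) next
      gr <- exp(-((r0:r1 - cr)^2) / (2 * sigma_px^2))
      gc <- exp(-((c0:c1 - cc)^2) / (2 * sigma_px^2))
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude * outer(gr, gc)
    }
  }
  if (noise_sd > 0)
    img <- img + stats::rnorm(nr * nc, 0, noise_sd)
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  storage.mode(img) <- "integer"
  img
}

# nm <-> px conversions (1-based pixel centres; x ~ col, y ~ row)
nm_to_px <- function(xy_nm, pixel_size_nm) {
  cbind(row = xy_nm[, 2] / pixel_size_nm + 1, col = xy_nm[, 1] / pixel_size_nm + 1)
}
px_to_nm <- function(rc_px, pixel_size_nm) {
  cbind(x_nm = (rc_px[, 2] - 1) * pixel_size_nm, y_nm = (rc_px[, 1] - 1) * pixel_size_nm)
}
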