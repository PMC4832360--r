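# Normalized cross-correlation of a template against a search window.
#
# Zero-mean, unit-variance within each window ("CCOEFF_NORMED"), which
# makes registration invariant to background offset and illumination
# drift. The numerator is a valid linear cross-correlation computed via
# 2-D FFT (the zero-padded template makes circular correlation equal to
# linear correlation on the valid placements); window sums for the
# denominator come from integral images.

# template: m x m, search: M x M with M >= m; returns (M-m+1)^2 matrix of
# correlation values in [-1, 1], entry [k, l] for template anchored at
# search[k..k+m-1, l..l+m-1].
ncc_map <- function(template, search) {
  m <- nrow(template); M <- nrow(search)
  stopifnot(ncol(template) == m, ncol(search) == M, M >= m)
  K <- M - m + 1L
  tz <- template - mean(template)
  den_t <- sqrt(sum(tz^2))
  if (den_t < 1e-12) return(matrix(0, K, K))

  tpad <- matrix(0, M, M)
  tpad[1:m, 1:m] <- tz
  cc <- Re(stats::fft(stats::fft(search) * Conj(stats::fft(tpad)),
                      inverse = TRUE)) / (M * M)
  num <- cc[1:K, 1:K, drop = FALSE]

  # integral images for window sums of S and S^2
  p1 <- apply(apply(search, 2, cumsum), 1, cumsum)   # transposed cumsums
  p1 <- rbind(0, cbind(0, t(p1)))
  p2 <- apply(apply(search^2, 2, cumsum), 1, cumsum)
  p2 <- rbind(0, cbind(0, t(p2)))
  ks <- 1:K
  s1 <- p1[ks + m, ks + m, drop = FALSE] - p1[ks, ks + m, drop = FALSE] -
    p1[ks + m, ks, drop = FALSE] + p1[ks, ks, drop = FALSE]
  s2 <- p2[ks + m, ks + m, drop = FALSE] - p2[ks, ks + m, drop = FALSE] -
    p2[ks + m, ks, drop = FALSE] + p2[ks, ks, drop = FALSE]
  var_s <- pmax(s2 - s1^2 / (m * m), 0)
  den <- den_t * sqrt(var_s)
  out <- ifelse(den < 1e-9, 0, num / den)
  out[out > 1] <- 1
  out[out < -1] <- -1
  out
}

# Integer peak of a correlation map with ties broken toward the smallest
# displacement magnitude relative to the map centre (odd-sized maps).
ncc_peak <- function(cc) {
  K <- nrow(cc)
  ctr <- (K + 1L) / 2
  mx <- max(cc)
  idx <- which(cc >= mx - 1e-12, arr.ind = TRUE)
  if (nrow(idx) > 1L) {
    d2 <- (idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2
    idx <- idx[which.min(d2), , drop = FALSE]
  }
  c(row = idx[1, 1], col = idx[1, 2], value = mx)
}

# Sub-pixel refinement: separable 1-D quadratic fits through the peak and
# its 4-neighbours. Returns fractional (d_row, d_col) in [-0.5, 0.5];
# zero along an axis where the peak sits on the map border.
ncc_subpixel <- function(cc, pr, pc) {
  quad <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= -1e-15) return(0)
    d <- 0.5 * (cm - cp) / den
    max(-0.5, min(0.5, d))
  }
  K <- nrow(cc)
  dr <- if (pr > 1L && pr < K) quad(cc[pr - 1L, pc], cc[pr, pc], cc[pr + 1L, pc]) else 0
  dc <- if (pc > 1L && pc < K) quad(cc[pr, pc - 1L], cc[pr, pc], cc[pr, pc + 1L]) else 0
  c(dr, dc)
}
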