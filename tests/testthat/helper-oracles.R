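# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force two-tailed p of the Wilcoxon signed-rank test by full
# enumeration of all 2^n sign assignments (no-ties case).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  min(1, 2 * min(mean(Vs <= v), mean(Vs >= v)))
}

# Value at in-plane point (p, 0) of a thin ring (radius R, centre (cx, 0),
# unit line density) convolved with an isotropic 2-D Gaussian of sd sigma,
# by dense numerical integration over the ring.
ring_conv_point <- function(p, cx, R, sigma, n_theta = 4000L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-1L]
  dx <- p - (cx + R * cos(th))
  dy <- -R * sin(th)
  g <- exp(-(dx^2 + dy^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  sum(g) * R * (2 * pi / n_theta)
}

ring_conv_profile <- function(pos, cx, R, sigma, amp = 1) {
  amp * vapply(pos, ring_conv_point, numeric(1), cx = cx, R = R, sigma = sigma)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Dense-grid brute force: peak position, half-maximum crossings (relative to
# background level bg) and the trough between two peaks of a 1-D curve.
dense_peak <- function(f, lo, hi, step = 5e-4) {
  x <- seq(lo, hi, by = step)
  y <- f(x)
  i <- which.max(y)
  list(position = x[i], height = y[i], x = x, y = y)
}

dense_half_max_crossings <- function(x, y, i_peak, level) {
  below_l <- which(y[seq_len(i_peak)] <= level)
  below_r <- which(y[i_peak:length(y)] <= level) + i_peak - 1L
  c(inner = x[max(below_l)], outer = x[min(below_r)])
}
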