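# Shared fixtures, built in code.

# A filled disc of radius r (pixel centres within r + 0.5 of the centre).
raster_disk <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  cx <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cx)^2 <= (r + 0.5)^2)
}

# A filled axis-aligned ellipse raster with semi-axes a (x) and b (y).
raster_ellipse <- function(a, b, pad = 4) {
  n <- 2 * ceiling(max(a, b)) + 2 * pad + 1
  cx <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) ((j - cx) / a)^2 + ((i - cx) / b)^2 <= 1)
}

# One cell state row for render_frame().
cell_state <- function(x, y, a, b, theta, intensity = 0.9, id = 1L) {
  data.frame(cell_id = id, x_um = x, y_um = y, orientation_deg = theta,
             area_mult = 1, aspect_mult = 1, intensity = intensity,
             semi_major_um = a, semi_minor_um = b)
}

no_noise <- list(background_level = 0, photon_noise_scale = 0, psf_sigma_px = 0)
mild_noise <- list(background_level = 0.05, photon_noise_scale = 0.02,
                   psf_sigma_px = 1)

# Numeric arc length of an ellipse by fine polygonal integration (oracle).
ellipse_arclength_oracle <- function(a, b, n = 2e5) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  sum(sqrt(diff(a * cos(th))^2 + diff(b * sin(th))^2))
}

# Axial von Mises mean resultant length by rejection sampling (oracle).
axial_mrl_oracle <- function(kappa, n = 1e6, seed = 424242) {
  set.seed(seed)
  acc <- numeric(0)
  while (length(acc) < n) {
    cand <- stats::runif(3 * n, 0, 2 * pi)
    keep <- stats::runif(3 * n) < exp(kappa * (cos(cand) - 1))
    acc <- c(acc, cand[keep])
  }
  phi <- acc[seq_len(n)]  # doubled angles around 0
  sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
}
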