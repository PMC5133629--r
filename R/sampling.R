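#' Draw von Mises variates (Best-Fisher rejection sampler)
#'
#' Used on doubled angles to sample axial orientations. For `kappa = 0` the
#' distribution is uniform on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, `>= 0`.
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.6))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      take <- min(n - got, length(th))
      out[(got + 1L):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  (out + mu) %% (2 * pi)
}

#' Sample axial orientations (period 180 degrees)
#'
#' Orientations of elongated cells are axial data: an orientation and its
#' 180-degree rotation are the same physical state. The standard generative
#' model is a von Mises distribution on doubled angles: draw
#' `phi ~ VM(2*mu, kappa)` and return `phi / 2`, giving a distribution on
#' `[0, 180)` with the correct period.
#'
#' @param n number of orientations.
#' @param mu_deg axial mean orientation, degrees in `[0, 180)`.
#' @param kappa concentration (`0` = uniform).
#' @return numeric vector of orientations in degrees, `[0, 180)`.
#' @export
sample_orientations <- function(n, mu_deg, kappa) {
  phi <- rvonmises(n, mu = 2 * mu_deg * pi / 180, kappa = kappa)
  (phi * 180 / (2 * pi)) %% 180
}

#' Axial mean resultant length
#'
#' Concentration statistic for axial data: the modulus of the mean of
#' `exp(2i * theta)`. 1 for perfectly aligned orientations, ~0 for uniform.
#'
#' @param theta_deg orientations in degrees.
#' @return scalar in `[0, 1]`.
#' @export
axial_resultant_length <- function(theta_deg) {
  th <- theta_deg * pi / 90  # doubled angle in radians
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Spreading kinetics of an attaching cell
#'
#' After seeding, a round unattached cell spreads: its projected area rises
#' from the round-cell value `pi * initial_radius^2` towards the condition's
#' plateau, and its aspect ratio rises from 1 towards the plateau ratio. Both
#' follow a saturating exponential approach with the condition's spreading
#' time constant (the data only constrain the qualitative rise-then-plateau
#' shape; the exponential is the simplest monotone saturating form).
#'
#' @param t_h time since seeding, hours (scalar or vector, `>= 0`).
#' @param params a [condition_params()] object.
#' @return list with numeric vectors `target_area_um2` and
#'   `target_aspect_ratio`, one element per time.
#' @examples
#' p <- condition_params("flat", area_plateau_um2 = 2000)
#' spreading_trajectory(0, p)$target_area_um2  # pi * 10^2
#' @export
spreading_trajectory <- function(t_h, params) {
  if (any(t_h < 0)) stop("time must be non-negative")
  a0 <- pi * params$initial_radius_um^2
  g <- 1 - exp(-t_h / params$area_timescale_h)
  list(target_area_um2 = a0 + (params$area_plateau_um2 - a0) * g,
       target_aspect_ratio = 1 + (params$aspect_ratio_plateau - 1) * g)
}

#' Sample an initial cell population for one field of view
#'
#' Places `n_cells_per_fov` cells in a field of view with rejection sampling
#' on centroid spacing (labelled cells are diluted among unlabelled ones, so
#' fields are sparse and overlaps are avoided by design). Each cell gets an
#' axial orientation drawn from the condition's von Mises model, and
#' per-cell lognormal multipliers for plateau area and aspect ratio that
#' persist over the whole time course (population heterogeneity).
#'
#' The returned states carry the *initial* (round) geometry; use
#' [grow_population()] to advance them along the spreading trajectory.
#'
#' @param params a [condition_params()] object.
#' @param fov_um field-of-view side lengths `c(width_um, height_um)`.
#' @param rng_seed optional integer seed (set for reproducibility; omit to
#'   use the current RNG stream).
#' @param min_spacing_um minimum centroid-to-centroid distance; default keeps
#'   fully spread cells from overlapping (twice the plateau semi-major axis).
#' @param max_tries placement retry budget per cell.
#' @return data.frame of cell states: `cell_id`, `x_um`, `y_um`,
#'   `orientation_deg`, `area_mult`, `aspect_mult`, `intensity`,
#'   `semi_major_um`, `semi_minor_um`.
#' @export
sample_population <- function(params, fov_um = c(512, 512), rng_seed = NULL,
                              min_spacing_um = NULL, max_tries = 400) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- params$n_cells_per_fov
  a_max <- sqrt(params$area_plateau_um2 * params$aspect_ratio_plateau / pi)
  if (is.null(min_spacing_um)) min_spacing_um <- 2 * a_max
  margin <- min(a_max, min(fov_um) / 4)
  xs <- ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, margin, fov_um[1] - margin)
      y <- stats::runif(1, margin, fov_um[2] - margin)
      if (length(xs) == 0L || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_spacing_um) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place cell %d of %d after %d tries; lower the density or the spacing",
                   i, n, max_tries))
  }
  theta <- sample_orientations(n, params$mean_orientation_deg,
                               params$orientation_concentration)
  area_mult <- stats::rlnorm(n, -params$area_cv^2 / 2, params$area_cv)
  aspect_mult <- stats::rlnorm(n, -params$aspect_cv^2 / 2, params$aspect_cv)
  intensity <- stats::runif(n, 0.7, 1.0)
  st <- data.frame(cell_id = seq_len(n), x_um = xs, y_um = ys,
                   orientation_deg = theta,
                   area_mult = area_mult, aspect_mult = aspect_mult,
                   intensity = intensity)
  grow_population(st, 0, params)
}

#' Advance a cell population to a given time
#'
#' Applies the condition's spreading trajectory to every cell of a sampled
#' population, scaling each cell by its persistent heterogeneity multipliers.
#' Centroids and orientations are fixed over time (per-frame population
#' statistics, not cell tracking, are the downstream target).
#'
#' @param states data.frame from [sample_population()].
#' @param t_h time since seeding, hours.
#' @param params the matching [condition_params()].
#' @return `states` with `semi_major_um` and `semi_minor_um` updated.
#' @export
grow_population <- function(states, t_h, params) {
  tr <- spreading_trajectory(t_h, params)
  area <- tr$target_area_um2 * states$area_mult
  ar <- pmax(1, 1 + (tr$target_aspect_ratio - 1) * states$aspect_mult)
  b <- sqrt(area / (pi * ar))
  states$semi_major_um <- ar * b
  states$semi_minor_um <- b
  states
}
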