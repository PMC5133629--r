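#' Orientation spectrum constructor
#' @param angles_deg bin centres in `[0, 180)`.
#' @param magnitude non-negative per-bin power sums.
#' @param normalized does `magnitude` sum to 1?
#' @param condition,timestamp_h,n_fovs_combined metadata.
#' @return object of class `orientation_spectrum`.
#' @keywords internal
orientation_spectrum <- function(angles_deg, magnitude, normalized = FALSE,
                                 condition = NA_character_,
                                 timestamp_h = NA_real_,
                                 n_fovs_combined = 1L) {
  stopifnot(length(angles_deg) == length(magnitude), all(magnitude >= 0))
  structure(list(angles_deg = angles_deg, magnitude = magnitude,
                 normalized = normalized, condition = condition,
                 timestamp_h = timestamp_h,
                 n_fovs_combined = as.integer(n_fovs_combined)),
            class = "orientation_spectrum")
}

#' @export
print.orientation_spectrum <- function(x, ...) {
  cat(sprintf("orientation spectrum (%s @ %g h): %d bins, peak at %g deg%s\n",
              x$condition, x$timestamp_h, length(x$angles_deg),
              x$angles_deg[which.max(x$magnitude)],
              if (x$normalized) " [normalized]" else ""))
  invisible(x)
}

#' Summed 2D-FFT power per orientation bin
#'
#' Quantifies population alignment directly from an image: features of
#' similar intensity aligned at some angle concentrate 2D-FFT power along
#' the perpendicular spectral direction, so summing the power spectrum per
#' angular bin gives an orientation distribution that works even when
#' features overlap. Angles are axial — the spectrum has period 180 degrees,
#' so orientations in `[180, 360)` are folded by construction.
#'
#' Details: the image is mean-subtracted and tapered with a Hann window
#' (otherwise the frame edges put a spurious cross at 0/90 degrees), the
#' centred power spectrum `|FFT|^2` is computed, the DC bin is excluded, and
#' each frequency pixel within the radial band is assigned by `atan2` to the
#' bin of its *real-space* feature orientation (the spectral angle rotated by
#' 90 degrees), using the same counter-clockwise-from-+x convention as the
#' rest of the package.
#'
#' @param image a `frame_image` or numeric matrix.
#' @param n_bins number of angular bins over `[0, 180)`; bin centres at
#'   `k * 180 / n_bins`. Default 180 (1-degree bins).
#' @param radial_band spatial-frequency band `c(min, max)` in cycles/pixel to
#'   integrate; default from 4 spectral pixels up to half Nyquist (the data
#'   do not pin this down; the default excludes the lowest bins, which carry
#'   field-of-view-scale structure, and the highest, which carry pixel noise).
#' @return unnormalized `orientation_spectrum`.
#' @export
angular_power_sum <- function(image, n_bins = 180, radial_band = NULL) {
  pix <- if (inherits(image, "frame_image")) image$pixels else image
  if (!is.matrix(pix)) stop("`image` must be a matrix or frame_image")
  if (any(!is.finite(pix))) stop("image contains non-finite pixels")
  if (n_bins < 8) stop("need at least 8 angular bins")
  nr <- nrow(pix); nc <- ncol(pix)
  if (is.null(radial_band)) radial_band <- c(4 / min(nr, nc), 0.25)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w <- outer(hann(nr), hann(nc))
  pw <- Mod(stats::fft((pix - mean(pix)) * w))^2
  fr <- seq_len(nr) - 1L; fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- seq_len(nc) - 1L; fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  fy <- matrix(-fr / nr, nr, nc)   # -row so spectral angles are CCW from +x
  fx <- matrix(rep(fc / nc, each = nr), nr, nc)
  rad <- sqrt(fx^2 + fy^2)
  keep <- rad >= radial_band[1] & rad <= radial_band[2]
  keep[1, 1] <- FALSE  # DC
  spec_angle <- (atan2(fy[keep], fx[keep]) * 180 / pi) %% 180
  feat_angle <- (spec_angle + 90) %% 180   # real-space elongation angle
  width <- 180 / n_bins
  bin <- (round(feat_angle / width) %% n_bins) + 1L
  mag <- vapply(split(pw[keep], factor(bin, levels = seq_len(n_bins))),
                sum, numeric(1))
  mag[is.na(mag)] <- 0
  meta <- if (inherits(image, "frame_image"))
    list(condition = image$condition, timestamp_h = image$timestamp_h)
  else list(condition = NA_character_, timestamp_h = NA_real_)
  orientation_spectrum(angles_deg = (seq_len(n_bins) - 1L) * width,
                       magnitude = unname(mag),
                       condition = meta$condition,
                       timestamp_h = meta$timestamp_h)
}

#' Combine spectra across fields of view and normalize
#'
#' Bin-wise sum of the angular power of all fields of view at one
#' condition/timepoint, renormalized to unit total so conditions and
#' timepoints are comparable regardless of total fluorescence.
#'
#' @param spectra list of `orientation_spectrum` objects with identical
#'   binning (a single spectrum is allowed).
#' @return normalized `orientation_spectrum` with `n_fovs_combined` set.
#' @export
combine_and_normalize <- function(spectra) {
  if (inherits(spectra, "orientation_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  ang <- spectra[[1]]$angles_deg
  for (s in spectra)
    if (length(s$angles_deg) != length(ang) || any(s$angles_deg != ang))
      stop("spectra have mismatched angular binning")
  total <- Reduce(`+`, lapply(spectra, `[[`, "magnitude"))
  s1 <- spectra[[1]]
  orientation_spectrum(ang, total / sum(total), normalized = TRUE,
                       condition = s1$condition, timestamp_h = s1$timestamp_h,
                       n_fovs_combined = sum(vapply(spectra, `[[`, integer(1),
                                                    "n_fovs_combined")))
}

#' Time-angle alignment surface
#'
#' Stacks one combined spectrum per timestamp into a (time x angle) matrix —
#' the full-course alignment picture in which a persistent ridge at one
#' angle marks a globally aligned population. Each row is unit-normalized;
#' the per-row argmax (peak trace) is returned alongside.
#'
#' @param spectra list of combined `orientation_spectrum` objects (one per
#'   timestamp, identical binning).
#' @param schedule optional vector of expected timestamps (hours); rows for
#'   timestamps with no spectrum are filled with `NA` and flagged.
#' @return list of class `time_angle_surface`: `surface` (matrix, rows =
#'   timestamps in order), `timestamps_h`, `angles_deg`, `peak_deg` (per-row
#'   argmax bin centre), `missing` (logical per row).
#' @export
build_time_angle_surface <- function(spectra, schedule = NULL) {
  stopifnot(length(spectra) >= 1)
  ts_have <- vapply(spectra, `[[`, numeric(1), "timestamp_h")
  ord <- order(ts_have)
  spectra <- spectra[ord]; ts_have <- ts_have[ord]
  if (anyDuplicated(ts_have)) stop("more than one spectrum per timestamp; combine first")
  ts <- if (is.null(schedule)) ts_have else as.numeric(schedule)
  ang <- spectra[[1]]$angles_deg
  surface <- matrix(NA_real_, length(ts), length(ang))
  peak <- rep(NA_real_, length(ts))
  missing <- rep(TRUE, length(ts))
  for (i in seq_along(ts)) {
    j <- which(abs(ts_have - ts[i]) < 1e-9)
    if (length(j) == 1L) {
      m <- spectra[[j]]$magnitude
      surface[i, ] <- m / sum(m)
      peak[i] <- ang[which.max(m)]
      missing[i] <- FALSE
    } else {
      warning(sprintf("no spectrum for timestamp %g h; row set to NA", ts[i]))
    }
  }
  structure(list(surface = surface, timestamps_h = ts, angles_deg = ang,
                 peak_deg = peak, missing = missing),
            class = "time_angle_surface")
}

#' Plot a time-angle alignment surface
#'
#' @param x a `time_angle_surface`.
#' @param ... passed to [graphics::image()].
#' @export
plot.time_angle_surface <- function(x, ...) {
  graphics::image(x$angles_deg, x$timestamps_h, t(x$surface),
                  xlab = "orientation (deg)", ylab = "time (h)",
                  useRaster = TRUE, ...)
  invisible(x)
}
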