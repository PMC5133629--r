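#' Frame geometry
#'
#' @param height_px,width_px frame size in pixels.
#' @param pixel_size_um microns per pixel (default 1, so pixel and micron
#'   units coincide).
#' @return list with `height_px`, `width_px`, `pixel_size_um`.
#' @export
frame_geometry <- function(height_px, width_px, pixel_size_um = 1) {
  stopifnot(height_px >= 1, width_px >= 1, pixel_size_um > 0)
  list(height_px = as.integer(height_px), width_px = as.integer(width_px),
       pixel_size_um = pixel_size_um)
}

# Pixel/angle conventions used throughout:
#   - matrices are indexed [row, col], 0-based pixel (0,0) at top-left;
#   - real-space x runs along columns, y along rows;
#   - orientations are axial, degrees in [0, 180), counter-clockwise from +x
#     when y is taken as pointing up (i.e. -row direction).
ellipse_inside <- function(xg, yg, x0, y0, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  dx <- xg - x0
  dy <- -(yg - y0)  # flip row direction so angles are CCW from +x
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  u * u + v * v <= 1
}

#' Render one synthetic fluorescent frame
#'
#' Draws each cell as a filled ellipse (uniform intensity) at its centroid
#' and orientation, convolves with a Gaussian point-spread function, then
#' adds a constant background and signal-dependent Gaussian (photon-like)
#' noise. A ground-truth label mask (same grid, 0 = background, labels in
#' cell order) is returned alongside the image.
#'
#' @param cells data.frame of cell states (see [sample_population()]),
#'   positions and semi-axes in microns.
#' @param geometry a [frame_geometry()].
#' @param noise list with `background_level`, `photon_noise_scale`,
#'   `psf_sigma_px`; any may be 0 for a clean render.
#' @param rng_seed optional integer seed for the noise draw.
#' @param timestamp_h,condition,fov_id metadata carried on the frame.
#' @return list of class `frame_image`: `pixels` (matrix in `[0, 1]`),
#'   `mask` (integer label matrix), `timestamp_h`, `condition`, `fov_id`,
#'   `pixel_size_um`, `clipped` (TRUE if any cell ran off the frame edge).
#' @export
render_frame <- function(cells, geometry,
                         noise = list(background_level = 0.05,
                                      photon_noise_scale = 0.02,
                                      psf_sigma_px = 1),
                         rng_seed = NULL, timestamp_h = NA_real_,
                         condition = NA_character_, fov_id = NA_character_) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nr <- geometry$height_px; nc <- geometry$width_px; ps <- geometry$pixel_size_um
  img <- matrix(0, nr, nc)
  mask <- matrix(0L, nr, nc)
  clipped <- FALSE
  n_cells <- if (is.null(cells)) 0L else nrow(cells)
  for (i in seq_len(n_cells)) {
    a <- cells$semi_major_um[i] / ps
    b <- cells$semi_minor_um[i] / ps
    # pixel centre of pixel (r, c) sits at ((c - 0.5) * ps, (r - 0.5) * ps)
    x0 <- cells$x_um[i] / ps + 0.5
    y0 <- cells$y_um[i] / ps + 0.5
    pad <- a + 2
    r_rng <- max(1L, floor(y0 - pad)):min(nr, ceiling(y0 + pad))
    c_rng <- max(1L, floor(x0 - pad)):min(nc, ceiling(x0 + pad))
    if (y0 - pad < 1 || y0 + pad > nr || x0 - pad < 1 || x0 + pad > nc)
      clipped <- TRUE
    xg <- matrix(rep(c_rng, each = length(r_rng)), nrow = length(r_rng))
    yg <- matrix(rep(r_rng, times = length(c_rng)), nrow = length(r_rng))
    inside <- ellipse_inside(xg, yg, x0, y0, a, b, cells$orientation_deg[i])
    sub_i <- img[r_rng, c_rng, drop = FALSE]
    sub_m <- mask[r_rng, c_rng, drop = FALSE]
    sub_i[inside] <- pmax(sub_i[inside], cells$intensity[i])
    sub_m[inside & sub_m == 0L] <- i
    img[r_rng, c_rng] <- sub_i
    mask[r_rng, c_rng] <- sub_m
  }
  sigma <- noise$psf_sigma_px %||% 0
  if (sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  bg <- noise$background_level %||% 0
  img <- img + bg
  sc <- noise$photon_noise_scale %||% 0
  if (sc > 0)
    img <- img + stats::rnorm(length(img), sd = sc) * sqrt(pmax(img, 0))
  img <- pmin(pmax(img, 0), 1)
  structure(list(pixels = img, mask = mask, timestamp_h = timestamp_h,
                 condition = condition, fov_id = fov_id, pixel_size_um = ps,
                 clipped = clipped),
            class = "frame_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf("frame %s/%s at %g h: %d x %d px @ %g um/px, %d truth object(s)\n",
              x$condition, x$fov_id, x$timestamp_h, nrow(x$pixels),
              ncol(x$pixels), x$pixel_size_um, max(x$mask)))
  invisible(x)
}
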