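#' Generative parameters of one experimental condition
#'
#' Bundles everything the synthetic generator needs to emulate one culture
#' condition: where cells point (an axial von Mises orientation distribution
#' with mean `mean_orientation_deg` and concentration `orientation_concentration`),
#' how they spread (saturating kinetics towards `area_plateau_um2` and
#' `aspect_ratio_plateau` with time constant `area_timescale_h`), how many
#' there are per field of view, and the imaging noise model.
#'
#' @param name condition label, e.g. `"flat"`, `"flat-osteo"`, `"random"`,
#'   `"aligned"`.
#' @param mean_orientation_deg axial mean orientation in `[0, 180)` degrees,
#'   measured counter-clockwise from the image +x (column) axis.
#' @param orientation_concentration concentration `kappa >= 0` of the axial
#'   von Mises distribution (on doubled angles); 0 gives uniform orientations.
#' @param area_plateau_um2 long-time mean spread cell area (square microns).
#' @param area_timescale_h spreading time constant (hours).
#' @param aspect_ratio_plateau long-time major/minor axis ratio, `>= 1`.
#' @param initial_radius_um radius of the initially round, unattached cell.
#' @param n_cells_per_fov number of labelled cells per field of view.
#' @param noise list with `background_level` (fraction of dynamic range),
#'   `photon_noise_scale` (signal-dependent noise amplitude) and
#'   `psf_sigma_px` (Gaussian PSF standard deviation in pixels).
#' @param area_cv,aspect_cv per-cell lognormal coefficient of variation of
#'   plateau area and aspect ratio (population heterogeneity).
#' @return object of class `condition_params`.
#' @export
condition_params <- function(name,
                             mean_orientation_deg = 90,
                             orientation_concentration = 0,
                             area_plateau_um2 = 2000,
                             area_timescale_h = 6,
                             aspect_ratio_plateau = 2,
                             initial_radius_um = 10,
                             n_cells_per_fov = 12,
                             noise = list(background_level = 0.05,
                                          photon_noise_scale = 0.02,
                                          psf_sigma_px = 1),
                             area_cv = 0.1,
                             aspect_cv = 0.05) {
  stopifnot(orientation_concentration >= 0,
            aspect_ratio_plateau >= 1,
            area_plateau_um2 > 0,
            area_timescale_h > 0,
            initial_radius_um > 0,
            n_cells_per_fov >= 1)
  mean_orientation_deg <- mean_orientation_deg %% 180
  structure(list(name = name,
                 mean_orientation_deg = mean_orientation_deg,
                 orientation_concentration = orientation_concentration,
                 area_plateau_um2 = area_plateau_um2,
                 area_timescale_h = area_timescale_h,
                 aspect_ratio_plateau = aspect_ratio_plateau,
                 initial_radius_um = initial_radius_um,
                 n_cells_per_fov = n_cells_per_fov,
                 noise = noise,
                 area_cv = area_cv,
                 aspect_cv = aspect_cv),
            class = "condition_params")
}

#' Default parameter sets for the four study conditions
#'
#' Emulates the morphological phenomenology of mesenchymal stem cells on the
#' four substrates: aligned nanotopography drives large, strongly elongated
#' cells oriented at ~90 degrees (the orientation of the underlying fibres);
#' random nanotopography supports the smallest, roundest cells with no global
#' orientation; flat glass is intermediate; flat glass under osteogenic medium
#' spreads isotropically to the largest area (and hence the largest minor
#' axis). Plateau areas and aspect ratios are generative stand-ins consistent
#' with these orderings; none are measured values.
#'
#' @param n_cells_per_fov labelled cells per field of view (cells expressing
#'   fluorescent markers are diluted with unlabelled cells to keep the field
#'   sparse, so this is deliberately small).
#' @return named list of [condition_params()] objects.
#' @export
default_conditions <- function(n_cells_per_fov = 12) {
  list(
    flat = condition_params("flat",
                            orientation_concentration = 0,
                            area_plateau_um2 = 2200,
                            aspect_ratio_plateau = 2.0,
                            n_cells_per_fov = n_cells_per_fov),
    `flat-osteo` = condition_params("flat-osteo",
                                    orientation_concentration = 0,
                                    area_plateau_um2 = 3800,
                                    aspect_ratio_plateau = 1.5,
                                    n_cells_per_fov = n_cells_per_fov),
    random = condition_params("random",
                              orientation_concentration = 0,
                              area_plateau_um2 = 1400,
                              aspect_ratio_plateau = 1.6,
                              n_cells_per_fov = n_cells_per_fov),
    aligned = condition_params("aligned",
                               mean_orientation_deg = 90,
                               orientation_concentration = 8,
                               area_plateau_um2 = 3200,
                               aspect_ratio_plateau = 4.0,
                               n_cells_per_fov = n_cells_per_fov)
  )
}

#' @export
print.condition_params <- function(x, ...) {
  cat(sprintf(
    "condition '%s': mu=%g deg, kappa=%g, area plateau %g um^2 (tau %g h), AR plateau %g, %d cells/FOV\n",
    x$name, x$mean_orientation_deg, x$orientation_concentration,
    x$area_plateau_um2, x$area_timescale_h, x$aspect_ratio_plateau,
    x$n_cells_per_fov))
  invisible(x)
}
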