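# Render one field of elongated cells with orientations drawn at (mu, kappa);
# kappa = 0 gives a uniform-orientation (isotropic) field.
render_oriented_field <- function(mu, kappa, seed, n_cells = 30, side = 512,
                                  aspect = 4, t_h = 1e6) {
  p <- condition_params("x", mean_orientation_deg = mu,
                        orientation_concentration = kappa,
                        area_plateau_um2 = pi * 400,
                        aspect_ratio_plateau = aspect, n_cells_per_fov = n_cells)
  # spacing below the worst-case non-overlap bound: touching cells are fine
  # for spectral purposes and allow denser fields
  pop <- grow_population(sample_population(p, fov_um = c(side, side),
                                           rng_seed = seed,
                                           min_spacing_um = 1.2 * sqrt(400 * aspect)),
                         t_h, p)
  render_frame(pop, frame_geometry(side, side, 1), noise = mild_noise,
               rng_seed = seed + 1000)
}

flatness <- function(spec) max(spec$magnitude) / stats::median(spec$magnitude)

test_that("gratings and aligned fields peak at their real-space orientation", {
  # horizontal stripes are features elongated along 0 degrees
  stripes <- matrix(rep(sin(2 * pi * (1:256) / 16)^2, times = 256), 256, 256)
  sp <- angular_power_sum(stripes)
  expect_equal(sp$angles_deg[which.max(sp$magnitude)], 0)
  # vertical stripes: elongated along 90 degrees
  sp_v <- angular_power_sum(t(stripes))
  expect_equal(sp_v$angles_deg[which.max(sp_v$magnitude)], 90)
  # field of cells all near 90 degrees peaks at 90 +/- one bin
  fr <- render_oriented_field(90, 8, seed = 51)
  spc <- combine_and_normalize(angular_power_sum(fr))
  expect_lte(min(abs(spc$angles_deg[which.max(spc$magnitude)] - 90)), 1)
})

test_that("isotropic white noise gives a flat spectrum", {
  set.seed(52)
  img <- matrix(stats::runif(512 * 512), 512, 512)
  expect_lt(flatness(angular_power_sum(img)), 1.5)
})

test_that("spectrum is 180-degree periodic and shifts with image rotation", {
  fr <- render_oriented_field(90, 8, seed = 53, side = 256, n_cells = 10)
  sp0 <- angular_power_sum(fr$pixels)
  # 180-degree rotation leaves the spectrum unchanged
  rot180 <- fr$pixels[nrow(fr$pixels):1, ncol(fr$pixels):1]
  sp180 <- angular_power_sum(rot180)
  expect_equal(sp180$magnitude, sp0$magnitude, tolerance = 1e-8)
  # 90-degree rotation shifts the argmax by 90 mod 180 (within one bin)
  rot90 <- t(fr$pixels)[ncol(fr$pixels):1, ]
  sp90 <- angular_power_sum(rot90)
  a0 <- sp0$angles_deg[which.max(sp0$magnitude)]
  a90 <- sp90$angles_deg[which.max(sp90$magnitude)]
  expect_lte(abs(((a90 - a0) %% 180) - 90), 1 + 1e-9)
})

test_that("normalization is exact and intensity-scale invariant", {
  fr <- render_oriented_field(45, 4, seed = 54, side = 256, n_cells = 10)
  sp <- angular_power_sum(fr)
  one <- combine_and_normalize(sp)
  expect_equal(sum(one$magnitude), 1, tolerance = 1e-12)
  # two identical spectra combine to the same normalized result as one
  two <- combine_and_normalize(list(sp, sp))
  expect_equal(two$magnitude, one$magnitude)
  expect_equal(two$n_fovs_combined, 2L)
  # image x constant: identical normalized spectrum
  sp_scaled <- angular_power_sum(fr$pixels * 3.7)
  expect_equal(combine_and_normalize(sp_scaled)$magnitude, one$magnitude,
               tolerance = 1e-9)
  # arithmetic: [1,3] + [3,1] over two bins -> [0.5, 0.5]
  s1 <- topomorph:::orientation_spectrum(c(0, 90), c(1, 3))
  s2 <- topomorph:::orientation_spectrum(c(0, 90), c(3, 1))
  expect_equal(combine_and_normalize(list(s1, s2))$magnitude, c(0.5, 0.5))
  s3 <- topomorph:::orientation_spectrum(c(0, 45, 90, 135), rep(1, 4))
  expect_error(combine_and_normalize(list(s1, s3)), "binning")
})

test_that("time-angle surface tracks alignment over the series", {
  # aligned series: peak trace stays at 90 +/- one bin for every timepoint
  spectra <- lapply(c(0.5, 1, 2), function(t) {
    fr <- render_oriented_field(90, 8, seed = 55 + round(10 * t), n_cells = 20,
                                t_h = 1e6)
    s <- combine_and_normalize(angular_power_sum(fr))
    s$timestamp_h <- t
    s
  })
  surf <- build_time_angle_surface(spectra)
  expect_true(all(abs(surf$peak_deg - 90) <= 1))
  expect_equal(rowSums(surf$surface), rep(1, 3), tolerance = 1e-12)
  # a missing timestamp yields an NA row and a flag
  expect_warning(
    surf2 <- build_time_angle_surface(spectra, schedule = c(0.5, 1, 1.5, 2)),
    "no spectrum")
  expect_true(surf2$missing[3])
  expect_true(all(is.na(surf2$surface[3, ])))
})

test_that("unaligned and day-0 round populations give flat spectra", {
  # Monte-Carlo calibration: flatness of FOV-combined spectra under uniform
  # orientations defines the null band; the flatness statistic of further
  # uniform draws and of round (day-0) cells must sit inside it, while the
  # aligned condition must sit far outside.
  combined_flatness <- function(mu, kappa, seeds, t_h = 1e6) {
    sp <- lapply(seeds, function(s)
      angular_power_sum(render_oriented_field(mu, kappa, seed = s, side = 256,
                                              n_cells = 8, t_h = t_h)))
    flatness(combine_and_normalize(sp))
  }
  null_stats <- vapply(1:4, function(k)
    combined_flatness(90, 0, seeds = 600 + 4 * k + 0:3), numeric(1))
  upper <- 2 * max(null_stats)
  expect_lt(combined_flatness(90, 0, seeds = 701:704), upper)
  expect_lt(combined_flatness(90, 0, seeds = 711:714, t_h = 0), upper)  # round cells
  expect_gt(combined_flatness(90, 8, seeds = 721:724), upper)           # aligned
})
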