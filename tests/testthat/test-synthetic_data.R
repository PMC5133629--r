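test_that("schedule covers the three-phase 21-day cadence exactly", {
  s <- make_schedule(default_phases())
  expect_identical(s$timestamps_h[1], 0)
  expect_equal(max(s$timestamps_h), 504)
  # brute-force enumeration of each phase grid, boundaries counted once
  oracle <- unique(c(seq(0, 6, by = 1 / 6), seq(6, 96, by = 0.25),
                     seq(96, 504, by = 1)))
  expect_equal(length(s$timestamps_h), 805)
  expect_equal(s$timestamps_h, oracle, tolerance = 1e-12)
  expect_lt(max(abs(s$timestamps_h - oracle)), 1e-9)
  expect_true(all(diff(s$timestamps_h) > 0))
})

test_that("single-phase schedules enumerate directly and bad phases error", {
  expect_equal(make_schedule(list(c(0, 1, 0.5)))$timestamps_h, c(0, 0.5, 1))
  expect_error(make_schedule(list(c(0, 6, 1), c(7, 9, 1))), "contiguous")
  expect_error(make_schedule(list(c(0, 6, 1), c(5, 9, 1))), "contiguous")
  expect_error(make_schedule(list(c(0, 5, 2))), "divide")
})

test_that("axial orientation sampling has the right concentration behaviour", {
  # degenerate: huge kappa collapses on mu
  th <- sample_orientations(200, mu_deg = 37, kappa = 5e4)
  expect_lt(max(abs(th - 37)), 1)
  # kappa = 0: uniform, axial resultant length near 0
  set.seed(11)
  th0 <- sample_orientations(10000, 90, 0)
  expect_lt(axial_resultant_length(th0), 0.05)
  # kappa = 2: matches a rejection-sampling oracle within 0.02
  set.seed(12)
  th2 <- sample_orientations(10000, 45, 2)
  expect_equal(axial_resultant_length(th2), axial_mrl_oracle(2), tolerance = 0.02)
})

test_that("orientation distributions have period 180 degrees", {
  set.seed(21)
  th <- sample_orientations(5000, 120, 4)
  expect_true(all(th >= 0 & th < 180))
  h1 <- hist(th, breaks = seq(0, 180, by = 10), plot = FALSE)$counts
  h2 <- hist((th + 180) %% 180, breaks = seq(0, 180, by = 10), plot = FALSE)$counts
  expect_identical(h1, h2)
})

test_that("spreading trajectory saturates from the round cell to the plateau", {
  p <- condition_params("flat", area_plateau_um2 = 2000, area_timescale_h = 6,
                        aspect_ratio_plateau = 3, initial_radius_um = 10)
  t0 <- spreading_trajectory(0, p)
  expect_equal(t0$target_area_um2, pi * 100)
  expect_equal(t0$target_aspect_ratio, 1)
  tinf <- spreading_trajectory(1e6, p)
  expect_equal(tinf$target_area_um2, 2000)
  expect_equal(tinf$target_aspect_ratio, 3)
  # closed form at t = tau for the exponential approach
  ttau <- spreading_trajectory(6, p)
  expect_equal(ttau$target_area_um2, pi * 100 + (2000 - pi * 100) * (1 - exp(-1)))
  # monotone rise
  tr <- spreading_trajectory(seq(0, 48, by = 0.5), p)
  expect_true(all(diff(tr$target_area_um2) > 0))
  expect_true(all(diff(tr$target_aspect_ratio) > 0))
  expect_error(spreading_trajectory(-1, p), "non-negative")
})

test_that("population placement respects spacing and errors on impossible density", {
  p <- condition_params("flat", n_cells_per_fov = 10, area_plateau_um2 = 1000)
  pop <- sample_population(p, fov_um = c(400, 400), rng_seed = 5)
  expect_equal(nrow(pop), 10)
  d <- as.matrix(dist(cbind(pop$x_um, pop$y_um)))
  diag(d) <- Inf
  expect_gte(min(d), 2 * sqrt(1000 * p$aspect_ratio_plateau / pi))
  p_dense <- condition_params("flat", n_cells_per_fov = 500)
  expect_error(sample_population(p_dense, fov_um = c(100, 100), rng_seed = 1),
               "density|place")
})

test_that("rendered frames match their ground truth", {
  # zero cells, zero noise: constant background
  fr0 <- render_frame(NULL, frame_geometry(64, 64, 1), noise = no_noise)
  expect_true(all(fr0$pixels == 0))
  # one clean ellipse: foreground pixel count within 3% of pi*a*b
  fr1 <- render_frame(cell_state(60, 60, 40, 10, 25), frame_geometry(120, 120, 1),
                      noise = no_noise)
  expect_equal(sum(fr1$pixels > 0), pi * 40 * 10, tolerance = 0.03)
  expect_equal(sum(fr1$mask > 0), sum(fr1$pixels > 0))
  expect_false(fr1$clipped)
  # clipping is flagged
  fr2 <- render_frame(cell_state(5, 60, 40, 10, 0), frame_geometry(120, 120, 1),
                      noise = no_noise)
  expect_true(fr2$clipped)
})

test_that("simulate_experiment bookkeeping, determinism and truth correspondence", {
  conds <- list(condition_params("flat", n_cells_per_fov = 4,
                                 area_plateau_um2 = 800))
  geom <- frame_geometry(128, 128, 1)
  sim <- simulate_experiment(conds, c(0, 2, 4), n_replicates = 1, n_fovs = 1,
                             geometry = geom, rng_seed = 9)
  expect_length(sim$frames, 3)
  expect_equal(nrow(sim$truth), 12)  # 4 cells x 3 timestamps
  # per-frame object count equals truth row count
  for (fr in sim$frames)
    expect_equal(max(fr$mask),
                 sum(sim$truth$timestamp_h == fr$timestamp_h))
  # same seed twice: identical truth tables
  sim2 <- simulate_experiment(conds, c(0, 2, 4), n_replicates = 1, n_fovs = 1,
                              geometry = geom, rng_seed = 9)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$frames[[2]]$pixels, sim2$frames[[2]]$pixels)
})

test_that("written TIFF frames and masks round-trip through the manifest", {
  conds <- list(condition_params("flat", n_cells_per_fov = 3,
                                 area_plateau_um2 = 600))
  out <- withr::local_tempdir()
  sim <- simulate_experiment(conds, c(0, 1), n_replicates = 1, n_fovs = 2,
                             geometry = frame_geometry(96, 96, 1),
                             rng_seed = 2, out_dir = out)
  mf <- read_manifest(file.path(out, "manifest.csv"))
  expect_equal(nrow(mf), 4)
  m <- read_mask_tiff(file.path(out, mf$mask_path[2]))
  expect_equal(max(m), 3)
  img <- read_frame_tiff(file.path(out, mf$path[2]))
  expect_true(all(img >= 0 & img <= 1))
})
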