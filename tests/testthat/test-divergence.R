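make_records <- function(conds, timestamps, n_per, gen) {
  rows <- list()
  for (cond in conds) for (t in timestamps) {
    v <- gen(cond, t, n_per)
    rows[[length(rows) + 1L]] <-
      data.frame(object_id = seq_len(n_per), condition = cond,
                 replicate = rep(1:2, length.out = n_per),
                 fov_id = rep(c("r1f1", "r1f2"), length.out = n_per),
                 timestamp_h = t, area_um2 = v, perimeter_um = sqrt(v),
                 circularity = pmin(1, 1 / (1 + v / 1000)),
                 major_axis_um = sqrt(v) * 2, minor_axis_um = sqrt(v) / 2,
                 orientation_deg = 0)
  }
  do.call(rbind, rows)
}

test_that("timeseries assembly pools objects across replicates and FOVs", {
  rec <- make_records("flat", c(0, 1), 10, function(c, t, n) rep(t + 1, n))
  ts <- assemble_timeseries(rec)
  s <- ts$series$flat$area
  expect_equal(lengths(s$values), c(10, 10))
  expect_equal(s$mean, c(1, 2))
  expect_equal(names(ts$series$flat),
               c("area", "circularity", "major_axis", "minor_axis"))
  expect_error(assemble_timeseries(rec, metrics = "volume"), "unknown metric")
})

test_that("assembled mean area rises and plateaus on a synthetic experiment", {
  p <- condition_params("flat", n_cells_per_fov = 6, area_plateau_um2 = 1200,
                        area_timescale_h = 4)
  sim <- simulate_experiment(list(p), seq(0, 36, by = 4), n_replicates = 1,
                             n_fovs = 2, geometry = frame_geometry(256, 256, 1),
                             rng_seed = 61)
  ts <- assemble_timeseries(sim$truth, "area")
  m <- ts$series$flat$area$mean
  # oracle: the generator's own spreading trajectory
  tr <- spreading_trajectory(seq(0, 36, by = 4), p)$target_area_um2
  expect_true(all(diff(m) > 0))
  expect_equal(m / tr, rep(1, length(m)), tolerance = 0.15)
})

test_that("two-group ANOVA F matches the t-test identity and handles degeneracy", {
  expect_equal(f_test(c(1, 2, 3), c(1, 2, 3))$F, 0)
  expect_equal(f_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # F = t^2 against the pooled-variance t-test oracle
  a <- c(1, 2); b <- c(3, 4)
  tt <- t.test(a, b, var.equal = TRUE)
  r <- f_test(a, b)
  expect_equal(r$F, unname(tt$statistic)^2)
  expect_equal(r$p, tt$p.value)
  # random fixtures
  set.seed(62)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), mean = runif(1))
    tt <- t.test(a, b, var.equal = TRUE)
    r <- f_test(a, b)
    expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
    # symmetry
    r2 <- f_test(b, a)
    expect_equal(r2$F, r$F)
    expect_equal(r2$p, r$p)
  }
  # zero within-group variance
  deg <- f_test(c(0, 0), c(1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  # variance mode agrees with var.test
  x <- rnorm(10); y <- rnorm(12, sd = 2)
  vr <- f_test(x, y, mode = "variance")
  expect_equal(vr$p, var.test(x, y)$p.value)
})

test_that("divergence_time implements the persistent first-rejection rule", {
  ts <- c(0, 0.5, 1, 1.5, 2)
  expect_true(is.na(divergence_time(rep(0.5, 5), ts)))
  p <- c(0.5, 0.5, 0.5, 0.01, 0.01)
  expect_equal(divergence_time(p, ts, persistence_k = 1), 1.5)
  expect_equal(divergence_time(p, ts, persistence_k = 2), 1.5)
  expect_true(is.na(divergence_time(p, ts, persistence_k = 3)))
  # an isolated rejection is skipped when persistence is required
  p2 <- c(0.5, 0.01, 0.5, 0.01, 0.01)
  expect_equal(divergence_time(p2, ts, persistence_k = 2), 1.5)
  # lowering alpha never gives an earlier hour
  set.seed(63)
  for (i in 1:50) {
    pv <- runif(20)
    tt <- seq_along(pv)
    h1 <- divergence_time(pv, tt, alpha = 0.05)
    h2 <- divergence_time(pv, tt, alpha = 0.01)
    expect_true(is.na(h2) || (!is.na(h1) && h2 >= h1))
  }
  expect_error(divergence_time(numeric(0), numeric(0)), "empty")
})

test_that("F-test type-I error is calibrated at the nominal level", {
  set.seed(64)
  n_sim <- 1000
  p <- vapply(seq_len(n_sim), function(i)
    f_test(rnorm(50), rnorm(50))$p, numeric(1))
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.02 / 0.05)
})

test_that("an injected hour-12 changepoint is recovered within two grid steps", {
  grid <- seq(0, 24, by = 1)
  hours <- vapply(1:50, function(seed) {
    set.seed(6400 + seed)
    pv <- vapply(grid, function(t) {
      a <- rnorm(200)
      b <- rnorm(200, mean = if (t >= 12) 1 else 0)  # 1 pooled-SD shift
      f_test(a, b)$p
    }, numeric(1))
    divergence_time(pv, grid)
  }, numeric(1))
  med <- median(hours, na.rm = TRUE)
  expect_gte(med, 12)
  expect_lte(med, 14)
})

test_that("identically generated conditions almost never diverge", {
  set.seed(65)
  never <- vapply(1:40, function(i) {
    pv <- vapply(1:30, function(t) f_test(rnorm(40), rnorm(40))$p, numeric(1))
    is.na(divergence_time(pv, 1:30, alpha = 0.05, persistence_k = 3))
  }, logical(1))
  expect_gte(mean(never), 0.95)
})

test_that("divergence_analysis and divergence_table report per-pair hours", {
  rec <- make_records(c("flat", "aligned"), seq(0, 10), 40,
                      function(c, t, n)
                        rnorm(n, mean = 100 + if (c == "aligned" && t >= 5) 50 else 0,
                              sd = 10))
  set.seed(66)
  ts <- assemble_timeseries(rec, "area")
  d <- divergence_analysis(ts, "flat", "aligned", "area", persistence_k = 2)
  expect_equal(d$divergence_hour, 5)
  expect_true(all(d$p >= 0 & d$p <= 1, na.rm = TRUE))
  tab <- divergence_table(rec, pairs = list(c("flat", "aligned")),
                          metrics = c("area", "minor_axis"), persistence_k = 2)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab[["flat/aligned"]][1], 5)
})

test_that("mean-ratio trajectories flag the most dissimilar condition", {
  rec <- make_records(c("flat", "random", "aligned"), 0:5, 30,
                      function(c, t, n)
                        rnorm(n, mean = c(flat = 2000, random = 700,
                                          aligned = 2600)[c], sd = 50))
  set.seed(67)
  ts <- assemble_timeseries(rec, "area")
  # identical series: ratio 1, summary 0
  same <- mean_ratio_trajectory(ts$series$flat$area, ts$series$flat$area)
  expect_true(all(same$ratio == 1))
  expect_equal(same$summary, 0)
  # doubling: ratio 0.5, summary log 2
  dbl <- ts$series$flat$area; dbl$mean <- 2 * dbl$mean
  half <- mean_ratio_trajectory(ts$series$flat$area, dbl)
  expect_equal(half$ratio, rep(0.5, 6))
  expect_equal(half$summary, log(2))
  # pair summaries furthest from unity all involve the smallest-area condition
  pairs <- list(c("flat", "random"), c("flat", "aligned"), c("random", "aligned"))
  sums <- vapply(pairs, function(pr)
    mean_ratio_trajectory(ts$series[[pr[1]]]$area, ts$series[[pr[2]]]$area)$summary,
    numeric(1))
  worst <- pairs[[which.max(sums)]]
  expect_true("random" %in% worst)
  expect_gt(max(sums[c(1, 3)]), sums[2])
})
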