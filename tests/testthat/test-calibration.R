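test_that("k grids include endpoints exactly with the requested spacing", {
  g <- k_grid(0.01, 100, 200, "log")
  expect_equal(g$k[1], 0.01)
  expect_equal(g$k[200], 100)
  expect_equal(length(g$k), 200L)
  ratios <- g$k[-1] / g$k[-200]
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-9)
  expect_equal(k_grid(1, 2, 2, "linear")$k, c(1, 2))
  expect_error(k_grid(0, 1, 10), "k_min")
  expect_error(k_grid(2, 1, 10), "k_min")
  expect_error(k_grid(1, 2, 1), "n_k")
})

test_that("alpha_for is l_ref * k, linear in k and covariant under scaling", {
  cube <- cube_cloud()
  expect_equal(alpha_for(cube, 2), sqrt(3), tolerance = 1e-12)
  expect_equal(alpha_for(cube, 0.5), alpha_for(cube, 1) / 2)
  big <- point_cloud(4 * cube$points, id = "big")
  expect_equal(alpha_for(big, 2), 4 * alpha_for(cube, 2), tolerance = 1e-12)
  expect_error(alpha_for(cube, -1), "positive")
})

test_that("log-log OLS recovers an exact power law and validates inputs", {
  v <- c(1, exp(1), exp(2))
  m <- exp(1) * v  # ln(m) = 1 + 1 * ln(v)
  fit <- fit_loglog_ols(v, m)
  expect_equal(fit$a, 1, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$mse, 0, tolerance = 1e-12)
  expect_equal(fit$n, 3L)

  expect_error(fit_loglog_ols(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_loglog_ols(c(1, 2, 3), c(1, 2)), "equal length")
  expect_error(fit_loglog_ols(c(1, -2, 3), c(1, 2, 3)), "positive")
  expect_error(fit_loglog_ols(c(1, 2, 3), c(0, 2, 3)), "positive")
  expect_error(fit_loglog_ols(c(2, 2, 2), c(1, 2, 3)), "variance")
})

test_that("confidence intervals bracket the estimates with t(n-2) width", {
  ref <- reference_skeletons()
  fit <- fit_loglog_ols(ref$alpha_vol_m3, ref$mass_kg)
  expect_lt(fit$a_ci95[1], fit$a)
  expect_gt(fit$a_ci95[2], fit$a)
  # half-width = t(0.975, n-2) * se, with unbiased residual variance
  x <- log(ref$alpha_vol_m3)
  se_b <- sqrt((fit$mse * fit$n / (fit$n - 2)) / sum((x - mean(x))^2))
  expect_equal(diff(fit$b_ci95) / 2, qt(0.975, fit$n - 2) * se_b,
               tolerance = 1e-9)
})

test_that("sweeps are reproducible, volumes monotone in k, plateau equals the hull fit", {
  fam <- small_family(n_spec = 4, n_points = 3000, seed = 2)
  inp <- family_inputs(fam)
  # the r2(k) plateau equals the hull fit only for k beyond the largest
  # finite circumradius (slivers can carry circumradii far beyond the
  # hull diameter), so size the grid top adaptively
  kr_max <- max(vapply(inp$masses$specimen_id, function(id) {
    max(vapply(1:2, function(r) {
      sub <- downsample_cloud(inp$clouds[[id]], 2500,
                              alphamass:::derive_seed(7, id, r))
      ac <- alpha_complex(sub)
      max(ac$circumradius[is.finite(ac$circumradius)]) / ac$l_ref
    }, numeric(1)))
  }, numeric(1)))
  grid <- k_grid(0.05, 2 * kr_max, 12)
  sw1 <- calibrate_sweep(inp$clouds, inp$masses, grid, n_points = 2500,
                         n_reps = 2, seed = 7)
  sw2 <- calibrate_sweep(inp$clouds, inp$masses, grid, n_points = 2500,
                         n_reps = 2, seed = 7)
  expect_identical(sw1$volumes, sw2$volumes)
  expect_identical(sw1$r2, sw2$r2)
  expect_identical(sw1$optimal_k, sw2$optimal_k)
  # volumes non-decreasing in k for every specimen
  for (s in seq_along(inp$clouds))
    expect_true(all(diff(sw1$volumes[s, ]) >= 0))
  expect_true(all(sw1$volumes <= vapply(
    inp$masses$specimen_id,
    function(id) convex_hull_volume(inp$clouds[[id]]), numeric(1)) + 1e-12))
  # at k far beyond every finite circumradius the fit IS the hull fit;
  # hull volumes go through QuickHull on the identical vertex sets the
  # sweep triangulated (independent route, same geometry)
  hull_means <- vapply(inp$masses$specimen_id, function(id) {
    mean(vapply(1:2, function(r) {
      sub <- downsample_cloud(inp$clouds[[id]], 2500,
                              alphamass:::derive_seed(7, id, r))
      convex_hull_volume(point_cloud(alpha_complex(sub)$vertices, id = id))
    }, numeric(1)))
  }, numeric(1))
  hull_fit <- fit_loglog_ols(hull_means, inp$masses$mass_kg)
  expect_equal(sw1$r2[12], hull_fit$r2, tolerance = 1e-9)
  expect_equal(sw1$models[[12]]$b, hull_fit$b, tolerance = 1e-9)
  # r2 and slope are invariant when every cloud is scaled uniformly
  scaled <- lapply(inp$clouds, function(cl)
    point_cloud(2 * cl$points, id = cl$id))
  sws <- calibrate_sweep(scaled, inp$masses, grid, n_points = 2500,
                         n_reps = 2, seed = 7)
  expect_equal(sws$r2, sw1$r2, tolerance = 1e-9)
  expect_equal(sws$volumes, 8 * sw1$volumes, tolerance = 1e-9)
})

test_that("optimal-k selection maximizes r2 and breaks ties toward smaller k", {
  fake <- function(r2s, ks) {
    structure(list(grid = structure(list(k = ks, n_k = length(ks)),
                                    class = "k_grid"),
                   r2 = r2s,
                   models = lapply(r2s, function(r) list(r2 = r))),
              class = "sweep_result")
  }
  sel <- select_optimal_k(fake(c(0.5, 0.9, 0.7), c(0.1, 1, 10)))
  expect_equal(sel$k, 1)
  sel <- select_optimal_k(fake(c(0.9, 0.9), c(0.1, 1)))
  expect_equal(sel$k, 0.1)
  sel <- select_optimal_k(fake(c(NA, 0.8, NA), c(0.1, 1, 10)))
  expect_equal(sel$k, 1)
  expect_error(select_optimal_k(fake(c(NA_real_, NA_real_), c(0.1, 1))),
               "degenerate")
})

test_that("specimen mismatches are reported by id", {
  fam <- small_family(n_spec = 3, n_points = 1000, seed = 5)
  inp <- family_inputs(fam)
  bad_masses <- rbind(inp$masses,
                      data.frame(specimen_id = "ghost", mass_kg = 10))
  expect_error(
    calibrate_sweep(inp$clouds, bad_masses, k_grid(0.1, 10, 3),
                    n_points = 900, n_reps = 1, seed = 1),
    "ghost")
})

test_that("model files round trip through JSON", {
  ref <- reference_skeletons()
  fit <- fit_loglog_ols(ref$alpha_vol_m3, ref$mass_kg, k = 0.427)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f, n_points = 500000L, seed = 1L)
  back <- read_model(f)
  for (field in c("a", "b", "a_ci95", "b_ci95", "r2", "mse", "n", "k"))
    expect_equal(back[[field]], fit[[field]], tolerance = 1e-12,
                 info = field)
  expect_equal(back$n_points, 500000L)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"nonsense\": true}", bad)
  expect_error(read_model(bad), "corrupt")
})

test_that("sweep CSVs are written in long format", {
  fam <- small_family(n_spec = 3, n_points = 1200, seed = 3)
  inp <- family_inputs(fam)
  sw <- calibrate_sweep(inp$clouds, inp$masses, k_grid(0.2, 5, 4),
                        n_points = 1000, n_reps = 2, seed = 1)
  stem <- withr::local_tempfile()
  write_sweep_csv(sw, stem)
  vols <- read.csv(paste0(stem, "_volumes.csv"))
  fits <- read.csv(paste0(stem, "_fits.csv"))
  expect_equal(nrow(vols), 3 * 4)
  expect_equal(names(vols),
               c("k", "specimen_id", "mean_volume_m3", "sd_volume_m3"))
  expect_equal(nrow(fits), 4)
  expect_equal(names(fits), c("k", "a", "b", "r2", "mse"))
})
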