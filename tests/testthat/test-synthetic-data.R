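test_that("force generator: no recruitment below the slack population", {
  # slack lengths live far above any displacement reached on the ramp
  tr <- synthetic_truth(recruitment = recruitment_params(20, 0.1, 10),
                        visco = list(phase_lag = 0, damping = 0,
                                     relax_frac = 1, tau = 10,
                                     laxity_rate = 0))
  rec <- gen_force_displacement(tr, loading_protocol(target_strain = 10),
                                noise_sd = 0, seed = 1)
  ramp <- rec$data[rec$data$segment == "ramp", ]
  expect_true(all(ramp$force == 0))
})

test_that("force generator: degenerate sigma gives the single-kink line", {
  tr <- synthetic_truth(recruitment = recruitment_params(5.05, 1e-9, 10),
                        visco = list(phase_lag = 0, damping = 0,
                                     relax_frac = 1, tau = 10,
                                     laxity_rate = 0))
  rec <- gen_force_displacement(tr, loading_protocol(target_strain = 10),
                                noise_sd = 0, seed = 1)
  ramp <- rec$data[rec$data$segment == "ramp", ]
  x <- 5 + ramp$displacement
  expect_equal(ramp$force, 10 * pmax(x - 5.05, 0), tolerance = 1e-8)
})

test_that("generated force is deterministic given a seed and labeled", {
  tr <- synthetic_truth()
  p <- loading_protocol(cyclic_magnitude = "low", cycle_count = 10)
  r1 <- gen_force_displacement(tr, p, noise_sd = 0.01, seed = 7)
  r2 <- gen_force_displacement(tr, p, noise_sd = 0.01, seed = 7)
  expect_identical(r1$data, r2$data)
  expect_setequal(unique(r1$data$segment),
                  c("precondition", "cyclic", "ramp", "hold",
                    "sweep_0.1", "sweep_1", "sweep_5", "sweep_10"))
  r3 <- gen_force_displacement(tr, p, noise_sd = 0.01, seed = 8)
  expect_false(identical(r1$data$force, r3$data$force))
})

test_that("noiseless monotone ramp force is non-negative, non-decreasing", {
  tr <- synthetic_truth()
  rec <- gen_force_displacement(tr, loading_protocol(target_strain = 10),
                                noise_sd = 0, seed = 1)
  f <- rec$data$force[rec$data$segment == "ramp"]
  expect_true(all(f >= 0))
  expect_true(all(diff(f) >= -1e-12))
})

test_that("polarizer stack: concentrated fibers put the minimum at the
           mean angle and isotropy gives uniform truth", {
  st <- gen_polarizer_stack(0, 1e8, n_angles = 30,
                            region_truth_grid = c(3, 3), noise_sd = 0,
                            seed = 1)
  # intensity minimum at theta_p = 0 for every region
  rm_ <- region_means(st$images, region_grid(dim(st$images[[1]])))
  expect_true(all(apply(rm_, 1, which.min) == which.min(abs(st$angles))))
  # isotropy: uniform truth angles on the 90-degree period
  st0 <- gen_polarizer_stack(0, 0, region_truth_grid = c(40, 50), seed = 2,
                             tile_px = 2)
  expect_gt(suppressWarnings(
    stats::ks.test(as.numeric(st0$truth_angles), "punif", -45, 45)$p.value),
    1e-4)
})

test_that("polarizer stack truth dispersion matches the von Mises closed
           form and n_angles < 4 errors", {
  st <- gen_polarizer_stack(0, 4, region_truth_grid = c(20, 25), seed = 3,
                            tile_px = 2)
  csd <- circular_stats(as.numeric(st$truth_angles), 90)$csd
  expect_rel_equal(csd, vonmises_axial_csd(4, 90), 0.05)
  expect_error(gen_polarizer_stack(0, 4, n_angles = 3), "at least 4")
})

test_that("SHG generator: delta populations give a bimodal truth histogram
           and density <= 0 errors", {
  g <- gen_shg_image(0, 1, fiber_density = 2, seed = 1, size = 128,
                     angles = c(0, 45))
  tab <- table(g$truth_angles)
  expect_setequal(as.numeric(names(tab)), c(0, 45))
  expect_lt(abs(tab[[1]] - tab[[2]]), 2)
  expect_error(gen_shg_image(0, 1, fiber_density = 0), "empty image")
})

test_that("SHG truth dispersion matches the analytic axial circular SD", {
  g <- gen_shg_image(0, 2, fiber_density = 40, seed = 2, size = 512)
  expect_gt(length(g$truth_angles), 9999)
  csd <- circular_stats(g$truth_angles, 180)$csd
  expect_rel_equal(csd, vonmises_axial_csd(2, 180), 0.05)
})

test_that("nuclei generator: exact truth shapes and placement failure", {
  # a circle has nAR 1 by construction in the truth table
  nu <- gen_nuclei_image(1, nAR_mean = 1, nAR_sd = 0, seed = 1, size = 64,
                         mean_area = pi * 100)
  expect_equal(nu$truth$nAR, 1, tolerance = 1e-12)
  nu4 <- gen_nuclei_image(1, nAR_mean = 4, nAR_sd = 0, seed = 1, size = 64)
  expect_equal(nu4$truth$nAR, 4, tolerance = 1e-12)
  expect_equal(nu4$truth$major / nu4$truth$minor, 4, tolerance = 1e-12)
  expect_error(gen_nuclei_image(500, seed = 1, size = 100),
               "placement error")
})

test_that("nuclei angular dispersion matches the analytic circular SD", {
  nu <- gen_nuclei_image(200, 2.5, 0.3, angle_concentration = 3, seed = 2,
                         size = 900, mean_area = 60)
  csd <- circular_stats(nu$truth$angle, 180)$csd
  expect_rel_equal(csd, vonmises_axial_csd(3, 180), 0.08)
})

test_that("regression generator: null model R^2 matches k/(n-1) and decays
           with n; AR(1) off gives DW near 2", {
  k <- length(regression_schema())
  r2_at <- function(n, reps) mean(vapply(seq_len(reps), function(i) {
    tab <- gen_regression_table(n, coefficients = c(cellularity = 0),
                                resid_sd = 1, seed = 100 + i)
    f <- stats::lm(stats::reformulate(regression_schema(), "nAR"),
                   data = tab)
    summary(f)$r.squared
  }, numeric(1)))
  r2_small <- r2_at(60, 40)
  r2_big <- r2_at(240, 40)
  expect_lt(abs(r2_small - k / (60 - 1)), 0.06)
  expect_lt(abs(r2_big - k / (240 - 1)), 0.03)
  expect_gt(r2_small, r2_big)
  dw <- mean(vapply(1:30, function(i) {
    tab <- gen_regression_table(200, ar1_rho = 0, seed = i)
    f <- stats::lm(nAR ~ cellularity + nCSD + healing, data = tab)
    as.numeric(durbin_watson(stats::residuals(f)))
  }, numeric(1)))
  expect_lt(abs(dw - 2), 0.1)
})

test_that("regression generator rejects a non-positive-definite
           collinearity matrix and honours ar1_rho", {
  k <- length(regression_schema())
  bad <- diag(k); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(gen_regression_table(50, collinearity_matrix = bad))
  tab <- gen_regression_table(400, ar1_rho = 0.8, seed = 5)
  f <- stats::lm(nAR ~ cellularity + nCSD + healing, data = tab)
  expect_lt(as.numeric(durbin_watson(stats::residuals(f))), 1.2)
})
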