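test_that("binning produces 100 width-0.01 bins with exact statistics", {
  set.seed(9)
  st <- runif(500)
  p <- bin_profile(rnorm(500), st)
  expect_equal(nrow(p$bins), 100L)
  expect_equal(p$bins$bin_right - p$bins$bin_left, rep(0.01, 100))
  expect_equal(sum(p$bins$n), 500L)

  # hand computation: {1,2,3} in one bin
  p3 <- bin_profile(c(1, 2, 3), c(0.555, 0.551, 0.559))
  b3 <- p3$bins[p3$bins$n > 0, ]
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$mean, 2)
  expect_equal(b3$se, 1 / sqrt(3), tolerance = 1e-4)  # 0.5774

  # constant values: every non-empty bin mean v, SE 0
  pc <- bin_profile(rep(4.2, 200), runif(200))
  bc <- pc$bins[pc$bins$n > 1, ]
  expect_true(all(bc$mean == 4.2))
  expect_true(all(bc$se == 0))

  # the value 1 lands in the last, right-closed bin
  p1 <- bin_profile(c(5, 6), c(1, 0))
  expect_equal(p1$bins$n[100], 1L)

  expect_error(bin_profile(1:3, c(0.1, 0.2)),
               class = "spatialtime_validation_error")
})

test_that("weighted recombination of bin means recovers the global mean", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    v <- rnorm(n, sd = runif(1, 0.1, 5))
    s <- runif(n)
    b <- bin_profile(v, s)$bins
    ne <- b$n > 0
    expect_equal(sum(b$mean[ne] * b$n[ne]) / sum(b$n), mean(v),
                 tolerance = 1e-9)
  }
})

test_that("the moving-average smoother has the expected fixed points", {
  # constants are preserved exactly
  pc <- smooth_profile(bin_profile(rep(2.5, 300), runif(300)))
  bc <- pc$bins[pc$bins$n > 0, ]
  expect_equal(bc$smoothed, rep(2.5, nrow(bc)))

  # window 1 is the identity
  set.seed(12)
  p <- bin_profile(rnorm(200), runif(200))
  p1 <- smooth_profile(p, window = 1)
  ne <- p1$bins$n > 0
  expect_equal(p1$bins$smoothed[ne], p1$bins$mean[ne])

  # linear-in-center means are preserved away from the ends
  st <- rep(seq(0.05, 0.95, 0.1), each = 3)       # 10 occupied bins
  v <- 2 * (floor(st / 0.1) * 0.1 + 0.005) + 1    # exact linear in center
  pl <- smooth_profile(bin_profile(v, st), window = 5)
  bl <- pl$bins[pl$bins$n > 0, ]
  expect_equal(bl$smoothed[3:8], bl$mean[3:8], tolerance = 1e-12)

  # smoothing stays within the raw envelope
  ps <- smooth_profile(p, window = 7)
  bs <- ps$bins[ps$bins$n > 0, ]
  expect_true(all(bs$smoothed >= min(bs$mean) - 1e-12 &
                    bs$smoothed <= max(bs$mean) + 1e-12))

  expect_error(smooth_profile(p, window = 0),
               class = "spatialtime_config_error")
})

test_that("profile features classify monotone, flat and peaked shapes", {
  set.seed(13)
  st <- runif(600)

  up <- profile_features(smooth_profile(bin_profile(3 * st, st)))
  expect_identical(up$direction, "increasing")
  expect_equal(up$trend_rho, 1)
  b_up <- smooth_profile(bin_profile(3 * st, st))$bins
  expect_equal(up$peak_spatialtime, max(b_up$center[b_up$n > 0]))

  flat <- profile_features(smooth_profile(bin_profile(rep(2, 600), st)))
  expect_identical(flat$direction, "flat")

  down <- profile_features(smooth_profile(
    bin_profile(5 - 4 * st + rnorm(600, 0, 0.3), st)))
  expect_identical(down$direction, "decreasing")
  expect_lt(down$trend_p, 0.01)

  expect_error(profile_features(bin_profile(c(1, 2), c(0.1, 0.9))),
               class = "spatialtime_insufficient_data_error")
})

test_that("a generated peaked gradient is recovered near its true maximum", {
  sc <- simulate_scene(seed = 21)
  norm <- suppressWarnings(normalize_expression(sc$table))
  p <- smooth_profile(bin_profile(as.numeric(norm["Thbs2", ]),
                                  sc$st$spatialtime))
  f <- profile_features(p)
  expect_identical(f$direction, "peaked")
  expect_lt(abs(f$peak_spatialtime - sc$ground_truth$thbs2_peak), 0.05)
})

test_that("profiles are scale-equivariant", {
  set.seed(14)
  st <- runif(400)
  v <- 1 + 4 * exp(-((st - 0.4) / 0.15)^2) + rnorm(400, 0, 0.2)
  p1 <- smooth_profile(bin_profile(v, st))
  p2 <- smooth_profile(bin_profile(7.3 * v, st))
  ne <- p1$bins$n > 0
  expect_equal(p2$bins$mean[ne], 7.3 * p1$bins$mean[ne], tolerance = 1e-12)
  expect_equal(p2$bins$se[ne], 7.3 * p1$bins$se[ne], tolerance = 1e-12)
  f1 <- profile_features(p1); f2 <- profile_features(p2)
  expect_equal(f2$trend_rho, f1$trend_rho)
  expect_equal(f2$peak_spatialtime, f1$peak_spatialtime)

  q <- smooth_profile(bin_profile(5 - 3 * st, st))
  expect_equal(crossing_points(p2, q), crossing_points(p1, q))
})

test_that("crossings are located by interpolation on scaled profiles", {
  st <- rep(seq(0.005, 0.995, 0.01), each = 2)
  a <- smooth_profile(bin_profile(st, st), window = 1)
  b <- smooth_profile(bin_profile(1 - st, st), window = 1)
  cr <- crossing_points(a, b)
  expect_equal(cr, 0.5, tolerance = 1e-9)

  # one scaled profile never falls below the other: no crossings
  conv <- smooth_profile(bin_profile(st^2, st), window = 1)
  expect_length(crossing_points(a, conv), 0)

  expect_warning(none <- crossing_points(a, a), "identical")
  expect_length(none, 0)
})

test_that("score-field crossing localizes the region border", {
  sc <- simulate_scene(seed = 22)
  pm <- smooth_profile(bin_profile(sc$table$scores$macrophage,
                                   sc$st$spatialtime))
  pp <- smooth_profile(bin_profile(sc$table$scores$mpc,
                                   sc$st$spatialtime))
  cr <- crossing_points(pm, pp)
  b <- sc$ground_truth$border_spatialtime
  expect_gt(length(cr), 0)
  expect_lt(abs(cr[1] - b), 0.05)
})
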