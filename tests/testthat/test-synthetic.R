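test_that("layout generation matches the disk geometry exactly", {
  # degenerate radius marks the single center pixel
  lay0 <- generate_layout(layout_spec(10, 10, 10, c(45, 45), 0))
  expect_equal(sum(lay0$region$raster), 1L)
  expect_true(lay0$region$raster[46, 46])

  # disk membership equals a brute-force point-in-disk scan
  lay <- generate_layout(layout_spec(20, 20, 5, c(47, 47), 15))
  r <- lay$region$raster
  brute <- 0L
  for (row in seq_len(nrow(r))) for (col in seq_len(ncol(r))) {
    inside <- sqrt((col - 1 - 47)^2 + (row - 1 - 47)^2) <= 15
    expect_identical(r[row, col], inside)
    brute <- brute + inside
  }
  expect_identical(sum(r), brute)

  # one spot per lattice node, unique ids
  expect_equal(nrow(lay$spots$spots), 400L)
  expect_false(anyDuplicated(lay$spots$spots$spot_id) > 0)

  # region escaping the lattice is a configuration error
  expect_error(layout_spec(10, 10, 10, c(5, 5), 20),
               class = "spatialtime_config_error")
})

test_that("generators are deterministic under a fixed seed", {
  spec <- layout_spec(15, 15, 8, c(56, 56), 20, seed = 11)
  a <- generate_layout(spec); b <- generate_layout(spec)
  expect_identical(a, b)
  ct <- list(m = gradient_spec("decreasing", 0.8, 0.1, width = 0.3))
  expect_identical(generate_prediction_scores(a, ct, 0.05, seed = 4),
                   generate_prediction_scores(b, ct, 0.05, seed = 4))
  gs <- list(g1 = gradient_spec("flat", 0, 5),
             g2 = gradient_spec("peaked", 10, 1, peak_position = 0.4,
                                width = 0.2))
  expect_identical(generate_counts(a, NULL, gs, seed = 4),
                   generate_counts(b, NULL, gs, seed = 4))
  f1 <- generate_fibril_image(64, 64, 15, 5, seed = 9)
  f2 <- generate_fibril_image(64, 64, 15, 5, seed = 9)
  expect_identical(f1, f2)
  # per-gene sub-streams: adding a gene leaves the others untouched
  gs2 <- c(gs, list(extra = gradient_spec("flat", 0, 2)))
  c2 <- generate_counts(a, NULL, gs2, seed = 4)
  expect_identical(as.matrix(c2[c("g1", "g2"), ]),
                   as.matrix(generate_counts(a, NULL, gs, seed = 4)))
})

test_that("gradient specs enforce their invariants", {
  expect_error(gradient_spec("wiggly", 1, 0), class = "spatialtime_config_error")
  expect_error(gradient_spec("peaked", 1, 0, width = 0.1),
               class = "spatialtime_config_error")
  expect_error(gradient_spec("decreasing", 1, 0, peak_position = 0.5),
               class = "spatialtime_config_error")
  expect_error(gradient_spec("flat", 0, 5, dispersion = 0),
               class = "spatialtime_config_error")
  # amplitude 0 forces a constant mean for every shape
  s <- seq(0, 1, 0.05)
  for (spec in list(gradient_spec("decreasing", 0, 3),
                    gradient_spec("peaked", 0, 3, peak_position = 0.2),
                    gradient_spec("flat", 0, 3)))
    expect_equal(gradient_mean(spec, s), rep(3, length(s)))
})

test_that("prediction scores follow the profile, stay in [0,1]", {
  lay <- generate_layout(layout_spec(20, 20, 10, c(95, 95), 30))
  st <- spatialtime_scores(lay$spots, lay$region)

  # noiseless inside-high field: strict ordering extremes
  sc0 <- generate_prediction_scores(lay, list(
    m = gradient_spec("decreasing", 0.8, 0.1, width = 0.3)), 0, seed = 1)
  near <- sc0$m[st$raw_distance == 0]
  far <- sc0$m[st$spatialtime == 1]
  expect_true(min(near) > max(far))

  # noiseless flat profile is exactly constant
  scf <- generate_prediction_scores(lay, list(
    f = gradient_spec("flat", 0, 0.7)), 0, seed = 1)
  expect_true(all(scf$f == 0.7))

  # noisy scores stay bounded and track the profile per distance stratum
  scn <- generate_prediction_scores(lay, list(
    m = gradient_spec("decreasing", 0.6, 0.2, width = 0.4)),
    noise_sd = 0.05, seed = 3)
  expect_true(all(scn$m >= 0 & scn$m <= 1))
  mu <- gradient_mean(gradient_spec("decreasing", 0.6, 0.2, width = 0.4),
                      st$spatialtime)
  strat <- cut(st$spatialtime, c(-0.01, 0.25, 0.5, 0.75, 1))
  for (lv in levels(strat)) {
    idx <- strat == lv
    expect_lt(abs(mean(scn$m[idx]) - mean(mu[idx])),
              3 * 0.05 / sqrt(sum(idx)))
  }

  expect_error(generate_prediction_scores(lay, list(
    m = gradient_spec("sideways", 1, 0)), 0, 1),
    class = "spatialtime_config_error")
})

test_that("count marginals match the negative-binomial means", {
  lay <- generate_layout(layout_spec(100, 100, 5, c(250, 250), 100))
  st <- spatialtime_scores(lay$spots, lay$region)
  n <- nrow(lay$spots$spots)
  expect_gte(n, 10000)

  # amplitude 0: grand mean within 3 Monte-Carlo SEs of the baseline
  for (shape in c("flat", "decreasing")) {
    spec <- gradient_spec(shape, 0, 5, dispersion = 8)
    cnt <- generate_counts(lay, st, setNames(list(spec), "g"), seed = 2)
    se <- sqrt((5 + 25 / 8) / n)
    expect_lt(abs(mean(cnt["g", ]) - 5), 3 * se)
  }

  # gradient shapes: empirical mean near SpatialTime 0 and 1 vs analytic
  for (spec in list(gradient_spec("decreasing", 12, 1, width = 0.3,
                                  dispersion = 5),
                    gradient_spec("peaked", 9, 2, peak_position = 0.5,
                                  width = 0.25, dispersion = 5))) {
    cnt <- generate_counts(lay, st, list(g = spec), seed = 6)
    for (band in list(st$spatialtime <= 0.05, st$spatialtime >= 0.95)) {
      mu <- mean(gradient_mean(spec, st$spatialtime[band]))
      v <- mu + mu^2 / spec$dispersion
      expect_lt(abs(mean(cnt["g", band]) - mu), 3 * sqrt(v / sum(band)))
    }
  }

  # degenerate all-zero case
  z <- generate_counts(lay, st, list(g = gradient_spec("flat", 0, 0)),
                       seed = 2)
  expect_true(all(z == 0))
  expect_true(all(generate_counts(lay, st, list(
    g = gradient_spec("decreasing", 4, 1, width = 0.3)), seed = 2) >= 0))
})

test_that("fibril ground truth behaves at the orientation-order limits", {
  # perfectly aligned limit
  f_inf <- generate_fibril_image(64, 64, 25, Inf, seed = 5)
  expect_equal(f_inf$anisotropy, 1)
  expect_equal(f_inf$orientation_deg, 25, tolerance = 1e-9)

  # uniform orientations: nematic order parameter near 0
  set.seed(1)
  th <- runif(10000, -pi / 2, pi / 2)
  q <- sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
  expect_lt(q, 0.05)
  f0 <- generate_fibril_image(48, 48, 0, 0, n_fibers = 10000, seed = 5)
  expect_lt(f0$anisotropy, 0.05)

  # ground-truth order is monotone in concentration (fixed seed)
  qs <- vapply(c(0, 1, 3, 10, 100), function(conc)
    generate_fibril_image(48, 48, 0, conc, seed = 7)$anisotropy, 0)
  expect_true(all(diff(qs) >= 0))

  img <- generate_fibril_image(64, 64, 10, 4, seed = 2)$image
  expect_true(all(img >= 0 & img <= 1))
  expect_error(generate_fibril_image(-5, 64, 0, 1),
               class = "spatialtime_config_error")
  expect_error(generate_fibril_image(64, 64, 0, -1),
               class = "spatialtime_config_error")
})
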