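test_that("anisotropy from a tensor matches closed-form eigenanalysis", {
  aligned <- anisotropy_from_tensor(matrix(c(1, 0, 0, 0), 2))
  expect_equal(aligned$au, 1)
  expect_equal(aligned$orientation_deg, 0)

  iso <- anisotropy_from_tensor(diag(0.5, 2))
  expect_equal(iso$au, 0)
  expect_true(is.na(iso$orientation_deg))    # no preferred direction

  # closed form for [[0.75, 0.25], [0.25, 0.25]]: lambda = 0.5 +- sqrt(0.125)
  t3 <- matrix(c(0.75, 0.25, 0.25, 0.25), 2)
  r3 <- anisotropy_from_tensor(t3)
  expect_equal(r3$au, 2 * sqrt(0.0625 + 0.0625), tolerance = 1e-12)
  e <- eigen(t3, symmetric = TRUE)           # independent eigensolver
  expect_equal(r3$au, e$values[1] - e$values[2])

  expect_error(anisotropy_from_tensor(matrix(c(1, 0.2, 0, 0), 2)),
               class = "spatialtime_validation_error")
  expect_error(anisotropy_from_tensor(matrix(c(0.9, 0, 0, 0.9), 2)),
               class = "spatialtime_validation_error")
})

test_that("nematic cancellation: +45 and -45 tangents average to isotropy", {
  # equal mass at +45 and -45 degrees: t t^T averages to I/2
  t45 <- c(cos(pi / 4), sin(pi / 4)); tm45 <- c(cos(-pi / 4), sin(-pi / 4))
  tensor <- (tcrossprod(t45) + tcrossprod(tm45)) / 2
  expect_equal(tensor, diag(0.5, 2))
  expect_equal(anisotropy_from_tensor(tensor)$au, 0)
})

test_that("the ROI tensor equals a brute-force per-pixel accumulation", {
  set.seed(15)
  img <- matrix(runif(20 * 24), 20, 24)
  tensor <- roi_nematic_tensor(img, c(2, 3, 18, 14), min_pixels = 5,
                               grad_eps = 1e-6)
  expect_equal(sum(diag(tensor)), 1, tolerance = 1e-9)

  # independent accumulation: explicit loops over the ROI interior
  sub <- img[4:17, 3:20]
  sm <- matrix(0, nrow(sub), ncol(sub))
  for (r in seq_len(nrow(sub))) for (c in seq_len(ncol(sub))) {
    rr <- pmin(pmax(r + (-1:1), 1), nrow(sub))
    cc <- pmin(pmax(c + (-1:1), 1), ncol(sub))
    sm[r, c] <- mean(sub[rr, cc])
  }
  acc <- matrix(0, 2, 2); used <- 0
  rng <- diff(range(sub))
  for (r in 2:(nrow(sm) - 1)) for (c in 2:(ncol(sm) - 1)) {
    gx <- (sm[r, c + 1] - sm[r, c - 1]) / 2
    gy <- (sm[r + 1, c] - sm[r - 1, c]) / 2
    g <- sqrt(gx^2 + gy^2)
    if (g > 1e-6 * rng) {
      tt <- c(-gy, gx) / g
      acc <- acc + tcrossprod(tt); used <- used + 1
    }
  }
  expect_equal(unclass(tensor), acc / used, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(tensor, "n_pixels_used"), used)
})

test_that("aligned stripes and white noise bracket the AU range", {
  stripes <- matrix(0.5 + 0.5 * sin(2 * pi * (0:127) / 8), 128, 128,
                    byrow = TRUE)
  r <- image_anisotropy(stripes)
  expect_gt(r$au, 0.95)
  expect_lt(abs(r$orientation_deg - 90), 2)

  set.seed(16)
  noise <- matrix(runif(256 * 256), 256, 256)
  expect_lt(image_anisotropy(noise)$au, 0.10)
})

test_that("AU is invariant to intensity scaling and equivariant to rotation", {
  th <- 30 * pi / 180
  base <- matrix(0.5 + 0.5 * sin(2 * pi * (0:127) / 8), 128, 128,
                 byrow = TRUE)
  r0 <- image_anisotropy(base)
  r_scaled <- image_anisotropy(base * 12.5)
  expect_equal(r_scaled$au, r0$au, tolerance = 1e-12)
  expect_equal(r_scaled$orientation_deg, r0$orientation_deg,
               tolerance = 1e-12)

  # same stripes rotated 30 degrees (synthesized band-limited pattern)
  phase <- outer(0:127, 0:127, function(y, x) x * cos(th) - y * sin(th))
  rot <- 0.5 + 0.5 * sin(2 * pi * phase / 8)
  r30 <- image_anisotropy(rot)
  expect_lt(abs(r30$au - r0$au), 0.05)
  # orientation 90 shifted by +30 wraps to -60 in (-90, 90]
  expect_lt(abs(r30$orientation_deg - (-60)), 2)
})

test_that("hessian variant agrees on strongly oriented patterns", {
  stripes <- matrix(0.5 + 0.5 * sin(2 * pi * (0:127) / 8), 128, 128,
                    byrow = TRUE)
  r <- image_anisotropy(stripes, method = "hessian")
  expect_gt(r$au, 0.9)
  expect_lt(abs(r$orientation_deg - 90), 2)
})

test_that("measured AU tracks generator ground truth across concentrations", {
  res <- t(vapply(c(0, 1, 3, 10, 100), function(conc) {
    f <- generate_fibril_image(192, 192, 20, conc, seed = 4)
    c(truth = f$anisotropy, measured = image_anisotropy(f$image)$au)
  }, c(truth = 0, measured = 0)))
  expect_true(all(diff(res[, "measured"]) >= 0))
  expect_true(all(abs(res[, "measured"] - res[, "truth"]) < 0.1))
})

test_that("ROI handling enforces geometry and counts", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_error(roi_nematic_tensor(img, c(50, 50, 30, 30)),
               class = "spatialtime_config_error")
  expect_error(roi_nematic_tensor(img, c(0, 0, 2, 2)),
               class = "spatialtime_config_error")
  expect_error(roi_nematic_tensor(matrix(0.5, 32, 32)),
               class = "spatialtime_insufficient_signal_error")
  expect_error(image_anisotropy(img, replicate(9, c(0, 0, 8, 8),
                                               simplify = FALSE)),
               class = "spatialtime_config_error")
  expect_warning(image_anisotropy(img, list(c(0, 0, 32, 32),
                                            c(16, 16, 32, 32))),
                 "overlap")

  rois <- data.frame(roi_id = c("a", "b"), x0 = c(0, 32), y0 = c(0, 0),
                     width = 32, height = 64)
  res <- image_anisotropy(img, rois)
  expect_identical(res$roi_id, c("a", "b"))
  expect_equal(attr(res, "mean_au"), mean(res$au))
})
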