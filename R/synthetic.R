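# Synthetic-data generators. These emulate the study inputs end to end:
# a spot lattice with a compact disk-shaped anlagen region, cell-type
# prediction-score fields (macrophage-like high inside the region,
# MPC-like peaking at its perimeter), count gradients with
# negative-binomial noise (a Thbs1-like gene decreasing along
# SpatialTime, a Thbs2-like gene peaking before decreasing again), and
# fibril images with a controllable orientation concentration. All
# generators are deterministic given their seed, and each gene or cell
# type draws from its own derived sub-stream so adding one does not
# perturb the others.

#' Gradient specification along the SpatialTime axis
#'
#' Describes the expected value of a quantity (counts or a score) as a
#' function of SpatialTime s in [0, 1]:
#' `decreasing`: baseline + amplitude * exp(-(s / width)^2);
#' `peaked`: baseline + amplitude * exp(-((s - peak_position) / width)^2);
#' `flat`: baseline. An amplitude of 0 forces a constant mean at the
#' baseline for every shape.
#'
#' @param shape `"decreasing"`, `"peaked"` or `"flat"`.
#' @param amplitude expected extra value at the gradient's extremum
#'   (>= 0).
#' @param baseline expected value far from the region (>= 0).
#' @param peak_position SpatialTime of the maximum; required (and only
#'   allowed) for `shape = "peaked"`.
#' @param width gradient length-scale on the SpatialTime axis (> 0).
#' @param dispersion negative-binomial dispersion theta (> 0; variance
#'   mu + mu^2 / theta). Only used by the count generator.
#' @return object of class `gradient_spec`.
#' @export
gradient_spec <- function(shape, amplitude, baseline, peak_position = NULL,
                          width = 0.2, dispersion = 10) {
  if (!is.character(shape) || length(shape) != 1L ||
      !shape %in% c("decreasing", "peaked", "flat"))
    stopf("unknown gradient shape '%s'", paste(shape, collapse = ","),
          class = "spatialtime_config_error")
  check_scalar_number(amplitude, "amplitude", 0)
  check_scalar_number(baseline, "baseline", 0)
  check_scalar_number(width, "width", 0, strict_lower = TRUE)
  check_scalar_number(dispersion, "dispersion", 0, strict_lower = TRUE)
  if (shape == "peaked") {
    if (is.null(peak_position))
      stopf("peak_position is required for shape = 'peaked'",
            class = "spatialtime_config_error")
    check_scalar_number(peak_position, "peak_position", 0, 1)
  } else if (!is.null(peak_position)) {
    stopf("peak_position is only meaningful for shape = 'peaked'",
          class = "spatialtime_config_error")
  }
  structure(list(shape = shape, amplitude = amplitude, baseline = baseline,
                 peak_position = peak_position, width = width,
                 dispersion = dispersion),
            class = "gradient_spec")
}

#' Evaluate a gradient's mean function
#'
#' @param spec a [gradient_spec()].
#' @param s SpatialTime values in [0, 1].
#' @return expected value at each `s`.
#' @export
gradient_mean <- function(spec, s) {
  stopifnot(inherits(spec, "gradient_spec"))
  switch(spec$shape,
    flat = rep(spec$baseline, length(s)),
    decreasing = spec$baseline + spec$amplitude * exp(-(s / spec$width)^2),
    peaked = spec$baseline + spec$amplitude *
      exp(-((s - spec$peak_position) / spec$width)^2))
}

#' Spot-lattice layout specification
#'
#' A rectangular lattice of spots (`grid_nx` x `grid_ny`, spaced
#' `pixel_pitch` pixels) with a disk-shaped marked region that must lie
#' fully inside the lattice bounding box.
#'
#' @param grid_nx,grid_ny lattice dimensions (spots).
#' @param pixel_pitch spacing between spot centers, pixels (> 0).
#' @param region_center `c(x, y)` disk center in pixels.
#' @param region_radius disk radius in pixels (>= 0; 0 marks the single
#'   pixel at the center).
#' @param seed integer RNG seed carried to the generators.
#' @return object of class `layout_spec`.
#' @export
layout_spec <- function(grid_nx, grid_ny, pixel_pitch, region_center,
                        region_radius, seed = 1L) {
  check_scalar_number(grid_nx, "grid_nx", 1)
  check_scalar_number(grid_ny, "grid_ny", 1)
  check_scalar_number(pixel_pitch, "pixel_pitch", 0, strict_lower = TRUE)
  check_scalar_number(region_radius, "region_radius", 0)
  xmax <- (grid_nx - 1) * pixel_pitch
  ymax <- (grid_ny - 1) * pixel_pitch
  cx <- region_center[1L]; cy <- region_center[2L]
  if (cx - region_radius < 0 || cx + region_radius > xmax ||
      cy - region_radius < 0 || cy + region_radius > ymax)
    stopf("region (center %g,%g radius %g) extends outside the lattice bounding box [0,%g] x [0,%g]",
          cx, cy, region_radius, xmax, ymax,
          class = "spatialtime_config_error")
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 pixel_pitch = pixel_pitch,
                 region_center = c(cx, cy), region_radius = region_radius,
                 seed = as.integer(seed)),
            class = "layout_spec")
}

#' Generate a spot lattice and region mask from a layout spec
#'
#' One spot per lattice node (row-major ids `spot_0001`, ...), and a
#' binary raster covering the lattice in which pixels whose centers lie
#' within `region_radius` of the disk center are positive (the rounded
#' center pixel is always marked, so the region is never empty).
#'
#' @param spec a [layout_spec()].
#' @return list with elements `spots` (a counts-free [spot_table]) and
#'   `region` (a [region_mask]).
#' @export
generate_layout <- function(spec) {
  stopifnot(inherits(spec, "layout_spec"))
  xs <- (seq_len(spec$grid_nx) - 1L) * spec$pixel_pitch
  ys <- (seq_len(spec$grid_ny) - 1L) * spec$pixel_pitch
  grid <- expand.grid(x = xs, y = ys)
  spots <- data.frame(
    spot_id = sprintf("spot_%04d", seq_len(nrow(grid))),
    x = grid$x, y = grid$y, stringsAsFactors = FALSE)
  width <- as.integer(floor(max(xs))) + 1L
  height <- as.integer(floor(max(ys))) + 1L
  px <- 0:(width - 1L); py <- 0:(height - 1L)
  d2 <- outer((py - spec$region_center[2L])^2,
              (px - spec$region_center[1L])^2, "+")
  raster <- d2 <= spec$region_radius^2
  raster[round(spec$region_center[2L]) + 1L,
         round(spec$region_center[1L]) + 1L] <- TRUE
  list(spots = spot_table(spots), region = region_mask(raster))
}

#' Generate per-spot cell-type prediction scores
#'
#' Evaluates each cell type's gradient profile at the spots'
#' SpatialTime, adds Gaussian noise, and clips to [0, 1] (the clipping
#' bias near the bounds is accepted and documented). Each cell type
#' uses its own RNG sub-stream derived from `seed` and the cell-type
#' name.
#'
#' @param layout result of [generate_layout()] (or a list with `spots`
#'   and `region`).
#' @param celltype_specs named list of [gradient_spec()]s, values on the
#'   score scale (baseline + amplitude should stay within [0, 1] for an
#'   unclipped mean).
#' @param noise_sd Gaussian score noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param signed use signed interior distances for the SpatialTime axis?
#' @return data.frame with `spot_id` and one score column per cell type.
#' @export
generate_prediction_scores <- function(layout, celltype_specs,
                                       noise_sd = 0.05, seed = 1L,
                                       signed = FALSE) {
  check_scalar_number(noise_sd, "noise_sd", 0)
  st <- spatialtime_scores(layout$spots, layout$region, signed = signed)
  out <- data.frame(spot_id = st$spot_id, stringsAsFactors = FALSE)
  for (nm in names(celltype_specs)) {
    spec <- celltype_specs[[nm]]
    mu <- gradient_mean(spec, st$spatialtime)
    set.seed(derive_seed(seed, paste0("score:", nm)))
    eps <- if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
    out[[nm]] <- pmin(1, pmax(0, mu + eps))
  }
  out
}

#' Generate a gene-by-spot count matrix with gradient-structured means
#'
#' Counts are negative binomial with mean given by each gene's gradient
#' evaluated at the spot's SpatialTime and variance mu + mu^2 / theta
#' (theta = each gene's `dispersion` field). Per-gene RNG sub-streams are
#' derived from `seed` and the gene name.
#'
#' @param layout result of [generate_layout()].
#' @param spatialtime per-spot SpatialTime values (e.g. from
#'   [spatialtime_scores()]); `NULL` computes unsigned scores from the
#'   layout.
#' @param gene_specs named list of [gradient_spec()]s.
#' @param seed integer seed.
#' @return sparse gene-by-spot integer count matrix
#'   (`Matrix::dgCMatrix`).
#' @export
generate_counts <- function(layout, spatialtime = NULL, gene_specs,
                            seed = 1L) {
  if (is.null(spatialtime))
    spatialtime <- spatialtime_scores(layout$spots, layout$region)
  if (inherits(spatialtime, "spatialtime_scores"))
    spatialtime <- spatialtime$spatialtime
  n <- length(spatialtime)
  rows <- lapply(names(gene_specs), function(nm) {
    spec <- gene_specs[[nm]]
    if (!inherits(spec, "gradient_spec"))
      stopf("gene_specs entries must be gradient_spec objects",
            class = "spatialtime_config_error")
    mu <- gradient_mean(spec, spatialtime)
    set.seed(derive_seed(seed, paste0("gene:", nm)))
    rnbinom(n, size = spec$dispersion, mu = mu)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(gene_specs)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Generate a synthetic fibril image with known orientation order
#'
#' Renders `n_fibers` straight fibers whose orientations are drawn from
#' a wrapped normal on the half-circle around `mean_angle_deg` with
#' standard deviation `1 / sqrt(concentration)` radians
#' (`concentration = 0` gives uniformly random orientations, `Inf`
#' perfect alignment). The ground-truth anisotropy returned with the
#' image is the nematic order parameter of the sampled angles,
#' `sqrt(mean(cos 2t)^2 + mean(sin 2t)^2)` — the exact analogue of the
#' tensor eigenvalue difference the measurement recovers.
#'
#' @param width,height image size in pixels (>= 16).
#' @param mean_angle_deg mean fibril orientation, degrees,
#'   counter-clockwise from +x.
#' @param concentration orientation concentration (>= 0), 1 / sigma^2.
#' @param n_fibers number of fibers rendered.
#' @param noise_sd additive Gaussian intensity noise.
#' @param seed integer seed.
#' @param fiber_length fiber length in pixels. The default,
#'   `1.5 * (width + height)`, makes every fiber span the full field of
#'   view (as collagen fibrils do in tendon SHG fields), so no fiber
#'   end caps lie inside the image.
#' @return list with `image` (matrix, intensities in [0, 1]),
#'   `anisotropy` (ground truth), `orientation_deg` (circular mean of
#'   the sampled angles), `angles_deg`.
#' @export
generate_fibril_image <- function(width, height, mean_angle_deg = 0,
                                  concentration = 10, n_fibers = 300,
                                  noise_sd = 0.02, seed = 1L,
                                  fiber_length = NULL) {
  if (!is.numeric(width) || !is.numeric(height) || width < 16 || height < 16)
    stopf("image dimensions must be >= 16 pixels",
          class = "spatialtime_config_error")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0)
    stopf("`concentration` must be a single number >= 0 (Inf = perfectly aligned)",
          class = "spatialtime_config_error")
  check_scalar_number(noise_sd, "noise_sd", 0)
  width <- as.integer(width); height <- as.integer(height)
  if (is.null(fiber_length)) fiber_length <- 1.5 * (width + height)
  set.seed(derive_seed(seed, "fibrils"))
  mu <- mean_angle_deg * pi / 180
  theta <- if (concentration == 0) {
    runif(n_fibers, -pi / 2, pi / 2)
  } else if (is.infinite(concentration)) {
    rep(mu, n_fibers)
  } else {
    ((mu + rnorm(n_fibers, 0, 1 / sqrt(concentration)) + pi / 2) %% pi) -
      pi / 2
  }
  q_c <- mean(cos(2 * theta)); q_s <- mean(sin(2 * theta))
  truth_au <- sqrt(q_c^2 + q_s^2)
  truth_deg <- atan2(q_s, q_c) / 2 * 180 / pi
  img <- matrix(0, nrow = height, ncol = width)
  cx <- runif(n_fibers, 0, width - 1)
  cy <- runif(n_fibers, 0, height - 1)
  sigma <- 1.2      # Gaussian cross-section width, px
  # tail must decay below the gradient floor before the box truncates it,
  # or the cut edge would contribute spurious axis-aligned gradients
  margin <- 8 * sigma
  half <- fiber_length / 2
  for (i in seq_len(n_fibers)) {
    # y runs down in the array, so a counter-clockwise angle moves -y
    ux <- cos(theta[i]); uy <- -sin(theta[i])
    x0 <- cx[i] - half * ux; x1 <- cx[i] + half * ux
    y0 <- cy[i] - half * uy; y1 <- cy[i] + half * uy
    xs <- max(0, floor(min(x0, x1) - margin)):min(width - 1,
                                                  ceiling(max(x0, x1) + margin))
    ys <- max(0, floor(min(y0, y1) - margin)):min(height - 1,
                                                  ceiling(max(y0, y1) + margin))
    if (length(xs) == 0L || length(ys) == 0L) next
    gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
    # distance from each pixel to the fiber segment; smooth analytic
    # ridge so gradients point exactly across the fiber
    tt <- pmin(fiber_length, pmax(0, (gx - x0) * ux + (gy - y0) * uy))
    d2 <- (gx - (x0 + tt * ux))^2 + (gy - (y0 + tt * uy))^2
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
      exp(-d2 / (2 * sigma^2))
  }
  if (max(img) > 0) img <- img / max(img)
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  img[] <- pmin(1, pmax(0, img))
  list(image = img, anisotropy = truth_au, orientation_deg = truth_deg,
       angles_deg = theta * 180 / pi)
}

#' Write a fibril image as 16-bit TIFF
#'
#' @param fib result of [generate_fibril_image()] or an intensity
#'   matrix in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fibril_image <- function(fib, path) {
  img <- if (is.list(fib)) fib$image else fib
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Simulate the default spatial scene
#'
#' The package's reference synthetic scene: a 50 x 40 spot lattice
#' (2 000 spots, pitch 10 px) with a disk-shaped anlagen (radius 60 px),
#' a macrophage-like prediction-score field high inside the region, an
#' MPC-like field peaking just outside its border, a Thbs1-like gene
#' whose expression is highest at the region and steadily decreases
#' along SpatialTime, and a Thbs2-like gene peaking at SpatialTime 0.30
#' before decreasing again. The SpatialTime axis uses signed interior
#' distances so the region border falls at a positive axis position
#' (returned as ground truth, computed from the realized layout).
#'
#' @param seed integer seed driving every generator sub-stream.
#' @param noise_sd prediction-score noise.
#' @return list with `table` (a [spot_table] with counts and scores),
#'   `region`, `st` (signed [spatialtime_scores]), and `ground_truth`
#'   (list: `border_spatialtime`, `thbs1_shape`, `thbs2_peak`,
#'   `mpc_peak`, `gene_specs`, `celltype_specs`).
#' @export
simulate_scene <- function(seed = 1L, noise_sd = 0.05) {
  spec <- layout_spec(grid_nx = 50, grid_ny = 40, pixel_pitch = 10,
                      region_center = c(150, 200), region_radius = 60,
                      seed = seed)
  layout <- generate_layout(spec)
  st <- spatialtime_scores(layout$spots, layout$region, signed = TRUE)
  border <- (0 - min(st$raw_distance)) /
    (max(st$raw_distance) - min(st$raw_distance))
  celltype_specs <- list(
    macrophage = gradient_spec("decreasing", amplitude = 0.85,
                               baseline = 0.05, width = 0.4),
    mpc = gradient_spec("peaked", amplitude = 0.8, baseline = 0.05,
                        peak_position = border + 0.05, width = 0.1))
  scores <- generate_prediction_scores(layout, celltype_specs,
                                       noise_sd = noise_sd, seed = seed,
                                       signed = TRUE)
  gene_specs <- c(list(
    Thbs1 = gradient_spec("decreasing", amplitude = 20, baseline = 0.5,
                          width = 0.35, dispersion = 10),
    Thbs2 = gradient_spec("peaked", amplitude = 15, baseline = 0.5,
                          peak_position = 0.30, width = 0.12,
                          dispersion = 10)),
    # flat background genes so spot totals are dominated by an
    # expression floor, as in a real panel; keeps the library-size
    # normalization well behaved
    stats::setNames(
      replicate(20, gradient_spec("flat", amplitude = 0, baseline = 5,
                                  dispersion = 10), simplify = FALSE),
      sprintf("bg%02d", 1:20)))
  counts <- generate_counts(layout, st, gene_specs, seed = seed)
  table <- spot_table(layout$spots$spots, counts, scores)
  list(table = table, region = layout$region, st = st,
       ground_truth = list(border_spatialtime = border,
                           thbs1_shape = "decreasing",
                           thbs2_peak = 0.30,
                           mpc_peak = border + 0.05,
                           gene_specs = gene_specs,
                           celltype_specs = celltype_specs))
}
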