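#' Per-spot distance to a marked region
#'
#' The raw "SpatialTime" quantity: for each spot center the minimum
#' Euclidean distance, in pixels, over all positive pixels of the marked
#' region (spot-center to pixel-center). A spot sitting on a positive
#' pixel scores 0. With `signed = TRUE`, spots whose containing pixel is
#' positive instead receive minus their distance to the region's
#' complement, so the region border stays at value 0 while interior
#' spots extend the axis below it — the convention used when profiles
#' are drawn across the anlagen border.
#'
#' @param spots a [spot_table] (or data.frame with `x`, `y`).
#' @param region a [region_mask] with at least one positive pixel.
#' @param signed emit negative distances for interior spots?
#' @return numeric vector of distances, one per spot.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE   # pixel (0,0)
#' sp <- data.frame(spot_id = "s1", x = 3, y = 4)
#' spot_region_distances(sp, region_mask(m))   # 5 (3-4-5 triangle)
#' @export
spot_region_distances <- function(spots, region, signed = FALSE) {
  xy <- spot_xy(spots)
  stopifnot(inherits(region, "region_mask"))
  if (!any(region$raster))
    stopf("region mask has no positive pixel",
          class = "spatialtime_empty_region_error")
  d <- min_dist_to_pixels(xy$x, xy$y, which(region$raster, arr.ind = TRUE))
  if (signed) {
    col <- pmin(pmax(round(xy$x), 0), region$width - 1L) + 1L
    row <- pmin(pmax(round(xy$y), 0), region$height - 1L) + 1L
    interior <- region$raster[cbind(row, col)]
    if (any(interior)) {
      comp <- which(!region$raster, arr.ind = TRUE)
      if (nrow(comp) == 0L) {
        warnf("region covers the whole frame; interior distances left at 0")
      } else {
        d[interior] <- -min_dist_to_pixels(xy$x[interior], xy$y[interior],
                                           comp)
      }
    }
  }
  d
}

# exact minimum over all target pixels, chunked over spots to bound memory
min_dist_to_pixels <- function(x, y, pix_rc) {
  px <- pix_rc[, "col"] - 1
  py <- pix_rc[, "row"] - 1
  n <- length(x)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / length(px)))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d2 <- outer(x[idx], px, "-")^2 + outer(y[idx], py, "-")^2
    # row minima via max.col (C-level), much faster than apply(.., min)
    j <- max.col(-d2, ties.method = "first")
    out[idx] <- sqrt(d2[cbind(seq_along(idx), j)])
  }
  out
}

spot_xy <- function(spots) {
  if (inherits(spots, "spot_table")) spots <- spots$spots
  spots <- as.data.frame(spots)
  if (!all(c("x", "y") %in% names(spots)))
    stopf("spots need x and y columns", class = "spatialtime_format_error")
  spots
}

#' Min-max scale raw distances to the SpatialTime axis
#'
#' Affine map sending the minimum raw distance to 0 ("at the marked
#' region") and the maximum to 1 ("farthest from it"); rank order is
#' preserved. When all distances are equal the axis is degenerate and
#' every spot maps to 0, with a warning.
#'
#' @param raw numeric vector of raw distances (any real values; signed
#'   interior distances are supported).
#' @return numeric vector in [0, 1].
#' @export
scale_distances <- function(raw) {
  if (length(raw) < 1L)
    stopf("need at least one spot", class = "spatialtime_validation_error")
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    warnf("all raw distances equal (%g); SpatialTime set to 0 for all spots",
          rng[1L])
    return(rep(0, length(raw)))
  }
  (raw - rng[1L]) / (rng[2L] - rng[1L])
}

#' Compute SpatialTime scores for a spot table
#'
#' Convenience wrapper: raw distances plus their min-max scaling.
#'
#' @inheritParams spot_region_distances
#' @return an object of class `spatialtime_scores`: a data.frame with
#'   columns `spot_id`, `raw_distance`, `spatialtime`.
#' @export
spatialtime_scores <- function(spots, region, signed = FALSE) {
  xy <- spot_xy(spots)
  raw <- spot_region_distances(spots, region, signed = signed)
  out <- data.frame(spot_id = as.character(xy$spot_id %||%
                                             seq_along(raw)),
                    raw_distance = raw,
                    spatialtime = scale_distances(raw),
                    stringsAsFactors = FALSE)
  class(out) <- c("spatialtime_scores", "data.frame")
  attr(out, "signed") <- signed
  out
}

#' @export
print.spatialtime_scores <- function(x, ...) {
  cat(sprintf(
    "<spatialtime_scores> %d spots, raw distance %.2f..%.2f px%s\n",
    nrow(x), min(x$raw_distance), max(x$raw_distance),
    if (isTRUE(attr(x, "signed"))) " (signed)" else ""))
  print.data.frame(head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more spots\n", nrow(x) - 4L))
  invisible(x)
}
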