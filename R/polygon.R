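#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray-casting test with an explicit on-boundary check: a point
#' whose distance to any polygon edge is below `eps` counts as inside.
#' This fixes the convention used throughout the package — a pixel center
#' lying exactly on the marked region's outline belongs to the region.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param vx,vy polygon vertex coordinates (closing vertex optional).
#' @param eps boundary tolerance in coordinate units.
#' @return logical vector, one entry per point.
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  if (n >= 3L && vx[1L] == vx[n] && vy[1L] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L
  }
  if (n < 3L)
    stopf("polygon needs at least 3 distinct vertices (got %d)", n,
          class = "spatialtime_format_error")
  inside <- logical(length(px))
  on_boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      on_boundary <- on_boundary |
        ((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2 <= eps^2)
    } else {
      on_boundary <- on_boundary | ((px - x1)^2 + (py - y1)^2 <= eps^2)
    }
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * dx / dy
      inside <- xor(inside, crosses & !is.na(xint) & px < xint)
    }
    j <- i
  }
  inside | on_boundary
}

polygon_area <- function(vx, vy) {
  n <- length(vx)
  if (n >= 3L && vx[1L] == vx[n] && vy[1L] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L
  }
  j <- c(n, seq_len(n - 1L))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

#' Rasterize a polygon onto a pixel frame
#'
#' Produces a binary region mask on the image pixel grid: a pixel is
#' positive iff its center (integer coordinates, 0-based, y down) lies
#' inside or on the boundary of the polygon. Polygons extending beyond
#' the frame are clipped with a warning.
#'
#' @param polygon two-column matrix or data.frame of vertex `x`, `y`
#'   coordinates in pixel units (closing vertex optional).
#' @param frame_shape integer vector `c(nrow, ncol)` — frame height and
#'   width in pixels.
#' @return a [region_mask] object.
#' @examples
#' m <- rasterize_polygon(cbind(x = c(0, 4, 0), y = c(0, 0, 4)), c(5, 5))
#' sum(m$raster)  # 15 pixel centers inside or on the triangle
#' @export
rasterize_polygon <- function(polygon, frame_shape) {
  polygon <- as.matrix(polygon)
  if (!is.numeric(polygon) || ncol(polygon) != 2L)
    stopf("`polygon` must be a numeric matrix with columns x, y",
          class = "spatialtime_format_error")
  vx <- polygon[, 1L]; vy <- polygon[, 2L]
  nv <- length(vx)
  if (nv >= 3L && vx[1L] == vx[nv] && vy[1L] == vy[nv]) {
    vx <- vx[-nv]; vy <- vy[-nv]
  }
  if (length(vx) < 3L)
    stopf("degenerate polygon: %d vertices (need >= 3)", length(vx),
          class = "spatialtime_format_error")
  if (polygon_area(vx, vy) == 0)
    stopf("zero-area polygon cannot mark a region",
          class = "spatialtime_empty_region_error")
  nr <- as.integer(frame_shape[1L]); nc <- as.integer(frame_shape[2L])
  if (nr < 1L || nc < 1L)
    stopf("frame_shape must be positive", class = "spatialtime_config_error")
  if (min(vx) < 0 || min(vy) < 0 || max(vx) > nc - 1L || max(vy) > nr - 1L)
    warnf("polygon bounding box exceeds the %d x %d frame; clipping", nr, nc)
  # restrict the scan to the polygon's bounding box
  xs <- max(0L, floor(min(vx))):min(nc - 1L, ceiling(max(vx)))
  ys <- max(0L, floor(min(vy))):min(nr - 1L, ceiling(max(vy)))
  raster <- matrix(FALSE, nrow = nr, ncol = nc)
  if (length(xs) > 0L && length(ys) > 0L && max(vx) >= 0 && max(vy) >= 0 &&
      min(vx) <= nc - 1L && min(vy) <= nr - 1L) {
    grid <- expand.grid(x = xs, y = ys)
    hit <- point_in_polygon(grid$x, grid$y, vx, vy)
    raster[cbind(grid$y[hit] + 1L, grid$x[hit] + 1L)] <- TRUE
  }
  if (!any(raster))
    stopf("polygon covers no pixel center inside the frame",
          class = "spatialtime_empty_region_error")
  region_mask(raster)
}
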