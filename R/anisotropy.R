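# Collagen-fibril alignment from grayscale images via an averaged
# orientation (nematic) tensor, in the spirit of the FibrilTool ImageJ
# macro. Images are matrices [row = y (down), col = x]; ROIs are
# axis-aligned rectangles in 0-based pixel coordinates. Orientations are
# reported in degrees from the +x axis, counter-clockwise with the image
# displayed y-up, mapped into (-90, 90] (180-degree nematic symmetry).

#' Nematic orientation tensor of an image ROI
#'
#' Smooths the ROI with a 3x3 mean prefilter, takes central-difference
#' gradients, and averages the outer product of the per-pixel unit
#' tangent (perpendicular to the intensity gradient) over all pixels
#' whose gradient magnitude exceeds `grad_eps` times the ROI intensity
#' range. The result is symmetric with trace 1; its eigenstructure
#' encodes the mean fibril orientation and the degree of alignment.
#'
#' With `method = "hessian"` the per-pixel tangent is instead taken
#' perpendicular to the dominant eigenvector of the local Hessian (the
#' ridge direction of second-derivative analysis); the gradient form is
#' the default.
#'
#' @param image numeric matrix of intensities (any scale; gradients are
#'   normalized per pixel so intensity scaling is irrelevant).
#' @param roi rectangle `c(x0, y0, width, height)` in 0-based pixels, or
#'   `NULL` for the whole image.
#' @param min_pixels minimum number of usable-gradient pixels.
#' @param grad_eps gradient-magnitude floor, as a fraction of the ROI
#'   intensity range. Pixels below it carry no reliable direction
#'   (background, noise, or flank-cancellation zones between adjacent
#'   fibers) and are excluded; with the unweighted tangent average a
#'   floor of a few percent is essential — near-zero gradients have
#'   numerically arbitrary directions that bias the score toward
#'   isotropy.
#' @param method `"gradient"` (default) or `"hessian"`.
#' @return 2x2 symmetric tensor with attribute `n_pixels_used`.
#' @export
roi_nematic_tensor <- function(image, roi = NULL, min_pixels = 32,
                               grad_eps = 0.05,
                               method = c("gradient", "hessian")) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image))
    stopf("`image` must be a numeric matrix",
          class = "spatialtime_format_error")
  if (is.null(roi)) roi <- c(0, 0, ncol(image), nrow(image))
  roi <- as.numeric(roi)
  x0 <- roi[1L]; y0 <- roi[2L]; w <- roi[3L]; h <- roi[4L]
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(image) || y0 + h > nrow(image))
    stopf("ROI (%g,%g,%gx%g) exceeds the %dx%d image", x0, y0, w, h,
          nrow(image), ncol(image), class = "spatialtime_config_error")
  if (w < 3 || h < 3)
    stopf("ROI must be at least 3x3 pixels",
          class = "spatialtime_config_error")
  sub <- image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)]
  sm <- mean_filter3(sub)
  nr <- nrow(sm); nc <- ncol(sm)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  # x along columns, y along rows (down)
  gx <- (sm[ri, ci + 1L] - sm[ri, ci - 1L]) / 2
  gy <- (sm[ri + 1L, ci] - sm[ri - 1L, ci]) / 2
  rng <- diff(range(sub))
  if (method == "gradient") {
    g <- sqrt(gx^2 + gy^2)
    use <- g > grad_eps * max(rng, .Machine$double.eps)
    tx <- -gy[use] / g[use]
    ty <- gx[use] / g[use]
  } else {
    hxx <- sm[ri, ci + 1L] - 2 * sm[ri, ci] + sm[ri, ci - 1L]
    hyy <- sm[ri + 1L, ci] - 2 * sm[ri, ci] + sm[ri - 1L, ci]
    hxy <- (sm[ri + 1L, ci + 1L] - sm[ri + 1L, ci - 1L] -
            sm[ri - 1L, ci + 1L] + sm[ri - 1L, ci - 1L]) / 4
    hmag <- sqrt(hxx^2 + 2 * hxy^2 + hyy^2)
    use <- hmag > grad_eps * max(rng, .Machine$double.eps)
    # eigenvector of the larger-|lambda| Hessian eigenvalue = across-ridge
    disc <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
    l1 <- (hxx + hyy + disc) / 2
    l2 <- (hxx + hyy - disc) / 2
    lam <- ifelse(abs(l1) >= abs(l2), l1, l2)
    ex <- ifelse(abs(hxy) > 1e-300, hxy, lam - hyy)[use]
    ey <- ifelse(abs(hxy) > 1e-300, lam - hxx, hxy)[use]
    en <- sqrt(ex^2 + ey^2)
    ok <- en > 0
    # tangent is perpendicular to the across-ridge direction
    tx <- (-ey[ok] / en[ok]); ty <- (ex[ok] / en[ok])
  }
  if (length(tx) < min_pixels)
    stopf("ROI (%g,%g,%gx%g): only %d usable pixels (< %d); insufficient signal",
          x0, y0, w, h, length(tx), min_pixels,
          class = "spatialtime_insufficient_signal_error")
  tensor <- matrix(c(mean(tx^2), mean(tx * ty),
                     mean(tx * ty), mean(ty^2)), 2L, 2L)
  attr(tensor, "n_pixels_used") <- length(tx)
  tensor
}

mean_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # replicate-padded 3x3 box filter, separable
  pad_r <- rbind(m[1L, , drop = FALSE], m, m[nr, , drop = FALSE])
  v <- (pad_r[1:nr, , drop = FALSE] + pad_r[2:(nr + 1L), , drop = FALSE] +
        pad_r[3:(nr + 2L), , drop = FALSE]) / 3
  pad_c <- cbind(v[, 1L, drop = FALSE], v, v[, nc, drop = FALSE])
  (pad_c[, 1:nc, drop = FALSE] + pad_c[, 2:(nc + 1L), drop = FALSE] +
     pad_c[, 3:(nc + 2L), drop = FALSE]) / 3
}

#' Anisotropy score and mean orientation from a nematic tensor
#'
#' The anisotropy score is the eigenvalue difference of the trace-1
#' orientation tensor: 0 for isotropic fibrils, 1 for perfect
#' alignment. The orientation is the leading eigenvector's angle, in
#' degrees in (-90, 90]; it is reported as `NA` for an exactly
#' isotropic tensor, where no direction is preferred.
#'
#' @param tensor symmetric positive-semidefinite 2x2 matrix with
#'   trace 1 (from [roi_nematic_tensor()]).
#' @param roi_id identifier carried into the result.
#' @return object of class `anisotropy_result`: a one-row data.frame
#'   with `roi_id`, `au`, `orientation_deg`, `n_pixels_used`.
#' @examples
#' anisotropy_from_tensor(matrix(c(1, 0, 0, 0), 2))   # au = 1, 0 deg
#' @export
anisotropy_from_tensor <- function(tensor, roi_id = "roi1") {
  if (!is.matrix(tensor) || !identical(dim(tensor), c(2L, 2L)) ||
      abs(tensor[1L, 2L] - tensor[2L, 1L]) > 1e-9)
    stopf("tensor must be a symmetric 2x2 matrix",
          class = "spatialtime_validation_error")
  if (abs(sum(diag(tensor)) - 1) > 1e-6)
    stopf("tensor trace must be 1 (got %g)", sum(diag(tensor)),
          class = "spatialtime_validation_error")
  e <- eigen(tensor, symmetric = TRUE)
  if (e$values[2L] < -1e-9)
    stopf("tensor is not positive semidefinite",
          class = "spatialtime_validation_error")
  au <- e$values[1L] - e$values[2L]
  orientation <- if (au < 1e-12) NA_real_ else {
    v <- e$vectors[, 1L]
    # array y runs down; negate for the counter-clockwise convention
    ang <- atan2(-v[2L], v[1L]) * 180 / pi
    ang <- ang %% 180
    if (ang > 90) ang - 180 else ang
  }
  out <- data.frame(roi_id = roi_id, au = au, orientation_deg = orientation,
                    n_pixels_used = attr(tensor, "n_pixels_used") %||%
                      NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("anisotropy_result", "data.frame")
  out
}

#' Per-ROI and image-level anisotropy
#'
#' Runs the nematic-tensor analysis on each region of interest and
#' averages the per-ROI scores (unweighted) into the image-level
#' anisotropy. Three to four ROIs per image is the recommended usage;
#' 1 to 8 are accepted. Overlapping ROIs trigger a warning, not an
#' error.
#'
#' @param image numeric intensity matrix.
#' @param rois data.frame with columns `roi_id` (optional), `x0`, `y0`,
#'   `width`, `height`, or a list of `c(x0, y0, width, height)` vectors.
#' @inheritParams roi_nematic_tensor
#' @return `anisotropy_result` data.frame (one row per ROI) with
#'   attribute `mean_au`.
#' @export
image_anisotropy <- function(image, rois = NULL, min_pixels = 32,
                             grad_eps = 0.05,
                             method = c("gradient", "hessian")) {
  method <- match.arg(method)
  if (is.null(rois)) rois <- list(c(0, 0, ncol(image), nrow(image)))
  if (is.data.frame(rois)) {
    ids <- if ("roi_id" %in% names(rois)) as.character(rois$roi_id)
           else paste0("roi", seq_len(nrow(rois)))
    rois <- lapply(seq_len(nrow(rois)), function(i)
      as.numeric(rois[i, c("x0", "y0", "width", "height")]))
    names(rois) <- ids
  } else if (is.null(names(rois))) {
    names(rois) <- paste0("roi", seq_along(rois))
  }
  if (length(rois) < 1L || length(rois) > 8L)
    stopf("between 1 and 8 ROIs are accepted (got %d)", length(rois),
          class = "spatialtime_config_error")
  if (length(rois) > 1L && any_roi_overlap(rois))
    warnf("some ROIs overlap")
  res <- do.call(rbind, lapply(names(rois), function(id) {
    tensor <- roi_nematic_tensor(image, rois[[id]], min_pixels = min_pixels,
                                 grad_eps = grad_eps, method = method)
    anisotropy_from_tensor(tensor, roi_id = id)
  }))
  class(res) <- c("anisotropy_result", "data.frame")
  attr(res, "mean_au") <- mean(res$au)
  res
}

any_roi_overlap <- function(rois) {
  n <- length(rois)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- rois[[i]]; b <- rois[[j]]
    if (a[1L] < b[1L] + b[3L] && b[1L] < a[1L] + a[3L] &&
        a[2L] < b[2L] + b[4L] && b[2L] < a[2L] + a[4L]) return(TRUE)
  }
  FALSE
}

#' @export
print.anisotropy_result <- function(x, ...) {
  cat(sprintf("<anisotropy_result> %d ROI(s)", nrow(x)))
  if (!is.null(attr(x, "mean_au")))
    cat(sprintf(", image AU = %.3f", attr(x, "mean_au")))
  cat("\n")
  print.data.frame(x)
  invisible(x)
}
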