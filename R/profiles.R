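#' Bin values along the SpatialTime axis
#'
#' Aggregates a per-spot quantity (expression, prediction score, ...)
#' into fixed-width bins of the SpatialTime axis: left-closed intervals
#' of width `bin_width` on [0, 1], the last bin closed on the right.
#' Each bin carries its spot count, mean, and standard error of the
#' mean (sample sd, n - 1 denominator; undefined for single-spot bins).
#' The default width 0.01 gives exactly 100 bins.
#'
#' @param values numeric vector, one value per spot.
#' @param spatialtime SpatialTime scores in [0, 1], aligned with
#'   `values` (a `spatialtime_scores` object is also accepted).
#' @param bin_width bin width; must divide 1 into a whole number of
#'   bins.
#' @return an object of class `binned_profile`: the per-bin table in
#'   `$bins` (columns `bin_left`, `bin_right`, `center`, `n`, `mean`,
#'   `se`, `smoothed`), plus the raw spot-level pairs in `$data` (used
#'   for spot-level trend tests).
#' @examples
#' st <- seq(0, 1, length.out = 200)
#' p <- bin_profile(5 - 3 * st + rnorm(200, 0, 0.1), st)
#' p
#' @export
bin_profile <- function(values, spatialtime, bin_width = 0.01) {
  if (inherits(spatialtime, "spatialtime_scores"))
    spatialtime <- spatialtime$spatialtime
  if (length(values) != length(spatialtime))
    stopf("`values` (%d) and `spatialtime` (%d) lengths differ",
          length(values), length(spatialtime),
          class = "spatialtime_validation_error")
  check_scalar_number(bin_width, "bin_width", 0, 1, strict_lower = TRUE)
  nbins <- round(1 / bin_width)
  if (abs(nbins * bin_width - 1) > 1e-9)
    stopf("bin_width %g does not tile [0,1] evenly", bin_width,
          class = "spatialtime_config_error")
  if (any(spatialtime < 0 | spatialtime > 1))
    stopf("spatialtime values must lie in [0, 1]",
          class = "spatialtime_validation_error")
  # left-closed bins; the value 1 falls in the last (right-closed) bin
  bin <- pmin(floor(spatialtime / bin_width) + 1L, nbins)
  n <- tabulate(bin, nbins)
  sums <- vapply(seq_len(nbins), function(i) sum(values[bin == i]), 0)
  mean_ <- ifelse(n > 0, sums / n, NA_real_)
  se <- vapply(seq_len(nbins), function(i) {
    if (n[i] >= 2L) sd(values[bin == i]) / sqrt(n[i]) else NA_real_
  }, 0)
  edges <- seq(0, 1, length.out = nbins + 1L)
  bins <- data.frame(bin_left = edges[-(nbins + 1L)], bin_right = edges[-1L],
                     center = (edges[-(nbins + 1L)] + edges[-1L]) / 2,
                     n = n, mean = mean_, se = se, smoothed = NA_real_)
  structure(list(bins = bins, bin_width = bin_width, window = NA_integer_,
                 data = data.frame(values = values,
                                   spatialtime = spatialtime)),
            class = "binned_profile")
}

#' Smooth a binned profile
#'
#' Default: centered moving average over the nearest `window` non-empty
#' bins (odd windows recommended); endpoint bins use their available
#' one-sided neighborhood, so a window of 1 reproduces the raw bin
#' means. Empty bins are skipped entirely and stay undefined.
#' `method = "loess"` fits a local-linear alternative (span 0.5,
#' weighted by bin counts) for users who prefer a smoother curve.
#'
#' @param binned a [bin_profile()] result.
#' @param window number of non-empty bins in the moving window.
#' @param method `"moving"` (default) or `"loess"`.
#' @return the `binned_profile` with `$bins$smoothed` filled in.
#' @export
smooth_profile <- function(binned, window = 5, method = c("moving", "loess")) {
  stopifnot(inherits(binned, "binned_profile"))
  method <- match.arg(method)
  if (!is.numeric(window) || window < 1)
    stopf("`window` must be >= 1", class = "spatialtime_config_error")
  window <- as.integer(window)
  b <- binned$bins
  ne <- which(b$n > 0L)
  if (length(ne) == 0L)
    stopf("no non-empty bin to smooth", class = "spatialtime_validation_error")
  m <- b$mean[ne]
  sm <- if (method == "moving") {
    h <- (window - 1L) %/% 2L
    k <- length(ne)
    vapply(seq_len(k), function(i)
      mean(m[max(1L, i - h):min(k, i + h)]), 0)
  } else {
    if (length(ne) < 4L) m else {
      fit <- stats::loess(m ~ b$center[ne], weights = b$n[ne],
                          span = 0.5, degree = 1,
                          control = stats::loess.control(surface = "direct"))
      stats::predict(fit)
    }
  }
  binned$bins$smoothed <- NA_real_
  binned$bins$smoothed[ne] <- sm
  binned$window <- window
  binned$smooth_method <- method
  binned
}

#' @export
print.binned_profile <- function(x, ...) {
  ne <- sum(x$bins$n > 0L)
  cat(sprintf(
    "<binned_profile> %d spots in %d bins (width %g), %d non-empty%s\n",
    nrow(x$data), nrow(x$bins), x$bin_width, ne,
    if (all(is.na(x$bins$smoothed))) ""
    else sprintf(", smoothed (window %d)", x$window)))
  invisible(x)
}

#' Plot a binned SpatialTime profile
#'
#' Bin means as a solid blue line, the standard-error band as dotted
#' blue lines, and the smoothed curve in black — the layout used for
#' SpatialTime expression figures.
#'
#' @param x a `binned_profile`.
#' @param ... passed to [plot()].
#' @export
plot.binned_profile <- function(x, ...) {
  b <- x$bins[x$bins$n > 0L, ]
  plot(b$center, b$mean, type = "l", col = "blue",
       xlab = "SpatialTime", ylab = "mean per bin", ...)
  ok <- !is.na(b$se)
  lines(b$center[ok], b$mean[ok] + b$se[ok], col = "blue", lty = 3)
  lines(b$center[ok], b$mean[ok] - b$se[ok], col = "blue", lty = 3)
  if (!all(is.na(b$smoothed))) lines(b$center, b$smoothed, col = "black",
                                     lwd = 2)
  invisible(x)
}

#' Extract gradient features from a smoothed profile
#'
#' Locates the smoothed maximum, tests the spot-level monotone trend
#' (Spearman correlation of value vs SpatialTime on the raw pairs, not
#' the bin means), and classifies the profile direction:
#' `"peaked"` when an interior smoothed maximum exceeds both profile
#' ends by at least `prominence` of the smoothed range; otherwise
#' `"increasing"`/`"decreasing"` by the sign of a significant trend;
#' `"flat"` when the trend is not significant at `alpha`. Each end
#' level is the smoothed maximum over the smoothing-window-many bins at
#' that end (not the single endpoint bin, which may hold very few
#' spots), and the peak must lie strictly between those end windows.
#'
#' @param binned a smoothed [binned_profile] (smoothed with defaults if
#'   not already).
#' @param alpha significance level for the trend test.
#' @param prominence interior-peak prominence threshold, as a fraction
#'   of the smoothed min-max range.
#' @return an object of class `profile_features`: list with
#'   `peak_spatialtime`, `trend_rho`, `trend_p`, `direction`,
#'   `prominence`.
#' @export
profile_features <- function(binned, alpha = 0.05, prominence = 0.1) {
  stopifnot(inherits(binned, "binned_profile"))
  if (all(is.na(binned$bins$smoothed))) binned <- smooth_profile(binned)
  b <- binned$bins[binned$bins$n > 0L, ]
  if (nrow(b) < 3L)
    stopf("need at least 3 non-empty bins (got %d)", nrow(b),
          class = "spatialtime_insufficient_data_error")
  ct <- suppressWarnings(
    cor.test(binned$data$spatialtime, binned$data$values,
             method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate); pval <- ct$p.value
  sm <- b$smoothed
  i_max <- which.max(sm)
  peak <- b$center[i_max]
  rng <- max(sm) - min(sm)
  # end level = smoothed maximum over the `window` bins at each end, so a
  # single noisy endpoint bin cannot manufacture an interior peak; the
  # peak must sit strictly between the two end windows to count
  w <- max(1L, min(binned$window, nrow(b) %/% 3L), na.rm = TRUE)
  ends <- max(sm[seq_len(w)], sm[seq(nrow(b) - w + 1L, nrow(b))])
  interior <- i_max > w && i_max <= nrow(b) - w
  prom <- if (rng > 0 && interior) (sm[i_max] - ends) / rng else 0
  direction <- if (prom >= prominence) "peaked"
    else if (!is.na(pval) && pval < alpha) {
      if (rho > 0) "increasing" else "decreasing"
    } else "flat"
  structure(list(peak_spatialtime = peak, trend_rho = rho, trend_p = pval,
                 direction = direction, prominence = prom, alpha = alpha),
            class = "profile_features")
}

#' @export
print.profile_features <- function(x, ...) {
  cat(sprintf(
    "<profile_features> direction: %s\n  peak at SpatialTime %.3f (prominence %.3f)\n  Spearman rho %.3f, p %.3g\n",
    x$direction, x$peak_spatialtime, x$prominence, x$trend_rho, x$trend_p))
  invisible(x)
}

#' Locate crossings of two SpatialTime profiles
#'
#' Each smoothed profile is min-max scaled to [0, 1] over the bins where
#' both are defined ("relative expression"), then every sign change of
#' their difference across consecutive common bins is located by linear
#' interpolation between bin centers. Tangential touches without a sign
#' change are not crossings; a zero run between opposite signs is
#' resolved to its midpoint.
#'
#' @param a,b smoothed [binned_profile] objects on the same binning.
#' @return numeric vector of crossing locations on the SpatialTime
#'   axis (possibly empty). Identical profiles yield no crossings, with
#'   a warning.
#' @export
crossing_points <- function(a, b) {
  stopifnot(inherits(a, "binned_profile"), inherits(b, "binned_profile"))
  if (nrow(a$bins) != nrow(b$bins))
    stopf("profiles use different binnings",
          class = "spatialtime_validation_error")
  if (all(is.na(a$bins$smoothed))) a <- smooth_profile(a)
  if (all(is.na(b$bins$smoothed))) b <- smooth_profile(b)
  common <- which(!is.na(a$bins$smoothed) & !is.na(b$bins$smoothed))
  if (length(common) < 2L)
    stopf("fewer than 2 bins where both profiles are defined",
          class = "spatialtime_insufficient_data_error")
  minmax <- function(v) {
    r <- range(v)
    if (r[1L] == r[2L]) rep(0, length(v)) else (v - r[1L]) / (r[2L] - r[1L])
  }
  av <- minmax(a$bins$smoothed[common])
  bv <- minmax(b$bins$smoothed[common])
  cen <- a$bins$center[common]
  d <- av - bv
  if (all(d == 0)) {
    warnf("profiles are identical after scaling; no crossings")
    return(numeric(0))
  }
  s <- sign(d)
  nz <- which(s != 0)
  out <- numeric(0)
  if (length(nz) >= 2L) {
    for (k in seq_len(length(nz) - 1L)) {
      p <- nz[k]; q <- nz[k + 1L]
      if (s[p] * s[q] < 0) {
        out <- c(out, if (q == p + 1L)
          cen[p] + d[p] * (cen[q] - cen[p]) / (d[p] - d[q])
        else mean(cen[(p + 1L):(q - 1L)]))  # zero run between signs
      }
    }
  }
  sort(unique(out))
}
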