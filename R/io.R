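#' Binary region mask
#'
#' Container for a manually marked tissue region (e.g. the HO anlagen)
#' rasterized onto the full-resolution image pixel grid. Coordinates are
#' 0-based pixel indices; `y` increases downward (image convention), so
#' `raster[y + 1, x + 1]` addresses pixel `(x, y)`.
#'
#' @param raster logical or 0/1 matrix; `TRUE` marks region pixels.
#' @return an object of class `region_mask` with elements `raster`,
#'   `width`, `height`.
#' @export
region_mask <- function(raster) {
  if (is.numeric(raster)) raster <- raster > 0
  if (!is.matrix(raster) || !is.logical(raster))
    stopf("`raster` must be a logical (or 0/1 numeric) matrix",
          class = "spatialtime_format_error")
  structure(list(raster = raster, width = ncol(raster),
                 height = nrow(raster)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d pixels, %d positive (%.1f%%)\n",
              x$height, x$width, sum(x$raster),
              100 * mean(x$raster)))
  invisible(x)
}

#' Spot table
#'
#' The spatial unit of analysis: spot identifiers and centers in
#' full-resolution pixel coordinates, a gene-by-spot count matrix, and
#' optional per-spot cell-type prediction scores in [0, 1] produced
#' upstream by label transfer.
#'
#' @param spots data.frame with columns `spot_id`, `x`, `y`.
#' @param counts gene-by-spot matrix of non-negative integer counts
#'   (dense or `Matrix` sparse); columns follow the spot order. May be
#'   `NULL` for layout-only tables.
#' @param scores optional data.frame with a `spot_id` column plus one
#'   numeric column per cell type, values in [0, 1], covering every spot.
#' @return an object of class `spot_table`.
#' @export
spot_table <- function(spots, counts = NULL, scores = NULL) {
  spots <- as.data.frame(spots)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(spots)))
    stopf("`spots` must have columns spot_id, x, y",
          class = "spatialtime_format_error")
  spots$spot_id <- as.character(spots$spot_id)
  if (anyDuplicated(spots$spot_id))
    stopf("spot_id values must be unique", class = "spatialtime_format_error")
  if (!is.null(counts)) {
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix")
    if (ncol(counts) != nrow(spots))
      stopf("counts has %d columns but the spot table has %d spots",
            ncol(counts), nrow(spots), class = "spatialtime_format_error")
    v <- counts@x
    if (length(v) && min(v) < 0)
      stopf("counts contain a negative entry (%g)", min(v),
            class = "spatialtime_validation_error")
    if (length(v) && any(v != floor(v)))
      stopf("counts contain a non-integer entry (%g)", v[v != floor(v)][1L],
            class = "spatialtime_validation_error")
    if (is.null(rownames(counts)))
      rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    colnames(counts) <- spots$spot_id
  }
  if (!is.null(scores)) {
    scores <- as.data.frame(scores)
    if (!"spot_id" %in% names(scores))
      stopf("`scores` must have a spot_id column",
            class = "spatialtime_format_error")
    scores$spot_id <- as.character(scores$spot_id)
    if (!setequal(scores$spot_id, spots$spot_id))
      stopf("prediction scores must cover exactly the spots in the table",
            class = "spatialtime_validation_error")
    scores <- scores[match(spots$spot_id, scores$spot_id), , drop = FALSE]
    rownames(scores) <- NULL
    num <- scores[setdiff(names(scores), "spot_id")]
    if (length(num) && (min(unlist(num)) < 0 || max(unlist(num)) > 1))
      stopf("prediction scores must lie in [0, 1]",
            class = "spatialtime_validation_error")
  }
  structure(list(spots = spots, counts = counts, scores = scores),
            class = "spot_table")
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("<spot_table> %d spots", nrow(x$spots)))
  if (!is.null(x$counts)) cat(sprintf(", %d genes", nrow(x$counts)))
  if (!is.null(x$scores))
    cat(sprintf(", scores for: %s",
                paste(setdiff(names(x$scores), "spot_id"), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Read a spot table from disk
#'
#' Reads spot metadata (CSV: `spot_id`, `x`, `y`), a gene-by-spot count
#' matrix in Matrix Market coordinate format with a one-gene-per-line
#' sidecar, and optionally per-spot prediction scores (CSV).
#' `write_spot_table()` followed by `read_spot_table()` is the identity
#' on valid tables.
#'
#' @param csv_path spot metadata CSV.
#' @param mtx_path Matrix Market counts (genes x spots); `NULL` to skip.
#' @param genes_path gene names, one per line; required with `mtx_path`.
#' @param scores_path optional prediction-score CSV.
#' @return a [spot_table].
#' @export
read_spot_table <- function(csv_path, mtx_path = NULL, genes_path = NULL,
                            scores_path = NULL) {
  spots <- read.csv(csv_path, stringsAsFactors = FALSE)
  counts <- NULL
  if (!is.null(mtx_path)) {
    counts <- Matrix::readMM(mtx_path)
    if (ncol(counts) != nrow(spots))
      stopf("dimension mismatch: MTX has %d spot columns, CSV has %d spots",
            ncol(counts), nrow(spots), class = "spatialtime_format_error")
    if (is.null(genes_path))
      stopf("`genes_path` is required when counts are read",
            class = "spatialtime_format_error")
    genes <- readLines(genes_path)
    if (length(genes) != nrow(counts))
      stopf("gene sidecar lists %d genes but MTX has %d rows",
            length(genes), nrow(counts), class = "spatialtime_format_error")
    rownames(counts) <- genes
  }
  scores <- if (!is.null(scores_path))
    read.csv(scores_path, stringsAsFactors = FALSE) else NULL
  spot_table(spots, counts, scores)
}

#' Write a spot table to disk
#'
#' @param x a [spot_table].
#' @param csv_path,mtx_path,genes_path,scores_path output paths; counts
#'   and scores are written only when present and a path is given.
#' @return `x`, invisibly.
#' @rdname read_spot_table
#' @export
write_spot_table <- function(x, csv_path, mtx_path = NULL, genes_path = NULL,
                             scores_path = NULL) {
  stopifnot(inherits(x, "spot_table"))
  write.csv(x$spots, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(x$counts) && !is.null(mtx_path)) {
    Matrix::writeMM(x$counts, mtx_path)
    if (is.null(genes_path))
      stopf("`genes_path` is required when counts are written",
            class = "spatialtime_format_error")
    writeLines(rownames(x$counts), genes_path)
  }
  if (!is.null(x$scores) && !is.null(scores_path))
    write.csv(x$scores, scores_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Read a marked region from GeoJSON or a mask image
#'
#' GeoJSON input (`.json`/`.geojson`) is rasterized onto `frame_shape`
#' with the pixel-center-inside-or-on-boundary rule; only the outer ring
#' of the first (Multi)Polygon is used — the marked anlagen is treated
#' as a simply connected blob, holes are not supported. PNG/TIFF input
#' must be single-channel and is binarized at intensity > 0.
#'
#' @param path GeoJSON polygon or single-channel PNG/TIFF mask.
#' @param frame_shape `c(nrow, ncol)`; required for GeoJSON input.
#' @return a [region_mask].
#' @export
read_region <- function(path, frame_shape = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "geojson")) {
    if (is.null(frame_shape))
      stopf("`frame_shape` is required to rasterize a GeoJSON region",
            class = "spatialtime_config_error")
    poly <- geojson_polygon(path)
    return(rasterize_polygon(poly, frame_shape))
  }
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L)
      stopf("region image must be single-channel (got %d channels)",
            dim(img)[3L], class = "spatialtime_format_error")
    img <- img[, , 1L]
  }
  if (all(img == 0))
    stopf("region image contains no positive pixel",
          class = "spatialtime_empty_region_error")
  region_mask(img > 0)
}

geojson_polygon <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1L]]
  if (identical(g$type, "Feature")) g <- g$geometry
  coords <- switch(g$type %||% "",
    Polygon = g$coordinates[[1L]],
    MultiPolygon = g$coordinates[[1L]][[1L]],
    stopf("GeoJSON geometry type '%s' is not a polygon", g$type %||% "?",
          class = "spatialtime_format_error"))
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
  colnames(m) <- c("x", "y")
  m
}

#' Write a region mask as PNG, or a polygon as GeoJSON
#'
#' @param x a [region_mask] (PNG) or a two-column vertex matrix (GeoJSON).
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_region <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "geojson")) {
    m <- as.matrix(x)
    ring <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
    ring <- c(ring, ring[1L])
    jsonlite::write_json(
      list(type = "Polygon", coordinates = list(ring)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    stopifnot(inherits(x, "region_mask"))
    png::writePNG(x$raster * 1.0, path)
  }
  invisible(path)
}
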