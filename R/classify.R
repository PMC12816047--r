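#' Classify spots as cell-type positive or negative
#'
#' Thresholds label-transfer prediction scores: a spot is positive for a
#' cell type when its score is at least `threshold` (ties count as
#' positive by default; set `strict = TRUE` for a strict inequality).
#' The 0.6 default is the cutoff used before any by-label expression
#' analysis. Spots may be positive for several cell types or for none —
#' classification is per cell type, with no forced assignment.
#'
#' @param scores data.frame with a `spot_id` column and one numeric
#'   score column in [0, 1] per cell type, or a [spot_table] carrying
#'   scores.
#' @param threshold positivity cutoff in [0, 1].
#' @param strict require score strictly above the threshold?
#' @return an object of class `spot_labels`: a data.frame of logicals
#'   (one column per cell type) plus `spot_id`, with the threshold
#'   recorded as an attribute.
#' @export
classify_spots <- function(scores, threshold = 0.6, strict = FALSE) {
  if (inherits(scores, "spot_table")) {
    if (is.null(scores$scores))
      stopf("spot table carries no prediction scores",
            class = "spatialtime_validation_error")
    scores <- scores$scores
  }
  scores <- as.data.frame(scores)
  check_scalar_number(threshold, "threshold", 0, 1)
  types <- setdiff(names(scores), "spot_id")
  if (length(types) == 0L)
    stopf("no score columns to classify", class = "spatialtime_format_error")
  vals <- as.matrix(scores[types])
  if (min(vals) < 0 || max(vals) > 1)
    stopf("prediction scores must lie in [0, 1] (found %g)",
          vals[vals < 0 | vals > 1][1L],
          class = "spatialtime_validation_error")
  lab <- as.data.frame(if (strict) vals > threshold else vals >= threshold)
  names(lab) <- types
  out <- cbind(data.frame(spot_id = as.character(scores$spot_id %||%
                                                   seq_len(nrow(scores))),
                          stringsAsFactors = FALSE), lab)
  class(out) <- c("spot_labels", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "strict") <- strict
  out
}

#' @export
print.spot_labels <- function(x, ...) {
  types <- setdiff(names(x), "spot_id")
  cat(sprintf("<spot_labels> %d spots, cutoff %s %.3g\n", nrow(x),
              if (isTRUE(attr(x, "strict"))) ">" else ">=",
              attr(x, "threshold")))
  for (t in types)
    cat(sprintf("  %s: %d positive\n", t, sum(x[[t]])))
  invisible(x)
}

#' Library-size log-normalization of a count matrix
#'
#' Scales each spot's counts to the median spot total, then applies
#' `log1p`. This is a standard library-size normalization standing in
#' for whatever upstream pipeline produced the counts; by-group
#' summaries built on it are comparable in rank and pattern, not in
#' absolute units. Spots with zero total are left at 0 with a warning.
#'
#' @param counts gene-by-spot matrix of non-negative counts (dense or
#'   sparse), or a [spot_table].
#' @return matrix (same class family as the input) of log-normalized
#'   values, with attribute `target_total`.
#' @export
normalize_expression <- function(counts) {
  if (inherits(counts, "spot_table")) counts <- counts$counts
  if (is.null(counts))
    stopf("no counts to normalize", class = "spatialtime_validation_error")
  if (min(counts) < 0)
    stopf("counts must be non-negative", class = "spatialtime_validation_error")
  totals <- Matrix::colSums(counts)
  pos <- totals > 0
  if (!all(pos))
    warnf("%d spot(s) have zero total counts; their values stay 0",
          sum(!pos))
  target <- if (any(pos)) median(totals[pos]) else 0
  scale <- ifelse(pos, target / totals, 0)
  norm <- counts %*% Matrix::Diagonal(x = scale)
  norm <- log1p(norm)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "target_total") <- target
  norm
}

#' Per-group expression summary (dot-plot statistics)
#'
#' For each requested gene and each cell-type label group, the fraction
#' of spots expressing the gene (normalized value > 0) and the mean
#' log-normalized expression — the two quantities a dot plot encodes.
#' Groups with no positive spot are skipped with a warning.
#'
#' @param normalized gene-by-spot matrix from [normalize_expression()].
#' @param labels a `spot_labels` object from [classify_spots()]; each
#'   cell-type column defines the group of its positive spots.
#' @param genes character vector of gene names to summarize.
#' @return data.frame with columns `group`, `gene`, `n_spots`,
#'   `fraction_expressing`, `mean_expression`.
#' @export
group_expression_summary <- function(normalized, labels, genes) {
  stopifnot(inherits(labels, "spot_labels"))
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing))
    stopf("gene(s) not in the matrix: %s", paste(missing, collapse = ", "),
          class = "spatialtime_validation_error")
  types <- setdiff(names(labels), "spot_id")
  rows <- list()
  for (ty in types) {
    sel <- which(labels[[ty]])
    if (length(sel) == 0L) {
      warnf("group '%s' has no positive spot; skipped", ty)
      next
    }
    sub <- as.matrix(normalized[genes, sel, drop = FALSE])
    rows[[ty]] <- data.frame(
      group = ty, gene = genes, n_spots = length(sel),
      fraction_expressing = rowMeans(sub > 0),
      mean_expression = rowMeans(sub),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stopf("every group is empty", class = "spatialtime_validation_error")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
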