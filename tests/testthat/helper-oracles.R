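# Independent oracles and fixture builders used across the suite.

# exhaustive spot-to-region distance: loop over every positive pixel
brute_min_dist <- function(spots, mask) {
  pos <- which(mask$raster, arr.ind = TRUE)
  vapply(seq_len(nrow(spots)), function(i) {
    min(sqrt((pos[, "col"] - 1 - spots$x[i])^2 +
             (pos[, "row"] - 1 - spots$y[i])^2))
  }, 0)
}

random_mask <- function(nr, nc, p = 0.1) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(length(m), 1L)] <- TRUE
  region_mask(m)
}

random_spots <- function(n, nr, nc) {
  data.frame(spot_id = sprintf("s%03d", seq_len(n)),
             x = runif(n, 0, nc - 1), y = runif(n, 0, nr - 1))
}

# simple random star-shaped polygon around a center (non-self-intersecting)
random_polygon <- function(nr, nc, nv = 7) {
  cx <- runif(1, nc * 0.3, nc * 0.7)
  cy <- runif(1, nr * 0.3, nr * 0.7)
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, 0.15, 0.45) * min(nr, nc)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

# per-group dot-plot statistics recomputed the long way
brute_group_summary <- function(normalized, members, genes) {
  do.call(rbind, lapply(genes, function(g) {
    v <- as.numeric(normalized[g, members])
    data.frame(gene = g, fraction_expressing = mean(v > 0),
               mean_expression = mean(v))
  }))
}
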