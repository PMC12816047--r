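# Internal helpers: validation, deterministic sub-seeding, provenance hash.

stopf <- function(fmt, ..., class = "spatialtime_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name,
          class = "spatialtime_config_error")
  if (x < lower || (strict_lower && x == lower) || x > upper)
    stopf("`%s` = %g is outside the allowed range %s%g, %g]", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          class = "spatialtime_config_error")
  invisible(x)
}

#' @noRd
# FNV-1a 32-bit over raw bytes; used to derive per-gene RNG sub-streams and
# the provenance hash written with every pipeline output.
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    # xor on the low 16 bits (bytes are < 256; high half unaffected)
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(h %% 65536), b)
    # 32-bit modular multiply by the FNV prime, split to keep doubles exact
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

hash_chr <- function(x) fnv1a32(utf8ToInt(x))

# Deterministic sub-seed: adding a gene/cell type must not perturb the
# streams of the others, so each name gets its own seed derived from the
# top-level seed and the name alone.  Kept below 2^31 - 1.
derive_seed <- function(seed, name) {
  as.integer(fnv1a32(utf8ToInt(paste0(seed, ":", name))) %% 2147483647)
}

config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, ascii = TRUE, version = 3L)
  h <- fnv1a32(raw)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Bare JSON-ready rounding-free number; jsonlite handles the rest.
`%||%` <- function(a, b) if (is.null(a)) b else a
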