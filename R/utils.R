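# Internal helpers shared across modules.

# Deterministic 32-bit FNV-1a hash of a character string. Used both for
# deriving per-variable RNG substreams and for config fingerprints.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits, so it stays exact in
    # doubles even though h can exceed the signed 32-bit range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619; split h so every
    # intermediate product stays below 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

# Substream seed: mixes the master seed with a variable name so that each
# simulated variable draws from its own reproducible stream. Adding a new
# variable (new name) never perturbs draws of existing ones.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(name) == 1L)
  h <- fnv1a32(paste0(name, ":", format(seed)))
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under the substream RNG, restoring the caller's RNG
# state afterwards so package draws never disturb the user's session.
with_substream <- function(seed, name, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Quartile assignment shared by the diet score and the exposure grouping.
# Cut-points are the empirical 25th/50th/75th percentiles (median-unbiased
# estimator, quantile type 8); intervals are half-open so tied values
# always share a quartile: x < Q1 -> 1, [Q1, Q2) -> 2, [Q2, Q3) -> 3,
# x >= Q3 -> 4. When all values coincide every observation lands in
# quartile 4 (the >= Q3 rule).
quartile_assign <- function(values) {
  if (length(values) == 0L) stop("cannot form quartiles of an empty value list")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop("non-finite value(s) at index ", paste(bad[seq_len(min(5, length(bad)))],
                                                collapse = ", "))
  }
  cuts <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 8, names = FALSE)
  findInterval(values, cuts) + 1L
}

# Column bundles used throughout the pipeline.
hnds_intake_cols <- function() {
  c("fruits_berries", "vegetables", "cereals", "lowfat_milk", "fish",
    "meat_products", "total_fat", "pufa", "sfa", "tfa", "ethanol")
}

hnds_hpl_cols <- function() sprintf("hpl_%02d", 1:18)

require_columns <- function(data, cols, where) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop(where, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
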