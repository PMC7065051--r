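#' Deterministic 32-bit hash of an R object
#'
#' FNV-1a over the deparsed representation of `x`. Used to stamp output files
#' with a short configuration fingerprint so that matrices and tables can be
#' traced back to the run that produced them.
#'
#' @param x Any R object with a stable `deparse()` representation.
#' @return An 8-character lowercase hex string.
#' @export
#' @examples
#' config_hash(list(seed = 1, d = 10))
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  # FNV-1a, 32 bit, carried in doubles (exact: intermediate products are
  # reduced mod 2^32 term-by-term to stay below 2^53)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- mulmod32(h, prime)
  }
  lo <- h %% 65536
  hi <- (h - lo) / 65536
  paste0(sprintf("%04x", hi), sprintf("%04x", lo))
}

bitwXor32 <- function(a, b) {
  # xor of doubles holding 32-bit unsigned values, via 16-bit halves
  a <- a %% 2^32; b <- b %% 2^32
  alo <- a %% 65536; ahi <- a %/% 65536
  blo <- b %% 65536; bhi <- b %/% 65536
  bitwXor(as.integer(ahi), as.integer(bhi)) * 65536 +
    bitwXor(as.integer(alo), as.integer(blo))
}

mulmod32 <- function(a, b) {
  # (a*b) mod 2^32 without losing precision: split a into 16-bit halves
  a <- a %% 2^32
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% 2^16) * 65536 + lo * b) %% 2^32
}

#' Derive a stage-local seed from a global seed
#'
#' Each pipeline stage draws its randomness from its own stream so stages can
#' be rerun independently and in any order without perturbing one another.
#' The derived seed is a deterministic function of the global seed and the
#' stage name, and always fits in a signed 32-bit integer.
#'
#' @param seed Non-negative integer global seed.
#' @param stage Character stage label, e.g. `"ptm"` or `"popsim"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  h <- 2166136261
  for (b in utf8ToInt(as.character(stage))) {
    h <- bitwXor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  m <- 2147483647  # 2^31 - 1, prime
  s <- (seed %% m) * 48271 + (h %% m)
  as.integer(s %% m + 1)
}

#' Provenance header lines for output files
#'
#' Every file the pipeline writes carries a `#` comment header stating the
#' matrix orientation convention, the configuration hash and the seed, so
#' numeric outputs are traceable to the run that produced them.
#'
#' @param hash Configuration hash (see [config_hash()]).
#' @param seed The seed used.
#' @param extra Additional header lines (without the leading `#`).
#' @return Character vector of header lines.
#' @export
provenance_header <- function(hash = NULL, seed = NULL, extra = character()) {
  lines <- c(
    "# stepstone output",
    "# orientation: rows = source/origin, columns = destination",
    if (!is.null(hash)) paste0("# config_hash: ", hash),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (length(extra)) paste0("# ", extra)
  )
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
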