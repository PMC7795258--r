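# Deterministic seed fan-out: a master seed plus a stage label yields a
# reproducible substream seed, so every pipeline stage draws from its own
# stream regardless of execution order.

# 32-bit FNV-1a hash of a character scalar, kept in double space.
fnv1a32 <- function(label) {
  bytes <- utf8ToInt(enc2utf8(label))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply by the FNV prime mod 2^32 without double overflow
    hi <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo16 * 16777619) %% 4294967296
  }
  h
}

#' Derive a labelled substream seed from a master seed
#'
#' Pipeline stages (masking, per-cluster imputation, k-means restarts, ...)
#' each draw from their own random stream. A substream seed is a deterministic
#' function of the master seed and a stage label, so results are reproducible
#' per stage independently of the order in which stages run.
#'
#' @param seed Integer master seed.
#' @param label Character stage label, e.g. `"mask/r3"` or `"mice/cluster2"`.
#' @return A positive integer seed suitable for [set.seed()].
#' @examples
#' rng_substream(42, "mask/r1")
#' rng_substream(42, "mask/r2")
#' @export
rng_substream <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label), length(label) == 1)
  h <- fnv1a32(label)
  s <- (h + (abs(seed) %% 2147483647) * 2654435761) %% 2147483646
  as.integer(s) + 1L
}
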