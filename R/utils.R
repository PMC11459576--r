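#' @importFrom stats sd rnorm rpois rnbinom median wilcox.test t.test
#'   cor.test p.adjust qnorm setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion head
NULL

# geometric mean of strictly positive values
geomMean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# round-half-up at `digits` decimals (base round() is half-to-even)
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

truncateAt <- function(x, digits = 1) {
  m <- 10^digits
  trunc(x * m) / m
}

#' Render a fraction as a percentage
#'
#' Percentages in cohort summaries are rendered at one decimal. The default
#' rounds half up (0.05 rounds to 0.1); a truncate mode is provided because
#' published reports mix conventions (26/35 is sometimes printed 74.2).
#'
#' @param x numeric fraction(s) in \[0, 1\].
#' @param digits decimals to keep (default 1).
#' @param mode `"half_up"` (default) or `"truncate"`.
#' @return numeric percentage(s) on the 0-100 scale.
#' @examples
#' formatPercent(26 / 35)                     # 74.3
#' formatPercent(26 / 35, mode = "truncate")  # 74.2
#' @export
formatPercent <- function(x, digits = 1, mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  p <- 100 * x
  if (mode == "half_up") roundHalfUp(p, digits) else truncateAt(p, digits)
}

# deterministic 32-bit FNV-1a hash of a character scalar, hex string.
# h can exceed 2^31, so the xor and the modular multiply are done on
# doubles (split into 16-bit halves) rather than through bitwXor
fnv1aHash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# seed a per-sample RNG stream; adding later samples never perturbs
# earlier ones because each stream depends only on (seed, index)
sampleStreamSeed <- function(seed, index) {
  as.integer(((seed %% 59999) * 35731 + index * 7919) %% 2147483647)
}
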