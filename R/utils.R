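#' Derive a reproducible sub-seed
#'
#' Stable string hash of a master seed plus stage/replicate labels, so
#' every stage of the pipeline gets its own independent, reproducible RNG
#' stream. The result is always a valid 32-bit seed.
#'
#' @param master master integer seed.
#' @param ... stage names / replicate indices (coerced to character).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# weighted quantile-free helpers used across modules
clip01 <- function(x) pmin(1, pmax(0, x))
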