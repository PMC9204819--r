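#' Derive a reproducible per-stage seed from one global seed
#'
#' All randomness in the package flows from a single integer seed. Each
#' simulation or analysis stage draws from its own named stream so that a
#' stage can be re-run in isolation and still reproduce exactly.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"proteins"`, `"noise"`).
#' @return An integer seed below 2^31, deterministic in `(seed, stage)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# Internal: log2 that tolerates NA and rejects non-positive finite values.
safe_log2 <- function(x) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) stop("non-positive intensities cannot be log2-transformed")
  log2(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
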