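#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats dhyper pchisq t.test setNames
#' @importFrom utils packageVersion
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific child seed (kept below 2^31) from a master seed.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 1009) %% 2147483647
}
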