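# Internal helpers shared across modules.

# let data.table's `[` dispatch with full semantics inside this package
.datatable.aware <- TRUE

#' Derive a reproducible sub-seed from a master seed and arbitrary keys
#'
#' Stable string hashing so that per-unit random streams (for example one
#' stream per participant/word-token/repeat) are reproducible and independent
#' of evaluation order. The result is always a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param ... further keys (coerced to character) identifying the unit.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- digest::digest2int(key)
  as.integer(abs(bitwXor(h, as.integer(master %% 2147483647L))) %% 2147483646L)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_readobs <- function(msg, class, ...) {
  stop(structure(class = c(class, "readobs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
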