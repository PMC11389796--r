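# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of an integer vector (polynomial rolling hash).
# Used for circular-fingerprint identifiers and scaffold keys; stable across
# platforms because all arithmetic stays below 2^53 in doubles.
hash_ints <- function(v) {
  mod <- 2147483647  # 2^31 - 1
  h <- 17
  for (x in as.numeric(v)) {
    h <- (h * 1000003 + (x %% mod)) %% mod
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Package-level instrumentation: model forward/backward call counters, used
# to verify that readout attribution needs exactly one pass of each kind.
.counters <- new.env(parent = emptyenv())
.counters$forward <- 0L
.counters$backward <- 0L

#' Reset the forward/backward call counters
#'
#' The encoder counts full forward and reverse passes so that the cost
#' contract of attribution methods (a single forward and a single backward
#' pass for readout relevance) can be verified empirically.
#' @return Invisibly, the previous counter values.
#' @export
reset_call_counts <- function() {
  prev <- get_call_counts()
  .counters$forward <- 0L
  .counters$backward <- 0L
  invisible(prev)
}

#' Read the forward/backward call counters
#' @return Named integer vector with elements `forward` and `backward`.
#' @export
get_call_counts <- function() {
  c(forward = .counters$forward, backward = .counters$backward)
}

count_forward <- function() .counters$forward <- .counters$forward + 1L
count_backward <- function() .counters$backward <- .counters$backward + 1L
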