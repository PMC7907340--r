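# internal argument checks and RNG helpers

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single finite number")
  }
  if (strict) {
    if (x <= min) stop("`", name, "` must be > ", min)
  } else if (x < min) {
    stop("`", name, "` must be >= ", min)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop("`", name, "` must be a single integer >= ", min)
  }
  invisible(as.integer(x))
}

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_count(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from one root seed; stays well below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  check_count(seed, "seed")
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
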