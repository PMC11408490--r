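# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip values into the unit interval
#' @param x numeric vector
#' @return `x` with values outside `[0, 1]` replaced by the nearest bound.
#' @keywords internal
clip01 <- function(x) pmin(1, pmax(0, x))

#' Derive a stream-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically from
#' a single master seed so that full runs are reproducible end to end. The
#' derived seed stays within the positive 32-bit integer range.
#'
#' @param master integer master seed.
#' @param stream character label of the consuming stage.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  # fold the stream label into the seed with a small rolling hash
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(master) * 7919 + h) %% 2147480009 + 1)
}

# run an expression under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# simple centered moving average, ends padded by shrinking the window
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- width %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

stop_domain <- function(...) stop(..., call. = FALSE)
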