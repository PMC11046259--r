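#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a reproducible child seed < 2^31 from a master seed and a key
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

## index range of a closed time window [w1, w2] on a time axis
window_idx <- function(times, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  idx <- which(times >= window[1] - 1e-12 & times <= window[2] + 1e-12)
  if (!length(idx)) stop("window [", window[1], ", ", window[2],
                         "] does not intersect the time axis")
  idx
}

## moving RMS with a centred rectangular window of `n` samples
moving_rms <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(abs(x))
  csum <- cumsum(c(0, x^2))
  half <- n %/% 2
  len <- length(x)
  lo <- pmax(seq_len(len) - half, 1L)
  hi <- pmin(seq_len(len) + (n - 1L - half), len)
  sqrt((csum[hi + 1L] - csum[lo]) / (hi - lo + 1L))
}

## wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a probability in [0, 1]")
}
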