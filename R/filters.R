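## FIR design and analytic-signal machinery.
##
## The decomposition follows the classic filter-Hilbert scheme: per band a
## linear-phase FIR high-pass (stop edge 0.6*f, pass edge 0.8*f) cascaded with
## a low-pass (pass edge 1.2*f, stop edge 1.4*f), >= 60 dB stop-band
## attenuation, group delay compensated so the output is zero-lag, followed by
## the Hilbert transform. Kernels are Kaiser-windowed sincs; the Kaiser length
## rule is checked against the measured response and lengthened if needed.

kaiser_beta <- function(atten_db) {
  if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
}

kaiser_window <- function(n, beta) {
  m <- seq(0, n - 1)
  x <- beta * sqrt(pmax(0, 1 - (2 * m / (n - 1) - 1)^2))
  besselI(x, 0, expon.scaled = TRUE) * exp(x - beta) / besselI(beta, 0, expon.scaled = TRUE)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## Kaiser-windowed sinc low-/high-pass. f_pass/f_stop in Hz; the cutoff sits
## midway and the length follows the Kaiser estimate for the requested
## attenuation over the transition band, then grows until the measured
## stop-edge response actually reaches the target.
fir_kaiser <- function(fs, f_pass, f_stop, atten_db = 60,
                       type = c("low", "high")) {
  type <- match.arg(type)
  df <- abs(f_stop - f_pass)
  if (df <= 0) stop("transition width must be positive")
  fc <- (f_pass + f_stop) / 2
  if (max(f_pass, f_stop) >= fs / 2) stop("filter edges must lie below Nyquist")
  beta <- kaiser_beta(atten_db)
  ntaps <- ceiling((atten_db - 7.95) / (2.285 * 2 * pi * df / fs)) + 1
  for (trial in 1:6) {
    if (ntaps %% 2 == 0) ntaps <- ntaps + 1
    m <- seq(-(ntaps - 1) / 2, (ntaps - 1) / 2)
    h <- 2 * (fc / fs) * sinc(2 * (fc / fs) * m) * kaiser_window(ntaps, beta)
    h <- h / sum(h)                       # unity DC gain
    if (type == "high") {
      h <- -h
      h[(ntaps + 1) / 2] <- h[(ntaps + 1) / 2] + 1
    }
    f_edge <- if (type == "low") f_stop else f_pass  # stop edge in both cases
    att <- -20 * log10(max(filter_response(h, fs, f_edge), .Machine$double.eps))
    if (att >= atten_db - 0.5) break
    ntaps <- ceiling(ntaps * 1.3)
  }
  h
}

#' Magnitude response of an FIR kernel
#'
#' Direct evaluation of |H(f)| at arbitrary frequencies (no FFT grid snap),
#' used both by the design loop and by the stop-band attenuation tests.
#'
#' @param h FIR coefficients.
#' @param fs sampling rate (Hz).
#' @param freqs frequencies (Hz) at which to evaluate.
#' @return numeric vector of magnitudes (linear gain).
#' @export
filter_response <- function(h, fs, freqs) {
  k <- seq_along(h) - 1
  mag <- vapply(freqs, function(f) {
    w <- -2i * pi * f / fs
    Mod(sum(h * exp(w * k)))
  }, numeric(1))
  mag
}

#' Log-spaced band-pass filter bank
#'
#' Geometric progression of centre frequencies between `f_min` and `f_max`.
#' Each band is the cascade of a Kaiser high-pass (stop edge `stop_lo * f`,
#' pass edge `pass_lo * f`) and low-pass (pass edge `pass_hi * f`, stop edge
#' `stop_hi * f`), each reaching at least `atten_db` stop-band attenuation.
#' Kernels are odd-length and symmetric, so zero-phase application is exact.
#'
#' @param fs sampling rate (Hz).
#' @param f_min,f_max frequency range (Hz); `stop_hi * f_max` must stay below
#'   Nyquist.
#' @param n_bands number of bands (default 30).
#' @param atten_db stop-band attenuation target in dB (default 60).
#' @param pass_lo,pass_hi,stop_lo,stop_hi band-edge multipliers; the stop
#'   multipliers are fixed by the method (0.6 / 1.4), the pass multipliers are
#'   a documented design choice (0.8 / 1.2).
#' @return an object of class `filter_bank`: list with `freqs`, `kernels`
#'   (list of numeric vectors), `fs`, and the edge multipliers.
#' @export
build_filter_bank <- function(fs, f_min = 3, f_max = 480, n_bands = 30,
                              atten_db = 60, pass_lo = 0.8, pass_hi = 1.2,
                              stop_lo = 0.6, stop_hi = 1.4) {
  stopifnot(f_min > 0, f_max > f_min, n_bands >= 1)
  if (stop_hi * f_max >= fs / 2)
    stop("f_max too close to Nyquist: need stop_hi * f_max < fs / 2")
  freqs <- if (n_bands == 1) f_min else
    exp(seq(log(f_min), log(f_max), length.out = n_bands))
  kernels <- lapply(freqs, function(f) {
    hp <- fir_kaiser(fs, f_pass = pass_lo * f, f_stop = stop_lo * f,
                     atten_db = atten_db, type = "high")
    lp <- fir_kaiser(fs, f_pass = pass_hi * f, f_stop = stop_hi * f,
                     atten_db = atten_db, type = "low")
    convolve(hp, rev(lp), type = "open")
  })
  structure(list(freqs = freqs, kernels = kernels, fs = fs,
                 atten_db = atten_db,
                 edges = c(stop_lo = stop_lo, pass_lo = pass_lo,
                           pass_hi = pass_hi, stop_hi = stop_hi)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> ", length(x$freqs), " bands, ",
      signif(min(x$freqs), 3), "-", signif(max(x$freqs), 3), " Hz @ fs ",
      x$fs, " Hz, >=", x$atten_db, " dB stop-band\n", sep = "")
  invisible(x)
}

## padded-FFT linear convolution; x is a time x trials matrix (or vector).
## Returns the "same"-aligned, group-delay-compensated result, optionally as
## the analytic signal (negative frequencies zeroed before the inverse FFT).
fir_apply <- function(x, h, analytic = FALSE) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x); L <- length(h)
  if (L %% 2 != 1) stop("zero-phase application needs an odd-length kernel")
  d <- (L - 1) / 2
  N <- stats::nextn(n + L - 1, c(2, 3, 5))
  H <- stats::fft(c(h, rep(0, N - L)))
  X <- stats::mvfft(rbind(x, matrix(0, N - n, ncol(x))))
  Y <- X * H
  if (analytic) {
    wt <- numeric(N)
    wt[1] <- 1
    if (N %% 2 == 0) { wt[N / 2 + 1] <- 1; wt[2:(N / 2)] <- 2 }
    else wt[2:((N + 1) / 2)] <- 2
    Y <- Y * wt
    out <- stats::mvfft(Y, inverse = TRUE) / N
  } else {
    out <- Re(stats::mvfft(Y, inverse = TRUE)) / N
  }
  out <- out[(d + 1):(d + n), , drop = FALSE]
  if (vec) out[, 1] else out
}

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric vector or time-by-trials matrix.
#' @return complex vector/matrix of the same shape; `Mod()` is the envelope,
#'   `Arg()` the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  X <- stats::mvfft(x)
  wt <- numeric(n)
  wt[1] <- 1
  if (n %% 2 == 0) { wt[n / 2 + 1] <- 1; wt[2:(n / 2)] <- 2 }
  else wt[2:((n + 1) / 2)] <- 2
  out <- stats::mvfft(X * wt, inverse = TRUE) / n
  if (vec) out[, 1] else out
}
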