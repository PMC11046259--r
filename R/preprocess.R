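## LFP cleaning, re-referencing and filter-bank decomposition.

#' Flag trials with large LFP artifacts
#'
#' A trial is flagged iff any sample on any channel exceeds `cutoff_uv` in
#' absolute value (default 1500 uV). Flagged trials are excluded from all
#' downstream analyses.
#'
#' @param recording a [session_recording()].
#' @param cutoff_uv rejection cutoff in uV.
#' @return the recording with its `artifact` flags set, plus attribute
#'   `rejection_fraction`.
#' @export
reject_artifact_trials <- function(recording, cutoff_uv = 1500) {
  mx <- apply(abs(recording$lfp), 2, max)
  flags <- mx > cutoff_uv
  recording$artifact <- flags
  attr(recording, "rejection_fraction") <- mean(flags)
  recording
}

#' Alpha-blend interpolation of stimulus spike artifacts
#'
#' Within a short window around each event (default -2.5 to +1.5 ms around
#' CS onset and CS offset), the trace is replaced by
#' `blend * original + (1 - blend) * L`, where `L` is the straight line
#' joining the samples at the window edges. `blend = 1` leaves the trace
#' unchanged; `blend = 0` is full linear interpolation. Overlapping windows
#' are merged.
#'
#' @param trace numeric vector (one channel, one trial).
#' @param times time axis (s).
#' @param event_times event times (s) to clean around.
#' @param window numeric(2) window around each event (s).
#' @param blend weight of the original signal in `[0, 1]` (default 0.45).
#' @return the cleaned trace.
#' @export
interpolate_stimulus_artifact <- function(trace, times,
                                          event_times = c(0, 0.2),
                                          window = c(-0.0025, 0.0015),
                                          blend = 0.45) {
  stopifnot(length(trace) == length(times), window[1] < window[2])
  n <- length(trace)
  mask <- rep(FALSE, n)
  for (ev in event_times) {
    lo <- ev + window[1]; hi <- ev + window[2]
    if (lo < times[1] || hi > times[n])
      stop("interpolation window around ", ev, " s lies outside the epoch")
    mask <- mask | (times >= lo - 1e-12 & times <= hi + 1e-12)
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- trace
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    a <- max(i0 - 1, 1); b <- min(i1 + 1, n)      # edge anchor samples
    idx <- i0:i1
    L <- trace[a] + (trace[b] - trace[a]) * (idx - a) / (b - a)
    out[idx] <- blend * trace[idx] + (1 - blend) * L
  }
  out
}

## vectorized application across a session: trials x time per channel
interpolate_recording <- function(recording, window = c(-0.0025, 0.0015),
                                  blend = 0.45) {
  evs <- c(recording$events$cs_on, recording$events$cs_off)
  for (ci in seq_along(recording$channels))
    for (tr in seq_len(dim(recording$lfp)[2]))
      recording$lfp[ci, tr, ] <- interpolate_stimulus_artifact(
        recording$lfp[ci, tr, ], recording$times, evs, window, blend)
  recording
}

#' Laplacian (CSD) re-referencing of an electrode bundle
#'
#' Second spatial difference across adjacent contacts,
#' `out_i = V_{i-1} - 2 V_i + V_{i+1}` (contact spacing treated as unit);
#' edge contacts have no neighbours and are dropped. Any spatially common
#' signal (including a linear depth gradient) is annihilated exactly, which
#' makes the result reference-free.
#'
#' @param v numeric matrix `contacts x time` (or `contacts x trials x time`
#'   array), contacts ordered along the bundle.
#' @return matrix/array with `contacts - 2` interior contacts.
#' @export
csd_rereference <- function(v) {
  d <- dim(v)
  if (is.null(d) || d[1] < 3)
    stop("CSD re-referencing needs at least 3 contacts in the bundle")
  if (length(d) == 2)
    return(v[1:(d[1] - 2), , drop = FALSE] - 2 * v[2:(d[1] - 1), , drop = FALSE] +
             v[3:d[1], , drop = FALSE])
  if (length(d) == 3) {
    out <- v[1:(d[1] - 2), , , drop = FALSE] - 2 * v[2:(d[1] - 1), , , drop = FALSE] +
      v[3:d[1], , , drop = FALSE]
    return(out)
  }
  stop("v must be a contacts x time matrix or contacts x trials x time array")
}

#' Filter-bank decomposition into analytic signals
#'
#' Per band: zero-phase FIR band-pass (see [build_filter_bank()]) followed by
#' the Hilbert transform, computed jointly in the frequency domain on the
#' zero-padded epoch. Returns phase and amplitude carriers for all
#' downstream metrics. The first and last `max(kernel length / 2, one cycle
#' of f_k)` samples of each band are recorded as edge-unreliable.
#'
#' @param recording a [session_recording()] (artifact trials should already
#'   be flagged; they are excluded unless `keep_artifacts = TRUE`).
#' @param bank a [build_filter_bank()] object with `bank$fs == recording$fs`.
#' @param channels channels to decompose (default all).
#' @param keep_artifacts include artifact-flagged trials.
#' @return named list (per channel) of `analytic_tfr` objects: complex array
#'   `coef[band, trial, time]`, plus `freqs`, `times`, `fs`, `trials` (the
#'   original trial indices), and `edge_guard` (samples per band).
#' @export
decompose <- function(recording, bank, channels = NULL,
                      keep_artifacts = FALSE) {
  stopifnot(inherits(bank, "filter_bank"))
  if (abs(bank$fs - recording$fs) > 1e-9)
    stop("filter bank was designed for fs = ", bank$fs,
         ", recording has fs = ", recording$fs)
  n_time <- dim(recording$lfp)[3]
  if (n_time < 3 * recording$fs / min(bank$freqs))
    stop("epoch shorter than 3 cycles of the lowest band")
  channels <- channels %||% recording$channels
  keep <- if (keep_artifacts) seq_len(dim(recording$lfp)[2]) else
    which(!recording$artifact)
  if (!length(keep)) stop("no trials left after artifact exclusion")

  Lmax <- max(vapply(bank$kernels, length, integer(1)))
  N <- stats::nextn(n_time + Lmax - 1, c(2, 3, 5))
  wt <- numeric(N); wt[1] <- 1
  if (N %% 2 == 0) { wt[N / 2 + 1] <- 1; wt[2:(N / 2)] <- 2 }
  else wt[2:((N + 1) / 2)] <- 2
  Hs <- lapply(bank$kernels, function(h) stats::fft(c(h, rep(0, N - length(h)))) * wt)
  delays <- vapply(bank$kernels, function(h) (length(h) - 1L) %/% 2L, integer(1))

  out <- list()
  for (ch in channels) {
    ci <- match(ch, recording$channels)
    if (is.na(ci)) stop("unknown channel: ", ch)
    x <- t(matrix(recording$lfp[ci, keep, , drop = FALSE],
                  nrow = length(keep)))          # time x trials
    coef <- array(0i, c(length(bank$freqs), length(keep), n_time))
    blocks <- split(seq_len(ncol(x)), ceiling(seq_len(ncol(x)) / 64))
    for (bl in blocks) {
      X <- stats::mvfft(rbind(x[, bl, drop = FALSE],
                              matrix(0, N - n_time, length(bl))))
      for (b in seq_along(bank$freqs)) {
        y <- stats::mvfft(X * Hs[[b]], inverse = TRUE) / N
        d <- delays[b]
        coef[b, bl, ] <- t(y[(d + 1):(d + n_time), , drop = FALSE])
      }
    }
    edge <- pmin(n_time,
                 pmax(delays, ceiling(recording$fs / bank$freqs)))
    out[[ch]] <- structure(
      list(coef = coef, freqs = bank$freqs, times = recording$times,
           fs = recording$fs, channel = ch, trials = keep,
           edge_guard = edge),
      class = "analytic_tfr")
  }
  out
}

#' @export
print.analytic_tfr <- function(x, ...) {
  cat("<analytic_tfr> channel ", x$channel, ": ", length(x$freqs),
      " bands x ", dim(x$coef)[2], " trials x ", dim(x$coef)[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

## phase (radians, (-pi, pi]) and amplitude accessors
#' Extract instantaneous phase from an analytic TFR
#' @param tfr an `analytic_tfr`.
#' @return array `[band, trial, time]` of phases in `(-pi, pi]`.
#' @export
tfr_phase <- function(tfr) Arg(tfr$coef)

#' Extract amplitude envelope from an analytic TFR
#' @param tfr an `analytic_tfr`.
#' @return array `[band, trial, time]` of non-negative amplitudes.
#' @export
tfr_amplitude <- function(tfr) Mod(tfr$coef)
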