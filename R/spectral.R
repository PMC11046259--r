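## Trial-averaged amplitude and intertrial coherence maps.

#' Trial-mean amplitude TFR with baseline correction
#'
#' Mean over trials of the band amplitude envelope, restricted to the
#' analysis window, then per band the mean over the baseline interval is
#' subtracted (raw maps are retained).
#'
#' @param tfr an `analytic_tfr` from [decompose()].
#' @param trials optional subset of trial positions (indices into
#'   `dim(tfr$coef)[2]`).
#' @param analysis_window numeric(2), s (default `[-0.6, 0.6]`).
#' @param baseline numeric(2), s (default `[-0.6, -0.1]`), must lie inside
#'   the analysis window.
#' @return list of class `amplitude_tfr`: `raw` and `corrected` band x time
#'   matrices (uV), `freqs`, `times`, `n_trials`.
#' @export
amplitude_tfr <- function(tfr, trials = NULL,
                          analysis_window = c(-0.6, 0.6),
                          baseline = c(-0.6, -0.1)) {
  if (baseline[1] < analysis_window[1] || baseline[2] > analysis_window[2])
    stop("baseline must lie within the analysis window")
  trials <- trials %||% seq_len(dim(tfr$coef)[2])
  if (length(trials) < 1) stop("empty trial set")
  ti <- window_idx(tfr$times, analysis_window)
  amp <- Mod(tfr$coef[, trials, ti, drop = FALSE])
  raw <- apply(amp, c(1, 3), mean)
  bi <- window_idx(tfr$times[ti], baseline)
  corrected <- raw - rowMeans(raw[, bi, drop = FALSE])
  structure(list(raw = raw, corrected = corrected, freqs = tfr$freqs,
                 times = tfr$times[ti], n_trials = length(trials)),
            class = "amplitude_tfr")
}

#' Intertrial coherence (phase-locking factor)
#'
#' `ITC(f, t) = | mean over trials of exp(i phi(f, t)) |`, in `[0, 1]`.
#' Measures phase-locking of a single site to stimulus onset: evoked
#' (phase-locked) activity raises ITC, induced (random-phase) activity does
#' not. A baseline-corrected variant mirroring [amplitude_tfr()] is
#' included.
#'
#' @inheritParams amplitude_tfr
#' @return list of class `itc_map`: `itc` (band x time, raw), `corrected`,
#'   `freqs`, `times`, `n_trials` (maps from a single trial are flagged
#'   `degenerate`).
#' @export
itc <- function(tfr, trials = NULL, analysis_window = c(-0.6, 0.6),
                baseline = c(-0.6, -0.1)) {
  trials <- trials %||% seq_len(dim(tfr$coef)[2])
  if (length(trials) < 1) stop("empty trial set")
  ti <- window_idx(tfr$times, analysis_window)
  ph <- tfr$coef[, trials, ti, drop = FALSE]
  ph <- ph / pmax(Mod(ph), .Machine$double.xmin)   # unit phasors
  m <- apply(ph, c(1, 3), mean)
  raw <- Mod(m)
  bi <- window_idx(tfr$times[ti], baseline)
  corrected <- raw - rowMeans(raw[, bi, drop = FALSE])
  structure(list(itc = raw, corrected = corrected, freqs = tfr$freqs,
                 times = tfr$times[ti], n_trials = length(trials),
                 degenerate = length(trials) == 1),
            class = "itc_map")
}
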