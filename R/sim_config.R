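#' Configuration for a synthetic TEBC experiment
#'
#' Describes a trace eyeblink conditioning (TEBC) recording experiment:
#' rats x sessions x trials of two-site hippocampal LFP ("fissure", "hilus")
#' plus an eyelid EMG channel, with CS onset at 0 s, CS offset at
#' `cs_duration`, and US onset at `us_onset`. The generator superimposes,
#' on 1/f background noise, the signal families the downstream analysis is
#' designed to detect: a phase-locked (evoked) broadband transient at CS
#' onset whose gain grows across sessions, induced (random-phase) band
#' oscillations, a low-frequency rhythm whose phase modulates a
#' high-frequency amplitude (n:m phase-amplitude coupling), a lagged
#' inter-site oscillation, EMG blink bursts following a per-session learning
#' curve, and occasional large artifacts.
#'
#' @param n_rats,n_sessions,n_trials experiment dimensions (defaults 8 rats,
#'   8 sessions, 60 trials, the standard TEBC protocol).
#' @param fs sampling rate in Hz (default 1000; in vivo systems often store
#'   at 2000, all analyses are rate-agnostic).
#' @param epoch numeric(2), epoch bounds in seconds relative to CS onset.
#'   Must contain `[-0.6, us_onset]` so the baseline and the trace period
#'   both exist.
#' @param cs_duration,trace_duration,us_onset task timing in seconds
#'   (defaults 0.2, 0.5, 0.7: 200 ms CS, 500 ms stimulus-free trace, US).
#' @param hr_curve per-session probability of a conditioned response (CR);
#'   length `n_sessions`, values in `[0, 1]`. Default: linear 0.1 to 0.8,
#'   an acquisition curve typical of rats over eight sessions.
#' @param evoked list: `gain` (uV, peak of the CS-onset transient on the
#'   fissure), `hilus_gain` (relative gain on the hilus), `freq` (Hz, centre
#'   of the damped wavelet), `decay` (s, amplitude e-folding time),
#'   `session_scaling` (length `n_sessions` multiplier; default linear 0.3
#'   to 1, the consolidation effect). Set `gain = 0` to disable.
#' @param induced_effects list of induced oscillation effects, each a list
#'   with `freq` (Hz), `window` (numeric(2), s), `channel` ("fissure" or
#'   "hilus"), `amplitude` (uV), `condition` one of `"all"` (every trial),
#'   `"cr"` (added on CR trials only), `"cr_relative"` (mean-preserving CR
#'   modulation: CR trials get `base + amplitude * (1 - HR_s)`, no-CR trials
#'   `base - amplitude * HR_s`, so the session-average injected amplitude is
#'   constant across sessions), and optionally `base` (uV, defaults to
#'   `amplitude`). Phases are random per trial, so induced effects raise
#'   amplitude but not intertrial coherence.
#' @param pac_spec `NULL` or list: `f_low` (Hz), `ratio` (integer n, the HF
#'   carrier sits at `n * f_low`), `m` (modulation depth in `[0, 1]`; the HF
#'   envelope is `1 + m * cos(phi_LF)`), `phase_channel`, `amp_channel`,
#'   `lf_amplitude`, `hf_amplitude` (uV), `window` (s).
#' @param lag_spec `NULL` or list: `freq` (Hz), `lag` (samples at `fs`; the
#'   receiver channel carries a copy delayed by `lag` samples), `source`,
#'   `target` channels, `amplitude` (uV), `window` (s).
#' @param noise list: `exponent` (power-spectral 1/f^exponent slope) and
#'   `rms` (uV).
#' @param artifact_rate per-trial probability of a large (> cutoff)
#'   artifact; default 0.006 matching the 0.6% rejection rate typical of
#'   freely-moving recordings.
#' @param emg list: `baseline_sd` (uV), `burst_amplitude` (in baseline-SD
#'   units, default 8), `burst_duration` (s), `band` (Hz, capped below
#'   Nyquist at generation time).
#' @param seed integer master seed; every stochastic draw derives from it.
#'
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_rats = 8, n_sessions = 8, n_trials = 60,
                       fs = 1000, epoch = c(-1, 1),
                       cs_duration = 0.2, trace_duration = 0.5,
                       us_onset = 0.7,
                       hr_curve = seq(0.1, 0.8, length.out = n_sessions),
                       evoked = list(),
                       induced_effects = default_induced_effects(),
                       pac_spec = default_pac_spec(),
                       lag_spec = default_lag_spec(),
                       noise = list(exponent = 1, rms = 50),
                       artifact_rate = 0.006,
                       emg = list(),
                       seed = 1L) {
  ## decay 0.03 s: a shorter (5-10 ms) wavelet leaves too few suprathreshold
  ## samples after band filtering for temporal-adjacency cluster statistics,
  ## which no in-vivo evoked response this method detects would do
  evoked <- utils::modifyList(list(
    gain = 120, hilus_gain = 0.5, freq = 70, decay = 0.03,
    session_scaling = seq(0.3, 1, length.out = n_sessions)), evoked)
  emg <- utils::modifyList(list(
    baseline_sd = 10, burst_amplitude = 8, burst_duration = 0.05,
    band = c(200, 400)), emg)
  noise <- utils::modifyList(list(exponent = 1, rms = 50), noise)

  cfg <- structure(list(
    n_rats = as.integer(n_rats), n_sessions = as.integer(n_sessions),
    n_trials = as.integer(n_trials), fs = fs, epoch = epoch,
    cs_duration = cs_duration, trace_duration = trace_duration,
    us_onset = us_onset, hr_curve = hr_curve, evoked = evoked,
    induced_effects = induced_effects, pac_spec = pac_spec,
    lag_spec = lag_spec, noise = noise, artifact_rate = artifact_rate,
    emg = emg, seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

default_induced_effects <- function() {
  list(
    list(freq = 9, window = c(0.25, 0.55), channel = "fissure",
         amplitude = 30, condition = "cr_relative"),
    list(freq = 18, window = c(0.25, 0.55), channel = "fissure",
         amplitude = 20, condition = "cr_relative"))
}

default_pac_spec <- function() {
  list(f_low = 9, ratio = 8, m = 0.8, phase_channel = "hilus",
       amp_channel = "fissure", lf_amplitude = 40, hf_amplitude = 25,
       window = c(0, 0.6))
}

default_lag_spec <- function() {
  list(freq = 9, lag = 11, source = "hilus", target = "fissure",
       amplitude = 30, window = c(0, 0.6))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_rats >= 1, cfg$n_sessions >= 1, cfg$n_trials >= 1,
            cfg$fs > 0, length(cfg$epoch) == 2, cfg$epoch[1] < cfg$epoch[2])
  if (cfg$epoch[1] > -0.6 || cfg$epoch[2] < cfg$us_onset)
    stop("epoch must contain [-0.6, us_onset]")
  if (length(cfg$hr_curve) != cfg$n_sessions)
    stop("hr_curve must have length n_sessions")
  if (any(cfg$hr_curve < 0 | cfg$hr_curve > 1))
    stop("hr_curve values must lie in [0, 1]")
  stop_if_not_scalar_prob(cfg$artifact_rate, "artifact_rate")
  if (!is.null(cfg$pac_spec)) {
    if (cfg$pac_spec$m < 0 || cfg$pac_spec$m > 1)
      stop("pac modulation depth m must lie in [0, 1]")
    if (cfg$pac_spec$ratio != round(cfg$pac_spec$ratio) || cfg$pac_spec$ratio < 1)
      stop("pac ratio must be a positive integer")
  }
  if (length(cfg$evoked$session_scaling) != cfg$n_sessions)
    stop("evoked$session_scaling must have length n_sessions")
  f_hi <- sim_max_freq(cfg)
  if (f_hi * 2 >= cfg$fs)
    stop("fs must exceed twice the highest synthesized frequency (",
         f_hi, " Hz)")
  invisible(cfg)
}

## highest LFP frequency the config injects (noise and EMG bands are
## synthesized adaptively below Nyquist and therefore excluded)
sim_max_freq <- function(cfg) {
  f <- 0
  if (cfg$evoked$gain > 0) f <- max(f, cfg$evoked$freq)
  for (e in cfg$induced_effects) f <- max(f, e$freq)
  if (!is.null(cfg$pac_spec))
    f <- max(f, cfg$pac_spec$f_low * cfg$pac_spec$ratio)
  if (!is.null(cfg$lag_spec)) f <- max(f, cfg$lag_spec$freq)
  f
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_rats, " rats x ", x$n_sessions, " sessions x ",
      x$n_trials, " trials @ ", x$fs, " Hz, epoch [", x$epoch[1], ", ",
      x$epoch[2], "] s\n", sep = "")
  cat("  HR curve: ", paste(signif(x$hr_curve, 2), collapse = " "), "\n",
      sep = "")
  cat("  effects: evoked gain ", x$evoked$gain, " uV; ",
      length(x$induced_effects), " induced; pac ",
      if (is.null(x$pac_spec)) "off" else
        paste0(x$pac_spec$f_low, " Hz x", x$pac_spec$ratio,
               " m=", x$pac_spec$m),
      "; lag ", if (is.null(x$lag_spec)) "off" else
        paste0(x$lag_spec$freq, " Hz +", x$lag_spec$lag, " smp"),
      "\n", sep = "")
  invisible(x)
}
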