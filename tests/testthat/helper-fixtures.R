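# Shared fixtures; everything is generated in code under fixed seeds.
# Reduced scales (fs 200-500 Hz, few bands) keep the suite inside the
# runtime budget; the generator itself is rate-agnostic.

# small, fast experiment config used by several files
tiny_config <- function(seed = 1, ...) {
  sim_config(n_rats = 2, n_sessions = 2, n_trials = 10, fs = 500,
             epoch = c(-0.8, 0.8), evoked = list(freq = 40),
             hr_curve = c(0.3, 0.7), seed = seed, ...)
}

# null world: nothing injected but 1/f noise (plus EMG machinery)
null_config <- function(seed = 1, ...) {
  sim_config(n_rats = 1, n_sessions = 1, n_trials = 10, fs = 500,
             epoch = c(-0.8, 0.8), evoked = list(gain = 0),
             induced_effects = list(), pac_spec = NULL, lag_spec = NULL,
             artifact_rate = 0, hr_curve = 0.5, seed = seed, ...)
}

# reduced filter bank reused across tests (built once per test run)
test_bank <- local({
  bank <- NULL
  function(fs = 500, f_min = 4, f_max = 80, n_bands = 10) {
    key <- paste(fs, f_min, f_max, n_bands)
    if (is.null(bank) || !identical(attr(bank, "key"), key)) {
      bank <<- build_filter_bank(fs = fs, f_min = f_min, f_max = f_max,
                                 n_bands = n_bands)
      attr(bank, "key") <- key
    }
    bank
  }
})

# analytic_tfr built directly from given phase/amplitude arrays, bypassing
# filtering: handy for exact ITC/PLV cases
tfr_from_phases <- function(phases, amplitudes = NULL, freqs = NULL,
                            fs = 100, t0 = -0.6) {
  # phases: band x trial x time
  amplitudes <- amplitudes %||% array(1, dim(phases))
  structure(list(
    coef = amplitudes * exp(1i * phases),
    freqs = freqs %||% seq_len(dim(phases)[1]),
    times = t0 + (seq_len(dim(phases)[3]) - 1) / fs,
    fs = fs, channel = "synthetic", trials = seq_len(dim(phases)[2]),
    edge_guard = rep(0L, dim(phases)[1])), class = "analytic_tfr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
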