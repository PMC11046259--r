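## Synthetic TEBC session generator with known ground truth.

#' Construct a session recording container
#'
#' @param lfp numeric array `[channel, trial, time]` in uV.
#' @param channels character vector of channel roles (unique); analysis sites
#'   are "fissure" and "hilus".
#' @param emg numeric matrix `[trial, time]` in uV.
#' @param fs sampling rate (Hz).
#' @param epoch numeric(2) epoch bounds (s relative to CS onset).
#' @param events named list/vector with `cs_on`, `cs_off`, `us_on` (s).
#' @param rat,session identifiers.
#' @param artifact optional logical per-trial artifact flags.
#' @return Object of class `session_recording`.
#' @export
session_recording <- function(lfp, channels, emg, fs, epoch, events,
                              rat = 1L, session = 1L, artifact = NULL) {
  stopifnot(length(dim(lfp)) == 3, dim(lfp)[1] == length(channels),
            !anyDuplicated(channels), dim(lfp)[2] == nrow(emg),
            dim(lfp)[3] == ncol(emg))
  n_time <- dim(lfp)[3]
  times <- epoch[1] + (seq_len(n_time) - 1) / fs
  ev <- unlist(events)
  if (any(ev < epoch[1] | ev > epoch[2]))
    stop("event times must lie inside the epoch")
  structure(list(lfp = lfp, channels = channels, emg = emg, fs = fs,
                 epoch = epoch, times = times, events = as.list(ev),
                 rat = rat, session = session,
                 artifact = artifact %||% rep(FALSE, dim(lfp)[2])),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording> rat ", x$rat, " session ", x$session, ": ",
      dim(x$lfp)[2], " trials x ", dim(x$lfp)[3], " samples @ ", x$fs,
      " Hz, channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## cosine-tapered (Tukey-like) gate over a time window
sim_gate <- function(times, window, taper = 0.2) {
  g <- numeric(length(times))
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx)) return(g)
  L <- length(idx)
  r <- max(1L, floor(taper * L))
  ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
  g[idx] <- 1
  g[idx[seq_len(r)]] <- ramp
  g[idx[L + 1 - seq_len(r)]] <- rev(ramp)
  g
}

## 1/f^exponent noise, one column per trial, via spectral shaping of white
## Gaussian noise; unit-variance white input scaled to the target RMS in
## expectation (so realized power fluctuates naturally across trials).
sim_pink_noise <- function(n_time, n_trials, fs, exponent, rms) {
  w <- matrix(stats::rnorm(n_time * n_trials), n_time, n_trials)
  j <- seq_len(n_time) - 1
  f_phys <- pmin(j, n_time - j) * fs / n_time
  s <- c(0, f_phys[-1]^(-exponent / 2))
  scale <- rms / sqrt(mean(s^2))
  Re(stats::mvfft(stats::mvfft(w) * s, inverse = TRUE)) / n_time * scale
}

## unit-RMS stochastic narrow-band oscillation centred at f (raised-cosine
## band mask over [0.7 f, 1.3 f]); phase evolves as a random walk, so it
## carries directed information when copied with a lag
sim_narrowband_noise <- function(n, fs, f, rel_bw = 0.3) {
  w <- stats::rnorm(n)
  fr <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * fs / n
  lo <- (1 - rel_bw) * f; hi <- (1 + rel_bw) * f
  mask <- numeric(n)
  inb <- fr >= lo & fr <= hi
  mask[inb] <- 0.5 * (1 - cos(2 * pi * (fr[inb] - lo) / (hi - lo)))
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n
  x / max(stats::sd(x), .Machine$double.eps)
}

## band-limited noise burst of `n` samples, unit RMS, Hann-gated
sim_burst <- function(n, fs, band) {
  hi <- min(band[2], 0.45 * fs)
  lo <- min(band[1], 0.6 * hi)
  w <- stats::rnorm(n)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * fs / n
  mask <- as.numeric(f >= lo & f <= hi)
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n
  x <- x / max(stats::sd(x), .Machine$double.eps)
  x * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

## per-trial randomized sinusoid a_i * sin(2*pi*f*t + phi_i),
## returned as a time x trials matrix (gating applied by the caller)
sim_rand_phase_osc <- function(times, freq, amps, phis) {
  base <- 2 * pi * freq * times
  (sin(base) %o% (amps * cos(phis))) + (cos(base) %o% (amps * sin(phis)))
}

## Generate all trials of one session. Returns lfp [2, trials, time]
## (fissure, hilus), emg [trials, time], and (optionally) the clean,
## pre-noise components for oracle tests.
sim_session_arrays <- function(cfg, session, cr, artifact, blink_time,
                               keep_components = FALSE) {
  fs <- cfg$fs
  n_time <- round((cfg$epoch[2] - cfg$epoch[1]) * fs)
  times <- cfg$epoch[1] + (seq_len(n_time) - 1) / fs
  ntr <- length(cr)
  chan <- c("fissure", "hilus")
  hr_s <- cfg$hr_curve[session]

  comp <- list()
  lfp <- array(0, c(2, ntr, n_time))

  add <- function(channel, mat) {  # mat: time x trials
    ci <- match(channel, chan)
    lfp[ci, , ] <<- lfp[ci, , ] + t(mat)
  }

  ## --- 1/f background -------------------------------------------------
  for (ci in 1:2)
    lfp[ci, , ] <- t(sim_pink_noise(n_time, ntr, fs, cfg$noise$exponent,
                                    cfg$noise$rms))
  if (keep_components) comp$noise <- lfp

  ## --- evoked broadband transient at CS onset (phase-locked) ----------
  if (cfg$evoked$gain > 0) {
    tt <- times - 0
    ev <- ifelse(tt >= 0,
                 sin(2 * pi * cfg$evoked$freq * tt) * exp(-tt / cfg$evoked$decay),
                 0)
    sc <- cfg$evoked$session_scaling[session] * cfg$evoked$gain
    ev_f <- matrix(ev * sc, n_time, ntr)
    ev_h <- ev_f * cfg$evoked$hilus_gain
    add("fissure", ev_f); add("hilus", ev_h)
    if (keep_components) comp$evoked <- list(fissure = ev * sc,
                                             hilus = ev * sc * cfg$evoked$hilus_gain)
  }

  ## --- induced band-limited oscillations (random phase per trial) -----
  for (e in cfg$induced_effects) {
    gate <- sim_gate(times, e$window)
    base <- e$base %||% e$amplitude
    amps <- switch(e$condition,
      all = rep(e$amplitude, ntr),
      cr = ifelse(cr, e$amplitude, 0),
      cr_relative = ifelse(cr, base + e$amplitude * (1 - hr_s),
                               base - e$amplitude * hr_s),
      stop("unknown induced condition: ", e$condition))
    amps <- pmax(amps, 0)
    phis <- stats::runif(ntr, -pi, pi)
    mat <- sim_rand_phase_osc(times, e$freq, amps, phis) * gate
    add(e$channel, mat)
    if (keep_components)
      comp$induced <- c(comp$induced, list(list(effect = e, mat = mat)))
  }

  ## --- n:m phase-amplitude coupling ------------------------------------
  ## LF: sinusoid with random per-trial phase (a defined phase is needed for
  ## the programmed envelope law). HF: stochastic narrow-band oscillation
  ## at ratio * f_low -- a pure-tone carrier is pathological here, since a
  ## neighbouring wide analysis band then demodulates it single-sideband
  ## with less 1/f noise and outranks the true ratio -- multiplied by the
  ## programmed envelope 1 + m cos(phi_LF).
  if (!is.null(cfg$pac_spec)) {
    p <- cfg$pac_spec
    gate <- sim_gate(times, p$window)
    phi0 <- stats::runif(ntr, -pi, pi)
    base_lf <- 2 * pi * p$f_low * times
    ## phi_LF per trial: base_lf + phi0_i
    lf <- (sin(base_lf) %o% (p$lf_amplitude * cos(phi0))) +
          (cos(base_lf) %o% (p$lf_amplitude * sin(phi0)))
    lf <- lf * gate
    env <- 1 + p$m * ((cos(base_lf) %o% cos(phi0)) - (sin(base_lf) %o% sin(phi0)))
    carrier <- vapply(seq_len(ntr), function(i)
      sim_narrowband_noise(n_time, fs, p$f_low * p$ratio, rel_bw = 0.25),
      numeric(n_time))
    hf <- (p$hf_amplitude / sqrt(2) / (1 + p$m)) * env * carrier * gate
    add(p$phase_channel, lf)
    add(p$amp_channel, hf)
    if (keep_components)
      comp$pac <- list(lf = lf, hf = hf, envelope = env * gate,
                       phi_lf = outer(base_lf, phi0, `+`))
  }

  ## --- lagged inter-site oscillation -----------------------------------
  ## stochastic narrow-band noise (not a pure sinusoid: a deterministic
  ## phase trajectory carries no directed information for phase TE); the
  ## target channel receives the same waveform delayed by `lag` samples
  if (!is.null(cfg$lag_spec)) {
    l <- cfg$lag_spec
    gate <- sim_gate(times, l$window)
    src <- matrix(0, n_time, ntr); tgt <- src
    for (i in seq_len(ntr)) {
      s <- sim_narrowband_noise(n_time + l$lag, fs, l$freq)
      s <- s * (l$amplitude / sqrt(2))          # RMS of a sinusoid of this peak
      src[, i] <- s[(l$lag + 1):(n_time + l$lag)] * gate
      tgt[, i] <- s[seq_len(n_time)] * gate     # tgt(t) = src(t - lag)
    }
    add(l$source, src); add(l$target, tgt)
    if (keep_components) comp$lag <- list(source = src, target = tgt)
  }

  ## --- artifacts --------------------------------------------------------
  for (i in which(artifact)) {
    ci <- sample(1:2, 1)
    t0 <- stats::runif(1, cfg$epoch[1] + 0.05, cfg$epoch[2] - 0.05)
    spike <- sample(c(-1, 1), 1) * 2500 * exp(-abs(times - t0) / 0.003)
    lfp[ci, i, ] <- lfp[ci, i, ] + spike
  }

  ## --- EMG --------------------------------------------------------------
  emg <- matrix(stats::rnorm(ntr * n_time, sd = cfg$emg$baseline_sd),
                ntr, n_time)
  nb <- round(cfg$emg$burst_duration * fs)
  amp <- cfg$emg$burst_amplitude * cfg$emg$baseline_sd
  for (i in seq_len(ntr)) {
    if (cr[i]) {
      i0 <- which.min(abs(times - blink_time[i]))
      idx <- i0:min(i0 + nb - 1, n_time)
      emg[i, idx] <- emg[i, idx] + amp * sim_burst(nb, fs, cfg$emg$band)[seq_along(idx)]
    }
    ## unconditioned response to the US (always present, after us_onset)
    i0 <- which.min(abs(times - (cfg$us_onset + 0.005)))
    nu <- round(1.2 * nb)
    idx <- i0:min(i0 + nu - 1, n_time)
    emg[i, idx] <- emg[i, idx] + 1.5 * amp * sim_burst(nu, fs, cfg$emg$band)[seq_along(idx)]
  }

  list(lfp = lfp, emg = emg, times = times,
       components = if (keep_components) comp else NULL)
}

#' Simulate a single TEBC trial
#'
#' Single-trial entry point, mainly for tests and inspection: returns the
#' two-channel LFP epoch, the EMG epoch, the ground-truth row, and (with
#' `keep_components = TRUE`) every clean, pre-noise injected component so
#' that oracle checks (envelope-phase correlation, cross-correlation lag)
#' can be run on noise-free signals.
#'
#' @param config a [sim_config()].
#' @param cr,artifact logical condition flags for this trial.
#' @param session session index (selects HR and evoked scaling).
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param keep_components return the clean component matrices.
#' @return list with `lfp` (`channel x time`, rows fissure/hilus), `emg`
#'   (vector), `truth` (1-row data.frame), `times`, and `components`.
#' @export
simulate_trial <- function(config, cr = TRUE, artifact = FALSE, session = 1,
                           seed = NULL, keep_components = FALSE) {
  validate_sim_config(config)
  with_seed(seed, {
    blink <- stats::runif(1, 0.5, 0.66)
    arrs <- sim_session_arrays(config, session, cr, artifact, blink,
                               keep_components = keep_components)
    list(lfp = matrix(arrs$lfp[, 1, ], nrow = 2,
                      dimnames = list(c("fissure", "hilus"), NULL)),
         emg = arrs$emg[1, ],
         truth = data.frame(rat = NA_integer_, session = session, trial = 1L,
                            cr = cr, blink_time = if (cr) blink else NA_real_,
                            artifact = artifact),
         times = arrs$times,
         components = arrs$components)
  })
}

#' Simulate a full TEBC experiment
#'
#' Generates `n_rats x n_sessions` session recordings. CR trials are
#' independent Bernoulli draws with per-session probability `hr_curve[s]`;
#' artifact trials are drawn at `artifact_rate`. Every session derives its
#' own child seed from the master seed, so output is bit-identical for a
#' given config regardless of evaluation order.
#'
#' @param config a [sim_config()].
#' @return Object of class `tebc_experiment`: list with `recordings`
#'   (nested list `[[rat]][[session]]` of [session_recording()]), `trials`
#'   (ground-truth trial table: rat, session, trial, cr, blink_time,
#'   artifact), `manifest` (injected-effect manifest) and `config`.
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  recs <- vector("list", config$n_rats)
  rows <- vector("list", config$n_rats * config$n_sessions)
  k <- 0
  for (r in seq_len(config$n_rats)) {
    recs[[r]] <- vector("list", config$n_sessions)
    for (s in seq_len(config$n_sessions)) {
      k <- k + 1
      sd_rs <- child_seed(config$seed, "session", r, s)
      res <- with_seed(sd_rs, {
        cr <- stats::runif(config$n_trials) < config$hr_curve[s]
        artifact <- stats::runif(config$n_trials) < config$artifact_rate
        blink <- stats::runif(config$n_trials, 0.5, 0.66)
        arrs <- sim_session_arrays(config, s, cr, artifact, blink)
        list(arrs = arrs, cr = cr, artifact = artifact, blink = blink)
      })
      recs[[r]][[s]] <- session_recording(
        lfp = res$arrs$lfp, channels = c("fissure", "hilus"),
        emg = res$arrs$emg, fs = config$fs, epoch = config$epoch,
        events = list(cs_on = 0, cs_off = config$cs_duration,
                      us_on = config$us_onset),
        rat = r, session = s, artifact = res$artifact)
      rows[[k]] <- data.frame(
        rat = r, session = s, trial = seq_len(config$n_trials),
        cr = res$cr, blink_time = ifelse(res$cr, res$blink, NA_real_),
        artifact = res$artifact)
    }
  }
  structure(list(recordings = recs, trials = do.call(rbind, rows),
                 manifest = sim_manifest(config), config = config),
            class = "tebc_experiment")
}

## ground-truth manifest: enumerates every non-noise component injected
sim_manifest <- function(cfg) {
  list(
    evoked = if (cfg$evoked$gain > 0) cfg$evoked,
    induced = cfg$induced_effects,
    pac = cfg$pac_spec,
    lag = cfg$lag_spec,
    noise = cfg$noise,
    artifact_rate = cfg$artifact_rate,
    hr_curve = cfg$hr_curve)
}

#' @export
print.tebc_experiment <- function(x, ...) {
  cat("<tebc_experiment> ", x$config$n_rats, " rats x ",
      x$config$n_sessions, " sessions x ", x$config$n_trials,
      " trials @ ", x$config$fs, " Hz\n", sep = "")
  cat("  true CR fraction: ",
      signif(mean(x$trials$cr), 3), ", artifacts: ",
      sum(x$trials$artifact), "\n", sep = "")
  invisible(x)
}
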