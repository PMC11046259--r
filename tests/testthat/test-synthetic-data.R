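# Synthetic TEBC generator: determinism, noise statistics, ground truth.

test_that("same seed gives bit-identical experiments", {
  cfg <- tiny_config(seed = 3)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$recordings[[2]][[1]]$lfp, e2$recordings[[2]][[1]]$lfp)
  expect_identical(e1$recordings[[1]][[2]]$emg, e2$recordings[[1]][[2]]$emg)
})

test_that("null config yields stationary 1/f noise with the right slope", {
  cfg <- null_config(seed = 5)
  cfg$n_trials <- 40L
  exp <- simulate_experiment(cfg)
  rec <- exp$recordings[[1]][[1]]
  # power-spectral slope on log-log regression over 3-100 Hz
  fs <- rec$fs; nt <- dim(rec$lfp)[3]
  spec <- 0
  for (i in seq_len(40)) spec <- spec + Mod(stats::fft(rec$lfp[1, i, ]))^2
  f <- (seq_len(nt) - 1) * fs / nt
  keep <- f >= 3 & f <= 100
  fit <- stats::lm(log10(spec[keep]) ~ log10(f[keep]))
  expect_equal(unname(stats::coef(fit)[2]), -cfg$noise$exponent,
               tolerance = 0.2)
  # stationarity: 9 Hz band amplitude the same pre- and post-CS
  bank <- test_bank()
  tfr <- decompose(rec, bank, channels = "fissure")$fissure
  b <- which.min(abs(bank$freqs - 9))
  amp <- Mod(tfr$coef[b, , ])
  pre <- mean(amp[, rec$times > -0.6 & rec$times < -0.1])
  post <- mean(amp[, rec$times > 0.1 & rec$times < 0.6])
  expect_lt(abs(post - pre) / pre, 0.15)
})

test_that("clean PAC component has the programmed envelope-phase coupling", {
  cfg <- null_config(seed = 8)
  cfg$pac_spec <- list(f_low = 9, ratio = 8, m = 0.8,
                       phase_channel = "hilus", amp_channel = "fissure",
                       lf_amplitude = 40, hf_amplitude = 25,
                       window = c(0, 0.6))
  tr <- simulate_trial(cfg, cr = TRUE, seed = 2, keep_components = TRUE)
  comp <- tr$components$pac
  inwin <- tr$times > 0.1 & tr$times < 0.5     # clear of the gate ramps
  env <- comp$envelope[inwin, 1]
  phi <- comp$phi_lf[inwin, 1]
  expect_gt(stats::cor(env, cos(phi)), 0.7)
  # envelope of the clean HF component tracks 1 + m cos(phi); the HF
  # carrier is stochastic narrow-band noise, so demodulate with a short
  # moving RMS (25 ms) to strip the carrier's own envelope fluctuations
  hf_env <- tebcosc:::moving_rms(comp$hf[, 1], round(0.025 * cfg$fs))[inwin]
  expect_gt(stats::cor(hf_env, 1 + 0.8 * cos(phi)), 0.7)
})

test_that("clean lagged component peaks at the programmed cross-correlation lag", {
  cfg <- null_config(seed = 9)
  cfg$lag_spec <- list(freq = 9, lag = 11, source = "hilus",
                       target = "fissure", amplitude = 30,
                       window = c(0, 0.6))
  tr <- simulate_trial(cfg, cr = TRUE, seed = 4, keep_components = TRUE)
  src <- tr$components$lag$source[, 1]
  tgt <- tr$components$lag$target[, 1]
  inwin <- which(tr$times > 0.12 & tr$times < 0.45)
  cc <- stats::ccf(tgt[inwin], src[inwin], lag.max = 25, plot = FALSE)
  # target is source delayed by +11 samples: peak at lag +11
  expect_equal(cc$lag[which.max(cc$acf)], 11)
})

test_that("artifact trials follow the configured rate", {
  cfg <- sim_config(n_rats = 1, n_sessions = 8, n_trials = 60, fs = 500,
                    epoch = c(-0.8, 0.8), evoked = list(gain = 0),
                    induced_effects = list(), pac_spec = NULL,
                    lag_spec = NULL, artifact_rate = 0.05,
                    hr_curve = rep(0.5, 8), seed = 12)
  exp <- simulate_experiment(cfg)
  n_art <- sum(exp$trials$artifact)
  # 480 trials at rate 0.05: 99% binomial interval
  expect_gte(n_art, stats::qbinom(0.005, 480, 0.05))
  expect_lte(n_art, stats::qbinom(0.995, 480, 0.05))
  # and the flags are exactly recoverable by the 1500 uV rejection rule
  flagged <- unlist(lapply(exp$recordings[[1]], function(r)
    reject_artifact_trials(r)$artifact))
  expect_identical(unname(flagged), exp$trials$artifact)
})

test_that("per-session CR draws follow the programmed learning curve", {
  # binomial coverage at reduced replication (full check in acceptance)
  hr <- seq(0.1, 0.8, length.out = 8)
  inside <- 0; total <- 0
  for (seed in 1:25) {
    cfg <- sim_config(n_rats = 1, n_sessions = 8, n_trials = 60, fs = 500,
                      epoch = c(-0.8, 0.8), evoked = list(gain = 0),
                      induced_effects = list(), pac_spec = NULL,
                      lag_spec = NULL, artifact_rate = 0, hr_curve = hr,
                      seed = seed)
    # draw only the CR flags the way simulate_experiment does
    tr <- simulate_experiment(cfg)$trials
    for (s in 1:8) {
      k <- sum(tr$cr[tr$session == s])
      lo <- stats::qbinom(0.005, 60, hr[s]); hi <- stats::qbinom(0.995, 60, hr[s])
      inside <- inside + (k >= lo && k <= hi)
      total <- total + 1
    }
  }
  expect_gte(inside / total, 0.95)
})

test_that("config validation enforces the stated invariants", {
  expect_error(sim_config(hr_curve = c(0.5, 1.2), n_sessions = 2), "\\[0, 1\\]")
  expect_error(sim_config(epoch = c(-0.4, 1)), "epoch")
  expect_error(sim_config(pac_spec = list(f_low = 9, ratio = 8, m = 1.4,
                                          phase_channel = "hilus",
                                          amp_channel = "fissure",
                                          lf_amplitude = 1, hf_amplitude = 1,
                                          window = c(0, 0.5))), "m must")
  # injected band beyond Nyquist is rejected
  expect_error(sim_config(fs = 100), "Nyquist|highest synthesized")
})
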