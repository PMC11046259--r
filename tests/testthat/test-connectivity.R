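# Interareal PLV, n:m PAC, phase transfer entropy.

# naive_te / rand_walk_phase oracles come from helper-oracles.R

test_that("PLV analytic cases: constant lag gives 1; rotation invariance", {
  nt <- 40; ntr <- 12
  set.seed(61)
  ph_a <- array(stats::runif(ntr * nt, -pi, pi), c(1, ntr, nt))
  ph_b <- ph_a + 0.7
  p <- interareal_plv(tfr_from_phases(ph_a), tfr_from_phases(ph_b),
                      n_shuffles = 10, seed = 1)
  expect_equal(max(abs(p$raw - 1)), 0, tolerance = 1e-12)
  # common rotation and common time shift leave raw PLV unchanged
  p2 <- interareal_plv(tfr_from_phases(ph_a + 1.3),
                       tfr_from_phases(ph_b + 1.3), n_shuffles = 10, seed = 1)
  expect_equal(p2$raw, p$raw, tolerance = 1e-12)
  expect_error(interareal_plv(tfr_from_phases(ph_a[, 1, , drop = FALSE]),
                              tfr_from_phases(ph_b[, 1, , drop = FALSE])),
               "2 trials")
})

test_that("normalized PLV is ~1 for independent channels", {
  set.seed(62)
  nt <- 60; ntr <- 50
  ph_a <- array(stats::runif(ntr * nt, -pi, pi), c(2, ntr, nt))
  ph_b <- array(stats::runif(ntr * nt, -pi, pi), c(2, ntr, nt))
  p <- interareal_plv(tfr_from_phases(ph_a), tfr_from_phases(ph_b),
                      n_shuffles = 100, seed = 3)
  expect_gt(mean(p$normalized), 0.8)
  expect_lt(mean(p$normalized), 1.2)
})

test_that("programmed inter-site lag produces detectable synchrony at 9 Hz", {
  cfg <- null_config(seed = 63)
  cfg$n_trials <- 25L
  cfg$lag_spec <- list(freq = 9, lag = 11, source = "hilus",
                       target = "fissure", amplitude = 40,
                       window = c(0, 0.6))
  exp <- simulate_experiment(cfg)
  bank <- test_bank()
  tfrs <- decompose(exp$recordings[[1]][[1]], bank)
  p <- interareal_plv(tfrs$hilus, tfrs$fissure, n_shuffles = 100, seed = 5,
                      keep_shuffles = TRUE)
  b <- which.min(abs(p$freqs - 9))
  win <- p$times >= 0.1 & p$times <= 0.5
  obs <- mean(p$raw[b, win])
  q95 <- stats::quantile(apply(p$shuffles[, b, win], 1, mean), 0.95)
  expect_gt(obs, q95)
  # and a band far from 9 Hz shows nothing
  b_far <- which.min(abs(p$freqs - 60))
  obs_far <- mean(p$raw[b_far, win])
  q95_far <- stats::quantile(apply(p$shuffles[, b_far, win], 1, mean), 0.95)
  expect_lt(obs_far, q95_far * 1.05)
})

test_that("PAC approaches 1 for a noise-free perfectly coupled pair", {
  # HF envelope = 1 + 0.8 cos(phi_LF) exactly, no noise
  fs <- 250; f <- 9; n <- 4
  epoch <- c(-1, 1)
  nt <- round(diff(epoch) * fs)
  times <- epoch[1] + (seq_len(nt) - 1) / fs
  ntr <- 6
  lfp <- array(0, c(2, ntr, nt))
  set.seed(64)
  for (i in seq_len(ntr)) {
    phi0 <- stats::runif(1, -pi, pi)
    phi <- 2 * pi * f * times + phi0
    lfp[2, i, ] <- 40 * sin(phi)                                   # hilus LF
    lfp[1, i, ] <- 10 * (1 + 0.8 * cos(phi)) * sin(n * phi + 1.1)  # fissure HF
  }
  rec <- session_recording(lfp, c("fissure", "hilus"),
                           emg = matrix(0, ntr, nt), fs = fs, epoch = epoch,
                           events = list(cs_on = 0, cs_off = 0.2,
                                         us_on = 0.7))
  pm <- pac_nm(rec, lf_freqs = f, ratios = n,
               windows = list(c(0.05, 0.55)))
  expect_gt(pm$post[1, 1, "H->F", 1], 0.9)
  # absent HF partner bands are marked NA
  pm2 <- pac_nm(rec, lf_freqs = f, ratios = c(4, 20),
                windows = list(c(0.05, 0.55)))
  expect_true(all(is.na(pm2$post[1, 2, , ])))
})

test_that("PAC at m = 0 is indistinguishable from its pre-stimulus level", {
  kcache <- tebcosc:::pac_kernel_cache()
  set.seed(65)
  diffs <- replicate(25, {
    cfg <- null_config(seed = sample.int(1e6, 1))
    cfg$fs <- 250; cfg$n_trials <- 10L
    cfg$pac_spec <- list(f_low = 9, ratio = 4, m = 0,
                         phase_channel = "hilus", amp_channel = "fissure",
                         lf_amplitude = 40, hf_amplitude = 25,
                         window = c(0, 0.6))
    exp <- simulate_experiment(cfg)
    pm <- pac_nm(exp$recordings[[1]][[1]], lf_freqs = 9, ratios = 4,
                 windows = list(c(0.1, 0.5)), cache = kcache)
    pm$post[1, 1, "H->F", 1] - pm$pre[1, 1, "H->F", 1]
  })
  expect_gt(stats::t.test(diffs)$p.value, 0.05)
})

test_that("programmed PAC recovers its LF frequency and laminar pair", {
  # the ratio coordinate is not identifiable at single-step resolution
  # (neighbouring octave-wide HF bands contain the same coupled
  # oscillation; see the acceptance suite and methods vignette), so the
  # package-level guarantee is on the (LF, pair) marginal of the argmax
  kcache <- tebcosc:::pac_kernel_cache()
  hits <- 0
  n_runs <- 20
  for (i in seq_len(n_runs)) {
    # 30 trials (half a session): at 20 the window-mean estimate is too
    # noisy for a reliable argmax (measured marginal 0.70 vs 0.94 at 30)
    cfg <- sim_config(n_rats = 1, n_sessions = 1, n_trials = 30, fs = 250,
                      epoch = c(-0.8, 0.8), evoked = list(gain = 0),
                      induced_effects = list(), lag_spec = NULL,
                      artifact_rate = 0, hr_curve = 0.5,
                      pac_spec = list(f_low = 9, ratio = 8, m = 0.8,
                                      phase_channel = "hilus",
                                      amp_channel = "fissure",
                                      lf_amplitude = 40, hf_amplitude = 25,
                                      window = c(0, 0.6)),
                      seed = 4300 + i)
    exp <- simulate_experiment(cfg)
    pm <- pac_nm(exp$recordings[[1]][[1]], lf_freqs = c(6, 9, 13),
                 ratios = 2:9, cache = kcache)
    avg <- apply(pm$post, c(1, 2, 3), mean)
    top <- arrayInd(which.max(avg), dim(avg))
    hits <- hits + (top[1] == 2 && top[3] == 2)   # 9 Hz, H->F
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("phase TE matches the naive triple-loop oracle exactly", {
  set.seed(66)
  for (B in c(4, 8)) {
    px <- rbind(rand_walk_phase(900), rand_walk_phase(900))
    py <- rbind(rand_walk_phase(900), rand_walk_phase(900))
    r <- suppressWarnings(phase_te(px, py, delay = 7, n_bins = B))
    # exact up to floating-point summation order
    expect_equal(r$te_xy, naive_te(px, py, 7, B), tolerance = 1e-12)
    expect_equal(r$te_yx, naive_te(py, px, 7, B), tolerance = 1e-12)
  }
})

test_that("dTE is zero for identical signals and antisymmetric under swap", {
  set.seed(67)
  px <- rbind(rand_walk_phase(600))
  r <- suppressWarnings(phase_te(px, px, delay = 5, n_bins = 4))
  expect_equal(r$dte, 0)
  py <- rbind(rand_walk_phase(600))
  a <- suppressWarnings(phase_te(px, py, delay = 5, n_bins = 4))
  b <- suppressWarnings(phase_te(py, px, delay = 5, n_bins = 4))
  expect_equal(a$dte, -b$dte)
  expect_equal(a$te_xy, b$te_yx)
})

test_that("dTE recovers the driver when Y is a delayed copy of X", {
  set.seed(68)
  hits <- replicate(60, {
    d <- 6
    x <- rand_walk_phase(500 + d)
    px <- rbind(x[(1 + d):(500 + d)])     # x runs ahead
    py <- rbind(x[1:500])                 # y(t) = x(t - d): x drives y
    suppressWarnings(phase_te(px, py, delay = d, n_bins = 4))$dte > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("low-sample estimates carry a warning and a flag", {
  set.seed(69)
  px <- rbind(rand_walk_phase(100)); py <- rbind(rand_walk_phase(100))
  expect_warning(r <- phase_te(px, py, delay = 3, n_bins = 8),
                 "low-confidence")
  expect_true(r$low_confidence)
})
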