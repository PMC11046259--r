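## Eyeblink EMG scoring: conditioned responses, hit rates, learning trends.

#' Detect a conditioned response in one EMG epoch
#'
#' The EMG is full-wave rectified and smoothed with a centred moving-RMS
#' window (default 10 ms; a raw-sample rule would fire on single-sample
#' noise). The threshold is the mean + `k_sd` SD of the *rectified raw*
#' pre-CS baseline — thresholding against the smoothed baseline's much
#' smaller SD would fire on a large fraction of pure-noise trials. A trial
#' is scored as a CR if the smoothed trace exceeds the threshold anywhere
#' inside `response_window` (default the last 200 ms of the trace period,
#' `[0.5, 0.7]` s); the reaction time is the first crossing.
#'
#' @param emg numeric vector, one trial of EMG (uV).
#' @param times time axis (s relative to CS onset), same length as `emg`.
#' @param baseline_window numeric(2), pre-CS baseline (default `[-0.6, 0]`).
#' @param response_window numeric(2), CR scoring window (default
#'   `[0.5, 0.7]`).
#' @param smooth_s moving-RMS window length in seconds (default 0.01).
#' @param k_sd threshold in baseline SD units (default 3).
#' @param fs sampling rate (Hz); inferred from `times` when `NULL`.
#' @return list with `cr` (logical) and `rt` (s from CS onset, `NA` when no
#'   CR).
#' @export
detect_cr <- function(emg, times, baseline_window = c(-0.6, 0),
                      response_window = c(0.5, 0.7), smooth_s = 0.01,
                      k_sd = 3, fs = NULL) {
  stopifnot(length(emg) == length(times))
  fs <- fs %||% (1 / stats::median(diff(times)))
  if (baseline_window[1] < times[1] - 1e-9 ||
      response_window[2] > times[length(times)] + 1e-9)
    stop("baseline or response window lies outside the epoch")
  proc <- moving_rms(emg, round(smooth_s * fs))
  bi <- window_idx(times, baseline_window)
  rect <- abs(emg[bi])
  mu <- mean(rect); sdv <- stats::sd(rect)
  if (sdv == 0) stop("zero-variance baseline")
  ri <- window_idx(times, response_window)
  hit <- proc[ri] > mu + k_sd * sdv
  if (any(hit)) list(cr = TRUE, rt = times[ri[which(hit)[1]]])
  else list(cr = FALSE, rt = NA_real_)
}

#' Score every trial of one session recording
#'
#' Applies [detect_cr()] trial-wise and returns a trial table. Trials
#' carrying an LFP-artifact flag keep their score but are marked `artifact`
#' and are excluded from hit rates downstream.
#'
#' @param recording a [session_recording()].
#' @inheritParams detect_cr
#' @return data.frame with columns `rat, session, trial, cr, rt_s, artifact`.
#' @export
score_session <- function(recording, baseline_window = c(-0.6, 0),
                          response_window = NULL, smooth_s = 0.01,
                          k_sd = 3) {
  response_window <- response_window %||%
    c(recording$events$us_on - 0.2, recording$events$us_on)
  ntr <- nrow(recording$emg)
  cr <- logical(ntr); rt <- rep(NA_real_, ntr)
  for (i in seq_len(ntr)) {
    d <- detect_cr(recording$emg[i, ], recording$times, baseline_window,
                   response_window, smooth_s, k_sd, fs = recording$fs)
    cr[i] <- d$cr; rt[i] <- d$rt
  }
  data.frame(rat = recording$rat, session = recording$session,
             trial = seq_len(ntr), cr = cr, rt_s = rt,
             artifact = recording$artifact)
}

#' Score all sessions of an experiment
#'
#' @param experiment a `tebc_experiment` (or plain list of
#'   [session_recording()]s).
#' @param ... passed to [score_session()].
#' @return combined trial table (one row per trial).
#' @export
score_experiment <- function(experiment, ...) {
  recs <- if (inherits(experiment, "tebc_experiment"))
    unlist(experiment$recordings, recursive = FALSE) else experiment
  do.call(rbind, lapply(recs, score_session, ...))
}

#' Behavioral summary: hit rates, reaction times, learning trend
#'
#' Hit rate (HR) is the proportion of non-artifact trials with a CR, per rat
#' and session. The learning trend is summarized by the Pearson correlation
#' of HR against session index pooled across rats, and by a one-way
#' repeated-measures ANOVA with rat as the repeated factor (session as the
#' within-subject effect).
#'
#' @param trial_table trial table from [score_experiment()] (columns `rat`,
#'   `session`, `cr`, `artifact`, `rt_s`).
#' @return list with `per_session` (data.frame rat, session, hr, n_valid),
#'   `mean_rt` and `sem_rt` (s, over CR trials), `pearson_r` / `pearson_p`
#'   (HR vs session; `NA` when HR is constant), and `anova` (data.frame with
#'   df, F, p for the session effect; `NULL` with a warning for a single
#'   rat).
#' @export
summarize_behavior <- function(trial_table) {
  tt <- trial_table[!trial_table$artifact, ]
  agg <- stats::aggregate(cr ~ rat + session, data = tt, FUN = mean)
  names(agg)[names(agg) == "cr"] <- "hr"
  agg$n_valid <- stats::aggregate(cr ~ rat + session, data = tt,
                                  FUN = length)$cr
  agg <- agg[order(agg$rat, agg$session), ]
  rts <- tt$rt_s[tt$cr & !is.na(tt$rt_s)]
  mean_rt <- if (length(rts)) mean(rts) else NA_real_
  sem_rt <- if (length(rts) > 1) stats::sd(rts) / sqrt(length(rts)) else NA_real_

  r <- p_r <- NA_real_
  if (stats::sd(agg$hr) > 0 && length(unique(agg$session)) > 1) {
    ct <- stats::cor.test(agg$session, agg$hr)
    r <- unname(ct$estimate); p_r <- ct$p.value
  }

  an <- NULL
  if (length(unique(agg$rat)) < 2) {
    warning("single rat: repeated-measures ANOVA skipped")
  } else if (length(unique(agg$session)) >= 2) {
    m <- stats::xtabs(hr ~ rat + session, data = agg)
    an <- rm_anova_1way(as.matrix(m))
  }
  list(per_session = agg, mean_rt = mean_rt, sem_rt = sem_rt,
       pearson_r = r, pearson_p = p_r, anova = an)
}

#' One-way repeated-measures ANOVA (hand partition)
#'
#' Classic subjects-by-conditions partition: the condition effect is tested
#' against the subject-by-condition interaction mean square. No sphericity
#' correction is applied.
#'
#' @param m numeric matrix, subjects x conditions (complete design).
#' @return data.frame with `effect`, `df1`, `df2`, `ss`, `F`, `p`.
#' @export
rm_anova_1way <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  ## additive (zero-residual) tables: error SS vanishes up to rounding
  if (ms_err <= 1e-10 * max(ss_tot, .Machine$double.xmin))
    F <- if (ss_cond > 0) Inf else 0
  else F <- (ss_cond / df1) / ms_err
  data.frame(effect = "condition", df1 = df1, df2 = df2, ss = ss_cond,
             F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}
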