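## Interareal phase synchronization, n:m phase-amplitude coupling, and
## directed phase transfer entropy between hippocampal sites.

#' Interareal phase-locking value with trial-shuffle normalization
#'
#' Raw `PLV(f, t) = | mean over trials of exp(i (phi_A - phi_B)) |`. To
#' control for stimulus-driven artificial synchronization the raw value is
#' divided by the mean PLV over `n_shuffles` surrogates in which the trial
#' pairing on channel B is cyclically permuted (a random non-zero rotation,
#' so no trial is ever paired with itself); under independence the
#' normalized value is ~1.
#'
#' @param tfr_a,tfr_b `analytic_tfr` objects for the two channels; same
#'   bands, same trials.
#' @param n_shuffles number of surrogate pairings (default 100).
#' @param seed integer seed for the shuffle draws.
#' @param keep_shuffles also return the full surrogate maps (array
#'   `shuffle x band x time`), e.g. to compare the empirical value against
#'   surrogate quantiles.
#' @return list of class `plv_map`: `raw`, `normalized`, `shuffle_mean`
#'   (band x time), `freqs`, `times`, `n_trials`, `n_shuffles`, and
#'   optionally `shuffles`.
#' @export
interareal_plv <- function(tfr_a, tfr_b, n_shuffles = 100, seed = NULL,
                           keep_shuffles = FALSE) {
  stopifnot(all(dim(tfr_a$coef) == dim(tfr_b$coef)))
  nb <- dim(tfr_a$coef)[1]; ntr <- dim(tfr_a$coef)[2]
  nt <- dim(tfr_a$coef)[3]
  if (ntr < 2) stop("need at least 2 trials")
  offsets <- with_seed(seed,
    sample(seq_len(ntr - 1), n_shuffles, replace = TRUE))
  raw <- matrix(0, nb, nt)
  shuf <- matrix(0, nb, nt)
  shuffles <- if (keep_shuffles) array(0, c(n_shuffles, nb, nt))
  for (b in seq_len(nb)) {
    A <- tfr_a$coef[b, , ]; B <- tfr_b$coef[b, , ]
    A <- A / pmax(Mod(A), .Machine$double.xmin)
    B <- B / pmax(Mod(B), .Machine$double.xmin)
    D <- A * Conj(B)
    raw[b, ] <- Mod(colMeans(D))
    acc <- numeric(nt)
    for (s in seq_along(offsets)) {
      o <- offsets[s]
      perm <- c((o + 1):ntr, 1:o)
      v <- Mod(colMeans(A * Conj(B[perm, , drop = FALSE])))
      if (keep_shuffles) shuffles[s, b, ] <- v
      acc <- acc + v
    }
    shuf[b, ] <- acc / n_shuffles
  }
  structure(list(raw = raw, normalized = raw / shuf, shuffle_mean = shuf,
                 freqs = tfr_a$freqs, times = tfr_a$times, n_trials = ntr,
                 n_shuffles = n_shuffles, shuffles = shuffles),
            class = "plv_map")
}

## Kaiser band-pass kernel for a single centre frequency, same edge scheme
## as the main bank; memoised per (fs, f) within a session of computation.
pac_kernel_cache <- function() new.env(parent = emptyenv())

band_kernel <- function(fs, f, atten_db = 60, cache = NULL,
                        edges = c(0.6, 0.8, 1.2, 1.4)) {
  key <- paste0(fs, "_", signif(f, 10))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  hp <- fir_kaiser(fs, f_pass = edges[2] * f, f_stop = edges[1] * f,
                   atten_db = atten_db, type = "high")
  lp <- fir_kaiser(fs, f_pass = edges[3] * f, f_stop = edges[4] * f,
                   atten_db = atten_db, type = "low")
  k <- convolve(hp, rev(lp), type = "open")
  if (!is.null(cache)) cache[[key]] <- k
  k
}

#' n:m phase-amplitude coupling matrix
#'
#' For each low frequency `f` and ratio `n`, the high-frequency band at
#' `n * f` is extracted, its amplitude envelope is band-filtered at `f`
#' (same FIR design as the main bank) and Hilbert-transformed, and coupling
#' is the 1:1 phase-locking value between the LF phase on the phase channel
#' and the envelope phase on the amplitude channel, pooled over trials and
#' window samples. Computed for all four laminar pairs (phase -> amplitude:
#' H->H, H->F, F->H, F->F) and for each analysis window, plus the mirrored
#' pre-stimulus windows for differencing. Ratios whose HF stop edge reaches
#' Nyquist are marked absent (`NA`).
#'
#' @param recording a [session_recording()] with "fissure" and "hilus"
#'   channels (artifact trials excluded automatically).
#' @param lf_freqs low-frequency centres (Hz).
#' @param ratios integer ratios `n` (default 2:9, HF = n * LF).
#' @param windows list of post-stimulus analysis windows (s), default
#'   `{0-0.1, 0.1-0.3, 0.3-0.5}`.
#' @param trials optional subset of trial indices.
#' @param atten_db stop-band attenuation of the extraction filters.
#' @param cache optional environment for kernel memoisation across calls.
#' @return list of class `pac_matrix`: arrays `post` and `pre` indexed
#'   `[lf, ratio, pair, window]`, with dimnames.
#' @export
pac_nm <- function(recording, lf_freqs = c(6, 9, 13), ratios = 2:9,
                   windows = list(c(0, 0.1), c(0.1, 0.3), c(0.3, 0.5)),
                   trials = NULL, atten_db = 60, cache = NULL) {
  fs <- recording$fs
  times <- recording$times
  trials <- trials %||% which(!recording$artifact)
  pairs <- c("H->H", "H->F", "F->H", "F->F")
  pair_def <- list(c("hilus", "hilus"), c("hilus", "fissure"),
                   c("fissure", "hilus"), c("fissure", "fissure"))
  win_names <- vapply(windows, function(w) paste0(w[1], "-", w[2], "s"),
                      character(1))
  post <- array(NA_real_, c(length(lf_freqs), length(ratios), 4,
                            length(windows)),
                dimnames = list(paste0(lf_freqs, "Hz"),
                                paste0("1:", ratios), pairs, win_names))
  pre <- post
  chans <- c(fissure = match("fissure", recording$channels),
             hilus = match("hilus", recording$channels))
  if (anyNA(chans)) stop("recording must contain fissure and hilus channels")
  xs <- lapply(chans, function(ci)
    t(matrix(recording$lfp[ci, trials, , drop = FALSE],
             nrow = length(trials))))          # time x trials

  post_idx <- lapply(windows, function(w) window_idx(times, w))
  pre_idx <- lapply(windows, function(w) window_idx(times, c(-w[2], -w[1])))

  for (li in seq_along(lf_freqs)) {
    f <- lf_freqs[li]
    klf <- band_kernel(fs, f, atten_db, cache)
    phi_lf <- lapply(xs, function(x) Arg(fir_apply(x, klf, analytic = TRUE)))
    for (ri in seq_along(ratios)) {
      fh <- f * ratios[ri]
      if (1.4 * fh >= fs / 2) next                 # absent: no HF partner
      khf <- band_kernel(fs, fh, atten_db, cache)
      phi_env <- lapply(xs, function(x) {
        env <- Mod(fir_apply(x, khf, analytic = TRUE))
        Arg(fir_apply(env, klf, analytic = TRUE))
      })
      for (pi in 1:4) {
        pd <- pair_def[[pi]]
        dphi <- exp(1i * (phi_lf[[pd[1]]] - phi_env[[pd[2]]]))
        for (wi in seq_along(windows)) {
          post[li, ri, pi, wi] <- Mod(mean(dphi[post_idx[[wi]], ]))
          pre[li, ri, pi, wi] <- Mod(mean(dphi[pre_idx[[wi]], ]))
        }
      }
    }
  }
  structure(list(post = post, pre = pre, lf_freqs = lf_freqs,
                 ratios = ratios, pairs = pairs, windows = windows,
                 n_trials = length(trials)),
            class = "pac_matrix")
}

## ---- phase transfer entropy ------------------------------------------

## equal-width phase bins over (-pi, pi]
phase_bin <- function(ph, n_bins) {
  b <- floor((ph + pi) / (2 * pi) * n_bins) + 1L
  b[b > n_bins] <- n_bins
  b[b < 1L] <- 1L
  b
}

## TE (bits) from binned phase matrices [trials x time]:
## TE_X->Y = sum p(yf, yp, xp) log2[ p(yf | yp, xp) / p(yf | yp) ]
te_binned <- function(bx, by, delay, n_bins) {
  T <- ncol(bx)
  if (delay >= T) stop("delay exceeds window length")
  src <- 1:(T - delay)
  xp <- as.vector(bx[, src, drop = FALSE])
  yp <- as.vector(by[, src, drop = FALSE])
  yf <- as.vector(by[, src + delay, drop = FALSE])
  idx <- (xp - 1L) * n_bins^2 + (yp - 1L) * n_bins + yf
  cnt <- tabulate(idx, n_bins^3)
  joint <- array(cnt, c(n_bins, n_bins, n_bins))   # [yf, yp, xp]
  n <- sum(joint)
  c_ypx <- colSums(joint)                          # [yp, xp]
  c_yfyp <- apply(joint, c(1, 2), sum)             # [yf, yp]
  c_yp <- colSums(c_yfyp)                          # [yp]
  p <- joint / n
  pcond_full <- joint / rep(c_ypx, each = n_bins)          # p(yf | yp, xp)
  pm <- c_yfyp / rep(c_yp, each = n_bins)                  # p(yf | yp)
  pcond_marg <- array(rep(pm, n_bins), c(n_bins, n_bins, n_bins))
  ok <- joint > 0
  sum(p[ok] * log2(pcond_full[ok] / pcond_marg[ok]))
}

#' Phase transfer entropy between two sites
#'
#' Directed information transfer estimated from binned instantaneous phase
#' time series: `TE_X->Y = sum p(y_{t+d}, y_t, x_t) log2[ p(y_{t+d} | y_t,
#' x_t) / p(y_{t+d} | y_t) ]`, with probabilities from equal-width phase-bin
#' histograms pooled over trials and window samples. The bias-free summary
#' is the differential TE `dTE = TE_X->Y - TE_Y->X`, positive when X leads;
#' swapping the inputs negates it exactly.
#'
#' @param phase_x,phase_y phase matrices `[trials x time]` in `(-pi, pi]`
#'   (conventionally X = hilus, Y = fissure).
#' @param delay prediction delay in samples; the standard choice is one
#'   cycle of the analysis frequency, `round(fs / f)`.
#' @param n_bins equal-width phase bins (default 8).
#' @param times optional time axis; with `window`, restricts the analysis.
#' @param window analysis window (s), default `c(0, 0.5)` post-CS when
#'   `times` is given.
#' @return list of class `pte_result`: `te_xy`, `te_yx`, `dte` (bits),
#'   `delay`, `n_bins`, `n_samples`, `low_confidence` flag (fewer pooled
#'   samples than 10x the bin-cell count).
#' @export
phase_te <- function(phase_x, phase_y, delay, n_bins = 8, times = NULL,
                     window = c(0, 0.5)) {
  phase_x <- rbind(phase_x); phase_y <- rbind(phase_y)
  stopifnot(all(dim(phase_x) == dim(phase_y)))
  if (!is.null(times)) {
    ti <- window_idx(times, window)
    phase_x <- phase_x[, ti, drop = FALSE]
    phase_y <- phase_y[, ti, drop = FALSE]
  }
  bx <- phase_bin(phase_x, n_bins)
  by <- phase_bin(phase_y, n_bins)
  n_samples <- nrow(bx) * (ncol(bx) - delay)
  low <- n_samples < 10 * n_bins^3
  if (low)
    warning("phase TE estimated from ", n_samples, " samples < 10 x ",
            n_bins^3, " bin cells; flagged low-confidence")
  te_xy <- te_binned(bx, by, delay, n_bins)
  te_yx <- te_binned(by, bx, delay, n_bins)
  structure(list(te_xy = te_xy, te_yx = te_yx, dte = te_xy - te_yx,
                 delay = delay, n_bins = n_bins, n_samples = n_samples,
                 low_confidence = low),
            class = "pte_result")
}

#' Per-band differential phase transfer entropy spectrum
#'
#' Convenience wrapper applying [phase_te()] band-by-band to a pair of
#' analytic TFRs (X = hilus, Y = fissure by convention), with the
#' one-cycle-per-band delay rule `delay = round(fs / f)`.
#'
#' @param tfr_x,tfr_y `analytic_tfr` objects with identical bands/trials.
#' @param window analysis window (s), default `c(0, 0.5)` post-CS.
#' @param n_bins phase bins (default 8).
#' @param delay optional fixed delay (samples); default per-band one cycle.
#' @return data.frame with `freq`, `delay`, `te_xy`, `te_yx`, `dte`,
#'   `low_confidence`; the binned trial phases are attached as attribute
#'   `phases` for surrogate testing.
#' @export
dte_spectrum <- function(tfr_x, tfr_y, window = c(0, 0.5), n_bins = 8,
                         delay = NULL) {
  stopifnot(all(dim(tfr_x$coef) == dim(tfr_y$coef)))
  ti <- window_idx(tfr_x$times, window)
  out <- vector("list", length(tfr_x$freqs))
  phases <- vector("list", length(tfr_x$freqs))
  for (b in seq_along(tfr_x$freqs)) {
    d <- delay %||% max(1L, round(tfr_x$fs / tfr_x$freqs[b]))
    px <- Arg(tfr_x$coef[b, , ti, drop = TRUE])
    py <- Arg(tfr_y$coef[b, , ti, drop = TRUE])
    px <- rbind(px); py <- rbind(py)
    r <- suppressWarnings(phase_te(px, py, delay = d, n_bins = n_bins))
    out[[b]] <- data.frame(freq = tfr_x$freqs[b], delay = d,
                           te_xy = r$te_xy, te_yx = r$te_yx, dte = r$dte,
                           low_confidence = r$low_confidence)
    phases[[b]] <- list(x = px, y = py, delay = d)
  }
  res <- do.call(rbind, out)
  attr(res, "phases") <- phases
  attr(res, "n_bins") <- n_bins
  res
}
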