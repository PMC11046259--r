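## Orchestration: simulate -> behavior -> preprocess -> spectral /
## connectivity -> statistics, with the two headline contrasts
## (CR vs no-CR within sessions; highest vs lowest %HR session per animal).

#' Analysis run configuration
#'
#' @param sim a [sim_config()] describing the experiment to simulate, or
#'   `NULL` with `data_dir` pointing at a directory written by
#'   [write_experiment()].
#' @param data_dir optional experiment directory to load instead of
#'   simulating.
#' @param f_min,f_max,n_bands filter-bank parameters; `f_max` defaults to
#'   the lesser of 480 Hz and 95% of Nyquist/1.4.
#' @param rhythms named list of canonical band ranges (Hz) used for
#'   reporting: theta 4-6, alpha 8-12, beta 12-30, gamma 30-40, high gamma
#'   50-100.
#' @param analysis_window,baseline spectral map windows (s).
#' @param pac_windows list of post-stimulus PAC analysis windows (s).
#' @param metrics metrics to contrast: subset of `c("amplitude", "itc")`.
#' @param do_connectivity run the interareal stage (PLV, PAC, dTE) on each
#'   animal's highest-%HR session.
#' @param lf_freqs,ratios PAC settings.
#' @param n_perm cluster permutations; `n_shuffles` PLV shuffles;
#'   `n_te_shuffles` phase-TE surrogates.
#' @param te_bins phase-TE bin count.
#' @param channels channels to analyse (default both sites).
#' @param seed master seed; every stochastic stage derives a child seed.
#' @param out_dir optional output directory for the report bundle.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), data_dir = NULL,
                       f_min = 3, f_max = NULL, n_bands = 30,
                       rhythms = list(theta = c(4, 6), alpha = c(8, 12),
                                      beta = c(12, 30), gamma = c(30, 40),
                                      high_gamma = c(50, 100)),
                       analysis_window = c(-0.6, 0.6),
                       baseline = c(-0.6, -0.1),
                       pac_windows = list(c(0, 0.1), c(0.1, 0.3),
                                          c(0.3, 0.5)),
                       metrics = c("amplitude", "itc"),
                       do_connectivity = FALSE,
                       lf_freqs = c(6, 9, 13), ratios = 2:9,
                       n_perm = 1000, n_shuffles = 100,
                       n_te_shuffles = 200, te_bins = 8,
                       channels = c("fissure", "hilus"),
                       seed = 1L, out_dir = NULL) {
  fs <- if (!is.null(sim)) sim$fs else NULL
  if (is.null(f_max)) {
    if (is.null(fs)) stop("f_max must be given when loading from data_dir")
    f_max <- min(480, 0.95 * fs / 2 / 1.4)
  }
  structure(list(sim = sim, data_dir = data_dir, f_min = f_min,
                 f_max = f_max, n_bands = n_bands, rhythms = rhythms,
                 analysis_window = analysis_window, baseline = baseline,
                 pac_windows = pac_windows, metrics = metrics,
                 do_connectivity = do_connectivity, lf_freqs = lf_freqs,
                 ratios = ratios, n_perm = n_perm, n_shuffles = n_shuffles,
                 n_te_shuffles = n_te_shuffles, te_bins = te_bins,
                 channels = channels,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Rank sessions by hit rate within each animal
#'
#' Ties are broken toward the earlier session for the lowest %HR and the
#' later session for the highest %HR (an animal at floor early and at
#' ceiling late is the canonical learning pattern).
#'
#' @param per_session data.frame with columns `rat`, `session`, `hr` (as
#'   returned in `summarize_behavior()$per_session`).
#' @return data.frame with `rat`, `lowest`, `highest`, `hr_lowest`,
#'   `hr_highest`.
#' @export
rank_sessions_by_hr <- function(per_session) {
  out <- lapply(split(per_session, per_session$rat), function(d) {
    d <- d[order(d$session), ]
    if (nrow(d) < 2) stop("need at least 2 sessions per animal")
    lo <- d$session[which.min(d$hr)]                   # earliest minimum
    hi <- d$session[nrow(d) + 1 - which.max(rev(d$hr))] # latest maximum
    data.frame(rat = d$rat[1], lowest = lo, highest = hi,
               hr_lowest = min(d$hr), hr_highest = max(d$hr))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Accumulate per-animal condition maps (amplitude and phasor sums) from a
## streamed pass over sessions, so full TFRs are never all held at once.
## Returns per-animal arrays for the CR and learning contrasts.
collect_condition_maps <- function(experiment, bank, trial_table, ranks,
                                   cfg) {
  sim <- experiment$config
  channels <- cfg$channels
  ti <- NULL; freqs <- bank$freqs
  acc <- list()
  for (r in seq_len(sim$n_rats)) {
    st <- list()
    for (ch in channels)
      st[[ch]] <- list(cr_amp = 0, cr_ph = 0i, cr_n = 0,
                       no_amp = 0, no_ph = 0i, no_n = 0,
                       lo_amp = 0, lo_ph = 0i, lo_n = 0,
                       hi_amp = 0, hi_ph = 0i, hi_n = 0)
    rk <- ranks[ranks$rat == r, ]
    for (s in seq_len(sim$n_sessions)) {
      rec <- experiment$recordings[[r]][[s]]
      rec <- reject_artifact_trials(rec)
      rec <- interpolate_recording(rec)
      tfrs <- decompose(rec, bank, channels = channels)
      kept <- tfrs[[1]]$trials
      tt <- trial_table[trial_table$rat == r & trial_table$session == s, ]
      cr_ids <- intersect(which(tt$cr), kept)
      no_ids <- setdiff(kept, which(tt$cr))
      eq <- NULL
      if (length(cr_ids) && length(no_ids))
        eq <- equalize_trials(cr_ids, no_ids,
                              seed = child_seed(cfg$seed, "eq", r, s))
      for (ch in channels) {
        tfr <- tfrs[[ch]]
        if (is.null(ti)) ti <- window_idx(tfr$times, cfg$analysis_window)
        coef <- tfr$coef[, , ti, drop = FALSE]
        amp <- Mod(coef)
        ph <- coef / pmax(amp, .Machine$double.xmin)
        pos <- function(ids) match(ids, kept)
        addc <- function(slot, ids) {
          if (!length(ids)) return()
          p <- pos(ids)
          st[[ch]][[paste0(slot, "_amp")]] <<-
            st[[ch]][[paste0(slot, "_amp")]] +
            apply(amp[, p, , drop = FALSE], c(1, 3), sum)
          st[[ch]][[paste0(slot, "_ph")]] <<-
            st[[ch]][[paste0(slot, "_ph")]] +
            apply(ph[, p, , drop = FALSE], c(1, 3), sum)
          st[[ch]][[paste0(slot, "_n")]] <<-
            st[[ch]][[paste0(slot, "_n")]] + length(ids)
        }
        if (!is.null(eq)) { addc("cr", eq$a); addc("no", eq$b) }
        if (s == rk$lowest) addc("lo", kept)
        if (s == rk$highest) addc("hi", kept)
      }
    }
    acc[[r]] <- st
  }
  list(acc = acc, times = NULL, ti = ti, freqs = freqs)
}

## baseline-correct a band x time map
baseline_correct <- function(map, times, baseline) {
  bi <- window_idx(times, baseline)
  map - rowMeans(map[, bi, drop = FALSE])
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the experiment, scores behavior, preprocesses and
#' decomposes every session, builds per-animal condition maps, and runs the
#' two cluster-permutation contrasts: retrieval (CR vs no-CR, trials
#' equalized within session, pooled across sessions) and consolidation
#' (highest vs lowest %HR session). Optionally runs the interareal stage
#' (normalized PLV, n:m PAC with group test, dTE spectrum with trial-shuffle
#' test) on each animal's highest-%HR session. All stochastic steps derive
#' child seeds from `config$seed`; identical config and seed give an
#' identical bundle. When `config$out_dir` is set, tables are written as
#' deterministic CSVs plus a provenance manifest.
#'
#' @param config a [run_config()].
#' @return list of class `tebc_run`: `behavior`, `ranks`, `maps` (per
#'   channel/metric/condition group maps), `contrasts` (cluster results per
#'   channel/metric/contrast), optional `connectivity`, `bank`, `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  experiment <- if (!is.null(config$data_dir)) read_experiment(config$data_dir)
    else simulate_experiment(config$sim)
  sim <- experiment$config

  ## ---- behavior -------------------------------------------------------
  trial_table <- score_experiment(experiment)
  trial_table$artifact <- trial_table$artifact |
    unlist(lapply(unlist(experiment$recordings, recursive = FALSE),
                  function(rec) reject_artifact_trials(rec)$artifact))
  behavior <- summarize_behavior(trial_table)
  ranks <- rank_sessions_by_hr(behavior$per_session)

  ## ---- preprocess + condition maps ------------------------------------
  bank <- build_filter_bank(fs = sim$fs, f_min = config$f_min,
                            f_max = config$f_max, n_bands = config$n_bands)
  cm <- collect_condition_maps(experiment, bank, trial_table, ranks, config)
  times <- experiment$recordings[[1]][[1]]$times[cm$ti]
  channels <- config$channels

  finalize <- function(slot, metric) {
    ## animal x band x time array of baseline-corrected maps
    out <- lapply(channels, function(ch) {
      mats <- lapply(cm$acc, function(st) {
        n <- st[[ch]][[paste0(slot, "_n")]]
        if (n == 0) return(NULL)
        m <- if (metric == "amplitude")
          st[[ch]][[paste0(slot, "_amp")]] / n
        else Mod(st[[ch]][[paste0(slot, "_ph")]]) / n
        baseline_correct(m, times, config$baseline)
      })
      keep <- !vapply(mats, is.null, logical(1))
      arr <- array(NA_real_, c(sum(keep), length(cm$freqs), length(times)))
      j <- 0
      for (i in which(keep)) { j <- j + 1; arr[j, , ] <- mats[[i]] }
      arr
    })
    names(out) <- channels
    out
  }

  contrasts <- list()
  maps <- list()
  for (metric in config$metrics) {
    a_cr <- finalize("cr", metric); a_no <- finalize("no", metric)
    a_hi <- finalize("hi", metric); a_lo <- finalize("lo", metric)
    for (ch in channels) {
      maps[[paste(metric, ch, "cr", sep = ".")]] <- a_cr[[ch]]
      maps[[paste(metric, ch, "nocr", sep = ".")]] <- a_no[[ch]]
      maps[[paste(metric, ch, "highest", sep = ".")]] <- a_hi[[ch]]
      maps[[paste(metric, ch, "lowest", sep = ".")]] <- a_lo[[ch]]
      contrasts[[paste(metric, ch, "cr", sep = ".")]] <-
        cluster_permutation(a_cr[[ch]], a_no[[ch]], n_perm = config$n_perm,
                            seed = child_seed(config$seed, "cl", metric, ch, "cr"))
      contrasts[[paste(metric, ch, "learning", sep = ".")]] <-
        cluster_permutation(a_hi[[ch]], a_lo[[ch]], n_perm = config$n_perm,
                            seed = child_seed(config$seed, "cl", metric, ch, "lr"))
    }
  }

  ## ---- connectivity on each animal's highest-%HR session --------------
  connectivity <- NULL
  if (isTRUE(config$do_connectivity)) {
    plv_sum <- 0; pac_post <- list(); pac_pre <- list(); dte_list <- list()
    kcache <- pac_kernel_cache()
    for (r in seq_len(sim$n_rats)) {
      s <- ranks$highest[ranks$rat == r]
      rec <- reject_artifact_trials(experiment$recordings[[r]][[s]])
      rec <- interpolate_recording(rec)
      tfrs <- decompose(rec, bank, channels = channels)
      plv <- interareal_plv(tfrs$fissure, tfrs$hilus,
                            n_shuffles = config$n_shuffles,
                            seed = child_seed(config$seed, "plv", r))
      plv_sum <- plv_sum + plv$normalized
      plv_times <- plv$times
      pm <- pac_nm(rec, lf_freqs = config$lf_freqs, ratios = config$ratios,
                   windows = config$pac_windows, cache = kcache)
      pac_post[[r]] <- as.vector(pm$post); pac_pre[[r]] <- as.vector(pm$pre)
      dte <- dte_spectrum(tfrs$hilus, tfrs$fissure, n_bins = config$te_bins)
      dte_list[[r]] <- dte
      if (r == 1) { pac_dims <- dimnames(pm$post); plv_freqs <- plv$freqs }
    }
    pac_post <- do.call(rbind, pac_post); pac_pre <- do.call(rbind, pac_pre)
    dte_mean <- Reduce(`+`, lapply(dte_list, function(d) d$dte)) /
      length(dte_list)
    connectivity <- list(
      plv_normalized = plv_sum / sim$n_rats, plv_freqs = bank$freqs,
      plv_times = plv_times,
      pac_test = pac_group_test(pac_post, pac_pre),
      pac_dimnames = pac_dims, pac_post = pac_post, pac_pre = pac_pre,
      dte_mean = dte_mean, dte_per_rat = dte_list,
      pte_test = pte_shuffle_test(dte_list[[1]],
                                  n_shuffles = config$n_te_shuffles,
                                  seed = child_seed(config$seed, "pte")))
  }

  run <- structure(list(behavior = behavior, ranks = ranks, maps = maps,
                        contrasts = contrasts, connectivity = connectivity,
                        freqs = cm$freqs, times = times, bank = bank,
                        trial_table = trial_table, config = config),
                   class = "tebc_run")
  if (!is.null(config$out_dir)) write_run_bundle(run, config$out_dir)
  run
}

## deterministic report bundle: tidy CSVs + provenance manifest
write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tidy_csv(run$behavior$per_session, file.path(dir, "behavior_hr.csv"))
  write_tidy_csv(run$ranks, file.path(dir, "session_ranks.csv"))
  cl <- do.call(rbind, lapply(names(run$contrasts), function(nm) {
    d <- run$contrasts[[nm]]$clusters
    if (!nrow(d)) return(NULL)
    d$contrast <- nm
    d$band_hz <- run$freqs[d$band]
    d$t_start_s <- run$times[d$start]
    d$t_end_s <- run$times[d$end]
    d
  }))
  if (is.null(cl))
    cl <- data.frame(contrast = character(), band = integer(),
                     band_hz = numeric(), start = integer(), end = integer(),
                     t_start_s = numeric(), t_end_s = numeric(),
                     sign = integer(), t_sum = numeric(), p = numeric(),
                     significant = logical())
  write_tidy_csv(cl, file.path(dir, "clusters.csv"))
  tidies <- lapply(names(run$maps), function(nm) {
    arr <- run$maps[[nm]]
    if (is.null(arr) || !length(arr)) return(NULL)
    map_to_tidy(apply(arr, c(2, 3), mean), run$freqs, run$times,
                contrast = nm)
  })
  write_tidy_csv(do.call(rbind, tidies), file.path(dir, "group_maps.csv"))
  if (!is.null(run$connectivity)) {
    write_tidy_csv(map_to_tidy(run$connectivity$plv_normalized, run$freqs,
                               run$connectivity$plv_times,
                               contrast = "plv_normalized"),
                   file.path(dir, "plv.csv"))
    ct <- run$connectivity
    pac_df <- data.frame(cell = seq_along(ct$pac_test$t),
                         t = ct$pac_test$t, p = ct$pac_test$p,
                         significant = ct$pac_test$mask,
                         mean_diff = ct$pac_test$mean_diff)
    write_tidy_csv(pac_df, file.path(dir, "pac_test.csv"))
    write_tidy_csv(ct$pte_test, file.path(dir, "pte_test.csv"))
  }
  manifest <- list(
    package = "tebcosc",
    version = as.character(utils::packageVersion("tebcosc")),
    seed = run$config$seed,
    config_hash = child_seed(0, jsonlite::toJSON(
      unclass(run$config)[setdiff(names(run$config), c("sim", "out_dir"))],
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)),
    sim = if (!is.null(run$config$sim)) unclass(run$config$sim),
    n_bands = length(run$freqs), freqs = run$freqs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.tebc_run <- function(x, ...) {
  cat("<tebc_run> ", length(x$freqs), " bands, ",
      length(x$contrasts), " contrasts\n", sep = "")
  for (nm in names(x$contrasts)) {
    cl <- x$contrasts[[nm]]$clusters
    cat("  ", nm, ": ", sum(cl$significant), " significant cluster(s)\n",
        sep = "")
  }
  invisible(x)
}
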