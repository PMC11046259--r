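## Plain-text session container and tidy result writers.
##
## Layout of an experiment directory:
##   manifest.json                         config + ground-truth manifest
##   trials.csv                            trial table
##   rat<i>_session<j>_<channel>.csv       LFP, trials x time (uV)
##   rat<i>_session<j>_emg.csv             EMG, trials x time (uV)

#' Write a simulated experiment to a directory of CSV/JSON files
#'
#' @param experiment a `tebc_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- experiment$config
  meta <- list(
    config = unclass(cfg),
    manifest = experiment$manifest,
    channels = experiment$recordings[[1]][[1]]$channels,
    format = "tebcosc-session-v1")
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(experiment$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  for (r in seq_len(cfg$n_rats))
    for (s in seq_len(cfg$n_sessions)) {
      rec <- experiment$recordings[[r]][[s]]
      for (ci in seq_along(rec$channels)) {
        fn <- file.path(dir, sprintf("rat%d_session%d_%s.csv", r, s,
                                     rec$channels[ci]))
        utils::write.table(
          format(rec$lfp[ci, , ], digits = 7, trim = TRUE, scientific = TRUE),
          fn, sep = ",", row.names = FALSE, col.names = FALSE,
          quote = FALSE)
      }
      utils::write.table(
        format(rec$emg, digits = 7, trim = TRUE, scientific = TRUE),
        file.path(dir, sprintf("rat%d_session%d_emg.csv", r, s)),
        sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  invisible(dir)
}

#' Read an experiment directory written by [write_experiment()]
#'
#' @param dir directory path.
#' @return a `tebc_experiment`-shaped list (recordings, trials, manifest,
#'   config); numeric precision is that of the CSV text.
#' @export
read_experiment <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  recs <- vector("list", cfg$n_rats)
  for (r in seq_len(cfg$n_rats)) {
    recs[[r]] <- vector("list", cfg$n_sessions)
    for (s in seq_len(cfg$n_sessions)) {
      mats <- lapply(meta$channels, function(ch)
        as.matrix(utils::read.csv(file.path(
          dir, sprintf("rat%d_session%d_%s.csv", r, s, ch)),
          header = FALSE)))
      lfp <- array(0, c(length(meta$channels), nrow(mats[[1]]),
                        ncol(mats[[1]])))
      for (ci in seq_along(mats)) lfp[ci, , ] <- mats[[ci]]
      emg <- as.matrix(utils::read.csv(file.path(
        dir, sprintf("rat%d_session%d_emg.csv", r, s)), header = FALSE))
      tt <- trials[trials$rat == r & trials$session == s, ]
      recs[[r]][[s]] <- session_recording(
        lfp = lfp, channels = meta$channels, emg = emg, fs = cfg$fs,
        epoch = cfg$epoch,
        events = list(cs_on = 0, cs_off = cfg$cs_duration,
                      us_on = cfg$us_onset),
        rat = r, session = s, artifact = tt$artifact)
    }
  }
  structure(list(recordings = recs, trials = trials,
                 manifest = meta$manifest, config = cfg),
            class = "tebc_experiment")
}

## tidy band x time map -> long data.frame
map_to_tidy <- function(map, freqs, times, ...) {
  extra <- list(...)
  df <- data.frame(
    band_hz = rep(freqs, times = length(times)),
    time_s = rep(times, each = length(freqs)),
    value = as.vector(map))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df[, c(names(extra), "band_hz", "time_s", "value")]
}

## deterministic CSV writer (fixed numeric formatting, no row names)
write_tidy_csv <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num])
    df[[nm]] <- format(df[[nm]], digits = digits, trim = TRUE,
                       scientific = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
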