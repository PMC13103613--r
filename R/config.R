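#' Default study configuration
#'
#' Returns the full configuration that drives both the synthetic-study
#' generator and the analysis defaults. The design constants mirror a
#' two-session talker-identification learning study: 24 participants learn
#' to identify 4 talkers x 10 sentences per language over 4 training blocks
#' of 40 trials plus one 40-trial test block with novel sentences, while
#' pupil size is sampled at 1000 Hz from -500 to 4000 ms around stimulus
#' onset.
#'
#' Generator defaults: each language has a cue weight `w` (how strongly the
#' correct-talker identity, as opposed to raw acoustic similarity, drives
#' the drift rates; 0.8 for the native language, 0.2 for the unfamiliar
#' one), a per-block gain schedule on the drifts, and a decision threshold.
#' The unfamiliar-language threshold and the blink rate are calibrated
#' constants (see the methods vignette): the thresholds equalize expected
#' log response times across languages, and the blink rate yields roughly
#' 12\% trial rejection at the 15\% blink screen.
#'
#' @return A list of class `study_config`.
#' @export
default_config <- function() {
  cfg <- list(
    n_participants = 24L,
    n_talkers = 4L,
    n_sentences = 10L,
    n_training_blocks = 4L,
    trials_per_block = 40L,
    sampling_rate_hz = 1000,
    pupil_window_ms = c(-500, 4000),
    rng_seed = 1L,
    languages = list(
      native = list(
        w = 0.8,
        gain = c(1.7, 2.0, 2.15, 2.3),
        threshold = 1.5
      ),
      unfamiliar = list(
        w = 0.2,
        gain = c(0.6, 0.9, 1.13, 1.32),
        threshold = 1.33
      )
    ),
    generator = list(
      mu_base = 1.0,
      delta_s = 0.35,
      participant_gain_sd = 0.12,
      participant_delta_sd = 0.08,
      pupil = list(
        a0 = 30, a1 = 4,
        kernel_n = 10.1, kernel_tmax_ms = 930,
        baseline_mean = 4000, baseline_cv = 0.1,
        noise_sd = 0.015, noise_tau_ms = 200,
        blink_rate_hz = 0.325,
        blink_dur_meanlog = log(0.20), blink_dur_sdlog = 0.4
      ),
      features = list(
        mean_f0 = c(170, 30),
        f0_range = c(80, 20),
        speech_rate = c(4.5, 0.5),
        jitter = c(1.2, 0.3),
        harmonicity = c(12, 2),
        formant_dispersion = c(1000, 80)
      )
    ),
    analysis = list(
      blink_threshold = 0.15,
      interp_pad_ms = 120,
      baseline_window_ms = 500,
      downsample_hz = 50,
      rt_outlier_sd = 3,
      rt_trim_fraction = 0.01,
      mcmc = list(iters = 6000L, burnin = 2000L, thin = 5L,
                  tau_rw = 0.3, blocks_independent = FALSE),
      gca_order = 4L
    )
  )
  class(cfg) <- "study_config"
  validate_config(cfg)
}

#' Validate a study configuration
#'
#' Checks counts, cue-weight and threshold ranges, and the pupil window.
#' Errors name the offending key.
#'
#' @param config A `study_config` list.
#' @return The validated config, invisibly classed as `study_config`.
#' @export
validate_config <- function(config) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok)) stop(sprintf("invalid config value for '%s': %s", key, what),
                          call. = FALSE)
  }
  for (key in c("n_participants", "n_talkers", "n_sentences",
                "n_training_blocks", "trials_per_block")) {
    chk(is.numeric(config[[key]]) && length(config[[key]]) == 1 &&
          config[[key]] >= 1, key, "must be a count >= 1")
  }
  chk(config$sampling_rate_hz > 0, "sampling_rate_hz", "must be positive")
  w <- config$pupil_window_ms
  chk(length(w) == 2 && w[1] < 0 && w[2] > 0, "pupil_window_ms",
      "must straddle stimulus onset (start < 0 < end)")
  for (lang in names(config$languages)) {
    lw <- config$languages[[lang]]$w
    chk(is.numeric(lw) && length(lw) == 1 && lw >= 0 && lw <= 1,
        paste0("languages.", lang, ".w"), "cue weight must lie in [0, 1]")
    g <- config$languages[[lang]]$gain
    chk(all(g > 0) && !is.unsorted(g),
        paste0("languages.", lang, ".gain"),
        "gain schedule must be positive and non-decreasing")
    chk(config$languages[[lang]]$threshold > 0,
        paste0("languages.", lang, ".threshold"), "must be positive")
  }
  chk(config$analysis$blink_threshold >= 0 && config$analysis$blink_threshold <= 1,
      "analysis.blink_threshold", "must lie in [0, 1]")
  chk(config$analysis$rt_trim_fraction >= 0 && config$analysis$rt_trim_fraction < 0.5,
      "analysis.rt_trim_fraction", "must lie in [0, 0.5)")
  chk(config$generator$delta_s >= 0, "generator.delta_s", "must be >= 0")
  for (f in names(config$generator$features)) {
    chk(config$generator$features[[f]][2] >= 0,
        paste0("generator.features.", f), "scale must be non-negative")
  }
  chk(config$trials_per_block == config$n_talkers * config$n_sentences,
      "trials_per_block", "must equal n_talkers * n_sentences")
  class(config) <- "study_config"
  invisible(config)
}

merge_defaults <- function(defaults, override) {
  for (key in names(override)) {
    if (is.list(defaults[[key]]) && is.list(override[[key]])) {
      defaults[[key]] <- merge_defaults(defaults[[key]], override[[key]])
    } else {
      v <- override[[key]]
      # keep the defaults' storage mode so round trips through YAML are exact
      if (is.numeric(v) && is.numeric(defaults[[key]]))
        storage.mode(v) <- storage.mode(defaults[[key]])
      defaults[[key]] <- v
    }
  }
  defaults
}

#' Load a study configuration from a YAML file
#'
#' Keys absent from the file take the documented defaults of
#' [default_config()]; an empty file yields the all-defaults configuration.
#'
#' @param path Path to a YAML config file.
#' @return A validated `study_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  if (!is.null(user)) {
    if (!is.list(user)) stop("config file must parse to a mapping: ", path,
                             call. = FALSE)
    cfg <- merge_defaults(cfg, user)
  }
  # YAML turns length-2 vectors into lists; flatten the known ones
  for (key in c("pupil_window_ms")) cfg[[key]] <- as.numeric(unlist(cfg[[key]]))
  for (lang in names(cfg$languages))
    cfg$languages[[lang]]$gain <- as.numeric(unlist(cfg$languages[[lang]]$gain))
  for (f in names(cfg$generator$features))
    cfg$generator$features[[f]] <- as.numeric(unlist(cfg$generator$features[[f]]))
  validate_config(cfg)
}

#' Write a study configuration to YAML
#'
#' @param config A `study_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  writeLines(yaml::as.yaml(unclass(config), precision = 12L), path)
  invisible(path)
}
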