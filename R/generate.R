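#' Generate talker acoustic feature tables
#'
#' Draws, independently per talker, the six voice features (mean F0, F0
#' range, speech rate, jitter, harmonicity, formant dispersion) from the
#' per-feature location/scale settings in `config$generator$features`.
#' Both languages share the same settings, so the between-talker distance
#' distributions are exchangeable across languages.
#'
#' @param config A [default_config()]-style `study_config`.
#' @param seed Integer seed.
#' @return Named list (one per language) of feature data.frames.
#' @export
gen_talkers <- function(config, seed = config$rng_seed) {
  set.seed(seed)
  fset <- config$generator$features
  for (f in names(fset))
    if (fset[[f]][2] < 0) stop("negative scale for feature ", f, call. = FALSE)
  K <- config$n_talkers
  if (K < 2) stop("n_talkers must be >= 2", call. = FALSE)
  out <- lapply(names(config$languages), function(lang) {
    df <- data.frame(talker = seq_len(K))
    for (f in names(fset)) {
      v <- rnorm(K, fset[[f]][1], fset[[f]][2])
      if (f == "jitter") v <- pmax(v, 0)
      df[[f]] <- v
    }
    df
  })
  names(out) <- names(config$languages)
  out
}

#' Drift and threshold schedule for one language and block
#'
#' Builds the race parameters that the generator plants:
#' `mu[d, s] = mu_base + g * (w * 1(d = s) + (1 - w) * sigma(d, s))` where
#' `sigma` is the ASM rescaled to [0, 1] with unit diagonal
#' ([similarity_weights()]), `w` is the language's cue weight, and `g` the
#' language's gain in that block (the test block reuses the final training
#' gain). Thresholds are constant across blocks at the language's default.
#' With `w = 1` all off-diagonal drifts collapse to `mu_base` (errors carry
#' no acoustic structure); with `w = 0` they are ordered exactly by
#' acoustic similarity.
#'
#' @param config A `study_config`.
#' @param asm ASM of the same talker set.
#' @param language Language name in `config$languages`.
#' @param block Block index (1..n_training_blocks + 1).
#' @return List with K x K matrices `mu` (columns = stimulus) and `b`.
#' @export
drift_schedule <- function(config, asm, language, block) {
  lg <- config$languages[[language]]
  if (is.null(lg)) stop("unknown language: ", language, call. = FALSE)
  nb <- config$n_training_blocks
  if (block < 1 || block > nb + 1) stop("block out of range", call. = FALSE)
  g <- if (block <= nb) lg$gain[block] else lg$gain[nb]
  sigma <- similarity_weights(asm)
  K <- nrow(sigma)
  ind <- diag(K)
  # sigma has unit diagonal, so mu[s, s] = mu_base + g regardless of w
  mu <- config$generator$mu_base + g * (lg$w * ind + (1 - lg$w) * sigma)
  if (any(mu <= 0)) stop("non-positive drift in schedule", call. = FALSE)
  b <- matrix(lg$threshold, K, K)
  list(mu = mu, b = b)
}

#' Assemble the generator's ground truth
#'
#' Draws the talker features, converts them to similarity weights, expands
#' the per-language drift/threshold schedules over blocks (training blocks
#' plus the test block), draws participant-level multipliers (drift gain
#' per participant x language, non-decision offset per participant, pupil
#' baseline per participant), and records the pupil-coupling and blink
#' parameters.
#'
#' @param config A `study_config`.
#' @param seed Integer seed.
#' @return A ground-truth list (see [write_truth()]).
#' @export
build_ground_truth <- function(config, seed = config$rng_seed) {
  features <- gen_talkers(config, seed)
  set.seed(seed + 1L)
  K <- config$n_talkers
  nb <- config$n_training_blocks + 1L  # + test block
  gen <- config$generator
  languages <- list()
  for (lang in names(config$languages)) {
    asm <- asm_from_features(features[[lang]])
    mu <- array(NA_real_, c(K, K, nb))
    b <- array(NA_real_, c(K, K, nb))
    for (j in seq_len(nb)) {
      sched <- drift_schedule(config, asm, lang, j)
      mu[, , j] <- sched$mu
      b[, , j] <- sched$b
    }
    languages[[lang]] <- list(
      w = config$languages[[lang]]$w,
      threshold = config$languages[[lang]]$threshold,
      sigma = similarity_weights(asm), mu = mu, b = b)
  }
  npart <- config$n_participants
  parts <- expand.grid(participant = seq_len(npart),
                       language = names(config$languages),
                       stringsAsFactors = FALSE)
  parts$gain_mult <- rlnorm(nrow(parts), 0, gen$participant_gain_sd)
  delta_mult <- rlnorm(npart, 0, gen$participant_delta_sd)
  baseline <- gen$pupil$baseline_mean *
    rlnorm(npart, 0, sqrt(log(1 + gen$pupil$baseline_cv^2)))
  parts$delta_mult <- delta_mult[parts$participant]
  parts$baseline <- baseline[parts$participant]
  list(
    seed = seed,
    languages = languages,
    delta_s = rep(gen$delta_s, K),
    participants = parts,
    pupil = gen$pupil,
    features = features)
}

#' Simulate trial-level behavior from the race model
#'
#' For every participant x language x block, all n_talkers x n_sentences
#' stimuli appear once in a seeded random order; on each trial independent
#' first-passage times are drawn for the K accumulators (drifts scaled by
#' the participant's gain multiplier) and the response is the accumulator
#' that finishes first, with `rt_ms = 1000 * (delta_s + min passage)`.
#' The test block uses novel sentence ids.
#'
#' @param config A `study_config`.
#' @param truth Ground truth from [build_ground_truth()].
#' @param seed Integer seed.
#' @return Trial data.frame (one row per trial).
#' @export
gen_behavior <- function(config, truth, seed = config$rng_seed) {
  set.seed(seed + 2L)
  K <- config$n_talkers
  ns <- config$n_sentences
  nb <- config$n_training_blocks
  out <- vector("list",
                config$n_participants * length(config$languages) * (nb + 1))
  i <- 0L
  for (lang in names(config$languages)) {
    lt <- truth$languages[[lang]]
    for (p in seq_len(config$n_participants)) {
      gm <- truth$participants$gain_mult[
        truth$participants$participant == p &
          truth$participants$language == lang]
      dm <- truth$participants$delta_mult[
        truth$participants$participant == p][1]
      for (j in seq_len(nb + 1)) {
        test <- j > nb
        sentences <- if (test) ns + seq_len(ns) else seq_len(ns)
        stimuli <- expand.grid(sentence = sentences, talker = seq_len(K))
        ord <- sample.int(nrow(stimuli))
        stimuli <- stimuli[ord, ]
        nt <- nrow(stimuli)
        # sample all K passage times for all trials of the block at once
        mu_trial <- gm * lt$mu[, stimuli$talker, j, drop = TRUE]
        b_trial <- lt$b[, stimuli$talker, j, drop = TRUE]
        tt <- matrix(rinvgauss_fp(K * nt, as.vector(mu_trial),
                                  as.vector(b_trial)), K, nt)
        choice <- apply(tt, 2, which.min)
        dtime <- tt[cbind(choice, seq_len(nt))]
        delta <- dm * truth$delta_s[stimuli$talker]
        i <- i + 1L
        out[[i]] <- data.frame(
          participant = p, language = lang,
          phase = if (test) "test" else "training",
          block = j, trial = seq_len(nt), sentence = stimuli$sentence,
          stimulus_talker = stimuli$talker, response_talker = choice,
          rt_ms = 1000 * (delta + dtime))
      }
    }
  }
  do.call(rbind, out)
}

pupil_kernel <- function(t_ms, n = 10.1, tmax_ms = 930) {
  h <- numeric(length(t_ms))
  pos <- t_ms > 0
  tp <- t_ms[pos]
  h[pos] <- (tp / tmax_ms)^n * exp(n * (1 - tp / tmax_ms))
  h
}

# blink event sampler: Poisson arrivals over the window, lognormal durations
sample_blink_events <- function(n_trials, rate_hz, window_s, meanlog, sdlog) {
  counts <- rpois(n_trials, rate_hz * window_s)
  lapply(counts, function(k) {
    if (k == 0) return(data.frame(onset = numeric(0), duration = numeric(0)))
    data.frame(onset = runif(k, 0, window_s),
               duration = rlnorm(k, meanlog, sdlog))
  })
}

#' Simulate trial-locked pupil traces
#'
#' One raw trace per trial record:
#' `trace = B_p * (1 + (A/100) * h(t) + eps(t))` after stimulus onset and
#' `B_p * (1 + eps(t))` in the baseline window, where `B_p` is the
#' participant's baseline, `h` a unit-peak pupil impulse-response kernel
#' `(t/t_max)^n * exp(n (1 - t/t_max))`, `eps` AR(1) noise, and the
#' amplitude `A = max(0, a0 - a1 * mu_ss)` (percent units) falls with the
#' trial's correct-choice evidence accumulation rate. Blink events arrive
#' as a Poisson process and mask lognormal-duration spans (samples set
#' missing, flagged in `is_blink`).
#'
#' @param config A `study_config`.
#' @param trials Trial table from [gen_behavior()].
#' @param truth Ground truth from [build_ground_truth()].
#' @param seed Integer seed.
#' @return List of raw [pupil_trace()] objects, one per trial row.
#' @export
gen_pupil <- function(config, trials, truth, seed = config$rng_seed) {
  set.seed(seed + 3L)
  pw <- config$pupil_window_ms
  sr <- config$sampling_rate_hz
  dt_ms <- 1000 / sr
  t_ms <- seq(pw[1], pw[2] - dt_ms, by = dt_ms)
  nsamp <- length(t_ms)
  pp <- truth$pupil
  h <- pupil_kernel(t_ms, pp$kernel_n, pp$kernel_tmax_ms)
  phi <- exp(-dt_ms / pp$noise_tau_ms)
  innov_sd <- pp$noise_sd * sqrt(1 - phi^2)
  window_s <- (pw[2] - pw[1]) / 1000
  n <- nrow(trials)
  blinks <- sample_blink_events(n, pp$blink_rate_hz, window_s,
                                pp$blink_dur_meanlog, pp$blink_dur_sdlog)
  amp_all <- numeric(n)
  base_lookup <- truth$participants[!duplicated(truth$participants$participant),
                                    c("participant", "baseline")]
  bl <- setNames(base_lookup$baseline, base_lookup$participant)
  gm_key <- paste(truth$participants$participant, truth$participants$language)
  gm <- setNames(truth$participants$gain_mult, gm_key)
  traces <- vector("list", n)
  any_pos <- FALSE
  for (i in seq_len(n)) {
    lang <- trials$language[i]
    s <- trials$stimulus_talker[i]
    j <- trials$block[i]
    mu_ss <- gm[[paste(trials$participant[i], lang)]] *
      truth$languages[[lang]]$mu[s, s, j]
    A <- max(0, pp$a0 - pp$a1 * mu_ss)
    if (A > 0) any_pos <- TRUE
    eps <- as.numeric(filter(rnorm(nsamp, 0, innov_sd), phi,
                             method = "recursive",
                             init = rnorm(1, 0, pp$noise_sd)))
    x <- bl[[as.character(trials$participant[i])]] *
      (1 + (A / 100) * h + eps)
    mask <- logical(nsamp)
    ev <- blinks[[i]]
    if (nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        lo <- pw[1] + 1000 * ev$onset[k]
        hi <- lo + 1000 * ev$duration[k]
        mask[t_ms >= lo & t_ms < hi] <- TRUE
      }
      x[mask] <- NA_real_
    }
    traces[[i]] <- pupil_trace(trials$participant[i], lang, j,
                               trials$trial[i], t_ms, x, mask, sr, "raw")
  }
  if (!any_pos)
    warning("pupil amplitude is zero for every trial (a1 too large); ",
            "traces are flat")
  traces
}

#' Generate and write a complete synthetic study
#'
#' Writes `trials.csv`, `pupil.csv`, `features_<language>.csv`,
#' `truth.json` and a `manifest.json` recording the seed and a hash of the
#' configuration. Two runs with the same config and seed produce identical
#' outputs.
#'
#' @param config A `study_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
gen_study <- function(config, out_dir, seed = config$rng_seed) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  truth <- build_ground_truth(config, seed)
  trials <- gen_behavior(config, truth, seed)
  pupil <- gen_pupil(config, trials, truth, seed)
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    pupil = file.path(out_dir, "pupil.csv"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_trials(trials, paths$trials)
  write_pupil(pupil, paths$pupil)
  for (lang in names(truth$features)) {
    paths[[paste0("features_", lang)]] <-
      file.path(out_dir, sprintf("features_%s.csv", lang))
    data.table::fwrite(truth$features[[lang]],
                       paths[[paste0("features_", lang)]])
  }
  write_truth(truth, paths$truth)
  cfg_yaml <- yaml::as.yaml(unclass(config), precision = 12L)
  manifest <- list(seed = seed,
                   config_sha = digest_string(cfg_yaml),
                   n_trials = nrow(trials), n_traces = length(pupil))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(list(config = config, truth = truth, trials = trials,
                 pupil = pupil, paths = paths))
}

# small polynomial hash; enough to detect config drift in a manifest
digest_string <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1e9
  sprintf("%09.0f", h)
}
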