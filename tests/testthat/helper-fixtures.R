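# shared fixtures: small configurations and hand-built traces

small_config <- function(n_participants = 2L) {
  cfg <- default_config()
  cfg$n_participants <- as.integer(n_participants)
  cfg
}

# a raw 1000 Hz trace carrying a clean planted kernel, no noise, no blinks
clean_trace <- function(amplitude = 10, baseline = 1000,
                        window = c(-500, 4000), participant = 1,
                        block = 1, trial = 1) {
  t_ms <- seq(window[1], window[2] - 1)
  h <- talkerlearn:::pupil_kernel(t_ms)
  pupil_trace(participant, "native", block, trial, t_ms,
              baseline * (1 + amplitude / 100 * h),
              rep(FALSE, length(t_ms)), rate_hz = 1000)
}

# stacked mean-trace cells generated from the growth-curve model's own
# likelihood (participant random effects on intercept and time terms)
simulate_gca_cells <- function(n_part = 8, n_bins = 30, blocks = 1:2,
                               beta_lang = 0, beta_int = c(1, 0, 0, 0, 0),
                               re_sd = c(0.8, 0.5, 0.5, 0.5, 0.5),
                               noise_sd = 0.5) {
  B <- cbind(1, ortho_basis(n_bins, 4))
  out <- list()
  for (p in seq_len(n_part)) {
    u <- rnorm(5, 0, re_sd)
    for (lang in c("native", "unfamiliar")) for (blk in blocks) {
      fe <- beta_int
      if (lang == "unfamiliar") fe[1] <- fe[1] + beta_lang
      y <- B %*% (fe + u) + rnorm(n_bins, 0, noise_sd)
      out[[length(out) + 1]] <- data.frame(
        participant = p, language = lang, block = blk,
        time_ms = seq(0, by = 20, length.out = n_bins), pupil = as.numeric(y),
        n_trials = 1)
    }
  }
  do.call(rbind, out)
}

# trial table with directly planted cell accuracies / log RTs, bypassing the
# race model (for the mixed-model recovery tests)
planted_trials <- function(n_part = 24, n_block = 4, n_trial = 40,
                           p_fun, logrt_fun, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(participant = seq_len(n_part),
                      language = c("native", "unfamiliar"),
                      block = seq_len(n_block), trial = seq_len(n_trial),
                      stringsAsFactors = FALSE)
  u <- rnorm(n_part)  # participant intercepts
  p <- p_fun(rows, u)
  st <- sample(1:4, nrow(rows), replace = TRUE)
  corr <- stats::rbinom(nrow(rows), 1, p)
  resp <- ifelse(corr == 1, st, ((st + sample(1:3, nrow(rows),
                                              replace = TRUE) - 1) %% 4) + 1)
  data.frame(participant = rows$participant, language = rows$language,
             phase = "training", block = rows$block, trial = rows$trial,
             stimulus_talker = st, response_talker = resp,
             rt_ms = exp(logrt_fun(rows, u) + rnorm(nrow(rows), 0, 0.3)),
             correct = corr)
}
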