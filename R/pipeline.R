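#' Run the full study pipeline on a synthetic dataset
#'
#' Generates a complete study under `config` and `seed`, then runs every
#' analysis stage: accuracy scoring and mixed models, log-RT screening and
#' mixed model, RT-tail trimming and the Bayesian race-model fit per
#' language (training phase), pupil preprocessing, the language x block
#' and evidence-accumulation-rate growth curve models, and the
#' confusion-versus-acoustic-similarity analysis.
#'
#' @param config A `study_config` (default [default_config()]).
#' @param seed Integer seed for the whole run.
#' @param mcmc Optional list overriding the MCMC schedule
#'   (`iters`, `burnin`, `thin`).
#' @param verbose Print stage progress?
#' @return A list with the generated data (`truth`, `trials`), analysis
#'   results per stage, and the seed.
#' @export
run_study_pipeline <- function(config = default_config(),
                               seed = config$rng_seed, mcmc = list(),
                               verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  mc <- modifyList(config$analysis$mcmc, mcmc)
  native <- names(config$languages)[1]

  say("generating study ...")
  truth <- build_ground_truth(config, seed)
  trials <- score_accuracy(gen_behavior(config, truth, seed))
  traces <- gen_pupil(config, trials, truth, seed)

  say("behavior ...")
  training <- trials[trials$phase == "training", ]
  acc_by_block <- aggregate(correct ~ language + block, data = training,
                            FUN = mean)
  acc_model <- fit_accuracy_model(trials, "training", native = native)
  acc_model_test <- fit_accuracy_model(trials, "test", native = native)
  excl <- exclude_rt_outliers(trials, k = config$analysis$rt_outlier_sd)
  rt_model <- fit_rt_model(excl$kept, "training", native = native)

  say("race model ...")
  ddm_fits <- list()
  ea_tables <- list()
  for (lang in names(config$languages)) {
    tl <- training[training$language == lang, ]
    tl <- trim_rt_tails(tl, config$analysis$rt_trim_fraction)
    fit <- fit_ddm(tl, config$n_talkers,
                   iters = mc$iters, burnin = mc$burnin, thin = mc$thin,
                   tau_rw = mc$tau_rw,
                   blocks_independent = mc$blocks_independent,
                   seed = seed + match(lang, names(config$languages)))
    ddm_fits[[lang]] <- fit
    cp <- correct_params(fit)
    mu_blocks <- cp$by_block[cp$by_block$parameter == "mu", ]
    ea_tables[[lang]] <- data.frame(block = mu_blocks$block,
                                    ea = mu_blocks$mean)
  }

  say("pupil ...")
  prep <- preprocess_pupil(
    traces, window = config$pupil_window_ms,
    target_hz = config$analysis$downsample_hz,
    blink_threshold = config$analysis$blink_threshold,
    pad_ms = config$analysis$interp_pad_ms,
    baseline_ms = config$analysis$baseline_window_ms)
  is_training <- vapply(prep$traces, function(tr)
    tr$block <= config$n_training_blocks, logical(1))
  agg <- aggregate_traces(prep$traces[is_training])
  gca_lang <- fit_gca_language_block(agg, order = config$analysis$gca_order,
                                     native = native)
  agg_correct <- aggregate_traces(prep$traces[is_training], trials,
                                  correct_only = TRUE)
  gca_ea <- list()
  for (lang in names(config$languages)) {
    agg_l <- agg_correct[agg_correct$language == lang, ]
    gca_ea[[lang]] <- fit_gca_ea_rate(agg_l, ea_tables[[lang]],
                                      order = config$analysis$gca_order)
  }

  say("error patterns ...")
  conf <- confusion_matrices(training, config$n_talkers)
  asms <- lapply(truth$features, asm_from_features)
  patterns <- reliance_patterns(conf, asms)
  contrast <- compare_languages(patterns, native = native)
  variance <- compare_feature_variance(truth$features[[native]],
                                       truth$features[[setdiff(
                                         names(config$languages), native)]])

  list(seed = seed, config = config, truth = truth, trials = trials,
       behavior = list(acc_by_block = acc_by_block, acc_model = acc_model,
                       acc_model_test = acc_model_test,
                       rt_exclusions = excl$report, rt_model = rt_model),
       ddm = list(fits = ddm_fits, ea = ea_tables),
       pupil = list(report = prep$report, gca_language_block = gca_lang,
                    gca_ea = gca_ea),
       asm = list(asms = asms, reliance = patterns, contrast = contrast,
                  feature_variance = variance))
}
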