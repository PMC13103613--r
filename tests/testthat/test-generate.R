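test_that("talker tables have the fixed six-feature inventory", {
  cfg <- small_config()
  feats <- gen_talkers(cfg, seed = 1)
  expect_named(feats, c("native", "unfamiliar"))
  for (f in feats) {
    expect_equal(nrow(f), 4)
    expect_named(f, c("talker", "mean_f0", "f0_range", "speech_rate",
                      "jitter", "harmonicity", "formant_dispersion"))
    expect_true(all(is.finite(as.matrix(f[-1]))))
    expect_true(all(f$jitter >= 0))
  }
})

test_that("zero feature scales give identical talkers and zero distances", {
  cfg <- small_config()
  for (f in names(cfg$generator$features)) cfg$generator$features[[f]][2] <- 0
  feats <- gen_talkers(cfg, seed = 2)
  D <- -unclass(asm_from_features(feats$native, standardize = FALSE))
  expect_true(all(D == 0))
})

test_that("language distance distributions are exchangeable under defaults", {
  # Both languages draw talkers from identical feature settings, so the
  # between-talker distance distributions are exchangeable. The 6 pairwise
  # distances per language share 4 talkers and are cross-correlated, which
  # makes the Mann-Whitney test anticonservative relative to its nominal
  # level on raw distances (and degenerate on within-language standardized
  # ones); the property asserted here is therefore symmetry of the null,
  # not nominal calibration: p-values are not systematically small and
  # neither language's distances are systematically larger.
  cfg <- small_config()
  nrep <- 400
  set.seed(99)
  seeds <- sample.int(1e6, nrep)
  stats <- vapply(seeds, function(s) {
    feats <- gen_talkers(cfg, seed = s)
    r <- compare_feature_variance(feats$native, feats$unfamiliar,
                                  standardize = FALSE)
    c(p = r$p.value, W = r$W)
  }, numeric(2))
  expect_gt(median(stats["p", ]), 0.15)
  expect_lt(mean(stats["p", ] < 0.05), 0.25)
  expect_gt(mean(stats["p", ] < 0.05), 0.005)
  # W symmetric about its null mean of 18 (6 x 6 / 2)
  expect_lt(abs(mean(stats["W", ]) - 18), 3 * sd(stats["W", ]) / sqrt(nrep))
})

test_that("drift schedule realizes the cue-weighting construction", {
  cfg <- small_config()
  feats <- gen_talkers(cfg, seed = 5)
  asm <- asm_from_features(feats$native)
  sigma <- similarity_weights(asm)

  # w = 1: off-diagonal drifts collapse to mu_base
  cfg$languages$native$w <- 1
  sch <- drift_schedule(cfg, asm, "native", 2)
  off <- sch$mu[row(sch$mu) != col(sch$mu)]
  expect_equal(unname(off), rep(cfg$generator$mu_base, 12))
  # diagonal equals mu_base + gain regardless of w
  expect_equal(unname(diag(sch$mu)),
               rep(cfg$generator$mu_base + cfg$languages$native$gain[2], 4))

  # w = 0: off-diagonal drifts ordered exactly by acoustic similarity
  cfg$languages$native$w <- 0
  sch0 <- drift_schedule(cfg, asm, "native", 2)
  offidx <- which(row(sigma) != col(sigma))
  expect_equal(order(sch0$mu[offidx]), order(sigma[offidx]))

  # default schedules: larger correct-choice drift margin for native, every block
  cfg <- small_config()
  asms <- lapply(gen_talkers(cfg, seed = 5), asm_from_features)
  for (j in 1:4) {
    margin <- vapply(c("native", "unfamiliar"), function(l) {
      sch <- drift_schedule(cfg, asms[[l]], l, j)
      min(diag(sch$mu) - apply(sch$mu - diag(diag(sch$mu)), 2, max))
    }, numeric(1))
    expect_gt(margin["native"], margin["unfamiliar"])
  }

  expect_error(drift_schedule(cfg, asms$native, "native", 9), "block")
  expect_error(drift_schedule(cfg, asms$native, "klingon", 1), "language")
})

test_that("gen_behavior produces the full crossed design", {
  cfg <- default_config()
  truth <- build_ground_truth(cfg, seed = 4)
  trials <- gen_behavior(cfg, truth, seed = 4)
  expect_equal(nrow(trials), 24 * 2 * 5 * 40)
  # every sentence x talker stimulus once per block
  one <- trials[trials$participant == 3 & trials$language == "native" &
                  trials$block == 2, ]
  expect_equal(nrow(one), 40)
  expect_equal(nrow(unique(one[c("sentence", "stimulus_talker")])), 40)
  expect_setequal(unique(one$sentence), 1:10)
  # test phase uses novel sentences
  tst <- trials[trials$phase == "test", ]
  expect_setequal(unique(tst$sentence), 11:20)
  expect_true(all(trials$rt_ms > 0))
})

test_that("a dominant accumulator wins essentially always", {
  cfg <- small_config(1)
  truth <- build_ground_truth(cfg, seed = 6)
  # correct-drift 50x the error drifts, with drifts large relative to the
  # barrier so noise-driven error crossings are negligible
  for (l in names(truth$languages)) {
    mu <- truth$languages[[l]]$mu
    mu[] <- 0.5
    for (j in 1:5) {
      m <- mu[, , j]; diag(m) <- 25; mu[, , j] <- m
    }
    truth$languages[[l]]$mu <- mu
  }
  truth$participants$gain_mult <- 1
  trials <- score_accuracy(gen_behavior(cfg, truth, seed = 6))
  expect_gt(mean(trials$correct), 0.99)
})

test_that("a symmetric race picks each option at the chance rate", {
  set.seed(8)
  sim <- simulate_race(rep(1.3, 4), rep(1.4, 4), 0.3, n = 10000)
  p <- tabulate(sim$choice, 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(p - 0.25) < 3 * se))
})

test_that("pupil traces carry the planted kernel exactly when noise-free", {
  cfg <- small_config(1)
  cfg$generator$pupil$noise_sd <- 0
  cfg$generator$pupil$blink_rate_hz <- 0
  truth <- build_ground_truth(cfg, seed = 9)
  trials <- gen_behavior(cfg, truth, seed = 9)[1:3, ]
  traces <- gen_pupil(cfg, trials, truth, seed = 9)
  tr <- traces[[1]]
  expect_equal(length(tr$pupil), 4500)
  expect_false(any(tr$is_blink))
  i <- 1
  lt <- truth$languages[[trials$language[i]]]
  gm <- truth$participants$gain_mult[
    truth$participants$participant == trials$participant[i] &
      truth$participants$language == trials$language[i]]
  A <- max(0, truth$pupil$a0 -
             truth$pupil$a1 * gm * lt$mu[trials$stimulus_talker[i],
                                         trials$stimulus_talker[i],
                                         trials$block[i]])
  bp <- truth$participants$baseline[
    truth$participants$participant == trials$participant[i]][1]
  rel <- 100 * (tr$pupil / bp - 1)
  # unit-peak kernel: maximum equals A, attained at t = 930 ms
  expect_equal(max(rel), A, tolerance = 1e-10)
  expect_equal(tr$time_ms[which.max(rel)], 930)
  # baseline window is flat at the participant baseline
  expect_equal(unique(tr$pupil[tr$time_ms < 0]), bp)
})

test_that("blink events have the configured Poisson mean", {
  set.seed(10)
  ev <- talkerlearn:::sample_blink_events(10000, rate_hz = 0.2,
                                          window_s = 4.5,
                                          meanlog = log(0.2), sdlog = 0.4)
  counts <- vapply(ev, nrow, integer(1))
  se <- sqrt(0.9 / 10000)
  expect_lt(abs(mean(counts) - 0.9), 3 * se)
})

test_that("zero pupil coupling equalizes expected amplitude across languages", {
  cfg <- small_config(1)
  cfg$generator$pupil$a1 <- 0
  cfg$generator$pupil$noise_sd <- 0
  cfg$generator$pupil$blink_rate_hz <- 0
  truth <- build_ground_truth(cfg, seed = 12)
  trials <- gen_behavior(cfg, truth, seed = 12)
  pick <- c(which(trials$language == "native")[1],
            which(trials$language == "unfamiliar")[1])
  traces <- gen_pupil(cfg, trials[pick, ], truth, seed = 12)
  amp <- vapply(traces, function(tr) {
    bp <- mean(tr$pupil[tr$time_ms < 0])
    max(100 * (tr$pupil / bp - 1))
  }, numeric(1))
  expect_equal(amp[1], amp[2], tolerance = 1e-10)
})

test_that("gen_study writes a reproducible, self-consistent artifact set", {
  cfg <- small_config(1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- gen_study(cfg, d1, seed = 21)
  out2 <- gen_study(cfg, d2, seed = 21)
  for (f in c("trials.csv", "truth.json", "manifest.json",
              "features_native.csv", "features_unfamiliar.csv", "pupil.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # pupil.csv holds 4500 samples per trial
  pup <- data.table::fread(out1$paths$pupil)
  expect_equal(nrow(pup), nrow(out1$trials) * 4500)
  expect_equal(unname(table(pup$trial[pup$block == 1 &
                                        pup$language == "native"])[1]), 4500)
  # truth.json round-trips
  back <- read_truth(out1$paths$truth)
  expect_equal(back$languages$native$mu, out1$truth$languages$native$mu)
})

test_that("default generator expectations match the study's headline pattern", {
  cfg <- default_config()
  gn <- cfg$languages$native$gain
  gu <- cfg$languages$unfamiliar$gain
  mu_n <- cfg$generator$mu_base + gn
  mu_u <- cfg$generator$mu_base + gu
  a0 <- cfg$generator$pupil$a0; a1 <- cfg$generator$pupil$a1
  amp_n <- pmax(0, a0 - a1 * mu_n)
  amp_u <- pmax(0, a0 - a1 * mu_u)
  # native amplitude below unfamiliar in every block
  expect_true(all(amp_n < amp_u))
  # the amplitude gap narrows over training (non-increasing, strictly so
  # by the last block)
  gap <- amp_u - amp_n
  expect_true(all(diff(gap) <= 1e-12))
  expect_lt(gap[4], gap[1])
})
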