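test_that("ASM construction negates Euclidean distances over the features", {
  # two identical talkers: similarity 0 (maximal)
  f2 <- data.frame(talker = 1:2, mean_f0 = c(150, 150), f0_range = c(60, 60),
                   speech_rate = c(4, 4), jitter = c(1, 1),
                   harmonicity = c(10, 10), formant_dispersion = c(900, 900))
  a2 <- asm_from_features(f2, standardize = FALSE)
  expect_equal(a2[1, 2], 0)

  # unit vectors along axes: pairwise distance sqrt(2), similarity -sqrt(2)
  f3 <- data.frame(talker = 1:3, mean_f0 = c(1, 0, 0), f0_range = c(0, 1, 0),
                   speech_rate = c(0, 0, 1), jitter = 0, harmonicity = 0,
                   formant_dispersion = 0)
  a3 <- asm_from_features(f3, standardize = FALSE)
  off <- a3[row(a3) != col(a3)]
  expect_equal(unname(off), rep(-sqrt(2), 6))

  # symmetric with zero diagonal, non-positive off-diagonal
  set.seed(60)
  f4 <- gen_talkers(small_config(), seed = 3)$native
  a4 <- asm_from_features(f4)
  expect_equal(unclass(a4), t(unclass(a4)), ignore_attr = TRUE)
  expect_equal(unname(diag(a4)), rep(0, 4))
  expect_true(all(a4[row(a4) != col(a4)] < 0))

  f0 <- f4; f0$jitter <- 1
  expect_error(asm_from_features(f0), "jitter")
})

test_that("similarity weights rescale to [0, 1] with unit diagonal", {
  f <- gen_talkers(small_config(), seed = 4)$native
  s <- similarity_weights(asm_from_features(f))
  expect_equal(unname(diag(s)), rep(1, 4))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(min(s), 0)  # the most dissimilar pair anchors 0
})

test_that("error-acoustic correlation pairs off-diagonal cells symmetrically", {
  f <- gen_talkers(small_config(), seed = 5)$native
  asm <- asm_from_features(f)
  # confusion cells a strictly increasing function of similarity: rho = 1
  K <- 4
  off <- which(row(matrix(0, K, K)) != col(matrix(0, K, K)))
  conf <- matrix(0, K, K)
  conf[off] <- plogis(unclass(asm)[off])
  r <- error_acoustic_correlation(conf, asm)
  expect_equal(r$n_pairs, 12)
  expect_equal(r$rho, 1)

  # missing rows are dropped pairwise
  conf[2, ] <- NA
  r2 <- error_acoustic_correlation(conf, asm)
  expect_equal(r2$n_pairs, 9)
  conf3 <- matrix(NA_real_, K, K); conf3[1, 2] <- 0.5
  expect_error(error_acoustic_correlation(conf3, asm), "fewer than 3")
})

test_that("rho is invariant to strictly increasing transforms of similarity", {
  set.seed(61)
  f <- gen_talkers(small_config(), seed = 6)$native
  asm <- asm_from_features(f)
  conf <- matrix(runif(16), 4, 4)
  diag(conf) <- 0
  conf <- conf / rowSums(conf)
  base <- error_acoustic_correlation(conf, asm)$rho
  for (tf in list(function(x) 2 * x + 5, function(x) -1 / (x - 1e-9),
                  function(x) exp(x / 2))) {
    a2 <- unclass(asm)
    a2[] <- tf(a2)
    expect_equal(error_acoustic_correlation(conf, a2)$rho, base)
  }
})

test_that("tie-corrected Spearman matches a brute-force rank computation", {
  set.seed(62)
  for (r in 1:20) {
    f <- gen_talkers(small_config(), seed = 100 + r)$native
    asm <- asm_from_features(f)
    counts <- matrix(stats::rmultinom(4, 10, prob = rep(0.25, 4)), 4, 4,
                     byrow = TRUE)
    conf <- counts / rowSums(counts)
    got <- error_acoustic_correlation(conf, asm)$rho
    off <- which(row(conf) != col(conf))
    x <- conf[off]; y <- unclass(asm)[off]
    want <- suppressWarnings(cor.test(x, y, method = "spearman")$estimate)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("confusions simulated independently of acoustics give null rho", {
  # w = 1 race: error direction carries no acoustic structure
  set.seed(63)
  cfg <- small_config()
  cfg$languages$native$w <- 1
  rhos <- replicate(300, {
    f <- gen_talkers(cfg, seed = sample.int(1e6, 1))$native
    asm <- asm_from_features(f)
    sch <- drift_schedule(cfg, asm, "native", 2)
    tr <- do.call(rbind, lapply(1:4, function(s) {
      sim <- simulate_race(sch$mu[, s], sch$b[, s], 0.3, 50)
      data.frame(participant = 1, language = "native", block = 1,
                 stimulus_talker = s, response_talker = sim$choice)
    }))
    conf <- confusion_matrices(tr, 4)$matrices[[1]]
    error_acoustic_correlation(conf, asm)$rho
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(300))
})

test_that("acoustic reliance falls as the cue weight rises", {
  # monotone linkage over a grid of w, >= 2000 trials per point; expected
  # accuracy rises with w as the off-diagonal drifts shrink
  set.seed(64)
  cfg <- small_config()
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  stats <- sapply(grid, function(w) {
    cfg$languages$native$w <- w
    rho <- acc <- 0
    nrep <- 8
    for (r in 1:nrep) {
      f <- gen_talkers(cfg, seed = 7000 + r)$native
      asm <- asm_from_features(f)
      sch <- drift_schedule(cfg, asm, "native", 2)
      tr <- do.call(rbind, lapply(1:4, function(s) {
        sim <- simulate_race(sch$mu[, s], sch$b[, s], 0.3, 63)
        data.frame(participant = 1, language = "native", block = 1,
                   stimulus_talker = s, response_talker = sim$choice)
      }))
      conf <- confusion_matrices(tr, 4)$matrices[[1]]
      rho <- rho + error_acoustic_correlation(conf, asm)$rho / nrep
      acc <- acc + mean(tr$stimulus_talker == tr$response_talker) / nrep
    }
    c(rho = rho, acc = acc)
  })
  # non-increasing reliance, increasing accuracy, up to Monte-Carlo slack
  expect_lt(stats["rho", 5], stats["rho", 1] - 0.2)
  expect_true(all(diff(stats["rho", ]) < 0.08))
  expect_gt(stats["acc", 5], stats["acc", 1] + 0.05)
  expect_true(all(diff(stats["acc", ]) > -0.03))
})

test_that("language comparison pairs participants and tests the difference", {
  set.seed(65)
  mk <- function(rho_n, rho_u, n = 24) {
    rbind(
      data.frame(participant = rep(1:n, each = 4), language = "native",
                 block = 1:4, rho = rnorm(4 * n, rho_n, 0.15), n_pairs = 12),
      data.frame(participant = rep(1:n, each = 4), language = "unfamiliar",
                 block = 1:4, rho = rnorm(4 * n, rho_u, 0.15), n_pairs = 12))
  }
  res <- compare_languages(mk(0.05, 0.35))
  expect_gt(res$difference$mean, 0)
  expect_lt(res$test$p.value, 0.05)
  expect_equal(nrow(res$by_participant), 24)

  res0 <- compare_languages(mk(0.2, 0.2))
  expect_lt(abs(res0$difference$mean), 2 * res0$difference$sem)

  one <- mk(0.05, 0.35, n = 1)
  res1 <- compare_languages(one)
  expect_null(res1$test)
  expect_equal(nrow(res1$descriptives), 2)
})

test_that("feature-variance comparison uses the 6 pairwise distances per language", {
  f <- gen_talkers(small_config(), seed = 8)
  res <- compare_feature_variance(f$native, f$unfamiliar)
  expect_length(res$distances_a, 6)
  expect_length(res$distances_b, 6)
  expect_true(res$p.value >= 0 && res$p.value <= 1)

  # identical tables: maximal ties, p ~ 1
  same <- compare_feature_variance(f$native, f$native)
  expect_gt(same$p.value, 0.9)

  # a x10 scale separation is detected on raw-unit distances
  big <- f$native
  for (cn in names(big)[-1]) big[[cn]] <- big[[cn]] * 10
  apart <- compare_feature_variance(f$native, big, standardize = FALSE)
  expect_lt(apart$p.value, 0.05)
})
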