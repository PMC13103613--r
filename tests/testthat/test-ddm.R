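test_that("first-passage density matches its closed form and normalizes", {
  expect_equal(ig_fpt_density(1, 1, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  # t -> 0+ limit
  expect_lt(ig_fpt_density(1e-6, 1.5, 1), 1e-100)
  # unit mass under quadrature
  expect_equal(integrate(function(t) ig_fpt_density(t, 1.5, 2), 0, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  expect_error(ig_fpt_density(-1, 1, 1), "positive")
  expect_error(ig_fpt_density(1, 0, 1), "positive")
})

test_that("survival is the complement of the integrated density", {
  expect_equal(ig_fpt_survival(0, 1, 1), 1)
  expect_lt(ig_fpt_survival(100, 1, 1), 1e-6)
  for (tt in c(0.05, 0.3, 0.9, 2, 6)) {
    expect_equal(
      ig_fpt_survival(tt, 1.3, 1.7) +
        integrate(function(u) ig_fpt_density(u, 1.3, 1.7), 0, tt,
                  rel.tol = 1e-11)$value,
      1, tolerance = 1e-8)
  }
  s <- ig_fpt_survival(seq(0, 5, by = 0.1), 1.2, 1.4)
  expect_true(all(diff(s) <= 0))
})

test_that("race log-likelihood composes density and survivals", {
  params <- list(mu = array(c(1.5, 1.0, 0.8, 1.2), c(1, 1, 1)),
                 b = array(1.4, c(1, 1, 1)), delta = 0.3)
  # K = 1 reduces to the lone density
  p1 <- list(mu = array(2, c(1, 1, 1)), b = array(1.5, c(1, 1, 1)),
             delta = 0.3)
  expect_equal(race_loglik(1, 1000, 1, p1, 1),
               ig_fpt_density(0.7, 2, 1.5, log = TRUE))
  # K = 4 explicit composition
  K <- 4
  p4 <- list(mu = array(rep(c(2, 1.1, 0.9, 1.4), 4), c(K, K, 1)),
             b = array(1.5, c(K, K, 1)), delta = rep(0.25, K))
  ll <- race_loglik(2, 900, 3, p4, 1)
  tau <- 0.9 - 0.25
  expect_equal(ll, ig_fpt_density(tau, p4$mu[2, 3, 1], 1.5, log = TRUE) +
                 sum(ig_fpt_survival(tau, p4$mu[c(1, 3, 4), 3, 1], 1.5,
                                     log = TRUE)))
  # non-positive decision time flagged
  bad <- race_loglik(1, 200, 3, p4, 1)
  expect_identical(as.numeric(bad), -Inf)
  expect_true(attr(bad, "invalid"))
})

test_that("symmetric accumulators imply 1/4 win probability each", {
  wp <- race_win_prob(rep(1.4, 4), rep(1.3, 4))
  expect_equal(wp, rep(0.25, 4), tolerance = 1e-7)
})

test_that("win probabilities conserve probability for arbitrary parameters", {
  set.seed(14)
  for (r in 1:5) {
    K <- sample(2:5, 1)
    mu <- runif(K, 0.4, 3)
    b <- runif(K, 0.6, 2.5)
    expect_equal(sum(race_win_prob(mu, b)), 1, tolerance = 1e-6)
  }
})

test_that("the exact sampler matches the inverse-Gaussian law and quadrature", {
  set.seed(15)
  x <- rinvgauss_fp(100000, 2, 1)
  se <- sd(x) / sqrt(100000)
  expect_lt(abs(mean(x) - 0.5), 3 * se)

  mu <- c(2.0, 1.3, 1.1, 1.6); b <- rep(1.5, 4)
  wp <- race_win_prob(mu, b)
  sim <- simulate_race(mu, b, 0.35, n = 50000)
  emp <- tabulate(sim$choice, 4) / 50000
  expect_true(all(abs(emp - wp) < 3 * sqrt(wp * (1 - wp) / 50000)))
  expect_true(all(sim$rt > 0.35))
})

test_that("RT-tail trimming removes floor(fraction*n) per side with stable ties", {
  mk <- function(n, rt) data.frame(participant = 1, language = "native",
                                   phase = "training", block = 1,
                                   trial = seq_len(n), stimulus_talker = 1,
                                   response_talker = 1, rt_ms = rt)
  t100 <- mk(100, c(5000, seq(900, 1100, length.out = 98), 100))
  kept <- trim_rt_tails(t100, 0.01)
  expect_equal(nrow(kept), 98)
  expect_false(any(kept$rt_ms %in% c(100, 5000)))

  expect_equal(nrow(trim_rt_tails(mk(50, runif(50, 500, 900)), 0.01)), 50)

  ties <- mk(200, rep(700, 200))
  keptt <- trim_rt_tails(ties, 0.01)
  expect_equal(attr(keptt, "n_trimmed"), 4)
  # stable order: first two and last two by input order removed
  expect_equal(keptt$trial, 3:198)

  # grouping is per participant x language
  two <- rbind(t100, transform(t100, participant = 2))
  expect_equal(nrow(trim_rt_tails(two, 0.01)), 196)
})

test_that("posterior chains are reproducible under a fixed seed", {
  set.seed(77)
  sim <- simulate_race(c(2, 1, 1, 1.2), rep(1.4, 4), 0.3, n = 300)
  tr <- data.frame(participant = 1, language = "x", block = 1,
                   stimulus_talker = sample(1:4, 300, TRUE),
                   response_talker = sim$choice, rt_ms = 1000 * sim$rt)
  f1 <- fit_ddm(tr, 4, iters = 400, burnin = 100, thin = 2, seed = 5)
  f2 <- fit_ddm(tr, 4, iters = 400, burnin = 100, thin = 2, seed = 5)
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_identical(f1$draws$delta, f2$draws$delta)
  f3 <- fit_ddm(tr, 4, iters = 400, burnin = 100, thin = 2, seed = 6)
  expect_false(identical(f1$draws$mu, f3$draws$mu))
})

test_that("credible intervals contract as trials per cell grow", {
  widths <- vapply(c(50, 200, 800), function(n) {
    set.seed(n)
    tr <- do.call(rbind, lapply(1:2, function(s) {
      mu <- c(2, 1); if (s == 2) mu <- rev(mu)
      sim <- simulate_race(mu, c(1.5, 1.5), 0.35, n)
      data.frame(participant = 1, language = "x", block = 1,
                 stimulus_talker = s, response_talker = sim$choice,
                 rt_ms = 1000 * sim$rt)
    }))
    fit <- fit_ddm(tr, 2, iters = 1500, burnin = 600, thin = 3, seed = 1)
    fit$mu$upper[1, 1, 1] - fit$mu$lower[1, 1, 1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("correct_params restricts to the diagonal and flags nonoverlap", {
  set.seed(31)
  rows <- list()
  for (s in 1:4) for (j in 1:4) {
    mu <- rep(1, 4); mu[s] <- 2
    sim <- simulate_race(mu, rep(1.5, 4), 0.35, n = 60)
    rows[[length(rows) + 1]] <- data.frame(
      participant = 1, language = "x", block = j, stimulus_talker = s,
      response_talker = sim$choice, rt_ms = 1000 * sim$rt)
  }
  fit <- fit_ddm(do.call(rbind, rows), 4, iters = 800, burnin = 300,
                 thin = 2, seed = 9)
  cp <- correct_params(fit)
  expect_equal(nrow(cp$by_stimulus), 2 * 16)  # mu and b, 4 stimuli x 4 blocks
  expect_equal(nrow(cp$by_block), 8)
  expect_true(all(cp$by_stimulus$lower <= cp$by_stimulus$mean))
  expect_true(all(cp$by_stimulus$mean <= cp$by_stimulus$upper))
  # constant truth across blocks: intervals overlap
  expect_false(any(cp$nonoverlap$mu[upper.tri(cp$nonoverlap$mu)]))
  expect_true(isSymmetric(unname(cp$nonoverlap$mu)))
})

test_that("empty stimulus-block cells warn and stay prior-dominated", {
  set.seed(32)
  sim <- simulate_race(c(2, 1), c(1.5, 1.5), 0.35, 120)
  tr <- data.frame(participant = 1, language = "x",
                   block = rep(1:2, each = 60), stimulus_talker = 1,
                   response_talker = sim$choice, rt_ms = 1000 * sim$rt)
  tr2 <- rbind(tr, transform(tr[1:60, ], stimulus_talker = 2, block = 1))
  expect_warning(fit_ddm(tr2, 2, iters = 300, burnin = 100, thin = 2,
                         seed = 2), "empty")
})
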