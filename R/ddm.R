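#' First-passage density of a drifting Wiener process
#'
#' Density (in 1/s) of the first passage time of a unit-diffusion Wiener
#' process with drift `mu` through an absorbing barrier `b`:
#' `b * (2 pi t^3)^(-1/2) * exp(-(b - mu t)^2 / (2 t))`, the
#' inverse-Gaussian law with mean `b / mu` and shape `b^2`. Computed in log
#' space internally.
#'
#' @param t Time in seconds (> 0).
#' @param mu Drift rate (> 0).
#' @param b Barrier (> 0).
#' @param log Return the log density?
#' @return Density values, recycled over arguments.
#' @export
ig_fpt_density <- function(t, mu, b, log = FALSE) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  if (any(b <= 0)) stop("b must be positive", call. = FALSE)
  n <- max(length(t), length(mu), length(b))
  t <- rep_len(t, n); mu <- rep_len(mu, n); b <- rep_len(b, n)
  ld <- cpp_lfpt_density(t, mu, b)
  if (log) ld else exp(ld)
}

#' Survival function of the Wiener first-passage time
#'
#' `P(T > t)` for the first-passage law of [ig_fpt_density()];
#' `ig_fpt_survival(0, ...) = 1` and the function is non-increasing in `t`.
#'
#' @inheritParams ig_fpt_density
#' @return Survival probabilities.
#' @export
ig_fpt_survival <- function(t, mu, b, log = FALSE) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  if (any(b <= 0)) stop("b must be positive", call. = FALSE)
  n <- max(length(t), length(mu), length(b))
  t <- rep_len(t, n); mu <- rep_len(mu, n); b <- rep_len(b, n)
  ls <- numeric(n)
  pos <- t > 0
  ls[!pos] <- 0
  if (any(pos)) ls[pos] <- cpp_lfpt_survival(t[pos], mu[pos], b[pos])
  if (log) ls else exp(ls)
}

#' Exact sampler for Wiener first-passage times
#'
#' Draws from the inverse-Gaussian first-passage law (mean `b/mu`, shape
#' `b^2`) by the Michael-Schucany-Haas transformation.
#'
#' @param n Number of draws.
#' @inheritParams ig_fpt_density
#' @return Numeric vector of passage times (s).
#' @export
rinvgauss_fp <- function(n, mu, b) {
  stopifnot(all(mu > 0), all(b > 0))
  m <- rep_len(b / mu, n)
  l <- rep_len(b^2, n)
  y <- rnorm(n)^2
  x <- m + m^2 * y / (2 * l) - m / (2 * l) * sqrt(4 * m * l * y + m^2 * y^2)
  u <- runif(n)
  ifelse(u <= m / (m + x), x, m^2 / x)
}

#' Race log-likelihood of one trial
#'
#' For a trial on which stimulus `s` drew response `d` at `rt_ms`, the race
#' likelihood is the first-passage density of accumulator `d` at the
#' decision time `tau = rt_ms/1000 - delta_s`, times the survival of every
#' other accumulator at `tau`. Returns `-Inf` (with attribute
#' `invalid = TRUE`) when `tau <= 0`.
#'
#' @param d Response option (1..K).
#' @param rt_ms Response time in ms.
#' @param s Stimulus category (1..K).
#' @param params A `race_params` list with arrays `mu[d, s, block]`,
#'   `b[d, s, block]` and offset vector `delta[s]` (s).
#' @param block Block index.
#' @return Scalar log-likelihood.
#' @export
race_loglik <- function(d, rt_ms, s, params, block = 1) {
  K <- dim(params$mu)[1]
  if (d < 1 || d > K || s < 1 || s > K) stop("invalid response/stimulus index",
                                             call. = FALSE)
  tau <- rt_ms / 1000 - params$delta[s]
  if (tau <= 0) {
    out <- -Inf
    attr(out, "invalid") <- TRUE
    return(out)
  }
  mu <- params$mu[, s, block]
  b <- params$b[, s, block]
  ll <- ig_fpt_density(tau, mu[d], b[d], log = TRUE)
  others <- setdiff(seq_len(K), d)
  if (length(others))
    ll <- ll + sum(ig_fpt_survival(tau, mu[others], b[others], log = TRUE))
  ll
}

#' Analytic race win probabilities and binned joint distribution
#'
#' `race_win_prob()` integrates density x product-of-survivals for each
#' accumulator over (0, Inf); the probabilities sum to 1 for any positive
#' parameter set. `race_joint_prob()` integrates the same product over RT
#' bins, giving the implied joint (choice, RT bin) distribution.
#'
#' @param mu,b Vectors of drift rates and barriers, one per accumulator.
#' @param breaks Bin edges for the decision time (s), strictly increasing.
#' @param rel.tol Quadrature tolerance.
#' @return For `race_win_prob`, a vector of win probabilities; for
#'   `race_joint_prob`, a K x (length(breaks) - 1) matrix.
#' @export
race_win_prob <- function(mu, b, rel.tol = 1e-10) {
  K <- length(mu)
  stopifnot(length(b) == K, all(mu > 0), all(b > 0))
  vapply(seq_len(K), function(d) {
    f <- function(t) {
      ld <- ig_fpt_density(t, mu[d], b[d], log = TRUE)
      for (k in setdiff(seq_len(K), d))
        ld <- ld + ig_fpt_survival(t, mu[k], b[k], log = TRUE)
      exp(ld)
    }
    integrate(f, 0, Inf, rel.tol = rel.tol, subdivisions = 500L)$value
  }, numeric(1))
}

#' @rdname race_win_prob
#' @export
race_joint_prob <- function(mu, b, breaks, rel.tol = 1e-9) {
  K <- length(mu)
  stopifnot(length(b) == K, !is.unsorted(breaks, strictly = TRUE))
  out <- matrix(0, K, length(breaks) - 1)
  for (d in seq_len(K)) {
    f <- function(t) {
      ld <- ig_fpt_density(t, mu[d], b[d], log = TRUE)
      for (k in setdiff(seq_len(K), d))
        ld <- ld + ig_fpt_survival(t, mu[k], b[k], log = TRUE)
      exp(ld)
    }
    for (j in seq_len(ncol(out))) {
      lo <- max(breaks[j], 1e-12)
      hi <- breaks[j + 1]
      if (hi > lo)
        out[d, j] <- integrate(f, lo, hi, rel.tol = rel.tol,
                               subdivisions = 500L)$value
    }
  }
  out
}

#' Sample choices and response times from the race model
#'
#' Each accumulator's passage time is drawn exactly from its
#' inverse-Gaussian law; the response is the accumulator with the smallest
#' passage time and the decision time is `delta + min passage`.
#'
#' @param mu,b Vectors of drift rates and barriers, one per accumulator.
#' @param delta Non-decision offset (s).
#' @param n Number of trials.
#' @return Data.frame with columns `choice` and `rt` (s).
#' @export
simulate_race <- function(mu, b, delta = 0, n = 1) {
  K <- length(mu)
  stopifnot(length(b) == K, n >= 1)
  tt <- matrix(rinvgauss_fp(n * K, rep(mu, each = n), rep(b, each = n)), n, K)
  choice <- max.col(-tt)
  rt <- delta + tt[cbind(seq_len(n), choice)]
  data.frame(choice = choice, rt = rt)
}

#' Brute-force diffusion simulation of the race
#'
#' Simulates the K Wiener paths directly (Euler-Maruyama, with a
#' Brownian-bridge correction for within-step barrier crossings) and
#' records the first accumulator to cross. Used as an independent oracle
#' for [simulate_race()] and [race_joint_prob()]; far slower than the
#' exact sampler.
#'
#' @inheritParams simulate_race
#' @param dt Step size (s), e.g. 1e-4.
#' @param horizon Give up (choice `NA`) after this many seconds.
#' @param seed Integer seed for the simulator's own RNG.
#' @return Data.frame with columns `choice` (NA if no crossing) and `rt` (s).
#' @export
simulate_race_paths <- function(mu, b, delta = 0, n = 1, dt = 1e-4,
                                horizon = 10, seed = 1) {
  K <- length(mu)
  stopifnot(length(b) == K, n >= 1, dt > 0)
  res <- cpp_race_em(mu, b, as.integer(n), dt, horizon, as.numeric(seed))
  choice <- res$choice
  choice[choice == 0L] <- NA_integer_
  data.frame(choice = choice, rt = delta + res$time)
}

#' Trim response-time tails
#'
#' Removes the `floor(fraction * n)` fastest and slowest trials within each
#' participant x language group, with ties broken by stable input order.
#'
#' @param trials Trial data.frame with `rt_ms`.
#' @param fraction Tail fraction per side (default 0.01).
#' @return The kept trials, with an attribute `n_trimmed`.
#' @export
trim_rt_tails <- function(trials, fraction = 0.01) {
  stopifnot(fraction >= 0, fraction < 0.5)
  grp <- interaction(trials$participant, trials$language, drop = TRUE)
  drop <- logical(nrow(trials))
  for (g in levels(grp)) {
    ix <- which(grp == g)
    k <- floor(fraction * length(ix))
    if (k == 0) next
    ord <- ix[order(trials$rt_ms[ix])]  # stable: ties keep input order
    drop[head(ord, k)] <- TRUE
    drop[tail(ord, k)] <- TRUE
  }
  out <- trials[!drop, , drop = FALSE]
  attr(out, "n_trimmed") <- sum(drop)
  out
}

#' Bayesian fit of the block-varying race model
#'
#' Adaptive random-walk Metropolis on `log mu[d, s, block]`,
#' `log b[d, s, block]` and logit-scaled per-stimulus offsets (bounded by
#' the minimum observed decision RT per stimulus). Priors are
#' lognormal(0, 1) on drifts and thresholds, with blocks coupled by a
#' Gaussian random walk on the log scale (sd `tau_rw`) unless
#' `blocks_independent`. The offset prior is uniform on its support.
#'
#' @param trials Training-phase trials of one language (columns
#'   `stimulus_talker`, `response_talker`, `block`, `rt_ms`).
#' @param n_talkers Number of response options K.
#' @param iters,burnin,thin MCMC schedule (defaults 6000 / 2000 / 5).
#' @param tau_rw Random-walk prior sd on the log scale.
#' @param blocks_independent Drop the across-block coupling?
#' @param prior_sd Prior sd of the log parameters at block 1.
#' @param seed Integer seed.
#' @return An object of class `ddm_fit`: posterior draws, means, 95\%
#'   pointwise credible intervals and effective sample sizes per parameter,
#'   acceptance rates, and the schedule used.
#' @export
fit_ddm <- function(trials, n_talkers, iters = 6000, burnin = 2000, thin = 5,
                    tau_rw = 0.3, blocks_independent = FALSE, prior_sd = 1,
                    seed = 1) {
  stopifnot(nrow(trials) > 0, iters > burnin, thin >= 1)
  K <- as.integer(n_talkers)
  blocks <- sort(unique(trials$block))
  B <- length(blocks)
  blk0 <- match(trials$block, blocks) - 1L
  s0 <- as.integer(trials$stimulus_talker) - 1L
  d0 <- as.integer(trials$response_talker) - 1L
  if (any(s0 < 0 | s0 >= K | d0 < 0 | d0 >= K))
    stop("talker index out of range 1..", K, call. = FALSE)
  rt <- trials$rt_ms / 1000
  delta_upper <- vapply(seq_len(K) - 1L, function(s) {
    rts <- rt[s0 == s]
    if (!length(rts)) stop("no trials for stimulus ", s + 1, call. = FALSE)
    0.999 * min(rts)
  }, numeric(1))
  empty <- 0L
  for (s in seq_len(K)) for (j in seq_len(B))
    if (!any(s0 == s - 1L & blk0 == j - 1L)) empty <- empty + 1L
  if (empty > 0)
    warning(empty, " empty stimulus x block cell(s); estimates there are ",
            "prior-dominated")
  set.seed(seed)
  raw <- cpp_ddm_mcmc(d0, s0, blk0, rt, K, B, delta_upper,
                      as.integer(iters), as.integer(burnin), as.integer(thin),
                      tau_rw, isTRUE(blocks_independent), prior_sd)
  nsave <- nrow(raw$mu)
  mu_draws <- array(raw$mu, c(nsave, K, K, B))
  b_draws <- array(raw$b, c(nsave, K, K, B))
  summ <- function(draws) {
    m <- apply(draws, 2:4, mean)
    lo <- apply(draws, 2:4, quantile, probs = 0.025, names = FALSE)
    hi <- apply(draws, 2:4, quantile, probs = 0.975, names = FALSE)
    es <- apply(draws, 2:4, ess)
    list(mean = m, lower = lo, upper = hi, ess = es)
  }
  fit <- list(
    mu = summ(mu_draws), b = summ(b_draws),
    delta = list(mean = colMeans(raw$delta),
                 lower = apply(raw$delta, 2, quantile, 0.025, names = FALSE),
                 upper = apply(raw$delta, 2, quantile, 0.975, names = FALSE),
                 ess = apply(raw$delta, 2, ess)),
    draws = list(mu = mu_draws, b = b_draws, delta = raw$delta),
    accept = list(mu = raw$accept_mu, b = raw$accept_b,
                  delta = raw$accept_delta),
    schedule = list(iters = iters, burnin = burnin, thin = thin,
                    tau_rw = tau_rw, blocks_independent = blocks_independent),
    K = K, blocks = blocks, seed = seed)
  class(fit) <- "ddm_fit"
  fit
}

# effective sample size via initial positive autocorrelation sums
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit: K = %d, %d blocks, schedule %d/%d/%d%s>\n",
              x$K, length(x$blocks), x$schedule$iters, x$schedule$burnin,
              x$schedule$thin,
              if (x$schedule$blocks_independent) ", independent blocks" else ""))
  invisible(x)
}

#' Correct-trial race parameters per block
#'
#' Restricts the posterior to the diagonal (response = stimulus) drift and
#' threshold parameters, reports them per stimulus and block, aggregates
#' across stimuli by averaging the posterior draws, and flags block pairs
#' whose 95\% pointwise credible intervals do not overlap.
#'
#' @param fit A [fit_ddm()] result.
#' @return List with `by_stimulus` (data.frame), `by_block` (data.frame of
#'   the across-stimulus aggregate), and `nonoverlap` (named list of
#'   block-pair flag matrices for mu and b).
#' @export
correct_params <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  K <- fit$K
  B <- length(fit$blocks)
  rows <- list()
  for (par in c("mu", "b")) {
    s3 <- fit[[par]]
    for (s in seq_len(K)) for (j in seq_len(B)) {
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, stimulus = s, block = fit$blocks[j],
        mean = s3$mean[s, s, j], lower = s3$lower[s, s, j],
        upper = s3$upper[s, s, j])
    }
  }
  by_stimulus <- do.call(rbind, rows)

  agg_rows <- list()
  nonoverlap <- list()
  for (par in c("mu", "b")) {
    draws <- fit$draws[[par]]
    # average the d = s draws over stimuli, per block
    diag_draws <- vapply(seq_len(B), function(j) {
      rowMeans(vapply(seq_len(K), function(s) draws[, s, s, j],
                      numeric(dim(draws)[1])))
    }, numeric(dim(draws)[1]))
    m <- colMeans(diag_draws)
    lo <- apply(diag_draws, 2, quantile, 0.025, names = FALSE)
    hi <- apply(diag_draws, 2, quantile, 0.975, names = FALSE)
    agg_rows[[par]] <- data.frame(parameter = par, block = fit$blocks,
                                  mean = m, lower = lo, upper = hi)
    flag <- matrix(FALSE, B, B,
                   dimnames = list(fit$blocks, fit$blocks))
    for (i in seq_len(B)) for (j in seq_len(B))
      flag[i, j] <- (lo[i] > hi[j]) || (lo[j] > hi[i])
    nonoverlap[[par]] <- flag
  }
  list(by_stimulus = by_stimulus,
       by_block = do.call(rbind, agg_rows),
       nonoverlap = nonoverlap)
}
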