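#' Score trial accuracy
#'
#' Adds (or recomputes) a `correct` column: 1 when the response talker
#' matches the stimulus talker, 0 otherwise. Input order is preserved.
#'
#' @param trials Trial data.frame.
#' @return The trials with an integer `correct` column.
#' @export
score_accuracy <- function(trials) {
  trials$correct <- as.integer(trials$stimulus_talker ==
                                 trials$response_talker)
  trials
}

#' Exclude log-RT outliers
#'
#' Log-transforms response times and, within each
#' participant x language x block cell, drops trials whose log RT deviates
#' from the cell mean by strictly more than `k` cell standard deviations.
#' A trial at exactly `mean + k * sd` is retained, and cells with zero
#' spread exclude nothing. Language is part of the cell because the two
#' language conditions are run in separate sessions.
#'
#' Note the screen is not idempotent: re-running it on the kept trials
#' recomputes the cell statistics and may drop further trials.
#'
#' @param trials Trial data.frame with positive `rt_ms`.
#' @param k Deviation threshold in standard deviations (default 3).
#' @return List with `kept` (trials), `excluded` (trials), and `report`
#'   (n_total, n_excluded, pct_excluded).
#' @export
exclude_rt_outliers <- function(trials, k = 3) {
  stopifnot(all(trials$rt_ms > 0))
  lrt <- log(trials$rt_ms)
  cell <- interaction(trials$participant, trials$language, trials$block,
                      drop = TRUE)
  drop <- logical(nrow(trials))
  for (g in levels(cell)) {
    ix <- which(cell == g)
    m <- mean(lrt[ix])
    s <- sd(lrt[ix])
    if (is.na(s) || s == 0) next
    drop[ix] <- abs(lrt[ix] - m) > k * s
  }
  report <- list(n_total = nrow(trials), n_excluded = sum(drop),
                 pct_excluded = 100 * sum(drop) / nrow(trials))
  list(kept = trials[!drop, , drop = FALSE],
       excluded = trials[drop, , drop = FALSE],
       report = report)
}

#' Behavioral confusion matrices
#'
#' Builds, for each group (participant x language x block by default), the
#' K x K matrix of response proportions: cell (i, j) is the proportion of
#' trials on which talker i was heard and talker j was answered. Rows are
#' normalized per stimulus; a stimulus row with zero trials is `NA`
#' (missing), never zero.
#'
#' @param trials Trial data.frame.
#' @param n_talkers Number of talkers K.
#' @param by Grouping columns.
#' @return List with `groups` (data.frame, one row per group), `matrices`
#'   (list of K x K proportion matrices), and `counts` (list of per-row
#'   trial counts).
#' @export
confusion_matrices <- function(trials, n_talkers,
                               by = c("participant", "language", "block")) {
  K <- n_talkers
  if (any(trials$stimulus_talker < 1 | trials$stimulus_talker > K |
          trials$response_talker < 1 | trials$response_talker > K))
    stop("talker index out of range 1..", K, call. = FALSE)
  grp <- interaction(trials[by], drop = TRUE, lex.order = TRUE)
  idx_split <- split(seq_len(nrow(trials)), grp)
  first <- vapply(idx_split, `[`, integer(1), 1)
  groups <- trials[first, by, drop = FALSE]
  rownames(groups) <- NULL
  mats <- vector("list", length(idx_split))
  cnts <- vector("list", length(idx_split))
  for (gi in seq_along(idx_split)) {
    ix <- idx_split[[gi]]
    tab <- table(factor(trials$stimulus_talker[ix], levels = seq_len(K)),
                 factor(trials$response_talker[ix], levels = seq_len(K)))
    counts <- rowSums(tab)
    prop <- matrix(as.numeric(tab / ifelse(counts == 0, 1, counts)), K, K)
    prop[counts == 0, ] <- NA_real_
    mats[[gi]] <- prop
    cnts[[gi]] <- as.integer(counts)
  }
  list(groups = groups, matrices = mats, counts = cnts)
}

check_separation <- function(trials) {
  cells <- aggregate(correct ~ language, data = trials, FUN = mean)
  deg <- cells[cells$correct %in% c(0, 1), ]
  if (nrow(deg))
    stop("complete separation: accuracy is ", deg$correct[1],
         " for language '", deg$language[1], "'", call. = FALSE)
}

term_table <- function(est, se, stat, p, stat_name = "z") {
  df <- data.frame(term = names(est), estimate = unname(est),
                   se = unname(se), stat = unname(stat), p = unname(p))
  names(df)[4] <- stat_name
  df
}

#' Mixed-effects model of trial accuracy
#'
#' Logistic mixed model fitted by maximum likelihood. For the training
#' phase: fixed effects of language, block (numeric, centered) and their
#' interaction; random participant intercept plus uncorrelated language
#' and block slopes. For the test phase: fixed language effect, random
#' intercept and language slope. Language is treatment-coded with the
#' native language as reference. Fixed-factor significance comes from a
#' Type III Wald chi-square table.
#'
#' @param trials Scored trials (see [score_accuracy()]).
#' @param phase "training" or "test".
#' @param native Reference language label.
#' @return List of class `model_summary` with elements `model`,
#'   `coefficients` (term table), and `anova` (Type III Wald chi-square).
#' @export
fit_accuracy_model <- function(trials, phase = c("training", "test"),
                               native = "native") {
  phase <- match.arg(phase)
  d <- trials[trials$phase == phase, , drop = FALSE]
  if (!nrow(d)) stop("no trials in phase ", phase, call. = FALSE)
  if (!"correct" %in% names(d)) d <- score_accuracy(d)
  check_separation(d)
  d$language <- stats::relevel(factor(d$language), ref = native)
  d$lang01 <- as.numeric(d$language != native)
  if (phase == "training") {
    d$block_c <- d$block - mean(range(d$block))
    form <- correct ~ language * block_c + (1 | participant) +
      (0 + lang01 | participant) + (0 + block_c | participant)
  } else {
    form <- correct ~ language + (1 | participant) +
      (0 + lang01 | participant)
  }
  mod <- lme4::glmer(form, data = d, family = stats::binomial,
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
  an <- car::Anova(mod, type = 3)
  co <- summary(mod)$coefficients
  out <- list(model = mod, anova = an,
              coefficients = term_table(co[, 1], co[, 2], co[, 3], co[, 4]),
              phase = phase)
  class(out) <- "model_summary"
  out
}

#' Mixed-effects model of log response time
#'
#' Linear mixed model on log RT, fitted by maximum likelihood: fixed
#' effects of language and block (training; no interaction) or language
#' alone (test); random participant intercept plus an uncorrelated
#' language slope. P-values use the normal (Wald) approximation by
#' default; `p_method = "satterthwaite"` uses the Satterthwaite
#' degrees-of-freedom approximation instead.
#'
#' @inheritParams fit_accuracy_model
#' @param p_method "wald" or "satterthwaite".
#' @return A `model_summary` list with `model`, `coefficients` and a Type
#'   III Wald chi-square `anova`.
#' @export
fit_rt_model <- function(trials, phase = c("training", "test"),
                         native = "native",
                         p_method = c("wald", "satterthwaite")) {
  phase <- match.arg(phase)
  p_method <- match.arg(p_method)
  d <- trials[trials$phase == phase, , drop = FALSE]
  if (!nrow(d)) stop("no trials in phase ", phase, call. = FALSE)
  if (length(unique(d$participant)) < 2)
    stop("need at least 2 participants", call. = FALSE)
  d$log_rt <- log(d$rt_ms)
  d$language <- stats::relevel(factor(d$language), ref = native)
  d$lang01 <- as.numeric(d$language != native)
  if (phase == "training") {
    d$block_c <- d$block - mean(range(d$block))
    form <- log_rt ~ language + block_c + (1 | participant) +
      (0 + lang01 | participant)
  } else {
    form <- log_rt ~ language + (1 | participant) +
      (0 + lang01 | participant)
  }
  if (p_method == "satterthwaite") {
    mod <- lmerTest::lmer(form, data = d, REML = FALSE,
                          control = lme4::lmerControl(optimizer = "bobyqa"))
    co <- summary(mod)$coefficients
    coefs <- term_table(co[, "Estimate"], co[, "Std. Error"],
                        co[, "t value"], co[, "Pr(>|t|)"], "t")
  } else {
    mod <- lme4::lmer(form, data = d, REML = FALSE,
                      control = lme4::lmerControl(optimizer = "bobyqa"))
    co <- summary(mod)$coefficients
    p <- 2 * pnorm(-abs(co[, "t value"]))
    coefs <- term_table(co[, "Estimate"], co[, "Std. Error"],
                        co[, "t value"], p, "t")
  }
  an <- car::Anova(mod, type = 3)
  out <- list(model = mod, anova = an, coefficients = coefs, phase = phase,
              p_method = p_method)
  class(out) <- "model_summary"
  out
}

#' @export
print.model_summary <- function(x, ...) {
  cat("Mixed-model summary (", x$phase, " phase)\n\n", sep = "")
  print(x$coefficients, digits = 4)
  cat("\nType III Wald chi-square:\n")
  print(x$anova)
  invisible(x)
}
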