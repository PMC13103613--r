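#' Orthogonal polynomial time basis
#'
#' Orthonormal polynomial regressors ot1..ot`order` over the analysis time
#' bins (stable QR orthogonalization of the centered powers, via
#' [stats::poly()]). Columns are mutually orthogonal and unit-norm; ot1 is
#' strictly increasing.
#'
#' @param n_bins Number of time bins (must exceed `order`).
#' @param order Polynomial order (default 4).
#' @return An `n_bins` x `order` matrix with columns ot1..ot`order` and a
#'   `bin` attribute.
#' @export
ortho_basis <- function(n_bins, order = 4) {
  if (n_bins <= order) stop("n_bins must exceed the polynomial order",
                            call. = FALSE)
  B <- unclass(poly(seq_len(n_bins), degree = order))
  colnames(B) <- paste0("ot", seq_len(order))
  attr(B, "coefs") <- NULL
  attr(B, "degree") <- NULL
  attr(B, "bin") <- seq_len(n_bins)
  B
}

#' Average preprocessed traces per cell
#'
#' Pointwise mean over surviving trials within each
#' participant x language x block cell, on the common preprocessed time
#' grid. With `correct_only`, only trials scored correct (looked up in
#' `trials` by the trial key) enter the mean — the input needed by the
#' evidence-accumulation-rate growth curve model.
#'
#' @param traces Preprocessed [pupil_trace()] list (common time grid).
#' @param trials Trial records matching the traces (required for
#'   `correct_only`).
#' @param correct_only Restrict to correct trials?
#' @return A long data.frame: participant, language, block, time_ms,
#'   pupil, n_trials.
#' @export
aggregate_traces <- function(traces, trials = NULL, correct_only = FALSE) {
  if (!length(traces)) stop("no traces to aggregate", call. = FALSE)
  if (correct_only) {
    if (is.null(trials)) stop("correct_only requires the trial records",
                              call. = FALSE)
    if (!"correct" %in% names(trials)) trials <- score_accuracy(trials)
    ok <- trials$correct == 1
    keys <- paste(trials$participant, trials$language, trials$block,
                  trials$trial, sep = "|")
    correct_keys <- keys[ok]
    traces <- Filter(function(tr) trace_key(tr) %in% correct_keys, traces)
    if (!length(traces)) stop("no correct-trial traces left", call. = FALSE)
  }
  tm <- traces[[1]]$time_ms
  M <- vapply(traces, function(tr) {
    if (length(tr$pupil) != length(tm))
      stop("traces are not on a common time grid", call. = FALSE)
    tr$pupil
  }, numeric(length(tm)))
  cellkey <- vapply(traces, function(tr)
    paste(tr$participant, tr$language, tr$block, sep = "|"), character(1))
  cells <- unique(cellkey)
  out <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    ix <- which(cellkey == cells[ci])
    parts <- strsplit(cells[ci], "|", fixed = TRUE)[[1]]
    avg <- if (length(ix) == 1) M[, ix] else rowMeans(M[, ix])
    out[[ci]] <- data.frame(
      participant = parts[1], language = parts[2],
      block = as.numeric(parts[3]), time_ms = tm, pupil = avg,
      n_trials = length(ix))
  }
  do.call(rbind, out)
}

gca_prepare <- function(agg, order) {
  bins <- sort(unique(agg$time_ms))
  basis <- ortho_basis(length(bins), order)
  ix <- match(agg$time_ms, bins)
  for (k in seq_len(order)) agg[[paste0("ot", k)]] <- basis[ix, k]
  agg
}

gca_coefs <- function(mod, p_method) {
  if (p_method == "satterthwaite") {
    co <- summary(mod)$coefficients
    term_table(co[, "Estimate"], co[, "Std. Error"], co[, "t value"],
               co[, "Pr(>|t|)"], "t")
  } else {
    co <- summary(mod)$coefficients
    p <- 2 * pnorm(-abs(co[, "t value"]))
    term_table(co[, "Estimate"], co[, "Std. Error"], co[, "t value"], p, "t")
  }
}

gca_fit_obj <- function(mod, coefs, order, p_method) {
  vc <- as.data.frame(lme4::VarCorr(mod))
  out <- list(model = mod, coefficients = coefs,
              varcomp = vc, logLik = as.numeric(logLik(mod)),
              converged = length(mod@optinfo$conv$lme4$messages) == 0,
              order = order, p_method = p_method)
  class(out) <- "gca_fit"
  out
}

#' @export
print.gca_fit <- function(x, ...) {
  cat("Growth curve fit (order ", x$order, ", ML)\n\n", sep = "")
  print(x$coefficients, digits = 4)
  cat("\nlogLik:", format(x$logLik), "  converged:", x$converged, "\n")
  invisible(x)
}

#' Growth curve model of language and block effects
#'
#' Linear mixed model of the stacked mean pupil traces on the orthogonal
#' time terms, language (treatment-coded, native reference), block
#' (numeric) and all two- and three-way interactions, with a participant
#' random intercept and random slopes on each time term (uncorrelated by
#' default to aid convergence; `diagonal_re = FALSE` fits the full
#' covariance). Maximum likelihood (not REML) with the BOBYQA optimizer.
#'
#' @param agg Mean traces from [aggregate_traces()] (training phase, both
#'   languages).
#' @param order Polynomial order (default 4).
#' @param native Reference language label.
#' @param diagonal_re Uncorrelated random effects?
#' @param p_method "wald" (normal approximation, default) or
#'   "satterthwaite".
#' @return A `gca_fit` list: fixed-effect table (estimate, se, t, p),
#'   variance components, log-likelihood, convergence flag.
#' @export
fit_gca_language_block <- function(agg, order = 4, native = "native",
                                   diagonal_re = TRUE,
                                   p_method = c("wald", "satterthwaite")) {
  p_method <- match.arg(p_method)
  d <- gca_prepare(agg, order)
  d$language <- stats::relevel(factor(d$language), ref = native)
  ot <- paste0("ot", seq_len(order))
  fe <- sprintf("(%s) * language * block", paste(ot, collapse = " + "))
  re <- sprintf("(1 + %s %s participant)", paste(ot, collapse = " + "),
                if (diagonal_re) "||" else "|")
  form <- as.formula(paste("pupil ~", fe, "+", re))
  fit_fun <- if (p_method == "satterthwaite") lmerTest::lmer else lme4::lmer
  mod <- fit_fun(form, data = d, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))
  gca_fit_obj(mod, gca_coefs(mod, p_method), order, p_method)
}

#' Growth curve model of the evidence accumulation rate
#'
#' For one language's correct-trial mean traces, regresses the pupil
#' response on the time terms, the evidence accumulation rate covariate
#' (posterior-mean correct-choice drift, aligned per block — broadcast to
#' participants when the race model was fitted pooled), and all
#' time x rate interactions; random structure as in
#' [fit_gca_language_block()].
#'
#' @param agg Correct-trial mean traces of one language.
#' @param ea Data.frame with columns `block` and `ea` (optionally
#'   `participant` for per-participant covariates).
#' @inheritParams fit_gca_language_block
#' @return A `gca_fit` list.
#' @export
fit_gca_ea_rate <- function(agg, ea, order = 4, diagonal_re = TRUE,
                            p_method = c("wald", "satterthwaite")) {
  p_method <- match.arg(p_method)
  d <- gca_prepare(agg, order)
  if ("participant" %in% names(ea)) {
    d <- merge(d, ea, by = c("participant", "block"))
  } else {
    d <- merge(d, ea, by = "block")
  }
  if (nrow(d) == 0) stop("evidence-accumulation covariate keys do not match",
                         call. = FALSE)
  if (var(d$ea) == 0)
    stop("evidence-accumulation covariate is constant across cells ",
         "(rank-deficient design)", call. = FALSE)
  ot <- paste0("ot", seq_len(order))
  fe <- sprintf("(%s) * ea", paste(ot, collapse = " + "))
  re <- sprintf("(1 + %s %s participant)", paste(ot, collapse = " + "),
                if (diagonal_re) "||" else "|")
  form <- as.formula(paste("pupil ~", fe, "+", re))
  fit_fun <- if (p_method == "satterthwaite") lmerTest::lmer else lme4::lmer
  mod <- fit_fun(form, data = d, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))
  gca_fit_obj(mod, gca_coefs(mod, p_method), order, p_method)
}
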