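#' Restrict a trace to the analysis window
#'
#' Keeps samples with `start <= t < end` (inclusive at the window start,
#' exclusive at the end). Errors if the trace does not cover the full
#' window; already-windowed traces pass through unchanged.
#'
#' @param trace A [pupil_trace()].
#' @param window Window in ms relative to stimulus onset.
#' @return The windowed trace.
#' @export
window_trace <- function(trace, window = c(-500, 4000)) {
  dt <- 1000 / trace$rate_hz
  tm <- trace$time_ms
  if (tm[1] > window[1] || (tm[length(tm)] + dt) < window[2])
    stop(sprintf("trace covers %g..%g ms; window %g..%g ms not covered",
                 tm[1], tm[length(tm)] + dt, window[1], window[2]),
         call. = FALSE)
  keep <- tm >= window[1] & tm < window[2]
  trace$time_ms <- tm[keep]
  trace$pupil <- trace$pupil[keep]
  trace$is_blink <- trace$is_blink[keep]
  trace
}

#' Downsample a trace by block means
#'
#' Averages non-overlapping bins of `rate_hz / target_hz` source samples
#' (20 samples per bin for 1000 -> 50 Hz). Bin timestamps are the bin
#' starts; a bin is blink-flagged if any source sample in it is flagged;
#' missing samples are excluded from the mean and an all-missing bin stays
#' missing.
#'
#' @param trace A [pupil_trace()].
#' @param target_hz Target rate; the source rate must be an integer
#'   multiple of it.
#' @return The downsampled trace.
#' @export
downsample_trace <- function(trace, target_hz = 50) {
  ratio <- trace$rate_hz / target_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("source rate ", trace$rate_hz, " Hz is not an integer multiple of ",
         target_hz, " Hz", call. = FALSE)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(trace)
  n <- length(trace$pupil)
  nbin <- n %/% ratio
  use <- seq_len(nbin * ratio)
  bins <- matrix(trace$pupil[use], nrow = ratio)
  vals <- colMeans(bins, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  mask <- matrix(trace$is_blink[use], nrow = ratio)
  trace$pupil <- vals
  trace$is_blink <- colSums(mask) > 0
  trace$time_ms <- trace$time_ms[seq(1, nbin * ratio, by = ratio)]
  trace$rate_hz <- target_hz
  trace
}

#' Blink-proportion screen
#'
#' Rejects a trace when strictly more than `threshold` of its samples are
#' blink-flagged; a trace at exactly the threshold is kept.
#'
#' @param trace A [pupil_trace()].
#' @param threshold Maximum tolerated blink proportion (default 0.15).
#' @return The trace, with `state` set to "rejected" when it fails and an
#'   attribute `blink_fraction`.
#' @export
screen_blinks <- function(trace, threshold = 0.15) {
  frac <- mean(trace$is_blink)
  if (frac > threshold) trace$state <- "rejected"
  attr(trace, "blink_fraction") <- frac
  trace
}

#' Interpolate blink gaps
#'
#' Widens every contiguous blink run by `pad_ms` on both sides (clipped to
#' the trace) and fills the widened gaps by linear interpolation between
#' the nearest valid samples; gaps touching a trace edge are filled by
#' nearest-value extension. The output has no missing samples; the blink
#' mask is replaced by the widened (interpolated) mask.
#'
#' @param trace A kept [pupil_trace()].
#' @param pad_ms Pad on each side of a blink run, in ms (default 120).
#' @return The gap-filled trace.
#' @export
interpolate_blinks <- function(trace, pad_ms = 120) {
  mask <- trace$is_blink | is.na(trace$pupil)
  if (!any(mask)) return(trace)
  if (all(mask))
    stop("trace is entirely blink-masked (participant ", trace$participant,
         ", block ", trace$block, ", trial ", trace$trial, ")",
         call. = FALSE)
  n <- length(mask)
  pad <- as.integer(round(pad_ms * trace$rate_hz / 1000))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  wide <- logical(n)
  for (k in which(r$values)) {
    lo <- max(1L, starts[k] - pad)
    hi <- min(n, ends[k] + pad)
    wide[lo:hi] <- TRUE
  }
  if (all(wide))
    stop("widened blink gap spans the whole trace (participant ",
         trace$participant, ", block ", trace$block, ", trial ",
         trace$trial, ")", call. = FALSE)
  good <- which(!wide)
  filled <- approx(x = trace$time_ms[good], y = trace$pupil[good],
                   xout = trace$time_ms, method = "linear", rule = 2)$y
  trace$pupil <- filled
  trace$is_blink <- wide
  trace
}

#' Baseline proportion-change normalization
#'
#' Uses the mean pupil size over the pre-stimulus baseline window
#' `[-baseline_ms, 0)` as the reference, expresses every post-onset sample
#' as percent change `100 * (x - baseline) / baseline`, and drops the
#' baseline window from the output (which then spans `t >= 0`).
#'
#' @param trace A gap-filled [pupil_trace()] including the baseline window.
#' @param baseline_ms Baseline window length in ms (default 500).
#' @return The normalized trace (state "preprocessed", percent units).
#' @export
baseline_normalize <- function(trace, baseline_ms = 500) {
  tm <- trace$time_ms
  in_base <- tm >= -baseline_ms & tm < 0
  if (!any(in_base))
    stop("trace has no samples in the baseline window", call. = FALSE)
  baseline <- mean(trace$pupil[in_base])
  if (!is.finite(baseline) || baseline <= 0)
    stop("non-positive baseline for participant ", trace$participant,
         ", block ", trace$block, ", trial ", trace$trial, call. = FALSE)
  keep <- tm >= 0
  trace$pupil <- 100 * (trace$pupil[keep] - baseline) / baseline
  trace$time_ms <- tm[keep]
  trace$is_blink <- trace$is_blink[keep]
  trace$state <- "preprocessed"
  attr(trace, "baseline") <- baseline
  trace
}

#' Full pupil preprocessing pipeline
#'
#' Applies, in order: windowing to the analysis window, downsampling to
#' the target rate, the blink-proportion screen (so blink bins are counted
#' at the downsampled rate), blink interpolation, and baseline
#' normalization. Per-trace failures are collected, not fatal.
#'
#' @param traces List of raw [pupil_trace()] objects.
#' @param window Analysis window (ms).
#' @param target_hz Downsampling target.
#' @param blink_threshold Rejection threshold (proportion).
#' @param pad_ms Interpolation pad.
#' @param baseline_ms Baseline window length.
#' @param screen_at_source Apply the blink screen before downsampling
#'   instead of after?
#' @return List with `traces` (the surviving preprocessed traces),
#'   `report` (totals and per-condition rejection percentages), and
#'   `errors` (per-trace failure messages, if any).
#' @export
preprocess_pupil <- function(traces, window = c(-500, 4000), target_hz = 50,
                             blink_threshold = 0.15, pad_ms = 120,
                             baseline_ms = 500, screen_at_source = FALSE) {
  kept <- vector("list", length(traces))
  errors <- character(0)
  meta <- data.frame(language = character(length(traces)),
                     block = numeric(length(traces)),
                     rejected = NA, stringsAsFactors = FALSE)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    meta$language[i] <- as.character(tr$language)
    meta$block[i] <- tr$block
    res <- tryCatch({
      tr <- window_trace(tr, window)
      if (screen_at_source) tr <- screen_blinks(tr, blink_threshold)
      tr <- downsample_trace(tr, target_hz)
      if (!screen_at_source) tr <- screen_blinks(tr, blink_threshold)
      if (tr$state == "rejected") {
        tr
      } else {
        tr <- interpolate_blinks(tr, pad_ms)
        baseline_normalize(tr, baseline_ms)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, conditionMessage(res))
      meta$rejected[i] <- TRUE
    } else if (res$state == "rejected") {
      meta$rejected[i] <- TRUE
    } else {
      meta$rejected[i] <- FALSE
      kept[[i]] <- res
    }
  }
  kept <- kept[!vapply(kept, is.null, logical(1))]
  by_cond <- aggregate(rejected ~ language + block, data = meta, FUN = mean)
  by_cond$pct_rejected <- 100 * by_cond$rejected
  by_cond$rejected <- NULL
  report <- list(n_total = nrow(meta), n_rejected = sum(meta$rejected),
                 pct_rejected = 100 * mean(meta$rejected),
                 by_condition = by_cond)
  list(traces = kept, report = report, errors = errors)
}
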