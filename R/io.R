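#' @title Trial-table and pupil-trace readers and writers
#' @description Plain-CSV readers/writers for the pipeline's tabular
#'   formats. Every writer/reader pair is a lossless round trip on valid
#'   data.
#' @name talker_io
NULL

TRIAL_COLUMNS <- c("participant", "language", "phase", "block", "trial",
                   "stimulus_talker", "response_talker", "rt_ms")

#' Read a trial table
#'
#' @param path CSV/TSV file with columns participant, language, phase,
#'   block, trial, stimulus_talker, response_talker, rt_ms (a `sentence`
#'   column, if present, is kept).
#' @param n_talkers If given, talker indices are validated against it.
#' @return A data.frame of trial records.
#' @export
read_trials <- function(path, n_talkers = NULL) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, sep = "auto"))
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$rt_ms) | df$rt_ms <= 0)
  if (length(bad))
    stop(sprintf("non-positive rt_ms at row %d (column rt_ms)", bad[1]),
         call. = FALSE)
  if (!is.null(n_talkers)) {
    for (col in c("stimulus_talker", "response_talker")) {
      bad <- which(df[[col]] < 1 | df[[col]] > n_talkers)
      if (length(bad))
        stop(sprintf("talker index out of range 1..%d at row %d (column %s)",
                     n_talkers, bad[1], col), call. = FALSE)
    }
  }
  if (!all(df$phase %in% c("training", "test")))
    stop("phase must be 'training' or 'test'", call. = FALSE)
  df
}

#' Write a trial table
#'
#' @param trials Data.frame of trial records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  data.table::fwrite(trials, path)
  invisible(path)
}

#' Construct a pupil trace
#'
#' One trial's pupil time series: raw traces are in arbitrary units at the
#' recording rate with blink samples missing; preprocessed traces are in
#' percent change from baseline at the downsampled rate.
#'
#' @param participant,language,block,trial Trial key.
#' @param time_ms Strictly increasing, uniformly spaced sample times (ms,
#'   relative to stimulus onset).
#' @param pupil Samples (NA where masked).
#' @param is_blink Logical blink mask, same length as `pupil`.
#' @param rate_hz Sampling rate.
#' @param state One of "raw", "preprocessed", "rejected".
#' @return An object of class `pupil_trace`.
#' @export
pupil_trace <- function(participant, language, block, trial, time_ms, pupil,
                        is_blink, rate_hz, state = "raw") {
  stopifnot(length(time_ms) == length(pupil),
            length(is_blink) == length(pupil))
  structure(
    list(participant = participant, language = language, block = block,
         trial = trial, time_ms = as.numeric(time_ms),
         pupil = as.numeric(pupil), is_blink = as.logical(is_blink),
         rate_hz = rate_hz, state = state),
    class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf(
    "<pupil_trace %s/%s block %s trial %s: %d samples @ %g Hz, %s>\n",
    x$participant, x$language, x$block, x$trial, length(x$pupil),
    x$rate_hz, x$state))
  invisible(x)
}

trace_key <- function(trace) {
  paste(trace$participant, trace$language, trace$block, trace$trial, sep = "|")
}

#' Read pupil traces from a long CSV
#'
#' Expects columns participant, language, block, trial, time_ms, pupil,
#' is_blink; one trace per (participant, language, block, trial) key with
#' strictly increasing, uniformly spaced time. The sampling rate is
#' inferred from the spacing.
#'
#' @param path Long-format CSV.
#' @return A list of [pupil_trace()] objects.
#' @export
read_pupil <- function(path) {
  if (!file.exists(path)) stop("pupil file not found: ", path, call. = FALSE)
  dt <- as.data.frame(data.table::fread(path))
  need <- c("participant", "language", "block", "trial", "time_ms", "pupil",
            "is_blink")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop("pupil table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  split_idx <- split(seq_len(nrow(dt)),
                     interaction(dt$participant, dt$language, dt$block,
                                 dt$trial, drop = TRUE, lex.order = TRUE))
  lapply(split_idx, function(ix) {
    rows <- dt[ix, , drop = FALSE]
    tm <- rows$time_ms
    key <- sprintf("participant %s language %s block %s trial %s",
                   rows$participant[1], rows$language[1], rows$block[1],
                   rows$trial[1])
    dts <- diff(tm)
    if (any(dts <= 0))
      stop("time_ms not strictly increasing for ", key, call. = FALSE)
    if (length(unique(round(dts, 9))) > 1)
      stop("inconsistent sampling interval for ", key, call. = FALSE)
    pupil_trace(rows$participant[1], rows$language[1], rows$block[1],
                rows$trial[1], tm, rows$pupil, as.logical(rows$is_blink),
                rate_hz = 1000 / dts[1],
                state = "raw")
  })
}

#' Write pupil traces to a long CSV
#'
#' @param traces A list of [pupil_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pupil <- function(traces, path) {
  if (inherits(traces, "pupil_trace")) traces <- list(traces)
  tabs <- lapply(traces, function(tr) {
    data.table::data.table(
      participant = tr$participant, language = tr$language, block = tr$block,
      trial = tr$trial, time_ms = tr$time_ms, pupil = tr$pupil,
      is_blink = tr$is_blink)
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Write and read generator ground truth as JSON
#'
#' @param truth Ground-truth list from [build_ground_truth()].
#' @param path JSON path.
#' @return For the writer, `path` invisibly; for the reader, the truth list.
#' @export
write_truth <- function(truth, path) {
  pack <- function(x) list(dim = dim(x), values = as.vector(x))
  for (lang in names(truth$languages)) {
    for (f in c("sigma", "mu", "b"))
      truth$languages[[lang]][[f]] <- pack(truth$languages[[lang]][[f]])
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path, call. = FALSE)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(x) array(as.numeric(x$values), dim = as.integer(x$dim))
  for (lang in names(truth$languages)) {
    for (f in c("sigma", "mu", "b"))
      truth$languages[[lang]][[f]] <- unpack(truth$languages[[lang]][[f]])
  }
  if (!is.null(truth$participants))
    truth$participants <- as.data.frame(truth$participants)
  truth
}
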