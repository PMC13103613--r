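#' Acoustic similarity matrix from talker voice features
#'
#' Builds the K x K similarity matrix over talkers as -1 times the pairwise
#' Euclidean distance across the six voice features (mean F0, F0 range,
#' speech rate, jitter, harmonicity, formant dispersion). Features are
#' z-scored across talkers by default because they live on incommensurate
#' scales (Hz, percent, dB); `standardize = FALSE` reproduces raw-unit
#' distances.
#'
#' @param features Data.frame with a `talker` column and the six feature
#'   columns.
#' @param standardize Z-score each feature across talkers first?
#' @return A symmetric K x K matrix of class `asm` with zero diagonal and
#'   non-positive off-diagonal entries.
#' @export
asm_from_features <- function(features, standardize = TRUE) {
  fcols <- setdiff(names(features), "talker")
  if (nrow(features) < 2) stop("need at least 2 talkers", call. = FALSE)
  X <- as.matrix(features[, fcols, drop = FALSE])
  if (standardize) {
    sds <- apply(X, 2, sd)
    zero <- fcols[sds == 0]
    if (length(zero))
      stop("zero-variance feature(s) with standardization on: ",
           paste(zero, collapse = ", "), call. = FALSE)
    X <- scale(X)
  }
  D <- as.matrix(dist(X))
  sim <- -D
  labels <- if ("talker" %in% names(features)) features$talker else
    seq_len(nrow(features))
  dimnames(sim) <- list(labels, labels)
  structure(sim, class = c("asm", "matrix"),
            standardized = standardize)
}

#' Rescale an ASM to unit similarity weights
#'
#' Maps similarities to `sigma(d, s) = 1 - D(d, s) / max(D)` so that
#' `sigma(s, s) = 1` and the most dissimilar pair scores 0. Used by the
#' study generator to couple off-diagonal drift rates to acoustic
#' similarity.
#'
#' @param asm An [asm_from_features()] matrix.
#' @return A K x K matrix in [0, 1] with unit diagonal.
#' @export
similarity_weights <- function(asm) {
  D <- -unclass(asm)
  attr(D, "standardized") <- NULL
  mx <- max(D)
  if (mx == 0) return(matrix(1, nrow(D), ncol(D), dimnames = dimnames(D)))
  1 - D / mx
}

#' Spearman correlation between confusion errors and acoustic similarity
#'
#' Pairs every off-diagonal confusion cell (i, j), i != j, with the
#' corresponding (symmetric) ASM entry and computes Spearman's rank
#' correlation with average-rank tie handling. The diagonal is excluded:
#' only the error pattern is analyzed. Missing confusion cells (rows with
#' zero trials) are dropped pairwise.
#'
#' @param confusion K x K row-normalized confusion matrix (rows = stimulus
#'   talker), `NA` rows allowed.
#' @param asm Matching K x K [asm_from_features()] matrix.
#' @return List with `rho` and `n_pairs`.
#' @export
error_acoustic_correlation <- function(confusion, asm) {
  K <- nrow(confusion)
  stopifnot(ncol(confusion) == K, nrow(asm) == K)
  off <- which(row(confusion) != col(confusion))
  x <- confusion[off]
  y <- unclass(asm)[off]
  keep <- !is.na(x)
  if (sum(keep) < 3) stop("fewer than 3 valid off-diagonal pairs",
                          call. = FALSE)
  rho <- cor(rank(x[keep]), rank(y[keep]))
  list(rho = rho, n_pairs = sum(keep))
}

#' Per-cell reliance on acoustic similarity
#'
#' Computes the confusion-ASM Spearman correlation for every
#' participant x language x block confusion matrix.
#'
#' @param confusions Result of [confusion_matrices()].
#' @param asms Named list of ASMs, one per language.
#' @return Data.frame with participant, language, block, rho, n_pairs.
#' @export
reliance_patterns <- function(confusions, asms) {
  out <- confusions$groups
  out$rho <- NA_real_
  out$n_pairs <- NA_integer_
  for (i in seq_len(nrow(out))) {
    asm <- asms[[as.character(out$language[i])]]
    r <- error_acoustic_correlation(confusions$matrices[[i]], asm)
    out$rho[i] <- r$rho
    out$n_pairs[i] <- r$n_pairs
  }
  out
}

#' Compare acoustic reliance between languages
#'
#' Averages each participant's confusion-ASM Spearman rho per language
#' (over blocks, or per block with `per_block = TRUE`), summarizes the
#' paired unfamiliar-minus-native difference with mean and SEM, and runs a
#' paired Wilcoxon signed-rank test. Positive differences mean stronger
#' acoustic reliance in the unfamiliar language.
#'
#' @param patterns Output of [reliance_patterns()].
#' @param native Label of the native (reference) language.
#' @param per_block Keep blocks separate instead of averaging?
#' @return List with `by_participant`, `descriptives` (per-language mean
#'   and SEM), `difference` (mean, sem), and `test` (the signed-rank
#'   result, NULL when only one participant).
#' @export
compare_languages <- function(patterns, native = "native",
                              per_block = FALSE) {
  langs <- unique(as.character(patterns$language))
  if (length(langs) != 2) stop("need exactly two languages", call. = FALSE)
  other <- setdiff(langs, native)
  by <- if (per_block) c("participant", "language", "block") else
    c("participant", "language")
  agg <- aggregate(rho ~ ., data = patterns[, c(by, "rho")], FUN = mean)
  wide <- merge(agg[agg$language == native, setdiff(names(agg), "language")],
                agg[agg$language == other, setdiff(names(agg), "language")],
                by = setdiff(by, "language"), suffixes = c("_native", "_other"))
  if (nrow(wide) < nrow(agg) / 2)
    stop("unpaired participant(s): both languages required for each",
         call. = FALSE)
  diffs <- wide$rho_other - wide$rho_native
  desc <- do.call(rbind, lapply(langs, function(l) {
    v <- agg$rho[agg$language == l]
    data.frame(language = l, mean_rho = mean(v),
               sem = sd(v) / sqrt(length(v)))
  }))
  test <- NULL
  if (length(diffs) > 1)
    test <- tryCatch(
      suppressWarnings(wilcox.test(wide$rho_other, wide$rho_native,
                                   paired = TRUE)),
      error = function(e) NULL)
  list(by_participant = wide, descriptives = desc,
       difference = list(mean = mean(diffs),
                         sem = sd(diffs) / sqrt(length(diffs))),
       test = test)
}

#' Compare between-talker acoustic variance across languages
#'
#' Two-sample Mann-Whitney-Wilcoxon test on the K(K-1)/2 pairwise
#' between-talker Euclidean distances of each language, checking that the
#' acoustical variance of the two stimulus sets is comparable.
#'
#' @param features_a,features_b Feature tables of the two languages.
#' @param standardize Z-score features within each language first?
#' @return List with the distances, the rank statistic `W` and two-sided
#'   `p.value`.
#' @export
compare_feature_variance <- function(features_a, features_b,
                                     standardize = TRUE) {
  dists <- function(f) {
    if (nrow(f) < 2) stop("need at least 2 talkers per language",
                          call. = FALSE)
    -unclass(asm_from_features(f, standardize = standardize))
  }
  da <- dists(features_a); db <- dists(features_b)
  va <- da[upper.tri(da)]
  vb <- db[upper.tri(db)]
  tst <- suppressWarnings(wilcox.test(va, vb))
  list(distances_a = va, distances_b = vb,
       W = unname(tst$statistic), p.value = tst$p.value)
}
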