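#' Occurrences per million tokens
#'
#' Zero counts are returned as `NA` (treated as missing rather than
#' smoothed); the number of zeroes dropped is attached as attribute
#' `n_zero`.
#'
#' @param count Non-negative occurrence counts.
#' @param corpus_size Corpus sizes in tokens (positive).
#' @param laplace Add-one smoothing instead of dropping zeroes (off by
#'   default).
#' @return Numeric vector of frequencies per million (`NA` where missing).
#' @export
fpm <- function(count, corpus_size, laplace = FALSE) {
  if (any(corpus_size <= 0)) stop("corpus_size must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  if (laplace) count <- count + 1
  out <- 1e6 * count / corpus_size
  out[count == 0] <- NA_real_
  structure(out, n_zero = sum(count == 0 & !laplace))
}

#' Center log frequencies within one corpus
#'
#' Subtracts the corpus mean log frequency from each record's log frequency,
#' so corpora of different sizes and registers share one scale; the mean of
#' the returned values is zero.
#'
#' @param log_fpm Log frequencies per million of the records of one corpus
#'   (`NA` allowed, ignored and returned as `NA`).
#' @return Centered values.
#' @export
center_within_corpus <- function(log_fpm) {
  if (all(is.na(log_fpm))) stop("no defined frequencies in corpus")
  log_fpm - mean(log_fpm, na.rm = TRUE)
}

#' Aggregated centered log frequency per million (clfpm)
#'
#' Converts corpus counts to log frequency per million, centers within each
#' corpus (over all study words present in that corpus, so lexical classes
#' share one scale), and averages the centered values over the corpora in
#' which each (language, meaning) occurs, with equal weight per corpus.
#'
#' @param counts Corpus counts from [read_frequency_table()] (or the same
#'   columns).
#' @param lexical_class Optional named vector mapping meaning to class; by
#'   default kin-type codes ([kin_types()]) are `kin` and all other meanings
#'   `swadesh`.
#' @param laplace Passed to [fpm()].
#' @return Data frame (`language`, `meaning`, `lexical_class`, `clfpm`,
#'   `n_corpora`), one row per (language, meaning).
#' @export
aggregate_clfpm <- function(counts, lexical_class = NULL, laplace = FALSE) {
  counts$fpm <- as.numeric(fpm(counts$count, counts$corpus_size,
                               laplace = laplace))
  counts$log_fpm <- log(counts$fpm)
  counts$clf <- stats::ave(counts$log_fpm, counts$corpus_id,
                           FUN = function(x) x - mean(x, na.rm = TRUE))
  ok <- !is.na(counts$clf)
  agg <- stats::aggregate(clf ~ language + meaning, data = counts[ok, ],
                          FUN = mean)
  ncorp <- stats::aggregate(clf ~ language + meaning, data = counts[ok, ],
                            FUN = length)
  names(agg)[3] <- "clfpm"
  agg$n_corpora <- ncorp$clf
  if (is.null(lexical_class)) {
    agg$lexical_class <- ifelse(agg$meaning %in% names(kin_types()),
                                "kin", "swadesh")
  } else {
    agg$lexical_class <- unname(lexical_class[agg$meaning])
  }
  agg[order(agg$language, agg$meaning),
      c("language", "meaning", "lexical_class", "clfpm", "n_corpora")]
}

#' Drop core-vocabulary duplicates of kinship meanings
#'
#' Removes rows whose lexical class is `swadesh` and whose meaning is one of
#' mother, father, husband or wife, so kin concepts enter the comparison
#' only through the kinship data. Kin-class rows are never removed.
#'
#' @param table Data frame with `meaning` and `lexical_class` columns.
#' @return The filtered table, with attribute `n_removed`.
#' @export
exclude_kin_swadesh <- function(table) {
  drop <- table$lexical_class == "swadesh" &
    tolower(table$meaning) %in% c("mother", "father", "husband", "wife")
  out <- table[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}
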