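#' Score trimming decisions against simulator ground truth
#'
#' A pair is a positive when the truth marks it contaminated, and a
#' predicted positive when the trimmer trimmed it. TP/FP/TN/FN are tallied
#' at the pair level; whether a true positive was cut at exactly the true
#' site is reported separately as `exact_site_fraction`, so detection and
#' localisation stay independently visible.
#'
#' Contaminated pairs whose true insert is shorter than `min_insert`
#' (typically the trimmer's `L`) are algorithmically undetectable — the
#' scan cannot propose a site below `L` — and, when `min_insert` is given,
#' are excluded from the confusion table and counted in `n_undetectable`.
#'
#' @param decisions A tibble with `pair_id`, `trimmed` and `insert_length`
#'   (from [trim_pairs()] or [read_trim_report()]).
#' @param truth A tibble with `pair_id`, `contaminated` and
#'   `insert_length` (from [simulate_pairs()] or [read_truth()]).
#' @param min_insert Smallest detectable true insert length, or `NULL` to
#'   evaluate every pair.
#' @return An object of class `confusion_metrics`: counts `tp`, `fp`,
#'   `tn`, `fn`, `n_undetectable`; derived `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`, `exact_site_fraction`. Ratios with an empty
#'   denominator are reported as 0 with a warning.
#' @export
classify_decisions <- function(decisions, truth, min_insert = NULL) {
  if (!setequal(decisions$pair_id, truth$pair_id) ||
      nrow(decisions) != nrow(truth)) {
    only_d <- setdiff(decisions$pair_id, truth$pair_id)
    only_t <- setdiff(truth$pair_id, decisions$pair_id)
    abort(sprintf(
      "decision and truth pair ids differ (e.g. %s only in decisions; %s only in truth)",
      paste(head(only_d, 3), collapse = ","),
      paste(head(only_t, 3), collapse = ",")))
  }
  m <- dplyr::inner_join(
    dplyr::select(decisions, "pair_id", pred = "trimmed",
                  site = "insert_length"),
    dplyr::select(truth, "pair_id", pos = "contaminated",
                  true_site = "insert_length"),
    by = "pair_id")

  n_undetectable <- 0L
  if (!is.null(min_insert)) {
    und <- m$pos & m$true_site < min_insert
    n_undetectable <- sum(und)
    m <- m[!und, , drop = FALSE]
  }

  tp <- sum(m$pos & m$pred)
  fp <- sum(!m$pos & m$pred)
  tn <- sum(!m$pos & !m$pred)
  fn <- sum(m$pos & !m$pred)
  exact <- sum(m$pos & m$pred & !is.na(m$site) & m$site == m$true_site)

  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (0/0); reporting 0", what))
      return(0)
    }
    num / den
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_undetectable = n_undetectable,
    sensitivity = ratio0(tp, tp + fn, "sensitivity"),
    specificity = ratio0(tn, tn + fp, "specificity"),
    accuracy = ratio0(tp + tn, tp + fp + tn + fn, "accuracy"),
    mcc = mcc(tp = tp, tn = tn, fp = fp, fn = fn),
    exact_site_fraction = ratio0(exact, tp, "exact_site_fraction")),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics> tp=%d fp=%d tn=%d fn=%d (undetectable: %d)\n",
    x$tp, x$fp, x$tn, x$fn, x$n_undetectable))
  cat(sprintf(
    "  sensitivity %.4f | specificity %.4f | accuracy %.4f | MCC %.4f | exact site %.4f\n",
    x$sensitivity, x$specificity, x$accuracy, x$mcc,
    x$exact_site_fraction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.confusion_metrics <- function(x, ...) {
  tibble(metric = c("tp", "fp", "tn", "fn", "n_undetectable",
                    "sensitivity", "specificity", "accuracy", "mcc",
                    "exact_site_fraction"),
         value = c(x$tp, x$fp, x$tn, x$fn, x$n_undetectable,
                   x$sensitivity, x$specificity, x$accuracy, x$mcc,
                   x$exact_site_fraction))
}

#' @export
glance.confusion_metrics <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy, mcc = x$mcc,
         exact_site_fraction = x$exact_site_fraction,
         n_undetectable = x$n_undetectable)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' summary of a binary confusion table, in \[-1, 1\]. When any factor of
#' the denominator is zero the value is defined as 0.
#'
#' @param x A `confusion_metrics` object, or `NULL` to pass counts
#'   directly.
#' @param tp,tn,fp,fn Counts (used when `x` is `NULL`).
#' @return A number in \[-1, 1\].
#' @examples
#' mcc(tp = 100, tn = 100, fp = 0, fn = 0)
#' @export
mcc <- function(x = NULL, tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn) {
  num <- as.numeric(tp) * tn - as.numeric(fp) * fn
  den <- (as.numeric(tp) + fp) * (as.numeric(tp) + fn) *
         (as.numeric(tn) + fp) * (as.numeric(tn) + fn)
  if (den == 0) return(0)
  num / sqrt(den)
}

#' Ratio of trimmed to untrimmed pairs
#'
#' A label-free diagnostic: under a half-contaminated benchmark a perfect
#' trimmer yields a ratio of 1.
#'
#' @param decisions A tibble with a logical `trimmed` column.
#' @return `count(trimmed) / count(untrimmed)`; `Inf` with a warning when
#'   nothing is untrimmed.
#' @export
trimmed_untrimmed_ratio <- function(decisions) {
  n_trim <- sum(decisions$trimmed)
  n_un <- sum(!decisions$trimmed)
  if (n_un == 0) {
    warn("no untrimmed pairs; ratio is infinite")
    return(Inf)
  }
  n_trim / n_un
}

#' Distribution of trimmed insert lengths
#'
#' For every insert length in `1 .. read_length - 1`, the fraction of
#' trimmed pairs cut at that length. Fractions sum to 1 over trimmed pairs
#' (all zero when none were trimmed).
#'
#' @param decisions A tibble with `trimmed` and `insert_length`.
#' @param read_length Mate length in bases.
#' @return A tibble with `insert_length`, `n` and `fraction`.
#' @export
length_distribution <- function(decisions, read_length = 101L) {
  lens <- decisions$insert_length[decisions$trimmed]
  counts <- tabulate(lens, nbins = read_length - 1L)
  tibble(insert_length = seq_len(read_length - 1L),
         n = counts,
         fraction = if (sum(counts) > 0) counts / sum(counts)
                    else rep(0, read_length - 1L))
}

#' Approximate true positives among trimmed pairs
#'
#' A label-free proxy for correct trims: a trimmed pair whose mates are
#' reverse complements (within `floor(length * tolerance)` mismatches) was
#' almost certainly cut at the true junction. Defaults to strict
#' reverse-complementarity (`tolerance = 0`).
#'
#' @param trimmed_pairs A tibble of already-trimmed pairs (`seq1`, `seq2`
#'   of equal length per row).
#' @param tolerance Mismatch fraction tolerated; 1 counts every pair.
#' @return Integer count.
#' @export
approximate_true_positives <- function(trimmed_pairs, tolerance = 0) {
  if (nrow(trimmed_pairs) == 0) return(0L)
  mm <- count_mismatches(reverse_complement(trimmed_pairs$seq1),
                         trimmed_pairs$seq2)
  budget <- mismatch_budget(nchar(trimmed_pairs$seq1), tolerance)
  sum(mm <= budget)
}

#' Full evaluation of a trimming run against ground truth
#'
#' Convenience wrapper combining [classify_decisions()],
#' [trimmed_untrimmed_ratio()], [length_distribution()] and (when trimmed
#' sequences are available) [approximate_true_positives()].
#'
#' @inheritParams classify_decisions
#' @param read_length Mate length in bases.
#' @param trimmed_pairs Optional tibble of trimmed pairs for the aTP count.
#' @param atp_tolerance Mismatch tolerance for aTP.
#' @return A list: `confusion` (`confusion_metrics`), `ratio`,
#'   `length_distribution` (tibble), `atp` (or `NA`).
#' @export
evaluate_trimming <- function(decisions, truth, min_insert = NULL,
                              read_length = 101L, trimmed_pairs = NULL,
                              atp_tolerance = 0) {
  atp <- NA_integer_
  if (!is.null(trimmed_pairs)) {
    atp <- approximate_true_positives(
      trimmed_pairs[trimmed_pairs$trimmed, , drop = FALSE], atp_tolerance)
  }
  list(confusion = classify_decisions(decisions, truth, min_insert),
       ratio = trimmed_untrimmed_ratio(decisions),
       length_distribution = length_distribution(decisions, read_length),
       atp = atp)
}
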