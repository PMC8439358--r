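#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN) * 100`. For multi-class batch evaluation
#' the same quantity reduces to percent-correct (TP = correct trials,
#' FP = incorrect trials, TN = FN = 0).
#'
#' @param tp,tn,fp,fn non-negative counts; total must be positive.
#' @return percentage in `[0, 100]`.
#' @export
accuracy_percent <- function(tp, tn = 0, fp = 0, fn = 0) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  (tp + tn) / total * 100
}

#' Wolpaw bits per trial
#'
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, the
#' information conveyed by one decision among `N` targets at accuracy `P`.
#' Continuous at `P = 1` (where `B = log2 N`) and zero at chance `P = 1/N`.
#' `P` below chance is flagged with a warning (the formula goes negative
#' there).
#'
#' @param N number of targets (>= 2).
#' @param P accuracy as a proportion in `(0, 1]`.
#' @return bits per trial.
#' @export
bits_per_trial <- function(N, P) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (P <= 0 || P > 1) stop("P must be in (0, 1]", call. = FALSE)
  if (P < 1 / N) warning("accuracy below chance level 1/N", call. = FALSE)
  if (P == 1) return(log2(N))
  log2(N) + P * log2(P) + (1 - P) * log2((1 - P) / (N - 1))
}

#' Information transfer rate in bits per minute
#'
#' Bits per trial times the decision rate `60 / (window_seconds +
#' gaze_seconds)`: each decision costs the analysis window plus the fixed
#' gaze-shift overhead the user spends reorienting to the next target
#' (1 s by default).
#'
#' @inheritParams bits_per_trial
#' @param window_seconds analysis window length per decision (> 0).
#' @param gaze_seconds fixed per-decision overhead in seconds.
#' @return bits per minute.
#' @export
itr_bits_per_min <- function(N, P, window_seconds, gaze_seconds = 1) {
  if (window_seconds <= 0) stop("window_seconds must be positive", call. = FALSE)
  if (gaze_seconds < 0) stop("gaze_seconds must be non-negative", call. = FALSE)
  bits_per_trial(N, P) * 60 / (window_seconds + gaze_seconds)
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`, either from a series of values or directly from summary
#' inputs. Scale-invariant for positive series.
#'
#' @param values numeric series (ignored when `mean` and `sd` are given).
#' @param mean,sd optional summary inputs.
#' @return percent.
#' @export
cv_percent <- function(values = NULL, mean = NULL, sd = NULL) {
  if (is.null(mean) || is.null(sd)) {
    if (is.null(values)) stop("supply `values` or both `mean` and `sd`",
                              call. = FALSE)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (mean == 0) stop("coefficient of variation undefined for zero mean",
                      call. = FALSE)
  100 * sd / mean
}
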