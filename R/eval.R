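# Batch evaluation: decision tables, sliding-window phase-effect experiments
# and window-length sweeps over configured detectors.
#
# A "detector" throughout is a function(window_matrix) -> detection_result;
# the factories below close over their references/templates/penalties.

#' Built-in detector constructors
#'
#' Wrap the three classifiers as window-level detector functions for the
#' batch evaluation drivers.
#'
#' @param refs a [build_references()] set fixing window length and harmonics.
#' @param templates an [train_ssvep_templates()] result (NLCCA).
#' @param ... passed through to the underlying classifier.
#' @return `function(window_matrix) -> detection_result`.
#' @name detectors
NULL

#' @rdname detectors
#' @export
detector_cca <- function(refs) function(window) cca_classify(window, refs)

#' @rdname detectors
#' @export
detector_lasso <- function(refs, ...) {
  function(window) lasso_classify(window, refs, ...)
}

#' @rdname detectors
#' @export
detector_nlcca <- function(templates, ...) {
  function(window) nlcca_classify(window, templates, ...)
}

#' Run detectors over fixed windows of every trial
#'
#' @param epochs an [epoch_array()].
#' @param detectors named list of detector functions.
#' @param start_sample 0-based window start inside each trial.
#' @param length_samples window length.
#' @return data.frame with one row per (approach, trial): true and decided
#'   labels, correctness, and flags.
#' @export
detect_epochs <- function(epochs, detectors, start_sample, length_samples) {
  idx <- (start_sample + 1L):(start_sample + length_samples)
  if (max(idx) > dim(epochs$data)[3L]) stop("window exceeds trial bounds",
                                            call. = FALSE)
  out <- list()
  for (name in names(detectors)) {
    fn <- detectors[[name]]
    res <- lapply(seq_len(n_trials(epochs)), function(i)
      fn(trial_matrix(epochs, i)[, idx, drop = FALSE]))
    out[[name]] <- data.frame(
      approach = name,
      trial = seq_len(n_trials(epochs)),
      true = epochs$labels,
      decided = vapply(res, function(r) r$decided, integer(1)),
      degenerate = vapply(res, function(r) r$degenerate, logical(1)),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$correct <- tab$true == tab$decided
  rownames(tab) <- NULL
  tab
}

#' Sliding-window phase-effect experiment
#'
#' Slides a window over every trial (typically one second in one-sample
#' steps) and records, per approach and window start, the accuracy across
#' trials and the resulting ITR. Run once with `trim_samples = 0` (transient
#' VEP stage included) and once with `trim_samples = 50` (~200 ms trimmed) to
#' expose the phase/transient effects; the per-approach coefficient of
#' variation over window positions summarizes stability.
#'
#' @param epochs an [epoch_array()].
#' @param detectors named list of detector functions (window length must
#'   match `spec$length_samples`).
#' @param spec a [window_spec()].
#' @param gaze_seconds per-decision overhead for the ITR.
#' @return list with `observations` (long data.frame: approach, start,
#'   accuracy, itr) and `summary` (per approach and response: mean, sd,
#'   cv percent).
#' @export
sliding_window_experiment <- function(epochs, detectors, spec,
                                      gaze_seconds = 1) {
  ns <- dim(epochs$data)[3L]
  starts <- window_starts(spec, ns, mode = "sliding")
  K <- epochs$grid$K
  win_sec <- spec$length_samples / epochs$sample_rate
  rows <- list()
  for (name in names(detectors)) {
    fn <- detectors[[name]]
    acc <- vapply(starts, function(s) {
      idx <- (s + 1L):(s + spec$length_samples)
      correct <- vapply(seq_len(n_trials(epochs)), function(i)
        fn(epochs$data[i, , idx, drop = TRUE])$decided == epochs$labels[i],
        logical(1))
      mean(correct) * 100
    }, numeric(1))
    itr <- vapply(acc / 100, function(p) {
      if (p <= 0) return(0)
      suppressWarnings(itr_bits_per_min(K, p, win_sec, gaze_seconds))
    }, numeric(1))
    rows[[name]] <- data.frame(approach = name, start = starts,
                               accuracy = acc, itr = itr,
                               stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  summ <- do.call(rbind, lapply(split(obs, obs$approach), function(d) {
    data.frame(
      approach = d$approach[1L],
      response = c("accuracy", "itr"),
      mean = c(mean(d$accuracy), mean(d$itr)),
      sd = c(stats::sd(d$accuracy), stats::sd(d$itr)),
      cv = c(cv_percent(d$accuracy), cv_percent(d$itr)),
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(observations = obs, summary = summ)
}

#' Accuracy/ITR sweep over window lengths
#'
#' Evaluates each detector at a grid of window lengths (0.5-4 s by default)
#' and reports, per detector, the accuracy and ITR at every length plus the
#' maximum-ITR row (the operating point trading window length against
#' accuracy).
#'
#' @param epochs an [epoch_array()].
#' @param detector_factories named list of `function(length_samples) ->
#'   detector function`; each factory builds a detector sized to the window
#'   (constructing references, or training templates, at that length).
#' @param lengths_seconds window lengths to evaluate.
#' @param start_sample 0-based window start (e.g. 50 to skip the transient).
#' @param gaze_seconds per-decision overhead for the ITR.
#' @return list with `table` (length x approach accuracy/ITR long
#'   data.frame) and `best` (per-approach maximum-ITR row).
#' @export
window_length_sweep <- function(epochs, detector_factories,
                                lengths_seconds = seq(0.5, 4, by = 0.5),
                                start_sample = 0L, gaze_seconds = 1) {
  S <- epochs$sample_rate
  ns <- dim(epochs$data)[3L]
  K <- epochs$grid$K
  rows <- list()
  for (len in lengths_seconds) {
    T_w <- as.integer(round(len * S))
    if (start_sample + T_w > ns) {
      stop(sprintf("window of %g s exceeds trial bounds", len), call. = FALSE)
    }
    for (name in names(detector_factories)) {
      fn <- detector_factories[[name]](T_w)
      tab <- detect_epochs(epochs, stats::setNames(list(fn), name),
                           start_sample, T_w)
      p <- mean(tab$correct)
      rows[[length(rows) + 1L]] <- data.frame(
        approach = name, window_seconds = len, accuracy = p * 100,
        itr = if (p > 0)
          suppressWarnings(itr_bits_per_min(K, p, len, gaze_seconds)) else 0,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- do.call(rbind, lapply(split(tab, tab$approach), function(d)
    d[which.max(d$itr), ]))
  rownames(best) <- NULL
  list(table = tab, best = best)
}

#' Aggregate per-user summaries, optionally dropping the worst user
#'
#' Column-wise means of a per-user table (e.g. each user's maximum-ITR
#' window, accuracy and ITR), with an option to exclude the user with the
#' lowest mean of a chosen column first — the generic form of "average
#' performance for all users except the worst".
#'
#' @param per_user data.frame of numeric per-user rows.
#' @param drop_lowest_by column name; when given, the single row with the
#'   lowest value in it is excluded before averaging.
#' @return named numeric vector of column means.
#' @export
aggregate_users <- function(per_user, drop_lowest_by = NULL) {
  num <- per_user[vapply(per_user, is.numeric, logical(1))]
  if (!is.null(drop_lowest_by)) {
    num <- num[-which.min(num[[drop_lowest_by]]), , drop = FALSE]
  }
  colMeans(num)
}
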