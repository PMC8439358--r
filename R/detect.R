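#' Per-trial detection result
#'
#' Score vector over the K stimuli plus the decided index. Ties are broken
#' toward the smallest stimulus index, so batch evaluation is deterministic.
#'
#' @param scores numeric vector of per-stimulus scores.
#' @param kind score type: `"cca_rho"`, `"lasso_contribution"` or
#'   `"nlcca_bicor"`.
#' @param degenerate flag set when the input window carried no usable signal
#'   (e.g. zero variance) and the decision is the tie-break default.
#' @param low_confidence flag set by template detectors when the best score
#'   falls below their confidence threshold.
#' @export
detection_result <- function(scores, kind, degenerate = FALSE,
                             low_confidence = FALSE) {
  decided <- which.max(scores)   # first maximum = lowest index on ties
  structure(list(scores = as.numeric(scores), decided = as.integer(decided),
                 kind = kind, degenerate = isTRUE(degenerate),
                 low_confidence = isTRUE(low_confidence)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result:%s> decided stimulus %d (score %.4f)%s%s\n",
              x$kind, x$decided, x$scores[x$decided],
              if (x$degenerate) " [degenerate]" else "",
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

# Coerce a single-trial epoch_array or matrix to [channel, sample].
as_window_matrix <- function(window) {
  if (is_epoch_array(window)) {
    if (n_trials(window) != 1L) stop("expected a single-trial window", call. = FALSE)
    return(trial_matrix(window, 1L))
  }
  if (!is.matrix(window)) stop("window must be a matrix or epoch_array", call. = FALSE)
  window
}
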