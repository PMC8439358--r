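#' Zero-phase IIR bandpass filtering
#'
#' Applies a Butterworth bandpass forward and backward over the sample axis of
#' every trial and channel, canceling the filter's phase response (zero group
#' delay in the passband). Edges are handled by odd-reflection padding of
#' three filter lengths, which suppresses startup transients on windows as
#' short as one second.
#'
#' @param epochs an [epoch_array()] (or a plain `[channel, sample]` matrix).
#' @param low,high band edges in Hz; `0 < low < high < sample_rate/2`.
#' @param order Butterworth order of the underlying low/high sections.
#' @param sample_rate required when `epochs` is a bare matrix.
#' @return object of the same type with filtered data.
#' @export
bandpass_zero_phase <- function(epochs, low = 6, high = 80, order = 4,
                                sample_rate = NULL) {
  if (is_epoch_array(epochs)) {
    S <- epochs$sample_rate
  } else if (is.matrix(epochs)) {
    if (is.null(sample_rate)) stop("`sample_rate` required for matrix input",
                                   call. = FALSE)
    S <- sample_rate
  } else stop("`epochs` must be an epoch_array or matrix", call. = FALSE)
  if (!(low > 0 && low < high && high < S / 2)) {
    stop("band edges must satisfy 0 < low < high < sample_rate/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (S / 2), type = "pass")
  if (is.matrix(epochs)) {
    return(t(apply(epochs, 1L, filtfilt_padded, bf = bf)))
  }
  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      out[i, ch, ] <- filtfilt_padded(epochs$data[i, ch, ], bf)
    }
  }
  epochs$data <- out
  epochs
}

# Forward-backward filtering with odd-reflection padding (3x the filter
# polynomial length), after scipy's filtfilt convention.
filtfilt_padded <- function(x, bf) {
  n <- length(x)
  pad <- min(3L * (length(bf$a) + length(bf$b)), n - 1L)
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filter(bf, ext)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Sinusoidal harmonic reference signals
#'
#' For each stimulus frequency `f_k` builds the `2*Nh x T` matrix with rows
#' `sin(2*pi*h*f_k*t), cos(2*pi*h*f_k*t)` for harmonics `h = 1..Nh` at
#' `t = 1/S, 2/S, ..., T/S`. These are the templates linear CCA and LASSO
#' regress the EEG against.
#'
#' @param grid a [stimulus_grid()].
#' @param Nh number of harmonics (>= 1); the fundamental plus `Nh - 1`
#'   overtones. Default 3.
#' @param T_samples window length in samples.
#' @param sample_rate sampling rate in Hz.
#' @return object of class `reference_set`: list with `Y` (list of K
#'   matrices), `Nh`, `T_samples`, `sample_rate`, `grid`.
#' @export
build_references <- function(grid, Nh = 3, T_samples, sample_rate) {
  stopifnot(Nh >= 1, T_samples >= 1)
  t <- seq_len(T_samples) / sample_rate
  Y <- lapply(grid$frequencies, function(f) {
    m <- matrix(NA_real_, nrow = 2 * Nh, ncol = T_samples)
    for (h in seq_len(Nh)) {
      m[2 * h - 1, ] <- sin(2 * pi * h * f * t)
      m[2 * h, ] <- cos(2 * pi * h * f * t)
    }
    rownames(m) <- as.vector(rbind(paste0("sin_h", seq_len(Nh)),
                                   paste0("cos_h", seq_len(Nh))))
    m
  })
  structure(list(Y = Y, Nh = as.integer(Nh), T_samples = as.integer(T_samples),
                 sample_rate = sample_rate, grid = grid),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d stimuli, %d harmonics, %d samples @ %g Hz\n",
              x$grid$K, x$Nh, x$T_samples, x$sample_rate))
  invisible(x)
}

#' Window specification
#'
#' Describes fixed or sliding window extraction over stored trials. All
#' sample indices are 0-based with sample 0 at the start of the stored trial.
#' `trim_samples` drops the initial samples (e.g. 50 samples at 256 Hz to
#' skip the ~200 ms transient VEP stage) before any window is placed.
#'
#' @param length_samples window length in samples (> 0).
#' @param start_sample first window position (fixed mode), 0-based.
#' @param step_samples stride between consecutive windows (sliding mode).
#' @param trim_samples samples discarded from the trial front.
#' @export
window_spec <- function(length_samples, start_sample = 0L, step_samples = 1L,
                        trim_samples = 0L) {
  stopifnot(length_samples > 0, start_sample >= 0, step_samples >= 1,
            trim_samples >= 0)
  structure(list(length_samples = as.integer(length_samples),
                 start_sample = as.integer(start_sample),
                 step_samples = as.integer(step_samples),
                 trim_samples = as.integer(trim_samples)),
            class = "window_spec")
}

#' Enumerate window start positions
#'
#' Fixed mode yields the single start `start_sample + trim_samples`; sliding
#' mode yields every start from `trim_samples` to `trial_length - window
#' length` inclusive, stepping by `step_samples`.
#'
#' @param spec a [window_spec()].
#' @param trial_samples number of samples per stored trial.
#' @param mode `"fixed"` or `"sliding"`.
#' @return integer vector of 0-based start positions.
#' @export
window_starts <- function(spec, trial_samples, mode = c("sliding", "fixed")) {
  mode <- match.arg(mode)
  last <- trial_samples - spec$length_samples
  if (mode == "fixed") {
    s <- spec$start_sample + spec$trim_samples
    if (s > last) stop("window exceeds trial bounds", call. = FALSE)
    return(s)
  }
  if (spec$trim_samples > last) stop("window exceeds trial bounds", call. = FALSE)
  seq.int(spec$trim_samples, last, by = spec$step_samples)
}

#' Extract fixed or sliding windows from epochs
#'
#' Returns a lazy sequence: start positions plus an accessor materializing the
#' windowed [epoch_array()] at a given position, so a full sliding sweep never
#' holds all windows in memory at once.
#'
#' @param epochs an [epoch_array()].
#' @param spec a [window_spec()].
#' @param mode `"fixed"` or `"sliding"`.
#' @return object of class `window_seq` with elements `starts` (0-based) and
#'   `at(start)` returning the windowed `epoch_array` (with `onset_offset`
#'   advanced accordingly). `length()` gives the number of windows.
#' @export
extract_windows <- function(epochs, spec, mode = c("sliding", "fixed")) {
  mode <- match.arg(mode)
  ns <- dim(epochs$data)[3L]
  starts <- window_starts(spec, ns, mode)
  at <- function(start) {
    idx <- (start + 1L):(start + spec$length_samples)
    epoch_array(epochs$data[, , idx, drop = FALSE],
                sample_rate = epochs$sample_rate, grid = epochs$grid,
                labels = epochs$labels, block_ids = epochs$block_ids,
                channel_names = epochs$channel_names,
                onset_offset = epochs$onset_offset + start)
  }
  structure(list(starts = starts, at = at, spec = spec),
            class = "window_seq")
}

#' @export
length.window_seq <- function(x) length(x$starts)
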