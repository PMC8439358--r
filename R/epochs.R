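#' Default occipital/parietal montage
#'
#' The eight-electrode montage covering the occipital and parietal cortex
#' where SSVEP responses are strongest.
#' @export
SSVEP_CHANNELS <- c("O1", "O2", "Oz", "PO7", "PO3", "POz", "PO4", "PO8")

#' Labeled multichannel EEG epochs
#'
#' Container for a set of equally shaped EEG trials, each labeled with the
#' index of the stimulus the user was attending. The trial tensor is ordered
#' `[trial, channel, sample]`, amplitudes are in microvolts, and sample 0 of
#' each stored trial is the flicker onset (minus any samples already trimmed,
#' tracked by `onset_offset`).
#'
#' @param data numeric 3-D array `[trial, channel, sample]`, microvolts.
#' @param sample_rate sampling rate in Hz (> 0); 256 Hz is the package default.
#' @param grid a [stimulus_grid()].
#' @param labels integer vector, one per trial, each in `1..grid$K`.
#' @param block_ids integer vector, one per trial, the acquisition block.
#' @param channel_names character vector naming the channel axis.
#' @param onset_offset non-negative integer: samples already removed from the
#'   front of every trial relative to stimulus onset.
#' @return An object of class `epoch_array`.
#' @examples
#' arr <- array(rnorm(2 * 8 * 64), dim = c(2, 8, 64))
#' ep <- epoch_array(arr, sample_rate = 256, grid = stimulus_grid(),
#'                   labels = c(1L, 5L), block_ids = c(1L, 1L))
#' n_trials(ep)
#' @export
epoch_array <- function(data, sample_rate = 256, grid = stimulus_grid(),
                        labels, block_ids = rep(1L, dim(data)[1L]),
                        channel_names = NULL, onset_offset = 0L) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop("`data` must be a numeric 3-D array [trial, channel, sample]",
         call. = FALSE)
  }
  d <- dim(data)
  if (is.null(channel_names)) {
    channel_names <- if (d[2L] == 8L) SSVEP_CHANNELS else
      paste0("ch", seq_len(d[2L]))
  }
  if (!is_stimulus_grid(grid)) stop("`grid` must be a stimulus_grid", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a positive scalar", call. = FALSE)
  }
  labels <- as.integer(labels)
  block_ids <- as.integer(block_ids)
  onset_offset <- as.integer(onset_offset)
  if (length(labels) != d[1L]) {
    stop(sprintf("`labels` has length %d but there are %d trials",
                 length(labels), d[1L]), call. = FALSE)
  }
  if (length(block_ids) != d[1L]) {
    stop(sprintf("`block_ids` has length %d but there are %d trials",
                 length(block_ids), d[1L]), call. = FALSE)
  }
  if (anyNA(labels) || any(labels < 1L) || any(labels > grid$K)) {
    stop(sprintf("`labels` must lie in [1, %d]", grid$K), call. = FALSE)
  }
  if (length(channel_names) != d[2L]) {
    stop(sprintf("`channel_names` has length %d but there are %d channels",
                 length(channel_names), d[2L]), call. = FALSE)
  }
  if (length(onset_offset) != 1L || is.na(onset_offset) || onset_offset < 0L) {
    stop("`onset_offset` must be a single non-negative integer", call. = FALSE)
  }
  structure(
    list(data = data, sample_rate = as.numeric(sample_rate), grid = grid,
         labels = labels, block_ids = block_ids,
         channel_names = as.character(channel_names),
         onset_offset = onset_offset),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_array> %d trials x %d channels x %d samples @ %g Hz (%g s)\n",
    d[1L], d[2L], d[3L], x$sample_rate, d[3L] / x$sample_rate))
  cat(sprintf("  stimuli: %d (%g-%g Hz), blocks: %d, onset offset: %d samples\n",
              x$grid$K, min(x$grid$frequencies), max(x$grid$frequencies),
              length(unique(x$block_ids)), x$onset_offset))
  invisible(x)
}

#' Number of trials in an epoch array
#' @param epochs an `epoch_array`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1L]

#' Extract one trial as a channels-by-samples matrix
#' @param epochs an `epoch_array`.
#' @param i trial index.
#' @return numeric matrix `[channel, sample]` with channel names as rownames.
#' @export
trial_matrix <- function(epochs, i) {
  stopifnot(i >= 1L, i <= n_trials(epochs))
  m <- epochs$data[i, , , drop = FALSE]
  dim(m) <- dim(epochs$data)[2:3]
  rownames(m) <- epochs$channel_names
  m
}

#' Subset trials of an epoch array
#' @param epochs an `epoch_array`.
#' @param idx integer or logical index over trials.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_array(epochs$data[idx, , , drop = FALSE],
              sample_rate = epochs$sample_rate, grid = epochs$grid,
              labels = epochs$labels[idx], block_ids = epochs$block_ids[idx],
              channel_names = epochs$channel_names,
              onset_offset = epochs$onset_offset)
}

is_epoch_array <- function(x) inherits(x, "epoch_array")
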