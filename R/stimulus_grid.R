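#' Stimulus frequency grid
#'
#' An ordered set of flicker frequencies driving the SSVEP stimuli. The
#' default grid is the 12-target layout used throughout the package: 9.25 Hz
#' to 14.75 Hz in 0.5 Hz steps. All frequencies must lie above 6 Hz, the
#' conventional lower bound of the steady-state regime (below it the visual
#' response stays transient).
#'
#' @param frequencies numeric vector of stimulus frequencies in Hz, strictly
#'   increasing, all > 6.
#' @return An object of class `stimulus_grid`: a list with elements
#'   `frequencies` and `K` (number of stimuli).
#' @examples
#' g <- stimulus_grid()
#' g$K                  # 12
#' g$frequencies[1]     # 9.25
#' @export
stimulus_grid <- function(frequencies = seq(9.25, 14.75, by = 0.5)) {
  if (!is.numeric(frequencies) || length(frequencies) < 1L) {
    stop("`frequencies` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(frequencies)) stop("`frequencies` must not contain NA", call. = FALSE)
  if (any(frequencies <= 6)) {
    stop("all stimulus frequencies must exceed 6 Hz (steady-state regime)",
         call. = FALSE)
  }
  if (length(frequencies) > 1L && any(diff(frequencies) <= 0)) {
    stop("`frequencies` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(frequencies = as.numeric(frequencies), K = length(frequencies)),
    class = "stimulus_grid"
  )
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf("<stimulus_grid> %d stimuli: %s Hz\n", x$K,
              paste(format(x$frequencies, trim = TRUE), collapse = ", ")))
  invisible(x)
}

is_stimulus_grid <- function(x) inherits(x, "stimulus_grid")
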