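#' Write an epoch array to a portable on-disk layout
#'
#' Persists epochs as one JSON metadata file (`epochs.json`) plus one
#' tab-delimited channels-by-samples matrix per trial (`trial_0001.tsv`, ...)
#' in a directory. Values are written with 17 significant digits so the
#' round trip through text is bit-exact for doubles.
#'
#' @param epochs a valid [epoch_array()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(epochs, path) {
  if (!is_epoch_array(epochs)) stop("`epochs` must be an epoch_array", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path),
                              call. = FALSE)
  d <- dim(epochs$data)
  meta <- list(
    format = "ssvepr-epochs",
    version = 1L,
    n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
    sample_rate = epochs$sample_rate,
    channel_names = epochs$channel_names,
    frequencies = epochs$grid$frequencies,
    labels = epochs$labels,
    block_ids = epochs$block_ids,
    onset_offset = epochs$onset_offset
  )
  jsonlite::write_json(meta, file.path(path, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(d[1L])) {
    m <- trial_matrix(epochs, i)
    lines <- apply(m, 1L, function(row)
      paste(sprintf("%.17g", row), collapse = "\t"))
    writeLines(lines, file.path(path, sprintf("trial_%04d.tsv", i)))
  }
  invisible(path)
}

#' Read an epoch array written by [write_epochs()]
#'
#' Validates the metadata against the trial matrices: a missing trial file or
#' a shape disagreement between `epochs.json` and any matrix is an error.
#'
#' @param path directory produced by [write_epochs()] (or conforming layout).
#' @return an [epoch_array()].
#' @export
read_epochs <- function(path) {
  meta_file <- file.path(path, "epochs.json")
  if (!file.exists(meta_file)) {
    stop(sprintf("no epochs.json metadata found in '%s'", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  req <- c("n_trials", "n_channels", "n_samples", "sample_rate",
           "channel_names", "frequencies", "labels", "block_ids")
  missing <- setdiff(req, names(meta))
  if (length(missing)) {
    stop(sprintf("metadata missing fields: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  nt <- as.integer(meta$n_trials)
  nc <- as.integer(meta$n_channels)
  ns <- as.integer(meta$n_samples)
  dat <- array(NA_real_, dim = c(nt, nc, ns))
  for (i in seq_len(nt)) {
    f <- file.path(path, sprintf("trial_%04d.tsv", i))
    if (!file.exists(f)) {
      stop(sprintf("trial matrix %d missing: '%s'", i, f), call. = FALSE)
    }
    rows <- strsplit(readLines(f), "\t", fixed = TRUE)
    if (length(rows) != nc || any(lengths(rows) != ns)) {
      stop(sprintf(
        "trial %d has shape %d x %d but metadata declares %d x %d",
        i, length(rows), if (length(rows)) length(rows[[1L]]) else 0L, nc, ns),
        call. = FALSE)
    }
    dat[i, , ] <- matrix(as.numeric(unlist(rows)), nrow = nc, byrow = TRUE)
  }
  epoch_array(dat,
              sample_rate = meta$sample_rate,
              grid = stimulus_grid(meta$frequencies),
              labels = meta$labels,
              block_ids = meta$block_ids,
              channel_names = meta$channel_names,
              onset_offset = if (is.null(meta$onset_offset)) 0L else
                as.integer(meta$onset_offset))
}
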