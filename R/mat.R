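# Minimal Level-5 MAT container reading, sufficient for the public SSVEP
# recording dumps: uncompressed numeric (double/single/integer) arrays only.
# Anything else is reported as an unsupported dialect.

MI_TYPES <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
              miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
              miINT64 = 12, miUINT64 = 13, miMATRIX = 14, miCOMPRESSED = 15,
              miUTF8 = 16)

mat5_unsupported <- function(msg) {
  stop(sprintf("unsupported MAT dialect: %s", msg), call. = FALSE)
}

# Decode a run of numeric payload bytes for a given mi type code.
mat5_decode_numeric <- function(bytes, type) {
  switch(as.character(type),
    "1" = readBin(bytes, "integer", n = length(bytes), size = 1, signed = TRUE),
    "2" = readBin(bytes, "integer", n = length(bytes), size = 1, signed = FALSE),
    "3" = readBin(bytes, "integer", n = length(bytes) / 2, size = 2, signed = TRUE),
    "4" = readBin(bytes, "integer", n = length(bytes) / 2, size = 2, signed = FALSE),
    "5" = readBin(bytes, "integer", n = length(bytes) / 4, size = 4),
    "6" = readBin(bytes, "integer", n = length(bytes) / 4, size = 4),
    "7" = readBin(bytes, "double", n = length(bytes) / 4, size = 4),
    "9" = readBin(bytes, "double", n = length(bytes) / 8, size = 8),
    mat5_unsupported(sprintf("numeric subelement of mi type %d", type)))
}

# Split a raw vector into (type, payload) data elements, honoring the
# small-data-element packing and 8-byte alignment.
mat5_elements <- function(raw) {
  out <- list()
  pos <- 1L
  n <- length(raw)
  while (pos + 7L <= n) {
    tag <- readBin(raw[pos:(pos + 3L)], "integer", size = 4)
    small_len <- bitwAnd(bitwShiftR(tag, 16L), 0xffffL)
    if (small_len > 0L) {
      type <- bitwAnd(tag, 0xffffL)
      payload <- raw[(pos + 4L):(pos + 3L + small_len)]
      pos <- pos + 8L
    } else {
      type <- tag
      len <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4)
      payload <- if (len > 0L) raw[(pos + 8L):(pos + 7L + len)] else raw(0)
      pos <- pos + 8L + len
      if (len %% 8L != 0L && type != MI_TYPES[["miCOMPRESSED"]]) {
        pos <- pos + (8L - len %% 8L)
      }
    }
    out[[length(out) + 1L]] <- list(type = type, payload = payload)
  }
  out
}

# Decode one miMATRIX payload into list(name, dims, values); NULL for array
# classes we do not handle (cell/struct/char/sparse).
mat5_decode_matrix <- function(payload) {
  sub <- mat5_elements(payload)
  if (length(sub) < 4L) mat5_unsupported("truncated miMATRIX element")
  flags <- readBin(sub[[1L]]$payload, "integer", size = 4, n = 2)
  class_id <- bitwAnd(flags[1L], 0xffL)
  if (!class_id %in% 6:15) return(NULL)  # only numeric array classes
  if (bitwAnd(flags[1L], bitwShiftL(1L, 11L)) != 0L) {
    mat5_unsupported("complex arrays")
  }
  dims <- readBin(sub[[2L]]$payload, "integer", size = 4,
                  n = length(sub[[2L]]$payload) / 4)
  name <- rawToChar(sub[[3L]]$payload)
  values <- mat5_decode_numeric(sub[[4L]]$payload, sub[[4L]]$type)
  if (length(values) != prod(dims)) mat5_unsupported("dimension/data mismatch")
  list(name = name, dims = dims, values = array(as.numeric(values), dim = dims))
}

# Parse a Level-5 MAT file into a named list of numeric arrays.
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128L) mat5_unsupported("file shorter than a MAT-5 header")
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") {
    mat5_unsupported("big-endian or non Level-5 container")
  }
  els <- mat5_elements(raw[-(1:128)])
  vars <- list()
  for (el in els) {
    if (el$type == MI_TYPES[["miCOMPRESSED"]]) {
      inflated <- tryCatch(memDecompress(el$payload, type = "gzip"),
                           error = function(e) NULL)
      if (is.null(inflated)) mat5_unsupported("compressed element (no zlib)")
      inner <- mat5_elements(inflated)
      if (length(inner) != 1L) next
      el <- inner[[1L]]
    }
    if (el$type != MI_TYPES[["miMATRIX"]]) next
    m <- mat5_decode_matrix(el$payload)
    if (!is.null(m)) vars[[m$name]] <- m$values
  }
  vars
}

#' Load SSVEP epochs from a Level-5 MAT container
#'
#' Best-effort ingestion of the public multi-stimulus SSVEP recording dumps.
#' The expected dialect is an uncompressed (or zlib-compressed) Level-5 MAT
#' file holding one 4-D numeric array laid out
#' `[stimulus, channel, sample, trial]`, optionally accompanied by a numeric
#' vector of stimulus frequencies whose length matches the stimulus axis.
#' When no frequency vector is present and the stimulus axis has length 12,
#' the default 9.25-14.75 Hz grid is assumed. Anything else raises an
#' unsupported-dialect error. Never required by the rest of the package.
#'
#' @param path path to the `.mat` file.
#' @param sample_rate sampling rate of the recordings in Hz.
#' @param onset_offset samples already trimmed from stimulus onset.
#' @return an [epoch_array()] with trials ordered block-major (all stimuli of
#'   block 1, then block 2, ...).
#' @export
load_external_mat <- function(path, sample_rate = 256, onset_offset = 0L) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  vars <- read_mat5(path)
  ndims <- vapply(vars, function(v) length(dim(v)), integer(1))
  tensors <- vars[ndims == 4L]
  if (length(tensors) == 0L) {
    mat5_unsupported("no 4-D numeric array found")
  }
  eeg <- tensors[[1L]]
  d <- dim(eeg)
  vecs <- vars[vapply(vars, function(v)
    length(dim(v)) <= 2L && min(dim(v)) == 1L, logical(1))]
  freqs <- NULL
  for (v in vecs) {
    if (length(v) == d[1L] && all(v > 6)) { freqs <- as.numeric(v); break }
  }
  if (is.null(freqs)) {
    if (d[1L] == 12L) {
      grid <- stimulus_grid()
    } else {
      mat5_unsupported(sprintf(
        "stimulus axis of length %d with no frequency vector", d[1L]))
    }
  } else {
    grid <- stimulus_grid(sort(freqs))
  }
  K <- d[1L]; nc <- d[2L]; ns <- d[3L]; nb <- d[4L]
  dat <- array(NA_real_, dim = c(K * nb, nc, ns))
  labels <- integer(K * nb)
  blocks <- integer(K * nb)
  idx <- 1L
  for (b in seq_len(nb)) {
    for (k in seq_len(K)) {
      dat[idx, , ] <- eeg[k, , , b]
      labels[idx] <- if (is.null(freqs)) k else match(freqs[k], grid$frequencies)
      blocks[idx] <- b
      idx <- idx + 1L
    }
  }
  epoch_array(dat, sample_rate = sample_rate, grid = grid, labels = labels,
              block_ids = blocks, onset_offset = onset_offset)
}
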