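# Minimal Level-5 MAT writer (uncompressed double arrays only), used to build
# loader fixtures in code at test time.

write_mat5_fixture <- function(path, arrays) {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, test fixture"))
  writeBin(desc[1:116], con)
  writeBin(raw(8L), con)                       # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)         # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)               # endian indicator
  pad8 <- function(n) if (n %% 8L) raw(8L - n %% 8L) else raw(0)
  for (name in names(arrays)) {
    a <- arrays[[name]]
    dims <- if (is.null(dim(a))) c(1L, length(a)) else dim(a)
    name_raw <- charToRaw(name)
    sub <- local({
      buf <- raw(0)
      emit <- function(type, payload) {
        tag <- writeBin(c(as.integer(type), length(payload)), raw(), size = 4)
        buf <<- c(buf, tag, payload, pad8(length(payload)))
      }
      emit(6L, writeBin(c(6L, 0L), raw(), size = 4))          # flags: double
      emit(5L, writeBin(as.integer(dims), raw(), size = 4))   # dimensions
      emit(1L, name_raw)                                      # name
      emit(9L, writeBin(as.numeric(a), raw(), size = 8))      # real data
      buf
    })
    writeBin(c(14L, length(sub)), con, size = 4)              # miMATRIX tag
    writeBin(sub, con)
  }
  invisible(path)
}
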