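#' WAV and sidecar I/O
#'
#' Minimal RIFF/WAVE reader and writer (mono, 16-bit PCM or 32-bit IEEE
#' float) plus the note-boundary CSV sidecar used alongside every stimulus.
#'
#' @name audio_io
NULL

#' Write an audio clip to a WAV file
#'
#' @param clip an `audio_clip`.
#' @param path output file path (`.wav`).
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @param sidecar if `TRUE` (default), write `<path>.csv` with note
#'   boundaries (note_index, start_s, end_s, target_semitone).
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bits = 16L, sidecar = TRUE) {
  stopifnot(inherits(clip, "audio_clip"), bits %in% c(16L, 32L))
  x <- clip$samples
  sr <- as.integer(clip$sample_rate)
  n <- length(x)
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, size = 2,
           endian = "little")                       # PCM / IEEE float
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  if (sidecar && !is.null(clip$note_boundaries)) {
    utils::write.csv(clip$note_boundaries, paste0(path, ".csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav]
#'
#' @param path file path; if `<path>.csv` exists it is read as the
#'   note-boundary sidecar.
#' @return an `audio_clip`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt_code <- NULL; bits <- NULL; sr <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_ch <- readBin(con, integer(), size = 2, endian = "little")
      if (n_ch != 1L) stop("only mono WAV supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (bits == 16L) {
        samples <- readBin(con, integer(), n = size / 2, size = 2,
                           endian = "little") / 32767
      } else if (bits == 32L && fmt_code == 3L) {
        samples <- readBin(con, numeric(), n = size / 4, size = 4,
                           endian = "little")
      } else stop("unsupported WAV encoding")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  bounds <- NULL
  sidecar <- paste0(path, ".csv")
  if (file.exists(sidecar)) bounds <- utils::read.csv(sidecar)
  new_audio_clip(samples, sr, bounds)
}
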