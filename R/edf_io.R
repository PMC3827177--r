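#' EDF (European Data Format) I/O
#'
#' Minimal EDF writer/reader (16-bit, 1-s data records) for multichannel
#' recordings, with events stored in a CSV sidecar (`<path>.events.csv`,
#' columns onset_s, label, trial_index) that round-trips exactly. Signal
#' values round-trip to within the 16-bit quantization step of each channel's
#' physical range.
#'
#' @name edf_io
NULL

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' @param rec a `raw_recording`.
#' @param path output path (`.edf`); events go to `<path>.events.csv`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  x <- rec$data
  fs <- rec$fs
  ns <- ncol(x)
  n <- nrow(x)
  n_rec <- ceiling(n / fs)
  n_pad <- n_rec * fs - n
  if (n_pad > 0) x <- rbind(x, matrix(rep(x[n, ], each = n_pad), n_pad, ns))
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  eq <- pmax_ - pmin_ < 1e-9
  pmax_[eq] <- pmin_[eq] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("synthetic participant", 80))
  wr(pad_field("erdvoice synthetic recording", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(256 * (ns + 1), 8))
  wr(pad_field(sprintf("NSAMP=%d", n), 44))   # true sample count (pre-pad)
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))
  wr(pad_field(ns, 4))
  labels <- colnames(x)
  for (l in labels) wr(pad_field(l, 16))
  for (l in labels) wr(pad_field("synthetic", 80))
  for (l in labels) wr(pad_field("uV", 8))
  for (v in pmin_) wr(pad_field(sprintf("%.6g", v), 8))
  for (v in pmax_) wr(pad_field(sprintf("%.6g", v), 8))
  for (l in labels) wr(pad_field(dmin, 8))
  for (l in labels) wr(pad_field(dmax, 8))
  for (l in labels) wr(pad_field("HP:none", 80))
  for (l in labels) wr(pad_field(fs, 8))
  for (l in labels) wr(pad_field("", 32))
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      dig <- round((x[rows, j] - pmin_[j]) * scale[j]) + dmin
      writeBin(as.integer(pmax(dmin, pmin(dmax, dig))), con, size = 2,
               endian = "little")
    }
  }
  if (!is.null(rec$events))
    utils::write.csv(rec$events, paste0(path, ".events.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read an EDF file written by [write_edf]
#'
#' @param path `.edf` file; `<path>.events.csv` is read if present.
#' @param channels optional montage data.frame to attach.
#' @return a `raw_recording`.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[j], size = 2, signed = TRUE,
                     endian = "little")
      data[((r - 1) * spr[j] + 1):(r * spr[j]), j] <-
        (dig - dmin[j]) * scale[j] + pmin_[j]
    }
  }
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+)", reserved))[[1]]
  if (length(m) == 2) data <- data[seq_len(as.integer(m[2])), , drop = FALSE]
  events <- NULL
  sidecar <- paste0(path, ".events.csv")
  if (file.exists(sidecar)) events <- utils::read.csv(sidecar)
  structure(list(data = data, channels = channels, fs = fs, events = events,
                 schedule = NULL),
            class = "raw_recording")
}
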