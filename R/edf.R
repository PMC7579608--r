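#' Write a recording to European Data Format (EDF)
#'
#' Minimal single-record EDF writer: the whole recording is stored as one
#' data record, each channel scaled to the 16-bit digital range from its own
#' physical extremes (quantization error at typical EEG gains is well below
#' 0.1 microvolt). Channel labels come from the montage.
#'
#' @param rec An `ms_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ms_recording"))
  dat <- rec$data
  ns <- ncol(dat); nsig <- nrow(dat)
  phys_max <- pmax(apply(abs(dat), 1, max), 1e-6)
  dig_max <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  dur <- ns / rec$fs
  wr(pad("0", 8))                       # version
  wr(pad("synthetic cohort", 80))       # patient id
  wr(pad("microstatr recording", 80))   # recording id
  wr(pad("01.01.00", 8))                # start date
  wr(pad("00.00.00", 8))                # start time
  wr(pad(256 + 256 * nsig, 8))          # header bytes
  wr(pad("", 44))                       # reserved
  wr(pad(1, 8))                         # n data records
  wr(pad(format(dur, digits = 7), 8))   # record duration (s)
  wr(pad(nsig, 4))                      # n signals
  labels <- rec$montage$channel_ids
  wr(paste(vapply(labels, pad, "", w = 16), collapse = ""))
  wr(strrep(" ", 80 * nsig))            # transducer
  wr(paste(rep(pad("uV", 8), nsig), collapse = ""))
  wr(paste(vapply(-phys_max, function(v) pad(format(v, digits = 6), 8), ""),
           collapse = ""))
  wr(paste(vapply(phys_max, function(v) pad(format(v, digits = 6), 8), ""),
           collapse = ""))
  wr(paste(rep(pad(-dig_max, 8), nsig), collapse = ""))
  wr(paste(rep(pad(dig_max, 8), nsig), collapse = ""))
  wr(strrep(" ", 80 * nsig))            # prefiltering
  wr(paste(rep(pad(ns, 8), nsig), collapse = ""))
  wr(strrep(" ", 32 * nsig))            # reserved
  for (i in seq_len(nsig)) {
    dig <- as.integer(round(dat[i, ] / phys_max[i] * dig_max))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a European Data Format (EDF) file
#'
#' Counterpart of [write_edf()]; reads standard EDF with any number of data
#' records, applying the per-channel physical/digital calibration. Fails
#' closed on truncated or malformed files (no partial object is returned).
#'
#' @param path EDF file path.
#' @param montage Optional `ms_montage`; its channel count must match the
#'   file. If omitted, a default montage of the right size is attached.
#' @return An `ms_recording`.
#' @export
read_edf <- function(path, montage = NULL) {
  size <- file.info(path)$size
  if (is.na(size) || size < 256)
    stop(sprintf("EDF error at byte 0: file too short (%s)", path),
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  num <- function(n, what, at) {
    s <- rd(n)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop(sprintf("EDF error at byte %d: bad %s field '%s'", at, what, s),
           call. = FALSE)
    v
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- num(8, "header-bytes", 184)
  rd(44)
  nrec <- num(8, "record-count", 236)
  dur <- num(8, "record-duration", 244)
  nsig <- as.integer(num(4, "signal-count", 252))
  if (nsig < 1) stop("EDF error at byte 252: no signals", call. = FALSE)
  labels <- vapply(seq_len(nsig), function(i) rd(16), "")
  rd(80 * nsig)
  rd(8 * nsig)                          # physical dimension
  phys_min <- vapply(seq_len(nsig), function(i) num(8, "phys-min", 256), 0)
  phys_max <- vapply(seq_len(nsig), function(i) num(8, "phys-max", 256), 0)
  dig_min <- vapply(seq_len(nsig), function(i) num(8, "dig-min", 256), 0)
  dig_max <- vapply(seq_len(nsig), function(i) num(8, "dig-max", 256), 0)
  rd(80 * nsig)
  spr <- vapply(seq_len(nsig), function(i) as.integer(num(8, "samples", 256)), 0L)
  rd(32 * nsig)
  expected <- header_bytes + nrec * sum(spr) * 2
  if (size < expected)
    stop(sprintf("EDF error at byte %d: truncated data (have %d, need %d bytes)",
                 size, size, expected), call. = FALSE)
  dat <- matrix(0, nsig, spr[1] * nrec)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nsig)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      dat[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        phys_min[i] + (dig - dig_min[i]) * scale
    }
  }
  fs <- spr[1] / dur
  if (is.null(montage)) {
    if (nsig < 8)
      stop("fewer than 8 signals; supply a montage explicitly", call. = FALSE)
    montage <- make_montage(nsig)
    if (!anyDuplicated(labels) && all(nzchar(labels)))
      montage$channel_ids <- labels
  } else if (n_channels(montage) != nsig) {
    stop(sprintf("montage has %d channels but EDF file has %d signals",
                 n_channels(montage), nsig), call. = FALSE)
  }
  eeg_recording(dat, fs, montage)
}
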