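#' Down-sample a recording with anti-alias filtering
#'
#' Applies a zero-phase (linear-phase windowed-sinc, centered convolution)
#' anti-alias low-pass with cutoff `0.4 * target_fs` before decimating to the
#' target rate. Integer rate ratios decimate exactly; non-integer ratios are
#' resampled on the common time axis by linear interpolation of the filtered
#' signal. `target_fs == fs` is an identity.
#'
#' @param rec An `ms_recording`.
#' @param target_fs Target sampling rate in Hz; must not exceed `rec$fs`.
#' @return An `ms_recording` at `target_fs`.
#' @export
eeg_resample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ms_recording"))
  if (target_fs > rec$fs)
    stop("target_fs exceeds the recording rate; upsampling is not supported",
         call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  h <- antialias_kernel(rec$fs, target_fs)
  filt <- t(apply(rec$data, 1, convolve_centered, h = h))
  n_in <- ncol(rec$data)
  n_out <- floor(n_in * target_fs / rec$fs)
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- 1 + (seq_len(n_out) - 1) * round(ratio)
    out <- filt[, idx, drop = FALSE]
  } else {
    t_in <- (seq_len(n_in) - 1) / rec$fs
    t_out <- (seq_len(n_out) - 1) / target_fs
    out <- t(apply(filt, 1, function(ch)
      stats::approx(t_in, ch, xout = t_out, rule = 2)$y))
  }
  eeg_recording(out, target_fs, rec$montage)
}

# Hamming-windowed sinc low-pass, cutoff 0.4*target_fs, transition width
# ~0.07*target_fs so the stopband is fully reached below the new Nyquist.
antialias_kernel <- function(fs, target_fs) {
  fc <- 0.4 * target_fs
  ntaps <- 2L * ceiling(3.3 * fs / (0.07 * target_fs) / 2) + 1L
  m <- (ntaps - 1L) / 2L
  n <- seq(-m, m)
  h <- 2 * fc / fs * sinc(2 * fc * n / fs)
  k <- seq(0, ntaps - 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (ntaps - 1L))
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# zero-phase FIR by symmetric convolution; edges padded by reflection
convolve_centered <- function(x, h) {
  m <- (length(h) - 1L) / 2L
  n <- length(x)
  pad <- c(x[pmin(n, m + 1L):2L], x, x[(n - 1L):pmax(1L, n - m)])
  y <- stats::filter(pad, h, method = "convolution", sides = 2)
  as.numeric(y[(m + 1L):(m + n)])
}

#' Zero-phase band-pass and notch filtering
#'
#' Forward-backward (zero-phase) Butterworth band-pass of two-pass order 4,
#' followed by a zero-phase biquad notch (quality factor 30) at the mains
#' frequency. Defaults follow a 2-20 Hz analysis band with a 60 Hz notch.
#'
#' @param rec An `ms_recording`.
#' @param lo,hi Band edges in Hz (`0 < lo < hi < fs/2`).
#' @param notch Notch frequency in Hz, or `NULL` to skip. Must be below
#'   Nyquist.
#' @param notch_q Notch quality factor (center frequency / -3 dB width).
#' @return A filtered `ms_recording`.
#' @export
eeg_bandpass <- function(rec, lo = 2, hi = 20, notch = 60, notch_q = 30) {
  stopifnot(inherits(rec, "ms_recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq) stop("hi must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
  out <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  if (!is.null(notch)) {
    if (notch >= nyq)
      stop("notch frequency must be below the Nyquist frequency", call. = FALSE)
    nb <- notch_biquad(notch, rec$fs, notch_q)
    out <- t(apply(out, 1, function(ch) signal::filtfilt(nb$b, nb$a, ch)))
  }
  eeg_recording(out, rec$fs, rec$montage)
}

# RBJ audio-EQ cookbook notch
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive non-overlapping windows; a trailing partial window is dropped.
#' Each epoch is baseline-corrected by subtracting the per-channel within-epoch
#' mean.
#'
#' @param rec An `ms_recording`.
#' @param epoch_s Epoch length in seconds (default 2).
#' @return An `ms_epochs` object.
#' @export
eeg_epoch <- function(rec, epoch_s = 2) {
  stopifnot(inherits(rec, "ms_recording"))
  n_per <- round(rec$fs * epoch_s)
  n_ep <- floor(ncol(rec$data) / n_per)
  if (n_ep < 1)
    stop("recording shorter than one epoch", call. = FALSE)
  dat <- array(0, dim = c(nrow(rec$data), n_per, n_ep))
  for (e in seq_len(n_ep)) {
    sl <- rec$data[, ((e - 1) * n_per + 1):(e * n_per), drop = FALSE]
    dat[, , e] <- sl - rowMeans(sl)
  }
  new_epochs(dat, rec$fs, epoch_s, rec$montage)
}

#' Flag artifact epochs and bad channels by amplitude and flatness
#'
#' A channel is marked bad within an epoch when its peak-to-peak amplitude
#' exceeds `amp_uV` or falls below `flat_uV` (a flat/disconnected channel).
#' An epoch is flagged as an artifact when the fraction of channels exceeding
#' `amp_uV` is above `max_bad_frac`, or when so many channels are bad that
#' interpolation would be unreliable (>= 25% of the montage). A deterministic,
#' explicit substitute for interactive artifact screening.
#'
#' @param ep An `ms_epochs`.
#' @param amp_uV Peak-to-peak rejection threshold in microvolts (default 200).
#' @param flat_uV Peak-to-peak flatness threshold in microvolts (default 0.5).
#' @param max_bad_frac Fraction of amplitude-exceeding channels above which
#'   the whole epoch is rejected (default 0.1).
#' @return The `ms_epochs` with `artifact_flags` and `bad_channels` filled in.
#' @export
flag_artifacts <- function(ep, amp_uV = 200, flat_uV = 0.5,
                           max_bad_frac = 0.1) {
  stopifnot(inherits(ep, "ms_epochs"))
  if (amp_uV <= 0 || flat_uV <= 0) stop("thresholds must be > 0", call. = FALSE)
  n_ch <- dim(ep$data)[1]
  flags <- logical(n_epochs(ep))
  bad <- vector("list", n_epochs(ep))
  for (e in seq_len(n_epochs(ep))) {
    sl <- ep$data[, , e, drop = FALSE]
    p2p <- apply(sl[, , 1, drop = FALSE], 1, function(v) diff(range(v)))
    over <- p2p > amp_uV
    flat <- p2p < flat_uV
    bad[[e]] <- which(over | flat)
    flags[e] <- mean(over) > max_bad_frac || length(bad[[e]]) >= 0.25 * n_ch
  }
  ep$artifact_flags <- flags
  ep$bad_channels <- bad
  ep
}

#' Keep the first n artifact-free epochs
#'
#' Walks epochs in temporal order, skips flagged ones and stops after `n`
#' clean epochs, mirroring a fixed-data-budget analysis (20 s at the default
#' 10 x 2 s).
#'
#' @param ep A flagged `ms_epochs`.
#' @param n Number of clean epochs to keep (default 10).
#' @return An `ms_epochs` containing at most `n` unflagged epochs.
#' @export
select_clean_epochs <- function(ep, n = 10) {
  stopifnot(inherits(ep, "ms_epochs"))
  keep <- which(!ep$artifact_flags)
  if (length(keep) < n)
    warning(sprintf("only %d artifact-free epochs available (requested %d)",
                    length(keep), n))
  keep <- utils::head(keep, n)
  subset_epochs(ep, keep)
}

subset_epochs <- function(ep, idx) {
  new_epochs(ep$data[, , idx, drop = FALSE], ep$fs, ep$epoch_s, ep$montage,
             artifact_flags = ep$artifact_flags[idx],
             bad_channels = ep$bad_channels[idx])
}

#' Re-reference to the common average
#'
#' Subtracts, at every time point, the instantaneous mean over channels, so
#' that every frame has zero channel mean. Idempotent; leaves global field
#' power unchanged on already-referenced data.
#'
#' @param x An `ms_epochs`, `ms_recording`, or a channels x samples matrix.
#' @return The same type, average-referenced.
#' @export
average_reference <- function(x) UseMethod("average_reference")

#' @export
average_reference.matrix <- function(x) {
  sweep(x, 2, colMeans(x))
}

#' @export
average_reference.numeric <- function(x) x - mean(x)

#' @export
average_reference.ms_recording <- function(x) {
  x$data <- average_reference(x$data)
  x
}

#' @export
average_reference.ms_epochs <- function(x) {
  for (e in seq_len(n_epochs(x)))
    x$data[, , e] <- average_reference(x$data[, , e])
  x
}
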