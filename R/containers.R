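#' Create a continuous EEG recording object
#'
#' @param data channels x samples numeric matrix of voltages (microvolts).
#' @param fs Sampling rate in Hz.
#' @param montage An `ms_montage` whose channel count matches `nrow(data)`.
#' @return An `ms_recording` object.
#' @export
eeg_recording <- function(data, fs, montage) {
  data <- as.matrix(data)
  validate_montage(montage)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  if (nrow(data) != n_channels(montage))
    stop("channel count of data does not match the montage", call. = FALSE)
  if (!all(is.finite(data)))
    stop("recording contains non-finite values", call. = FALSE)
  structure(
    list(data = data, fs = fs, montage = montage),
    class = "ms_recording"
  )
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

new_epochs <- function(data, fs, epoch_s, montage,
                       artifact_flags = NULL, bad_channels = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_ep <- dim(data)[3]
  if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, n_ep)
  if (is.null(bad_channels)) bad_channels <- rep(list(integer(0)), n_ep)
  stopifnot(length(artifact_flags) == n_ep, length(bad_channels) == n_ep)
  structure(
    list(data = data, fs = fs, epoch_s = epoch_s, montage = montage,
         artifact_flags = artifact_flags, bad_channels = bad_channels),
    class = "ms_epochs"
  )
}

#' @export
print.ms_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ms_epochs> %d epochs x %d channels x %d samples @ %g Hz (%d flagged)\n",
    d[3], d[1], d[2], x$fs, sum(x$artifact_flags)))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[3]
epoch_samples <- function(ep) dim(ep$data)[2]
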