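#' Centre and linearly detrend each epoch
#'
#' Removes, per trial and channel, the temporal mean and the best-fitting
#' straight line, so every trace has mean zero and zero least-squares slope.
#'
#' @param epochs An `epochs_set` with at least 2 samples per epoch.
#' @return The detrended `epochs_set`.
#' @export
epoch_and_detrend <- function(epochs) {
  d <- dim(epochs$data)
  if (d[3] < 2) abort("need at least 2 samples per epoch")
  y <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3]) # time x traces
  x <- cbind(1, epochs$times)
  beta <- solve(crossprod(x), crossprod(x, y))  # 2 x traces
  y <- y - x %*% beta
  epochs$data <- aperm(array(y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared magnitude response of a 4th-order Butterworth
#' band-pass (the forward-backward / zero-phase response) to every
#' trial-channel trace in the frequency domain. Filter coefficients come
#' from [signal::butter()]; applying `|H(f)|^2` multiplicatively on the FFT
#' reproduces the forward-backward magnitude response with exactly zero
#' phase and circular (transient-free) edge handling.
#'
#' @param epochs An `epochs_set`.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < srate/2`.
#' @param order Filter order (default 4).
#' @return The filtered `epochs_set`.
#' @export
bandpass <- function(epochs, lo = 1, hi = 100, order = 4) {
  srate <- epochs$srate
  if (!(lo > 0 && lo < hi && hi < srate / 2))
    abort("invalid band: need 0 < lo < hi < srate/2 (srate = %g)", srate)
  bf <- signal::butter(order, c(lo, hi) / (srate / 2), type = "pass")
  d <- dim(epochs$data)
  n <- d[3]
  # zero-pad to a 2-3-5-smooth FFT length (also buffers the circular edge)
  np <- stats::nextn(n, factors = c(2, 3, 5))
  # digital frequency response at the FFT bin frequencies
  w <- 2 * pi * (0:(np - 1)) / np
  z <- exp(-1i * w)
  num <- outer(z, seq_along(bf$b) - 1, `^`) %*% bf$b
  den <- outer(z, seq_along(bf$a) - 1, `^`) %*% bf$a
  h2 <- as.vector(Mod(num / den)^2)              # |H|^2, real, zero phase
  y <- matrix(0, np, d[1] * d[2])
  y[seq_len(n), ] <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
  yf <- mvfft(y) * h2
  y <- Re(mvfft(yf, inverse = TRUE))[seq_len(n), , drop = FALSE] / np
  epochs$data <- aperm(array(y, dim = c(n, d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample of every trial, the mean over channels, so the
#' channel mean is zero everywhere.
#'
#' @param epochs An `epochs_set` with at least 2 channels.
#' @return The re-referenced `epochs_set`.
#' @export
rereference_common_average <- function(epochs) {
  d <- dim(epochs$data)
  if (d[2] < 2) abort("common-average reference needs at least 2 channels")
  m <- colMeans(aperm(epochs$data, c(2, 1, 3)))  # trials x time
  for (ch in seq_len(d[2]))
    epochs$data[, ch, ] <- epochs$data[, ch, ] - m
  epochs
}

#' Re-lock epochs to the cue or the stimulus
#'
#' Shifts each trial's time axis so that t = 0 falls at the requested event,
#' using the per-trial cue-to-stimulus onset asynchrony (`soa_ms`) recorded
#' in the epochs' schedule. Because the SOA varies across trials, the data
#' are re-aligned by integer sample shifts and cropped to the time range
#' common to all trials.
#'
#' @param epochs An `epochs_set`.
#' @param lock Target lock, `"cue"` or `"stimulus"`.
#' @param validate If `TRUE` (default), error when any SOA falls outside the
#'   design bounds of 1500-1900 ms.
#' @return An `epochs_set` locked to the requested event.
#' @export
timelock <- function(epochs, lock = c("cue", "stimulus"), validate = TRUE) {
  lock <- match.arg(lock)
  if (lock == epochs$lock) return(epochs)
  soa <- epochs$schedule$soa_ms
  if (is.null(soa) || anyNA(soa))
    abort("cue-to-stimulus offsets (soa_ms) missing from the epochs' schedule")
  if (validate && any(soa < 1500 | soa > 1900))
    abort("soa_ms outside the design bounds 1500-1900 ms")
  dt <- 1000 / epochs$srate
  # sample shift per trial: cue-time = stimulus-time + soa
  k <- round(soa / dt)
  sgn <- if (lock == "cue") 1L else -1L
  k <- sgn * k
  d <- dim(epochs$data)
  # new axis: intersection over trials of (times + k_i * dt)
  lo <- epochs$times[1] + max(k) * dt
  hi <- epochs$times[d[3]] + min(k) * dt
  if (hi <= lo) abort("no common time range after re-locking")
  n_new <- floor(round((hi - lo) / dt, 6)) + 1L
  new_times <- lo + (0:(n_new - 1)) * dt
  out <- array(NA_real_, dim = c(d[1], d[2], n_new))
  for (i in seq_len(d[1])) {
    # index into old axis: old_time = new_time - k_i * dt
    j0 <- round((new_times[1] - k[i] * dt - epochs$times[1]) / dt) + 1L
    out[i, , ] <- epochs$data[i, , j0 + 0:(n_new - 1L)]
  }
  epochs$data <- out
  epochs$times <- new_times
  epochs$lock <- lock
  epochs
}

#' Default baseline windows
#'
#' The cue-locked baseline is the 500 ms window from -650 to -150 ms before
#' cue onset (ending 150 ms before the cue because of the 150 ms half-taper
#' length). The stimulus-locked baseline is the same physical window
#' expressed on the stimulus-locked axis: the cue-locked window shifted by
#' the maximum cue-to-stimulus interval (500 ms cue plus the longest
#' 1400 ms blank), giving -2550 to -2050 ms.
#'
#' @param cue_window Cue-locked baseline window (ms).
#' @param cue_ms Cue duration (ms).
#' @param blank_max_ms Longest cue-stimulus blank (ms).
#' @return Length-2 numeric window in ms.
#' @examples
#' cue_baseline_window()                 # c(-650, -150)
#' stimulus_baseline_window()            # c(-2550, -2050)
#' @export
cue_baseline_window <- function() c(-650, -150)

#' @rdname cue_baseline_window
#' @export
stimulus_baseline_window <- function(cue_window = cue_baseline_window(),
                                     cue_ms = 500, blank_max_ms = 1400) {
  cue_window - (cue_ms + blank_max_ms)
}
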