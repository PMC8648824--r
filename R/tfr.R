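#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' matrix whose eigenvectors are the Slepian sequences. Tapers are
#' orthonormal (`crossprod` is the identity) and ordered by decreasing
#' spectral concentration.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (`T * W`, dimensionless).
#' @param k Number of tapers.
#' @return `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k < 1 || k > n) abort("k must be in 1..n")
  if (nw <= 0 || nw >= n / 2) abort("nw must be in (0, n/2)")
  i <- 0:(n - 1)
  w <- nw / n
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign convention: positive mean, or positive initial lobe
  # for the antisymmetric tapers
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) < 1e-8) s <- sum(v[seq_len(ceiling(n / 2)), j])
    if (s < 0) v[, j] <- -v[, j]
  }
  v
}

# shared sliding-window machinery: project every trace segment centred on
# the step grid onto tapered complex exponentials at exact frequencies.
# tapers: n_win x K (columns orthonormal or a single Hann window);
# returns list(power = traces x nfreq x ncenters, centers_ms)
.sliding_tfr <- function(epochs, freqs, window_ms, step_ms, tapers, scale,
                         center_windows = NULL) {
  d <- dim(epochs$data)
  n_t <- d[3]
  dt <- 1000 / epochs$srate
  n_win <- nrow(tapers)
  if (n_win > n_t) abort("analysis window (%g ms) longer than epoch", window_ms)
  half_l <- floor((n_win - 1) / 2)
  half_r <- n_win - 1 - half_l
  tmin <- epochs$times[1] + half_l * dt
  tmax <- epochs$times[n_t] - half_r * dt
  centers <- seq(ceiling(tmin / step_ms) * step_ms,
                 floor(tmax / step_ms) * step_ms, by = step_ms)
  if (!is.null(center_windows)) {
    if (!is.list(center_windows)) center_windows <- list(center_windows)
    keep <- Reduce(`|`, lapply(center_windows, function(wd)
      centers >= wd[1] & centers <= wd[2]))
    centers <- centers[keep]
  }
  if (!length(centers)) abort("epoch too short for one full analysis window")
  t_rel <- (-half_l:half_r) * dt / 1000           # s, relative to centre
  K <- ncol(tapers)
  # real/imag projection matrix: n_win x (2 * K * nfreq), freq-major
  ang <- outer(t_rel, 2 * pi * freqs)             # n_win x nfreq
  G <- matrix(0, n_win, 2 * K * length(freqs))
  for (fi in seq_along(freqs)) for (kk in seq_len(K)) {
    j <- (fi - 1) * 2 * K + (kk - 1) * 2
    G[, j + 1] <- tapers[, kk] * cos(ang[, fi])
    G[, j + 2] <- tapers[, kk] * sin(ang[, fi])
  }
  y <- matrix(epochs$data, nrow = d[1] * d[2])    # traces x time
  power <- array(NA_real_, dim = c(d[1] * d[2], length(freqs),
                                   length(centers)))
  for (ci in seq_along(centers)) {
    c_idx <- round((centers[ci] - epochs$times[1]) / dt) + 1L
    seg <- y[, (c_idx - half_l):(c_idx + half_r), drop = FALSE]
    pr <- seg %*% G                               # traces x 2K nfreq
    sq <- pr^2
    # sum real^2 + imag^2, average over tapers
    p <- sq[, seq(1, ncol(sq), by = 2), drop = FALSE] +
      sq[, seq(2, ncol(sq), by = 2), drop = FALSE] # traces x (K nfreq)
    if (K > 1) {
      p <- array(p, dim = c(nrow(p), K, length(freqs)))
      p <- colMeans(aperm(p, c(2, 1, 3)))          # traces x nfreq
    }
    power[, , ci] <- p * scale
  }
  list(power = array(power, dim = c(d[1], d[2], length(freqs),
                                    length(centers))),
       centers = centers)
}

#' Per-trial time-frequency power, sliding Hanning window
#'
#' Power at each requested frequency and window centre equals the squared
#' magnitude of the inner product of the Hann-tapered segment with a complex
#' exponential at exactly that frequency (no FFT zero-padding), scaled so a
#' unit-amplitude sinusoid at an analysed frequency has power ~1. Window
#' centres lie on the `step_ms` grid; windows that would need samples
#' outside the epoch are dropped.
#'
#' @param epochs An `epochs_set` (detrended; the estimate is not
#'   mean-invariant at the lowest frequencies otherwise).
#' @param freqs Analysis frequencies in Hz (default 1-30 Hz in 1 Hz steps).
#' @param window_ms Window length (default 300 ms).
#' @param step_ms Step size between window centres (default 50 ms).
#' @param center_windows Optional window (or list of windows) in ms; only
#'   window centres falling inside are computed (e.g. baseline plus test
#'   window), saving time on long epochs.
#' @return An object of class `tfr_trials`: list with `power` (trials x
#'   channels x freqs x times array), `freqs`, `times` (window centres, ms),
#'   `lock`, `srate`, `subject_id`, `schedule`, `channels`, `band`.
#' @export
tfr_hanning <- function(epochs, freqs = 1:30, window_ms = 300, step_ms = 50,
                        center_windows = NULL) {
  n_win <- round(window_ms / 1000 * epochs$srate)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(n_win - 1)) / (n_win - 1))
  res <- .sliding_tfr(epochs, freqs, window_ms, step_ms,
                      tapers = matrix(h, ncol = 1),
                      scale = (2 / sum(h))^2, center_windows = center_windows)
  structure(list(power = res$power, freqs = freqs, times = res$centers,
                 lock = epochs$lock, srate = epochs$srate,
                 subject_id = epochs$subject_id, schedule = epochs$schedule,
                 channels = epochs$channels, band = "low"),
            class = "tfr_trials")
}

#' Per-trial time-frequency power, sliding multitaper window
#'
#' Multitaper estimate for the high-frequency band: power is the average
#' over K Slepian tapers of the squared magnitudes of tapered-segment
#' projections onto exact-frequency complex exponentials. With the default
#' 200 ms window and 15 Hz half-bandwidth smoothing, the time-bandwidth
#' product is 3 and `K = floor(2 * T * W) - 1 = 5` tapers are used.
#'
#' @param epochs An `epochs_set`.
#' @param freqs Analysis frequencies in Hz (default 31-100 Hz in 1 Hz steps).
#' @param window_ms Window length (default 200 ms).
#' @param step_ms Step size (default 50 ms).
#' @param smoothing_hz Spectral smoothing half-bandwidth W in Hz (default 15).
#' @param n_tapers Number of tapers; default `floor(2 * T * W) - 1`.
#' @param center_windows Optional window (or list of windows) in ms; only
#'   window centres falling inside are computed.
#' @return A `tfr_trials` object (see [tfr_hanning()]) with `band = "high"`.
#' @export
tfr_multitaper <- function(epochs, freqs = 31:100, window_ms = 200,
                           step_ms = 50, smoothing_hz = 15, n_tapers = NULL,
                           center_windows = NULL) {
  n_win <- round(window_ms / 1000 * epochs$srate)
  nw <- (window_ms / 1000) * smoothing_hz
  if (is.null(n_tapers)) n_tapers <- max(1L, floor(2 * nw) - 1L)
  v <- dpss_tapers(n_win, nw, n_tapers)
  res <- .sliding_tfr(epochs, freqs, window_ms, step_ms, tapers = v,
                      scale = 2 / n_win, center_windows = center_windows)
  structure(list(power = res$power, freqs = freqs, times = res$centers,
                 lock = epochs$lock, srate = epochs$srate,
                 subject_id = epochs$subject_id, schedule = epochs$schedule,
                 channels = epochs$channels, band = "high"),
            class = "tfr_trials")
}

#' @export
print.tfr_trials <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_trials> %s: %d trials x %d ch x %d freqs (%g-%g Hz) x %d times, %s-locked\n",
    x$subject_id, d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4], x$lock))
  invisible(x)
}

#' Average per-trial TFRs into the nine condition cells
#'
#' Arithmetic mean of trial power within each cue-stimulus condition cell,
#' with per-cell trial counts recorded (needed for trial-weighted pooling at
#' the baselining stage).
#'
#' @param tfr A `tfr_trials` whose schedule rows carry `cell` indices (as
#'   produced by [simulate_subject_eeg()]), or cue/stim intensities.
#' @return An object of class `tfr_cond`: list with `power` (9 x channels x
#'   freqs x times), `n_trials` (length 9), `freqs`, `times`, `band`,
#'   `lock`, `subject_id`, `channels`, `baselined = FALSE`.
#' @export
average_by_condition <- function(tfr) {
  sch <- tfr$schedule
  cell <- sch$cell
  if (is.null(cell)) cell <- condition_index(sch$cue_intensity,
                                             sch$stim_intensity)
  d <- dim(tfr$power)
  n_cells <- 9L
  counts <- tabulate(cell, nbins = n_cells)
  if (any(counts == 0)) {
    g <- build_condition_grid()
    i <- which(counts == 0)[1]
    abort("no trials in condition cell %d (cue %s / stim %s)",
          i, g$cue_intensity[i], g$stim_intensity[i])
  }
  pw <- matrix(tfr$power, nrow = d[1])            # trials x rest
  avg <- rowsum(pw, group = cell) / counts        # 9 x rest
  structure(list(power = array(avg, dim = c(n_cells, d[2], d[3], d[4])),
                 n_trials = counts, freqs = tfr$freqs, times = tfr$times,
                 band = tfr$band, lock = tfr$lock,
                 subject_id = tfr$subject_id, channels = tfr$channels,
                 baselined = FALSE, baseline_window = NULL),
            class = "tfr_cond")
}

#' @export
print.tfr_cond <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_cond> %s: 9 cells x %d ch x %d freqs x %d times, %s-locked, %s\n",
    x$subject_id, d[2], d[3], d[4], x$lock,
    if (isTRUE(x$baselined))
      sprintf("z-baselined [%g, %g] ms", x$baseline_window[1],
              x$baseline_window[2])
    else "raw power"))
  invisible(x)
}

#' z-score baseline correction of a condition-averaged TFR
#'
#' For every channel-frequency combination, the baseline mean and standard
#' deviation are estimated from the all-trial average power (condition cells
#' pooled with their trial counts as weights) over the window's time points;
#' every data point is then transformed to `(x - mean) / SD`. The SD uses
#' the sample (N-1) convention over the baseline time points. After the
#' transformation the all-trial-average baseline samples have mean 0 and
#' SD 1 exactly.
#'
#' @param tfr A `tfr_cond` (raw power).
#' @param window Baseline window in ms (closed interval over window-centre
#'   times), e.g. [cue_baseline_window()] or [stimulus_baseline_window()].
#' @return The z-baselined `tfr_cond` with `baselined = TRUE` and the
#'   window recorded.
#' @export
zbaseline <- function(tfr, window) {
  if (isTRUE(tfr$baselined)) abort("TFR is already baselined")
  sel <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (length(sel) < 2)
    abort("baseline window [%g, %g] ms covers fewer than 2 time points",
          window[1], window[2])
  d <- dim(tfr$power)
  wts <- tfr$n_trials / sum(tfr$n_trials)
  # all-trial average: channels x freqs x times
  avg <- apply(tfr$power * wts, c(2, 3, 4), sum)
  base <- avg[, , sel, drop = FALSE]              # ch x freq x n_base
  m <- apply(base, c(1, 2), mean)
  s <- apply(base, c(1, 2), stats::sd)
  if (any(s == 0)) {
    i <- which(s == 0, arr.ind = TRUE)[1, ]
    abort("zero baseline SD for subject %s, channel %s, frequency %g Hz",
          tfr$subject_id, tfr$channels[i[1]], tfr$freqs[i[2]])
  }
  for (cell in seq_len(d[1]))
    tfr$power[cell, , , ] <- (tfr$power[cell, , , ] -
                                as.vector(m)) / as.vector(s)
  tfr$baselined <- TRUE
  tfr$baseline_window <- window
  tfr
}

#' Stack per-subject condition TFRs into a group array
#'
#' @param tfrs List of `tfr_cond` objects with identical grids.
#' @return An object of class `tfr_group`: list with `power` (subjects x 9
#'   cells x channels x freqs x times), `freqs`, `times`, `band`, `lock`,
#'   `channels`, `subjects`, `baselined`.
#' @export
stack_subjects <- function(tfrs) {
  if (!length(tfrs)) abort("empty TFR list")
  f0 <- tfrs[[1]]$freqs; t0 <- tfrs[[1]]$times
  for (x in tfrs)
    if (!identical(x$freqs, f0) || !identical(x$times, t0))
      abort("subjects have mismatching TFR grids")
  d <- dim(tfrs[[1]]$power)
  pw <- array(NA_real_, dim = c(length(tfrs), d))
  for (s in seq_along(tfrs)) pw[s, , , , ] <- tfrs[[s]]$power
  structure(list(power = pw, freqs = f0, times = t0,
                 band = tfrs[[1]]$band, lock = tfrs[[1]]$lock,
                 channels = tfrs[[1]]$channels,
                 subjects = vapply(tfrs, function(x) x$subject_id, ""),
                 baselined = tfrs[[1]]$baselined),
            class = "tfr_group")
}

#' Restrict a group TFR to a time window (and optionally frequencies)
#'
#' Samples are selected by window-centre timestamp within the closed
#' interval.
#'
#' @param tfr A `tfr_group`.
#' @param time_window Length-2 ms window, e.g. `c(0, 2000)`.
#' @param freqs Optional frequency subset (Hz).
#' @return The restricted `tfr_group`.
#' @export
subset_tfr <- function(tfr, time_window = NULL, freqs = NULL) {
  ti <- seq_along(tfr$times)
  if (!is.null(time_window))
    ti <- which(tfr$times >= time_window[1] & tfr$times <= time_window[2])
  fi <- seq_along(tfr$freqs)
  if (!is.null(freqs)) fi <- which(tfr$freqs %in% freqs)
  if (!length(ti) || !length(fi)) abort("empty TFR selection")
  tfr$power <- tfr$power[, , , fi, ti, drop = FALSE]
  tfr$freqs <- tfr$freqs[fi]
  tfr$times <- tfr$times[ti]
  tfr
}

#' @export
print.tfr_group <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_group> %d subjects x 9 cells x %d ch x %d freqs x %d times (%s band, %s-locked)\n",
    d[1], d[3], d[4], d[5], x$band, x$lock))
  invisible(x)
}

#' Read or write a TFR container
#'
#' Round-trips condition or group TFRs (power as 64-bit float, metadata
#' bit-exact) through a single-file RDS container.
#'
#' @param tfr A `tfr_cond` or `tfr_group`.
#' @param path File path.
#' @return `read_tfr` returns the object; `write_tfr` returns `path`
#'   invisibly.
#' @export
write_tfr <- function(tfr, path) {
  saveRDS(tfr, path)
  invisible(path)
}

#' @rdname write_tfr
#' @export
read_tfr <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("tfr_cond", "tfr_group", "tfr_trials")))
    abort("file does not contain a TFR object")
  obj
}
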