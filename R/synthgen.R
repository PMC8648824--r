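#' @importFrom stats rnorm fft mvfft
NULL

#' Specification of injected oscillatory effects
#'
#' Parameters of the generative model for synthetic condition-dependent EEG.
#' Each trial is 1/f background noise plus three band-limited oscillations
#' (alpha ~ 10 Hz, beta ~ 20 Hz, gamma ~ 55 Hz) with per-trial random phase
#' and frequency jitter, weighted across channels by smooth topographies.
#' During 0-2000 ms post-stimulus the alpha and beta amplitudes are
#' multiplied by `1 + g_pe_low * PE - g_int * INT - g_exp * EXP` and the
#' gamma amplitude by `1 + g_pe_gamma * PE`, so that post-stimulus
#' alpha-to-beta power decreases with stimulus valence (INT) and cued
#' valence (EXP) — an event-related desynchronization — while power from
#' alpha to gamma increases with the absolute prediction error.
#'
#' @param alpha_hz,beta_hz,gamma_hz Band centre frequencies (Hz).
#' @param alpha_hw,beta_hw,gamma_hw Half-widths of the per-trial frequency
#'   jitter (Hz).
#' @param amp_alpha,amp_beta,amp_gamma Baseline oscillation amplitudes A0
#'   (arbitrary microvolt-scale units).
#' @param g_int,g_exp Amplitude modulation gains of the INT and EXP factors
#'   on the alpha/beta bands (positive gain = deeper desynchronization for
#'   higher levels).
#' @param g_pe_low,g_pe_gamma Amplitude modulation gains of the PE factor on
#'   the alpha/beta bands and the gamma band.
#' @param noise_exponent Spectral exponent of the 1/f background.
#' @param noise_scale Standard deviation of the background noise.
#' @param topo_smoothness Spatial width (grid units) of the Gaussian
#'   topography bumps.
#' @return An object of class `effect_spec`. Errors if the modulation gains
#'   can drive any band amplitude non-positive over the nine condition cells.
#' @export
effect_spec <- function(alpha_hz = 10, alpha_hw = 2,
                        beta_hz = 20, beta_hw = 3,
                        gamma_hz = 55, gamma_hw = 10,
                        amp_alpha = 10, amp_beta = 7, amp_gamma = 5,
                        g_int = 0.3, g_exp = 0.3,
                        g_pe_low = 0.12, g_pe_gamma = 0.45,
                        noise_exponent = 1, noise_scale = 10,
                        topo_smoothness = 1.5) {
  spec <- list(bands = data.frame(
                 band = c("alpha", "beta", "gamma"),
                 center = c(alpha_hz, beta_hz, gamma_hz),
                 halfwidth = c(alpha_hw, beta_hw, gamma_hw),
                 amp = c(amp_alpha, amp_beta, amp_gamma)),
               g_int = g_int, g_exp = g_exp,
               g_pe_low = g_pe_low, g_pe_gamma = g_pe_gamma,
               noise_exponent = noise_exponent, noise_scale = noise_scale,
               topo_smoothness = topo_smoothness)
  class(spec) <- "effect_spec"
  validate_effect_spec(spec)
  spec
}

#' @rdname effect_spec
#' @param spec An `effect_spec`.
#' @export
validate_effect_spec <- function(spec) {
  g <- build_condition_grid()
  m_low <- spec$g_pe_low * g$pe_code - spec$g_int * g$int_code -
    spec$g_exp * g$exp_code
  m_gamma <- spec$g_pe_gamma * g$pe_code
  if (any(abs(m_low) >= 1) || any(abs(m_gamma) >= 1))
    abort(paste0("effect gains drive a band amplitude non-positive: ",
                 "max |low-band modulation| = %.3f, ",
                 "max |gamma modulation| = %.3f (both must be < 1)"),
          max(abs(m_low)), max(abs(m_gamma)))
  invisible(spec)
}

# amplitude multipliers for the 9 condition cells: list(low, gamma), each 9
.cell_modulation <- function(spec) {
  g <- build_condition_grid()
  list(low = 1 + spec$g_pe_low * g$pe_code - spec$g_int * g$int_code -
         spec$g_exp * g$exp_code,
       gamma = 1 + spec$g_pe_gamma * g$pe_code)
}

# 1/f^(exponent) noise, one column per trace, each normalised to unit SD
# then scaled; n x m matrix. Generated at a 2-3-5-smooth FFT length and
# truncated (FFTs of lengths with large prime factors are quadratic).
.pink_noise <- function(n, m, exponent, scale) {
  if (scale == 0) return(matrix(0, n, m))
  np <- stats::nextn(n, factors = c(2, 3, 5))
  white <- matrix(rnorm(np * m), np, m)
  if (exponent == 0) return(white[seq_len(n), , drop = FALSE] * scale)
  xf <- mvfft(white)
  f <- c(1, seq_len(np - 1))           # DC treated like the first bin
  f <- pmin(f, np - f + 1)             # fold to two-sided frequency index
  w <- f^(-exponent / 2)
  xf <- xf * w
  x <- Re(mvfft(xf, inverse = TRUE)) / np
  x <- x[seq_len(n), , drop = FALSE]
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  x <- (x - rep(colMeans(x), each = n)) / rep(sds, each = n)
  x * scale
}

# raised-cosine gate: 0 outside [on, off] ms, cosine ramps of ramp ms inside
.cos_gate <- function(t_ms, on, off, ramp) {
  g <- numeric(length(t_ms))
  g[t_ms >= on + ramp & t_ms <= off - ramp] <- 1
  up <- t_ms >= on & t_ms < on + ramp
  g[up] <- 0.5 - 0.5 * cos(pi * (t_ms[up] - on) / ramp)
  dn <- t_ms > off - ramp & t_ms <= off
  g[dn] <- 0.5 - 0.5 * cos(pi * (off - t_ms[dn]) / ramp)
  g
}

#' Simulate one subject's epoched multichannel EEG
#'
#' Synthesises stimulus-locked epochs for the modality-congruent picture
#' trials of a schedule under the generative model of [effect_spec()]:
#' per-channel independent 1/f background noise plus amplitude-modulated
#' sinusoids with per-trial uniform random phase (induced, non-phase-locked
#' activity), spatially weighted by smooth per-band topographies. The
#' condition-dependent amplitude modulation applies within 0-2000 ms
#' post-stimulus with 100 ms cosine ramps; outside that window amplitudes
#' equal the baseline values. Deterministic given `seed`.
#'
#' @param schedule A `trial_schedule`; only rows with picture cue and
#'   picture stimulus (the analysed condition cells) receive EEG.
#' @param montage An `eeg_montage`.
#' @param effects An `effect_spec`.
#' @param srate Sampling rate in Hz.
#' @param window Epoch window in ms relative to stimulus onset; must cover
#'   the stimulus-locked baseline and 0-2000 ms.
#' @param seed Integer seed.
#' @param subject_id Subject label.
#' @return An object of class `epochs_set`: list with `data` (trials x
#'   channels x time array), `srate`, `times` (ms), `lock = "stimulus"`,
#'   `subject_id`, `schedule` (the simulated rows, with factor codes and
#'   `schedule_ref` row indices into the input schedule), and `channels`.
#' @export
simulate_subject_eeg <- function(schedule, montage, effects = effect_spec(),
                                 srate = 250, window = c(-2750, 2200),
                                 seed = 1L, subject_id = "s01") {
  validate_effect_spec(effects)
  if (window[1] > -2550 || window[2] < 2000)
    abort("epoch window must cover the stimulus-locked baseline (-2550 ms) and 0-2000 ms post-stimulus")
  keep <- which(!schedule$is_catch &
                  schedule$cue_modality == "picture" &
                  schedule$stim_modality == "picture")
  if (!length(keep)) abort("schedule contains no picture-cued picture trials")
  rows <- schedule[keep, , drop = FALSE]
  codes <- code_factors(rows$cue_intensity, rows$stim_intensity)
  cell <- condition_index(rows$cue_intensity, rows$stim_intensity)
  mods <- .cell_modulation(effects)

  dt <- 1000 / srate
  times <- seq(window[1], window[2], by = dt)
  n_t <- length(times)
  n_ch <- length(montage$channels)
  n_tr <- nrow(rows)
  bands <- effects$bands

  out <- with_seed(seed, {
    # smooth per-band topographies: baseline level + Gaussian bump at a
    # random channel position
    pos <- montage$positions
    topo <- sapply(seq_len(nrow(bands)), function(b) {
      ctr <- pos[sample.int(n_ch, 1), ]
      d2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
      0.4 + 0.6 * exp(-d2 / (2 * effects$topo_smoothness^2))
    })
    topo <- matrix(topo, nrow = n_ch)                # n_ch x 3
    freqs <- matrix(runif(n_tr * 3, -1, 1), n_tr, 3) *
      rep(bands$halfwidth, each = n_tr) + rep(bands$center, each = n_tr)
    phases <- matrix(runif(n_tr * 3, 0, 2 * pi), n_tr, 3)
    noise <- .pink_noise(n_t, n_tr * n_ch, effects$noise_exponent,
                         effects$noise_scale)
    t_s <- times / 1000
    gate <- .cos_gate(times, 0, 2000, 100)
    # band signals for all trials at once: trials x time per band
    sig <- vector("list", 3)
    for (b in 1:3) {
      m <- if (b < 3) mods$low[cell] else mods$gamma[cell]
      env <- 1 + outer(m - 1, gate)              # trials x time
      osc <- sin(outer(2 * pi * freqs[, b], t_s) + phases[, b])
      sig[[b]] <- bands$amp[b] * env * osc
    }
    # noise columns are channel-fastest: reshape to trials x time x channel
    A <- aperm(array(noise, dim = c(n_t, n_ch, n_tr)), c(3, 1, 2))
    for (ch in seq_len(n_ch))
      A[, , ch] <- A[, , ch] + topo[ch, 1] * sig[[1]] +
        topo[ch, 2] * sig[[2]] + topo[ch, 3] * sig[[3]]
    aperm(A, c(1, 3, 2))                         # trials x channels x time
  })

  rows$schedule_ref <- keep
  rows <- cbind(rows, codes)
  rows$cell <- cell
  epochs_set(out, srate = srate, times = times, lock = "stimulus",
             subject_id = subject_id, schedule = rows,
             channels = montage$channels)
}

#' Construct an epoched-EEG container
#'
#' @param data Numeric array, trials x channels x time samples.
#' @param srate Sampling rate (Hz).
#' @param times Time axis in ms relative to the lock event; strictly
#'   increasing with uniform step `1000/srate`.
#' @param lock `"cue"` or `"stimulus"`.
#' @param subject_id Subject label.
#' @param schedule Data frame of the trials' schedule rows (one per data
#'   row), including factor codes and `soa_ms`.
#' @param channels Channel names (length = dim 2 of `data`).
#' @return An object of class `epochs_set`.
#' @export
epochs_set <- function(data, srate, times, lock, subject_id, schedule,
                       channels) {
  stopifnot(length(dim(data)) == 3)
  if (length(times) != dim(data)[3])
    abort("times length must match the time dimension of data")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1000 / srate)) > 1e-6))
    abort("times must increase uniformly with step 1000/srate ms")
  if (!is.null(schedule) && nrow(schedule) != dim(data)[1])
    abort("one data row per referenced trial required")
  if (length(channels) != dim(data)[2])
    abort("channels length must match the channel dimension of data")
  structure(list(data = data, srate = srate, times = times,
                 lock = match.arg(lock, c("cue", "stimulus")),
                 subject_id = subject_id, schedule = schedule,
                 channels = channels),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs_set> %s: %d trials x %d channels x %d samples @ %g Hz, %s-locked [%g, %g] ms\n",
    x$subject_id, d[1], d[2], d[3], x$srate, x$lock,
    x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Read or write an epochs container
#'
#' Round-trips the full epochs object (data as 64-bit float, metadata
#' bit-exact) through a single-file RDS container.
#'
#' @param epochs An `epochs_set`.
#' @param path File path.
#' @return `read_epochs` returns an `epochs_set`; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(epochs, path) {
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  do.call(epochs_set, obj[c("data", "srate", "times", "lock", "subject_id",
                            "schedule", "channels")])
}

#' Simulate ordinal aversiveness ratings for a schedule
#'
#' Latent-variable ratings on the four-point scale: for every non-catch
#' trial, `u = beta0 + beta_int * INT + beta_pe * PE + Normal(0, sigma)`,
#' and the reported rating is `u` rounded and clipped to 1-4. Expectation
#' (EXP) has no effect on the latent mean, mirroring the empirical pattern
#' that ratings rise with stimulus valence and with expectation violations
#' but not with the cued valence itself.
#'
#' @param schedule A `trial_schedule`.
#' @param beta0 Latent intercept.
#' @param beta_int Latent effect per INT unit.
#' @param beta_pe Latent effect per PE unit.
#' @param sigma Latent noise SD (> 0; may be 0 for the deterministic limit).
#' @param seed Integer seed.
#' @return Data frame with columns `schedule_row`, `cue_intensity`,
#'   `stim_intensity`, `int_code`, `exp_code`, `pe_code`, `rating`.
#' @export
simulate_ratings <- function(schedule, beta0 = 2.2, beta_int = 1.2,
                             beta_pe = 0.3, sigma = 0.5, seed = 1L) {
  if (sigma < 0) abort("sigma must be >= 0")
  keep <- which(!schedule$is_catch & !is.na(schedule$stim_intensity))
  rows <- schedule[keep, , drop = FALSE]
  codes <- code_factors(rows$cue_intensity, rows$stim_intensity)
  u <- with_seed(seed,
    beta0 + beta_int * codes$int_code + beta_pe * codes$pe_code +
      rnorm(nrow(rows), 0, sigma))
  data.frame(schedule_row = keep,
             cue_intensity = rows$cue_intensity,
             stim_intensity = rows$stim_intensity,
             codes,
             # half-up rounding (round() would round 2.5 down to 2)
             rating = pmin(4, pmax(1, floor(u + 0.5))))
}

#' Subject-by-condition mean ratings
#'
#' Collapses per-trial ratings of the modality-congruent picture trials to
#' the nine cue-stimulus condition cells.
#'
#' @param ratings A ratings table from [simulate_ratings()].
#' @param schedule The schedule the ratings refer to.
#' @return Numeric vector of length 9 (condition-grid order) of cell mean
#'   ratings.
#' @export
ratings_cell_means <- function(ratings, schedule) {
  rows <- schedule[ratings$schedule_row, , drop = FALSE]
  keep <- rows$cue_modality == "picture" & rows$stim_modality == "picture"
  r <- ratings[keep, , drop = FALSE]
  cell <- condition_index(r$cue_intensity, r$stim_intensity)
  if (length(unique(cell)) < 9)
    abort("ratings do not cover all 9 condition cells")
  as.numeric(tapply(r$rating, factor(cell, levels = 1:9), mean))
}
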