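mk_ep <- function(data, srate = 250, t0 = 0) {
  d <- dim(data)
  epochs_set(data, srate = srate,
             times = t0 + (0:(d[3] - 1)) * 1000 / srate, lock = "stimulus",
             subject_id = "t", schedule = NULL,
             channels = sprintf("ch%02d", seq_len(d[2])))
}

test_that("Hanning TFR localises a pure sinusoid at its frequency", {
  srate <- 250; n <- 500
  t <- (0:(n - 1)) / srate
  x <- sin(2 * pi * 10 * t)
  tfr <- tfr_hanning(mk_ep(array(x, dim = c(1, 1, n)), srate),
                     freqs = c(10, 25))
  p10 <- tfr$power[1, 1, 1, ]
  p25 <- tfr$power[1, 1, 2, ]
  # near-unit, near-constant power at 10 Hz over interior centres
  expect_lt(diff(range(p10)) / mean(p10), 0.02)
  expect_equal(mean(p10), 1, tolerance = 0.02)
  expect_gt(mean(p10) / mean(p25), 100)
  # all-zero input -> all-zero power
  z <- tfr_hanning(mk_ep(array(0, dim = c(1, 1, n)), srate), freqs = 1:5)
  expect_equal(max(z$power), 0)
  # quadratic amplitude scaling
  tfr2 <- tfr_hanning(mk_ep(array(2 * x, dim = c(1, 1, n)), srate),
                      freqs = c(10, 25))
  expect_equal(tfr2$power, 4 * tfr$power, tolerance = 1e-12)
  # window longer than the epoch
  expect_error(tfr_hanning(mk_ep(array(x[1:50], dim = c(1, 1, 50)), srate)),
               "longer than epoch")
})

test_that("DPSS tapers are orthonormal and concentrated", {
  v <- dpss_tapers(50, 3, 5)
  expect_equal(crossprod(v), diag(5), tolerance = 1e-8)
  # leading taper concentrates energy within the half-bandwidth W = nw/n
  h <- v[, 1]
  fr <- seq(0, 0.5, by = 0.001)            # cycles/sample
  spec <- vapply(fr, function(f)
    Mod(sum(h * exp(-2i * pi * f * (0:49))))^2, 0)
  inband <- sum(spec[fr <= 3 / 50]) / sum(spec)
  expect_gt(inband, 0.99)
})

test_that("multitaper smears a sinusoid over the smoothing bandwidth only", {
  srate <- 250; n <- 500
  t <- (0:(n - 1)) / srate
  x <- sin(2 * pi * 55 * t)
  tfr <- tfr_multitaper(mk_ep(array(x, dim = c(1, 1, n)), srate),
                        freqs = seq(31, 100, 3))
  pm <- apply(tfr$power[1, 1, , , drop = FALSE], 3, mean)
  fr <- tfr$freqs
  # elevated through ~40-70 Hz, near floor at 31 Hz and beyond 80 Hz
  expect_gt(min(pm[fr >= 46 & fr <= 64]) / pm[fr == 31], 50)
  expect_gt(min(pm[fr >= 46 & fr <= 64]) / pm[fr == 97], 50)
  # all-zero input
  z <- tfr_multitaper(mk_ep(array(0, dim = c(1, 1, n)), srate),
                      freqs = c(40, 60))
  expect_equal(max(z$power), 0)
})

test_that("multitaper white-noise spectrum is flat across the high band", {
  set.seed(3)
  srate <- 250; n <- 400; ntr <- 120
  d <- array(rnorm(ntr * n), dim = c(ntr, 1, n))
  tfr <- tfr_multitaper(mk_ep(d, srate), freqs = seq(35, 95, 5))
  pm <- apply(tfr$power, 3, mean)
  expect_lt(max(abs(pm / mean(pm) - 1)), 0.1)
})

test_that("TFR power is non-negative and offset-invariant after detrending", {
  set.seed(4)
  d <- array(rnorm(4 * 2 * 400), dim = c(4, 2, 400))
  ep <- epoch_and_detrend(mk_ep(d))
  tfr <- tfr_hanning(ep, freqs = seq(5, 25, 5))
  expect_true(all(tfr$power >= 0))
  ep_off <- ep; ep_off$data <- ep$data + 100
  ep_off <- epoch_and_detrend(ep_off)
  tfr_off <- tfr_hanning(ep_off, freqs = seq(5, 25, 5))
  expect_equal(tfr_off$power, tfr$power, tolerance = 1e-8)
})

test_that("TFR is additive over orthogonal-phase components on average", {
  # linearity in expectation: power(A + B) averaged over random relative
  # phases equals power(A) + power(B)
  srate <- 250; n <- 500
  t <- (0:(n - 1)) / srate
  set.seed(5)
  ntr <- 200
  dA <- array(NA_real_, dim = c(ntr, 1, n))
  dB <- dA; dAB <- dA
  for (i in seq_len(ntr)) {
    phA <- runif(1, 0, 2 * pi); phB <- runif(1, 0, 2 * pi)
    a <- sin(2 * pi * 10 * t + phA); b <- sin(2 * pi * 17 * t + phB)
    dA[i, 1, ] <- a; dB[i, 1, ] <- b; dAB[i, 1, ] <- a + b
  }
  f <- c(10, 17)
  pA <- apply(tfr_hanning(mk_ep(dA, srate), freqs = f)$power, 3, mean)
  pB <- apply(tfr_hanning(mk_ep(dB, srate), freqs = f)$power, 3, mean)
  pAB <- apply(tfr_hanning(mk_ep(dAB, srate), freqs = f)$power, 3, mean)
  expect_equal(pAB, pA + pB, tolerance = 0.05)
})

test_that("condition averaging is a per-cell arithmetic mean", {
  sch <- build_balanced_schedule(2, seed = 6)
  m <- make_montage(2, 2)
  ep <- simulate_subject_eeg(sch, m, effect_spec(), seed = 7)
  tfr <- tfr_hanning(ep, freqs = c(10, 20),
                     center_windows = list(c(0, 500)))
  avg <- average_by_condition(tfr)
  expect_equal(avg$n_trials, rep(2L, 9))
  cell <- tfr$schedule$cell
  expect_equal(avg$power[1, , , ],
               (tfr$power[which(cell == 1)[1], , , ] +
                  tfr$power[which(cell == 1)[2], , , ]) / 2,
               tolerance = 1e-12)
  # permutation invariance over trial order
  perm <- sample(nrow(tfr$schedule))
  tfr_p <- tfr
  tfr_p$power <- tfr$power[perm, , , , drop = FALSE]
  tfr_p$schedule <- tfr$schedule[perm, ]
  expect_equal(average_by_condition(tfr_p)$power, avg$power,
               tolerance = 1e-12)
  # missing cell errors with the cell named
  tfr_m <- tfr
  keep <- tfr$schedule$cell != 5
  tfr_m$power <- tfr$power[keep, , , , drop = FALSE]
  tfr_m$schedule <- tfr$schedule[keep, ]
  expect_error(average_by_condition(tfr_m), "cell 5")
})

test_that("z-baselining matches hand arithmetic and is exact on average", {
  # baseline samples {1, 3}: mean 2, sample SD sqrt(2); point 4 -> 1.41421
  tfr <- structure(list(
    power = array(rep(c(1, 3, 4), each = 9), dim = c(9, 1, 1, 3)),
    n_trials = rep(1L, 9), freqs = 10, times = c(0, 50, 100),
    band = "low", lock = "stimulus", subject_id = "t", channels = "ch01",
    baselined = FALSE, baseline_window = NULL), class = "tfr_cond")
  z <- zbaseline(tfr, c(0, 50))
  expect_equal(z$power[1, 1, 1, 3], (4 - 2) / sqrt(2), tolerance = 1e-6)
  expect_equal(round(z$power[1, 1, 1, 3], 5), 1.41421)
  expect_true(z$baselined)
  expect_error(zbaseline(z, c(0, 50)), "already baselined")
  # zero-SD baseline names the offender
  flat <- tfr
  flat$power[] <- 5
  expect_error(zbaseline(flat, c(0, 50)), "ch01")
  # exactness on simulated data, trial-weighted across unequal cells
  sch <- build_trial_schedule(50, seed = 8)
  m <- make_montage(2, 2)
  ep <- simulate_subject_eeg(sch, m, effect_spec(), seed = 9)
  tf <- average_by_condition(tfr_hanning(ep, freqs = c(10, 20),
    center_windows = list(stimulus_baseline_window(), c(0, 300))))
  zz <- zbaseline(tf, stimulus_baseline_window())
  w <- zz$n_trials / sum(zz$n_trials)
  avg <- apply(zz$power * w, c(2, 3, 4), sum)
  sel <- which(zz$times >= -2550 & zz$times <= -2050)
  base <- avg[, , sel]
  expect_lt(max(abs(apply(base, c(1, 2), mean))), 1e-10)
  expect_lt(max(abs(apply(base, c(1, 2), sd) - 1)), 1e-10)
})

test_that("group stacking and subsetting preserve the grid", {
  sch <- build_balanced_schedule(1, seed = 10)
  m <- make_montage(2, 2)
  tfrs <- lapply(1:3, function(s) {
    ep <- simulate_subject_eeg(sch, m, effect_spec(), seed = 10 + s,
                               subject_id = sprintf("s%d", s))
    average_by_condition(tfr_hanning(ep, freqs = c(10, 20),
                                     center_windows = list(c(-200, 500))))
  })
  grp <- stack_subjects(tfrs)
  expect_equal(dim(grp$power)[1:2], c(3, 9))
  expect_equal(grp$power[2, , , , ], tfrs[[2]]$power, tolerance = 1e-12)
  sub <- subset_tfr(grp, time_window = c(0, 200), freqs = 10)
  expect_equal(sub$freqs, 10)
  expect_true(all(sub$times >= 0 & sub$times <= 200))
  # TFR container round trip
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  write_tfr(grp, path)
  expect_equal(read_tfr(path), grp)
})
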