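#' Partial out nuisance factors from nine-cell values
#'
#' For display of a factor's main effect, the other two predictors are
#' removed: per subject, the cell values are regressed by OLS on the two
#' non-target factor code vectors (plus intercept) and the residuals are
#' returned with the subject's grand mean added back.
#'
#' @param values Subjects x 9 matrix of cell values.
#' @param target_factor The factor to keep (`"INT"`, `"EXP"` or `"PE"`).
#' @return Subjects x 9 matrix of adjusted values.
#' @export
partial_out <- function(values, target_factor = c("INT", "EXP", "PE")) {
  target_factor <- match.arg(target_factor)
  values <- as.matrix(values)
  if (ncol(values) != 9) abort("values must be subjects x 9")
  g <- build_condition_grid()
  nuisance <- setdiff(c("INT", "EXP", "PE"), target_factor)
  cols <- list(INT = g$int_code, EXP = g$exp_code, PE = g$pe_code)
  X <- cbind(1, cols[[nuisance[1]]], cols[[nuisance[2]]])
  H <- X %*% solve(crossprod(X), t(X))             # 9 x 9 hat matrix
  resid <- values - values %*% t(H)
  resid + rowMeans(values)
}

#' Pipeline run configuration
#'
#' Bundles all stage parameters of the simulate - preprocess - TFR -
#' statistics pipeline with defaults at the desk scale: 12 subjects, a 4 x 4
#' grid montage (16 channels), 250 Hz, the probabilistic schedule with 50
#' trials per cue, low band 1-30 Hz (300 ms Hanning window), high band
#' 31-100 Hz (200 ms multitaper window, 15 Hz smoothing), 50 ms steps,
#' cue-locked baseline (-650, -150) ms and the derived stimulus-locked
#' baseline (-2550, -2050) ms, and 1000 permutations at alpha 0.05.
#'
#' @param n_subjects Number of simulated subjects.
#' @param design List: `n_per_cue`, `n_blocks`, `catch_per_block`, `seed`.
#' @param synth List: `montage_rows`, `montage_cols`, `srate`, `window`
#'   (epoch window, ms), `effects` (arguments to [effect_spec()]), `ratings`
#'   (arguments to [simulate_ratings()] minus schedule/seed), `seed`.
#' @param spectral List: `low_freqs`, `high_freqs`, `low_window_ms`,
#'   `high_window_ms`, `step_ms`, `smoothing_hz`, `baseline_cue`,
#'   `baseline_stimulus`.
#' @param stats List: `alpha`, `cluster_alpha`, `n_perm`, `tail`, `add_one`,
#'   `seed`, `test_window_stimulus`, `test_window_cue`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(n_subjects = 12,
                       design = list(), synth = list(), spectral = list(),
                       stats = list()) {
  cfg <- list(
    n_subjects = n_subjects,
    design = utils::modifyList(
      list(n_per_cue = 50, n_blocks = 4, catch_per_block = 4, seed = 11),
      design),
    synth = utils::modifyList(
      list(montage_rows = 4, montage_cols = 4, srate = 250,
           window = c(-2750, 2200), effects = list(),
           ratings = list(beta0 = 2.2, beta_int = 1.2, beta_pe = 0.3,
                          sigma = 0.5),
           seed = 21),
      synth),
    spectral = utils::modifyList(
      list(low_freqs = 1:30, high_freqs = 31:100,
           low_window_ms = 300, high_window_ms = 200, step_ms = 50,
           smoothing_hz = 15,
           baseline_cue = cue_baseline_window(),
           baseline_stimulus = stimulus_baseline_window()),
      spectral),
    stats = utils::modifyList(
      list(alpha = 0.05, cluster_alpha = 0.05, n_perm = 1000,
           tail = "two-sided", add_one = FALSE, seed = 31,
           test_window_stimulus = c(0, 2000), test_window_cue = c(0, 1500)),
      stats))
  lo <- cfg$spectral$low_freqs; hi <- cfg$spectral$high_freqs
  if (min(lo) < 1 || max(lo) > 30) abort("low band must lie within 1-30 Hz")
  if (min(hi) < 31 || max(hi) > 100)
    abort("high band must lie within 31-100 Hz")
  class(cfg) <- "run_config"
  cfg
}

#' Read or write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  run_config(n_subjects = obj$n_subjects, design = obj$design,
             synth = obj$synth, spectral = obj$spectral, stats = obj$stats)
}

# simulate and preprocess one subject; returns list of z-baselined tfr_cond
# per band and lock requested
.subject_tfrs <- function(schedule, montage, cfg, seed, subject_id,
                          locks = c("stimulus", "cue")) {
  sp <- cfg$spectral
  effects <- do.call(effect_spec, cfg$synth$effects)
  ep <- simulate_subject_eeg(schedule, montage, effects,
                             srate = cfg$synth$srate,
                             window = cfg$synth$window,
                             seed = seed, subject_id = subject_id)
  ep <- epoch_and_detrend(ep)
  ep <- bandpass(ep, 1, 100)
  ep <- rereference_common_average(ep)
  out <- list()
  for (lk in locks) {
    epl <- timelock(ep, lk)
    bw <- if (lk == "stimulus") sp$baseline_stimulus else sp$baseline_cue
    tw <- if (lk == "stimulus") cfg$stats$test_window_stimulus
          else cfg$stats$test_window_cue
    cw <- list(bw, tw)      # only baseline and test-window centres needed
    low <- tfr_hanning(epl, freqs = sp$low_freqs,
                       window_ms = sp$low_window_ms, step_ms = sp$step_ms,
                       center_windows = cw)
    high <- tfr_multitaper(epl, freqs = sp$high_freqs,
                           window_ms = sp$high_window_ms,
                           step_ms = sp$step_ms,
                           smoothing_hz = sp$smoothing_hz,
                           center_windows = cw)
    out[[paste0(lk, ".low")]] <- zbaseline(average_by_condition(low), bw)
    out[[paste0(lk, ".high")]] <- zbaseline(average_by_condition(high), bw)
  }
  out
}

#' Run the full simulation and analysis pipeline
#'
#' Simulates `n_subjects` subjects' EEG and ratings from per-subject
#' probabilistic schedules, preprocesses (centre/detrend, 1-100 Hz
#' zero-phase Butterworth, common-average reference), computes z-baselined
#' low-band (Hanning) and high-band (multitaper) TFRs for stimulus-locked
#' and cue-locked data, and runs the cluster permutation tests of the
#' factorial test matrix: stimulus-locked data tested for INT, EXP and PE in
#' both bands (6 analyses), cue-locked data tested for EXP in both bands (2
#' analyses). Behavioural ratings are tested with the linear-trend ANOVA per
#' factor. Fully reproducible from the three stage seeds in the config.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, cluster results (JSON),
#'   the schedules and ratings (CSV) and the montage (JSON) are written
#'   there.
#' @param verbose Print stage progress.
#' @return An object of class `pc_report`: list with `eeg_tests` (named list
#'   `factor.band.lock` of `cluster_test` objects), `posthoc` (post-hoc
#'   tables for significant clusters), `ratings` (a `ratings_anova`),
#'   `config`, `montage`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  cfg <- config
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  montage <- make_montage(cfg$synth$montage_rows, cfg$synth$montage_cols)
  n <- cfg$n_subjects

  say("stage design+synth+spectral: %d subjects", n)
  tfrs <- vector("list", n)
  cellmeans_ratings <- matrix(NA_real_, n, 9)
  schedules <- vector("list", n)
  for (s in seq_len(n)) {
    sch <- build_trial_schedule(cfg$design$n_per_cue, cfg$design$n_blocks,
                                cfg$design$catch_per_block,
                                seed = cfg$design$seed + s)
    schedules[[s]] <- sch
    tfrs[[s]] <- .subject_tfrs(sch, montage, cfg, seed = cfg$synth$seed + s,
                               subject_id = sprintf("s%02d", s))
    rat <- do.call(simulate_ratings,
                   c(list(schedule = sch), cfg$synth$ratings,
                     list(seed = cfg$synth$seed + 10000 + s)))
    cellmeans_ratings[s, ] <- ratings_cell_means(rat, sch)
    if (!is.null(out_dir) && s == 1) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_schedule(sch, file.path(out_dir, "schedule_s01.csv"))
      utils::write.csv(rat, file.path(out_dir, "ratings_s01.csv"),
                       row.names = FALSE)
    }
  }

  say("stage clusterstats: permutation tests")
  analyses <- rbind(
    expand.grid(factor = c("INT", "EXP", "PE"), band = c("low", "high"),
                lock = "stimulus", stringsAsFactors = FALSE),
    expand.grid(factor = "EXP", band = c("low", "high"), lock = "cue",
                stringsAsFactors = FALSE))
  eeg_tests <- list()
  posthoc <- list()
  for (i in seq_len(nrow(analyses))) {
    an <- analyses[i, ]
    key <- paste(an$factor, an$band, an$lock, sep = ".")
    grp <- stack_subjects(lapply(tfrs, `[[`, paste0(an$lock, ".", an$band)))
    tw <- if (an$lock == "stimulus") cfg$stats$test_window_stimulus
          else cfg$stats$test_window_cue
    grp <- subset_tfr(grp, time_window = tw)
    tst <- permutation_test(grp$power, an$factor, montage,
                            n_perm = cfg$stats$n_perm,
                            alpha = cfg$stats$alpha,
                            seed = cfg$stats$seed + i,
                            cluster_alpha = cfg$stats$cluster_alpha,
                            tail = cfg$stats$tail,
                            add_one = cfg$stats$add_one,
                            freqs = grp$freqs, times = grp$times)
    eeg_tests[[key]] <- tst
    for (j in seq_along(tst$clusters)) {
      if (tst$clusters[[j]]$significant) {
        posthoc[[paste0(key, ".cluster", j)]] <-
          posthoc_pairwise(tst$clusters[[j]], grp$power, an$factor)
      }
    }
    say("  %s: %d cluster(s), %d significant", key, length(tst$clusters),
        sum(vapply(tst$clusters, function(x) x$significant, TRUE)))
  }

  ratings <- ratings_tests(cellmeans_ratings, alpha = cfg$stats$alpha)

  rep <- structure(list(eeg_tests = eeg_tests, posthoc = posthoc,
                        ratings = ratings, ratings_cells = cellmeans_ratings,
                        config = cfg, montage = montage),
                   class = "pc_report")
  if (!is.null(out_dir)) {
    write_montage(montage, file.path(out_dir, "montage.json"))
    write_report_json(rep, file.path(out_dir, "clusters.json"))
  }
  rep
}

#' Serialise a pipeline report's cluster results as JSON
#'
#' Writes, per analysis, the factor, band, lock, threshold, permutation
#' count, seed and per-cluster summaries (sign, value, p, member count,
#' channel list, frequency and time extent).
#'
#' @param report A `pc_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list()
  for (key in names(report$eeg_tests)) {
    tst <- report$eeg_tests[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out[[key]] <- list(
      factor = parts[1], band = parts[2], lock = parts[3],
      threshold = tst$threshold, n_perm = tst$n_perm, seed = tst$seed,
      tail = tst$tail,
      clusters = lapply(tst$clusters, function(cl) list(
        sign = cl$sign, value = cl$value, p = cl$p,
        n_members = cl$n_members,
        channels = sort(unique(tst$channels[cl$members[, 1]])),
        freq_range = range(tst$freqs[cl$members[, 2]]),
        time_range = range(tst$times[cl$members[, 3]]))))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.pc_report <- function(x, ...) {
  cat(sprintf("<pc_report> %d subjects, %d cluster analyses\n",
              x$config$n_subjects, length(x$eeg_tests)))
  for (key in names(x$eeg_tests)) {
    tst <- x$eeg_tests[[key]]
    sig <- vapply(tst$clusters, function(cl) cl$significant, TRUE)
    cat(sprintf("  %-18s %d cluster(s), %d significant\n", key,
                length(tst$clusters), sum(sig)))
  }
  cat("ratings: ")
  for (f in names(x$ratings$factors))
    cat(sprintf("%s p=%.3g%s  ", f, x$ratings$factors[[f]]$p,
                if (x$ratings$factors[[f]]$significant) "*" else ""))
  cat("\n")
  invisible(x)
}

#' Plot the channel-averaged F map of a cluster test
#'
#' Time-frequency image of the per-sample F statistic averaged over
#' channels, with samples belonging to significant clusters outlined by
#' dots.
#'
#' @param x A `cluster_test` with `freqs` and `times` metadata.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.cluster_test <- function(x, ...) {
  if (is.null(x$freqs) || is.null(x$times))
    abort("cluster test has no freqs/times metadata to plot")
  fm <- apply(x$F_map, c(2, 3), mean)
  graphics::image(x$times, x$freqs, t(fm), xlab = "time (ms)",
                  ylab = "frequency (Hz)",
                  main = sprintf("factor %s: channel-mean F", x$factor),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  for (cl in x$clusters) {
    if (!cl$significant) next
    pts <- unique(cl$members[, 2:3, drop = FALSE])
    graphics::points(x$times[pts[, 2]], x$freqs[pts[, 1]], pch = 16,
                     cex = 0.4)
  }
  invisible(x)
}
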