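#' @importFrom stats runif
NULL

# canonical factor levels of the 2 (modality) x 3 (intensity) cue set
.levels <- c("low", "medium", "high")
.modalities <- c("picture", "pain")

#' Intensity levels and modalities of the cue-stimulus design
#'
#' The design crosses two stimulus modalities (affective picture, pain) with
#' three intensity/valence levels. Cues indicate modality with 70% validity
#' and intensity with 60% validity.
#'
#' @return Character vector of levels (`intensity_levels()`) or modalities
#'   (`modalities()`).
#' @export
intensity_levels <- function() .levels

#' @rdname intensity_levels
#' @export
modalities <- function() .modalities

.level_code <- function(level) {
  i <- match(level, .levels)
  if (anyNA(i))
    abort("unknown intensity level(s): %s (expected one of %s)",
          paste(unique(level[is.na(i)]), collapse = ", "),
          paste(.levels, collapse = ", "))
  i - 2L
}

#' Predictive-coding factor codes for a cue-stimulus pair
#'
#' Maps cue and stimulus intensity levels onto the three within-subject
#' factors of the predictive-coding model: stimulus intensity
#' (INT: -1/0/1 for low/medium/high), expectation (EXP: the same linear code
#' of the cued intensity), and absolute prediction error
#' (PE = |EXP - INT|, taking values 0, 1, 2).
#'
#' @param cue_intensity,stim_intensity Character vectors of levels
#'   (`"low"`, `"medium"`, `"high"`); recycled to common length.
#' @return A data frame with columns `int_code`, `exp_code`, `pe_code`.
#' @examples
#' code_factors("low", "low")     # INT -1, EXP -1, PE 0
#' code_factors("high", "low")    # INT -1, EXP  1, PE 2
#' @export
code_factors <- function(cue_intensity, stim_intensity) {
  ec <- .level_code(cue_intensity)
  ic <- .level_code(stim_intensity)
  n <- max(length(ec), length(ic))
  ec <- rep_len(ec, n); ic <- rep_len(ic, n)
  data.frame(int_code = ic, exp_code = ec, pe_code = abs(ec - ic))
}

#' The 3 x 3 cue-stimulus condition grid
#'
#' Enumerates all nine cue-intensity by stimulus-intensity conditions of the
#' modality-congruent (picture-cued picture) design, in stimulus-major order
#' (stimulus intensity varies slowest, low to high; cue intensity low to
#' high within).
#'
#' @return A 9-row data frame with columns `stim_intensity`, `cue_intensity`,
#'   `int_code`, `exp_code`, `pe_code`.
#' @examples
#' g <- build_condition_grid()
#' table(g$pe_code)               # 3 cells PE=0, 4 cells PE=1, 2 cells PE=2
#' sum(g$int_code * g$pe_code)    # 0: PE orthogonal to INT
#' @export
build_condition_grid <- function() {
  stim <- rep(.levels, each = 3)
  cue <- rep(.levels, times = 3)
  cbind(data.frame(stim_intensity = stim, cue_intensity = cue),
        code_factors(cue, stim))
}

#' Index of a cue-stimulus pair into the condition grid
#'
#' @param cue_intensity,stim_intensity Level vectors.
#' @return Integer vector of row indices into [build_condition_grid()].
#' @export
condition_index <- function(cue_intensity, stim_intensity) {
  si <- match(stim_intensity, .levels)
  ci <- match(cue_intensity, .levels)
  if (anyNA(si) || anyNA(ci)) abort("unknown intensity level")
  (si - 1L) * 3L + ci
}

# per-cue joint probabilities of the (stim modality, stim intensity) outcome
# under the independence factorization of the 70% modality / 60% intensity
# contingencies, with incorrect-intensity mass split equally
.cue_outcome_probs <- function() {
  p_mod <- c(congruent = 0.70, incongruent = 0.30)
  p_int <- c(correct = 0.60, wrong = 0.20) # each of the two wrong levels
  list(p_mod = p_mod, p_int = p_int)
}

#' Build a probabilistic cue-stimulus trial schedule
#'
#' Generates the trial list of the probabilistic cueing design: six cue types
#' (2 modalities x 3 intensities) each presented `n_per_cue` times. Per cue,
#' the stimulus modality matches the cued modality in exactly 70% of trials
#' and the stimulus intensity matches the cued digit in exactly 60%, with the
#' remaining 40% split equally between the two incorrect levels (modality and
#' intensity congruence independent). Trial order is pseudorandomised by a
#' uniform seeded shuffle; catch trials (cue only, no stimulus) are appended
#' per block. Each non-catch trial gets a cue-to-stimulus onset asynchrony
#' `soa_ms` drawn uniformly from 1500-1900 ms (500 ms cue plus a 1000-1400 ms
#' blank).
#'
#' All per-cue joint counts (0.42, 0.14, 0.14, 0.18, 0.06, 0.06 times
#' `n_per_cue` per intensity outcome) must be whole numbers, which requires
#' `n_per_cue` to be a multiple of 50; otherwise an error names the first
#' offending cell.
#'
#' @param n_per_cue Trials per cue type (multiple of 50).
#' @param n_blocks Number of blocks the trials are split into.
#' @param catch_per_block Catch trials appended to each block.
#' @param seed Integer seed for the shuffle and the SOA jitter.
#' @return A data frame of class `trial_schedule` with columns `block`,
#'   `trial_index`, `cue_modality`, `cue_intensity`, `stim_modality`,
#'   `stim_intensity`, `is_catch`, `soa_ms`. Catch trials have `NA` stimulus
#'   fields and `NA` `soa_ms`.
#' @examples
#' sch <- build_trial_schedule(50, seed = 1)
#' schedule_summary(sch)$modality_congruent   # exactly 0.70
#' @export
build_trial_schedule <- function(n_per_cue, n_blocks = 4L,
                                 catch_per_block = 4L, seed = 1L) {
  if (!is.numeric(n_per_cue) || length(n_per_cue) != 1 || n_per_cue < 1)
    abort("n_per_cue must be a positive integer")
  pr <- .cue_outcome_probs()
  # joint per-cue probabilities over (modality outcome, intensity outcome)
  cell_p <- c(outer(c(pr$p_int["correct"], pr$p_int["wrong"], pr$p_int["wrong"]),
                    pr$p_mod))
  names(cell_p) <- c("congruent-modality/correct-intensity",
                     "congruent-modality/wrong-intensity-a",
                     "congruent-modality/wrong-intensity-b",
                     "incongruent-modality/correct-intensity",
                     "incongruent-modality/wrong-intensity-a",
                     "incongruent-modality/wrong-intensity-b")
  counts <- cell_p * n_per_cue
  bad <- which(abs(counts - round(counts)) > 1e-9)
  if (length(bad))
    abort(paste0("n_per_cue = %s gives a non-integral trial count for cell ",
                 "'%s' (%.4g * %s = %.4g); use a multiple of 50"),
          n_per_cue, names(cell_p)[bad[1]], cell_p[bad[1]], n_per_cue,
          counts[bad[1]])
  counts <- round(counts)

  rows <- list()
  for (cm in .modalities) {
    other_m <- setdiff(.modalities, cm)
    for (ci in .levels) {
      wrong <- setdiff(.levels, ci)
      sm <- rep(c(cm, cm, cm, other_m, other_m, other_m),
                times = counts)
      si <- rep(c(ci, wrong[1], wrong[2], ci, wrong[1], wrong[2]),
                times = counts)
      rows[[length(rows) + 1L]] <-
        data.frame(cue_modality = cm, cue_intensity = ci,
                   stim_modality = sm, stim_intensity = si,
                   is_catch = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  n <- nrow(trials)

  sch <- with_seed(seed, {
    trials <- trials[sample.int(n), , drop = FALSE]
    trials$soa_ms <- round(runif(n, 1500, 1900))
    # split into blocks as evenly as possible, then append catch trials
    sizes <- rep(n %/% n_blocks, n_blocks)
    if (n %% n_blocks) sizes[seq_len(n %% n_blocks)] <-
        sizes[seq_len(n %% n_blocks)] + 1L
    blocks <- vector("list", n_blocks)
    at <- 0L
    for (b in seq_len(n_blocks)) {
      blk <- trials[at + seq_len(sizes[b]), , drop = FALSE]
      at <- at + sizes[b]
      if (catch_per_block > 0) {
        k <- sample.int(6L, catch_per_block, replace = TRUE)
        catch <- data.frame(
          cue_modality = .modalities[(k - 1L) %/% 3L + 1L],
          cue_intensity = .levels[(k - 1L) %% 3L + 1L],
          stim_modality = NA_character_, stim_intensity = NA_character_,
          is_catch = TRUE, soa_ms = NA_real_)
        blk <- rbind(blk, catch)
      }
      blk$block <- b
      blk$trial_index <- seq_len(nrow(blk))
      blocks[[b]] <- blk
    }
    do.call(rbind, blocks)
  })
  sch <- sch[, c("block", "trial_index", "cue_modality", "cue_intensity",
                 "stim_modality", "stim_intensity", "is_catch", "soa_ms")]
  rownames(sch) <- NULL
  class(sch) <- c("trial_schedule", "data.frame")
  sch
}

#' Build a balanced picture-only schedule for simulation studies
#'
#' A design with exactly `n_per_cell` trials in each of the nine
#' modality-congruent picture conditions, without the 70/60 probabilistic
#' contingencies. The probabilistic design necessarily yields unequal cell
#' counts (intensity-congruent cells receive three times the mass of each
#' incongruent cell), so simulation studies of the inference machinery use
#' this balanced variant.
#'
#' @param n_per_cell Trials per condition cell.
#' @param seed Integer seed for trial order and SOA jitter.
#' @return A `trial_schedule` data frame (single block, no catch trials).
#' @export
build_balanced_schedule <- function(n_per_cell, seed = 1L) {
  g <- build_condition_grid()
  trials <- data.frame(
    cue_modality = "picture",
    cue_intensity = rep(g$cue_intensity, each = n_per_cell),
    stim_modality = "picture",
    stim_intensity = rep(g$stim_intensity, each = n_per_cell),
    is_catch = FALSE)
  n <- nrow(trials)
  sch <- with_seed(seed, {
    trials <- trials[sample.int(n), , drop = FALSE]
    trials$soa_ms <- round(runif(n, 1500, 1900))
    trials
  })
  sch$block <- 1L
  sch$trial_index <- seq_len(n)
  sch <- sch[, c("block", "trial_index", "cue_modality", "cue_intensity",
                 "stim_modality", "stim_intensity", "is_catch", "soa_ms")]
  rownames(sch) <- NULL
  class(sch) <- c("trial_schedule", "data.frame")
  sch
}

#' Realized contingencies of a trial schedule
#'
#' Joint and marginal proportions over the non-catch trials of a schedule.
#'
#' @param schedule A `trial_schedule`.
#' @return A list with `joint` (proportion table over cue modality x cue
#'   intensity x stimulus modality x stimulus intensity, summing to 1),
#'   `modality_congruent` and `intensity_congruent` marginal proportions,
#'   and `n_trials`.
#' @export
schedule_summary <- function(schedule) {
  s <- schedule[!schedule$is_catch, , drop = FALSE]
  if (nrow(s) == 0) abort("schedule has no non-catch trials")
  joint <- table(cue_modality = s$cue_modality,
                 cue_intensity = s$cue_intensity,
                 stim_modality = s$stim_modality,
                 stim_intensity = s$stim_intensity) / nrow(s)
  list(joint = joint,
       modality_congruent = mean(s$cue_modality == s$stim_modality),
       intensity_congruent = mean(s$cue_intensity == s$stim_intensity),
       n_trials = nrow(s))
}

#' Read or write a trial schedule as CSV
#'
#' @param schedule A `trial_schedule`.
#' @param path File path.
#' @return `read_schedule` returns a `trial_schedule`; `write_schedule`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sch <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "trial_index", "cue_modality", "cue_intensity",
            "stim_modality", "stim_intensity", "is_catch")
  miss <- setdiff(need, names(sch))
  if (length(miss)) abort("schedule CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  class(sch) <- c("trial_schedule", "data.frame")
  sch
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d trials (%d catch) in %d block(s)\n",
              nrow(x), sum(x$is_catch), length(unique(x$block))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
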