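# shared fixtures and independent oracles for the suite

# brute-force spatial-neighbour prefilter: literal per-sample rule
brute_spatial_filter <- function(mask, montage) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (c1 in seq_len(d[1])) for (f in seq_len(d[2])) for (t in seq_len(d[3])) {
    if (!mask[c1, f, t]) next
    nb <- match(montage$neighbors[[montage$channels[c1]]], montage$channels)
    out[c1, f, t] <- length(nb) > 0 && any(mask[nb, f, t])
  }
  out
}

# brute-force connected components by stack-based flood fill over the
# orthogonal adjacency (c,f+-1,t), (c,f,t+-1), (neighbour(c),f,t)
brute_components <- function(mask, montage) {
  d <- dim(mask)
  nb_idx <- lapply(montage$channels,
                   function(ch) match(montage$neighbors[[ch]],
                                      montage$channels))
  seen <- array(FALSE, d)
  comps <- list()
  idx_all <- which(mask)
  for (start in idx_all) {
    if (seen[start]) next
    stack <- start
    members <- integer(0)
    seen[start] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      co <- arrayInd(cur, d)
      cands <- list()
      if (co[2] > 1) cands <- c(cands, list(c(co[1], co[2] - 1, co[3])))
      if (co[2] < d[2]) cands <- c(cands, list(c(co[1], co[2] + 1, co[3])))
      if (co[3] > 1) cands <- c(cands, list(c(co[1], co[2], co[3] - 1)))
      if (co[3] < d[3]) cands <- c(cands, list(c(co[1], co[2], co[3] + 1)))
      for (cn in nb_idx[[co[1]]]) cands <- c(cands, list(c(cn, co[2], co[3])))
      for (cand in cands) {
        li <- cand[1] + (cand[2] - 1) * d[1] + (cand[3] - 1) * d[1] * d[2]
        if (mask[li] && !seen[li]) { seen[li] <- TRUE; stack <- c(stack, li) }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# canonicalise a component list for comparison
canon_comps <- function(comps) {
  comps <- lapply(comps, function(x) as.integer(sort(x)))
  comps[order(vapply(comps, `[`, 0L, 1))]
}

# fraction of the injected (freq x time) extent covered by the union of
# significant same-sign clusters of a cluster_test
injected_overlap <- function(tst, sgn, freq_bands, time_window = c(0, 2000)) {
  fr <- tst$freqs; tm <- tst$times
  infr <- Reduce(`|`, lapply(freq_bands, function(b) fr >= b[1] & fr <= b[2]))
  inj <- outer(infr, tm >= time_window[1] & tm <= time_window[2])
  cov <- matrix(FALSE, length(fr), length(tm))
  for (cl in tst$clusters) if (cl$significant && cl$sign == sgn)
    cov[cbind(cl$members[, 2], cl$members[, 3])] <- TRUE
  sum(cov & inj) / sum(inj)
}

# one subject's z-baselined stimulus-locked low-band condition TFR from a
# balanced schedule (desk-scale defaults unless overridden)
sim_subject_lowband <- function(seed, n_per_cell = 27, montage = NULL,
                                effects = effect_spec(),
                                freqs = seq(2, 30, 2), preprocess = TRUE) {
  if (is.null(montage)) montage <- make_montage(4, 4)
  sch <- build_balanced_schedule(n_per_cell, seed = seed)
  ep <- simulate_subject_eeg(sch, montage, effects, seed = seed + 7,
                             subject_id = sprintf("s%03d", seed))
  if (preprocess)
    ep <- rereference_common_average(bandpass(epoch_and_detrend(ep), 1, 100))
  cw <- list(stimulus_baseline_window(), c(0, 2000))
  zbaseline(average_by_condition(
    tfr_hanning(ep, freqs = freqs, center_windows = cw)),
    stimulus_baseline_window())
}

# null effect spec: all modulation gains zero
null_effects <- function() effect_spec(g_int = 0, g_exp = 0,
                                       g_pe_low = 0, g_pe_gamma = 0)
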