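test_that("factor level means collapse the grid as prescribed", {
  g <- build_condition_grid()
  # all cells equal -> all level means equal
  const <- matrix(3.5, 2, 9)
  for (f in c("INT", "EXP", "PE"))
    expect_equal(unname(factor_level_means(const, f)),
                 matrix(3.5, 2, 3), ignore_attr = TRUE)
  # cells valued by their own codes recover the codes
  expect_equal(unname(factor_level_means(rbind(g$pe_code), "PE")[1, ]),
               c(0, 1, 2))
  expect_equal(unname(factor_level_means(rbind(g$int_code), "INT")[1, ]),
               c(-1, 0, 1))
  expect_equal(unname(factor_level_means(rbind(g$exp_code), "EXP")[1, ]),
               c(-1, 0, 1))
  # PE levels pool 3/4/2 cells
  fl <- factor_levels("PE")
  expect_equal(lengths(fl$cells), c(3, 4, 2))
  expect_error(factor_level_means(matrix(c(NA, 1:8), 1, 9), "INT"),
               "missing")
})

test_that("linear-trend F equals the hand-worked two-subject example", {
  res <- linear_trend_F(rbind(c(0, 1, 2), c(0, 2, 4)), c(-1, 0, 1))
  expect_equal(res$slopes, c(1, 2))
  expect_equal(res$F, 9)
  expect_equal(res$df, c(1, 1))
  # symmetric means give zero slope for that subject, F still defined
  res2 <- linear_trend_F(rbind(c(1, 2, 1), c(0, 1, 2)), c(-1, 0, 1))
  expect_equal(res2$slopes, c(0, 1))
  expect_equal(res2$F, (0.5 / (sqrt(0.5) / sqrt(2)))^2)
  expect_error(linear_trend_F(rbind(c(0, 1, 2)), c(-1, 0, 1)),
               "at least 2")
  expect_error(linear_trend_F(rbind(c(0, 1, 2), c(0, 2, 4)), c(1, 1, 1)),
               "not all be equal")
  expect_error(linear_trend_F(rbind(c(0, 1, 2), c(1, 2, 3)), c(-1, 0, 1)),
               "degenerate")
})

test_that("linear-trend F is invariant to affine recoding of the levels", {
  set.seed(11)
  lm_ <- matrix(rnorm(8 * 3), 8, 3)
  base <- linear_trend_F(lm_, c(-1, 0, 1))
  for (ab in list(c(2, 0), c(-1, 5), c(0.1, -3))) {
    res <- linear_trend_F(lm_, ab[1] * c(-1, 0, 1) + ab[2])
    expect_equal(res$F, base$F, tolerance = 1e-10)
  }
})

test_that("linear-trend F matches an independent per-subject regression oracle", {
  set.seed(12)
  for (rep_ in 1:20) {
    n <- 8
    lm_ <- matrix(rnorm(n * 3), n, 3)
    codes <- c(-1, 0, 1)
    ours <- linear_trend_F(lm_, codes)
    slopes <- vapply(seq_len(n), function(s)
      unname(coef(lm(lm_[s, ] ~ codes))[2]), 0)
    tt <- t.test(slopes)
    expect_equal(ours$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(ours$p, tt$p.value, tolerance = 1e-8)
  }
})

test_that("critical F values match the distributional references", {
  expect_equal(round(f_critical(1, 28, 0.05), 3), 4.196)
  # normal limit: square of the upper 0.975 normal quantile
  expect_equal(f_critical(1, 1e6, 0.05), qnorm(0.975)^2, tolerance = 1e-3)
  # median check by direct CDF integration
  fc <- f_critical(1, 28, 0.5)
  cdf <- integrate(function(x) df(x, 1, 28), 0, fc)$value
  expect_equal(cdf, 0.5, tolerance = 1e-6)
  expect_error(f_critical(0, 28, 0.05), "degrees of freedom")
  expect_error(f_critical(1, 28, 1.2), "alpha")
})

test_that("spatial neighbour rule keeps only spatially supported samples", {
  m <- make_montage(2, 2)
  mask <- array(FALSE, dim = c(4, 3, 3))
  # lone supra-threshold sample is removed
  mask[1, 2, 2] <- TRUE
  expect_false(any(spatial_neighbor_filter(mask, m)))
  # two neighbouring channels at the same (f, t) are both retained
  mask[2, 2, 2] <- TRUE    # ch02 neighbours ch01 in a 2x2 grid
  out <- spatial_neighbor_filter(mask, m)
  expect_true(out[1, 2, 2] && out[2, 2, 2])
  expect_equal(sum(out), 2)
  # channel with an empty neighbour set loses everything
  m1 <- make_montage(1, 1)
  mask1 <- array(TRUE, dim = c(1, 3, 3))
  expect_false(any(spatial_neighbor_filter(mask1, m1)))
})

test_that("spatial filter agrees with the literal per-sample rule", {
  set.seed(13)
  m <- make_montage(2, 3)
  for (rep_ in 1:20) {
    mask <- array(runif(6 * 5 * 7) < 0.4, dim = c(6, 5, 7))
    expect_identical(spatial_neighbor_filter(mask, m),
                     brute_spatial_filter(mask, m))
  }
})

test_that("cluster formation matches the worked example and the sign rule", {
  m <- make_montage(2, 2)
  F_map <- array(0, dim = c(4, 3, 3))
  slope <- array(1, dim = c(4, 3, 3))
  # channels 1 and 2 (neighbours), freqs 1-2, times 1-2, all F = 5
  F_map[1:2, 1:2, 1:2] <- 5
  cl <- form_clusters(F_map, slope, 4.196, m)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$value, 40)
  expect_equal(cl[[1]]$n_members, 8)
  expect_equal(cl[[1]]$sign, "positive")
  # slopes split by sign across the two channels: each sign's mask has a
  # single channel, which fails the neighbour rule -> no clusters
  slope2 <- slope
  slope2[2, , ] <- -1
  expect_length(form_clusters(F_map, slope2, 4.196, m), 0)
  # threshold is strict: F exactly at threshold is excluded
  expect_length(form_clusters(F_map, slope, 5, m), 0)
})

test_that("raising the threshold never grows clusters", {
  set.seed(14)
  m <- make_montage(2, 3)
  F_map <- array(rexp(6 * 8 * 8, 1 / 3), dim = c(6, 8, 8))
  slope <- array(rnorm(6 * 8 * 8), dim = c(6, 8, 8))
  sizes <- function(thr) {
    cl <- form_clusters(F_map, slope, thr, m)
    sum(vapply(cl, function(x) x$n_members, 0L))
  }
  s <- vapply(c(2, 4, 6, 8), sizes, 0L)
  expect_true(all(diff(s) <= 0))
})

test_that("cluster formation equals brute-force flood fill on random maps", {
  set.seed(15)
  m <- make_montage(2, 3)
  for (rep_ in 1:40) {
    F_map <- array(rexp(6 * 8 * 10, 1 / 4), dim = c(6, 8, 10))
    slope <- array(rnorm(6 * 8 * 10), dim = c(6, 8, 10))
    thr <- 4.196
    cl <- form_clusters(F_map, slope, thr, m)
    ours <- canon_comps(lapply(cl, function(x)
      x$members[, 1] + (x$members[, 2] - 1) * 6 + (x$members[, 3] - 1) * 48))
    ref <- list()
    for (sgn in c(1, -1)) {
      mask <- (F_map > thr) & (sign(slope) == sgn)
      mask <- brute_spatial_filter(mask, m)
      ref <- c(ref, brute_components(mask, m))
    }
    expect_identical(ours, canon_comps(ref))
    # cluster values recompute from members
    for (x in cl)
      expect_equal(x$value, sum(F_map[x$members]), tolerance = 1e-12)
  }
})

test_that("permutation test finds injected effects and respects definitions", {
  set.seed(16)
  m <- make_montage(2, 2)
  g <- build_condition_grid()
  n <- 10
  # strong INT effect on all channels of a small grid + noise
  mkdata <- function(effect) {
    arr <- array(rnorm(n * 9 * 4 * 3 * 4, sd = 0.3),
                 dim = c(n, 9, 4, 3, 4))
    for (cell in 1:9) arr[, cell, , , ] <- arr[, cell, , , ] +
        effect * g$int_code[cell]
    arr
  }
  arr <- mkdata(2)
  tst <- permutation_test(arr, "INT", m, n_perm = 100, seed = 17)
  expect_true(length(tst$clusters) >= 1)
  top <- tst$clusters[[1]]
  expect_equal(top$sign, "positive")
  # observed effect exceeds every permutation maximum -> plain proportion 0
  expect_equal(top$p, 0)
  expect_true(top$significant)
  # add-one option gives (b+1)/(n+1), doubled for the two-sided report
  tst2 <- permutation_test(arr, "INT", m, n_perm = 100, seed = 17,
                           add_one = TRUE)
  expect_equal(tst2$clusters[[1]]$p, 2 * 1 / 101)
  # per-tail mode halves nothing
  tst3 <- permutation_test(arr, "INT", m, n_perm = 100, seed = 17,
                           tail = "per-tail")
  expect_equal(tst3$clusters[[1]]$p, 0)
  expect_error(permutation_test(arr[1, , , , , drop = FALSE], "INT", m),
               "at least 2")
})

test_that("relabelling one factor's levels leaves the other factors' maps unchanged", {
  set.seed(18)
  m <- make_montage(2, 2)
  arr <- array(rnorm(6 * 9 * 4 * 2 * 3), dim = c(6, 9, 4, 2, 3))
  tst_int <- permutation_test(arr, "INT", m, n_perm = 10, seed = 19)
  # swap EXP levels low <-> high within every stimulus level: cells are
  # (stim-major, cue within), so swap cue positions 1 and 3 in each triplet
  swap <- c(3, 2, 1, 6, 5, 4, 9, 8, 7)
  arr_swapped <- arr[, swap, , , , drop = FALSE]
  tst_int2 <- permutation_test(arr_swapped, "INT", m, n_perm = 10, seed = 19)
  expect_equal(tst_int2$F_map, tst_int$F_map, tolerance = 1e-10)
  expect_equal(tst_int2$slope_map, tst_int$slope_map, tolerance = 1e-10)
})

test_that("post-hoc tests match a paired t-test oracle and handle edge cases", {
  set.seed(20)
  cm <- matrix(rnorm(12 * 9), 12, 9)
  ph <- posthoc_pairwise(NULL, cm, "INT")
  L <- factor_level_means(cm, "INT")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(pairs)) {
    tt <- t.test(L[, pairs[[k]][2]], L[, pairs[[k]][1]], paired = TRUE)
    expect_equal(ph$pairs$p_raw[k], tt$p.value, tolerance = 1e-10)
    expect_equal(ph$pairs$p_bonferroni[k], min(1, 3 * tt$p.value),
                 tolerance = 1e-10)
  }
  # identical level data: t = 0, adjusted p = 1
  same <- matrix(rep(rnorm(12), 9), 12, 9)
  ph0 <- posthoc_pairwise(NULL, same, "EXP")
  expect_true(all(ph0$pairs$t == 0))
  expect_true(all(ph0$pairs$p_bonferroni == 1))
  # constant nonzero difference with zero variance is degenerate
  g <- build_condition_grid()
  shifted <- matrix(rep(g$int_code, each = 12), 12, 9)
  expect_error(posthoc_pairwise(NULL, shifted, "INT"), "degenerate")
})

test_that("post-hoc tests on a cluster average only its member samples", {
  set.seed(21)
  n <- 8
  arr <- array(rnorm(n * 9 * 4 * 3 * 4), dim = c(n, 9, 4, 3, 4))
  cluster <- list(members = cbind(c(1, 2), c(1, 1), c(2, 2)))
  ph <- posthoc_pairwise(cluster, arr, "PE")
  manual <- sapply(1:9, function(cell)
    rowMeans(cbind(arr[, cell, 1, 1, 2], arr[, cell, 2, 1, 2])))
  ph_manual <- posthoc_pairwise(NULL, manual, "PE")
  expect_equal(ph$pairs, ph_manual$pairs, tolerance = 1e-12)
})

test_that("ratings tests reproduce construction cases", {
  g <- build_condition_grid()
  n <- 10
  # pure INT data with tiny noise: INT significant, EXP/PE not
  set.seed(22)
  cm <- matrix(rep(g$int_code + 2, each = n), n, 9) +
    matrix(rnorm(n * 9, sd = 0.01), n, 9)
  rt <- ratings_tests(cm)
  expect_lt(rt$factors$INT$p, 0.001)
  expect_false(rt$factors$EXP$significant)
  expect_false(rt$factors$PE$significant)
  # exact (noise-free) INT data is degenerate for every factor
  cm0 <- matrix(rep(g$int_code + 2, each = n), n, 9)
  expect_error(ratings_tests(cm0), "degenerate")
  # all-equal ratings are degenerate too
  expect_error(ratings_tests(matrix(2, n, 9)), "degenerate")
})

test_that("pre-shuffled null data reproduce the permutation max distribution", {
  # exchangeability: randomly relabelling the factor levels of null data
  # per subject draws from exactly the distribution the permutation null
  # estimates
  set.seed(40)
  m <- make_montage(2, 2)
  arr <- array(rnorm(8 * 9 * 4 * 4 * 5), dim = c(8, 9, 4, 4, 5))
  tst <- permutation_test(arr, "INT", m, n_perm = 200, seed = 41)
  perms6 <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                   6, 3, byrow = TRUE)
  fl <- factor_levels("INT")
  set.seed(42)
  obs <- vapply(1:100, function(i) {
    arr2 <- arr
    for (s in 1:8) {
      pp <- perms6[sample.int(6, 1), ]
      for (l in 1:3)
        arr2[s, fl$cells[[l]], , , ] <- arr[s, fl$cells[[pp[l]]], , , ]
    }
    t2 <- permutation_test(arr2, "INT", m, n_perm = 1, seed = 1)
    vals <- vapply(t2$clusters, function(x)
      if (x$sign == "positive") x$value else 0, 0)
    if (length(vals)) max(vals) else 0
  }, 0)
  ks <- suppressWarnings(ks.test(obs, tst$null_max_pos))
  expect_gt(ks$p.value, 0.001)
})
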