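#' @importFrom stats qf pf sd t.test
NULL

#' Factor level structure over the condition grid
#'
#' For a factor, the level codes and which of the nine condition cells feed
#' each level: INT and EXP have three cells per level (codes -1, 0, 1); PE
#' has 3, 4 and 2 cells for levels 0, 1 and 2.
#'
#' @param factor One of `"INT"`, `"EXP"`, `"PE"`.
#' @return List with `codes` (numeric level codes) and `cells` (list of cell
#'   index vectors per level).
#' @export
factor_levels <- function(factor = c("INT", "EXP", "PE")) {
  factor <- match.arg(factor)
  g <- build_condition_grid()
  code <- switch(factor, INT = g$int_code, EXP = g$exp_code, PE = g$pe_code)
  lev <- sort(unique(code))
  list(codes = lev,
       cells = lapply(lev, function(l) which(code == l)))
}

#' Collapse nine-cell values to per-factor level means
#'
#' Unweighted mean over the condition cells sharing each factor level, per
#' subject (and per sample for arrays).
#'
#' @param values Numeric subjects x 9 matrix, or a subjects x 9 x ... array
#'   of per-sample values; all nine cells must be present (no `NA`).
#' @param factor `"INT"`, `"EXP"` or `"PE"`.
#' @return Subjects x 3 matrix (or subjects x 3 x ... array) of level means,
#'   with the level codes as an attribute `codes`.
#' @export
factor_level_means <- function(values, factor) {
  fl <- factor_levels(factor)
  d <- dim(values)
  if (is.null(d) || d[2] != 9) abort("values must be subjects x 9 (x ...)")
  if (anyNA(values)) abort("missing condition cell value")
  # work on a cells-first matrix view: 9 x (subjects * rest)
  vm <- matrix(aperm(values, c(2, seq_along(d)[-2])), nrow = d[2])
  lev_m <- vapply(fl$cells,
                  function(cells) colMeans(vm[cells, , drop = FALSE]),
                  numeric(ncol(vm)))                 # rest x 3
  lev_arr <- array(t(lev_m), dim = c(length(fl$codes), d[-2]))
  out <- aperm(lev_arr, c(2, 1, seq_along(d)[-(1:2)] + 0))
  attr(out, "codes") <- fl$codes
  out
}

#' Repeated-measures linear-trend F statistic
#'
#' The single-degree-of-freedom linear-trend test underlying the per-sample
#' statistics: each subject's three level means are regressed on the level
#' codes by ordinary least squares, and the group of per-subject slopes is
#' tested against zero with a one-sample t; `F = t^2` on `df = (1, n - 1)`.
#' The fixed factor estimate is the average slope over subjects. The test is
#' invariant to affine rescaling of the level codes.
#'
#' @param level_means Subjects x 3 matrix of level means.
#' @param codes Numeric level codes (length 3, not all equal).
#' @return List with `F`, `slope_mean`, `slopes`, `t`, `df` (length 2) and
#'   `p` (parametric upper-tail probability). Errors when fewer than 2
#'   subjects or when the between-subject slope SD is zero (degenerate).
#' @examples
#' lm2 <- rbind(c(0, 1, 2), c(0, 2, 4))
#' linear_trend_F(lm2, c(-1, 0, 1))$F   # slopes 1 and 2 -> F = 9
#' @export
linear_trend_F <- function(level_means, codes) {
  level_means <- as.matrix(level_means)
  n <- nrow(level_means)
  if (n < 2) abort("need at least 2 subjects")
  if (length(codes) != ncol(level_means)) abort("codes/levels mismatch")
  cc <- codes - mean(codes)
  if (all(cc == 0)) abort("level codes must not all be equal")
  w <- cc / sum(cc^2)
  slopes <- as.numeric(level_means %*% w)
  sb <- sd(slopes)
  if (sb == 0)
    abort("degenerate: zero between-subject slope standard deviation")
  tt <- mean(slopes) / (sb / sqrt(n))
  list(F = tt^2, slope_mean = mean(slopes), slopes = slopes, t = tt,
       df = c(1, n - 1), p = pf(tt^2, 1, n - 1, lower.tail = FALSE))
}

# vectorised linear-trend statistics over many samples:
# level_means: subjects x 3 x m array -> list(F = m, slope = m)
# degenerate samples (zero slope SD) get F = Inf with the slope's sign
.trend_stat_map <- function(level_means, codes) {
  d <- dim(level_means)
  n <- d[1]
  cc <- codes - mean(codes)
  w <- cc / sum(cc^2)
  m <- prod(d[-(1:2)])
  lm2 <- matrix(level_means, nrow = n * d[2])      # (n*3) x m
  slopes <- matrix(0, n, m)
  for (j in seq_len(d[2]))
    slopes <- slopes + w[j] * lm2[(j - 1) * n + seq_len(n), , drop = FALSE]
  mb <- colMeans(slopes)
  vb <- (colSums(slopes^2) - n * mb^2) / (n - 1)
  vb[vb < 0] <- 0
  Fv <- ifelse(vb == 0, Inf, n * mb^2 / vb)
  list(F = Fv, slope = mb)
}

#' Critical F value for cluster forming
#'
#' Upper-`alpha` quantile of the F distribution. With 29 subjects the
#' per-sample linear-trend statistic has `df = (1, 28)` and the 5% threshold
#' is 4.196.
#'
#' @param df1,df2 Degrees of freedom (>= 1).
#' @param alpha Upper-tail probability in (0, 1).
#' @return The F threshold.
#' @examples
#' round(f_critical(1, 28, 0.05), 3)   # 4.196
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  if (df1 < 1 || df2 < 1) abort("degrees of freedom must be >= 1")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  qf(1 - alpha, df1, df2)
}

#' Spatial-neighbour restriction of a supra-threshold mask
#'
#' A sample (channel, frequency, time) survives only if at least one
#' spatially neighbouring channel is also supra-threshold at the same
#' frequency and time. Channels with an empty neighbour set lose all their
#' samples.
#'
#' @param mask Logical channels x freqs x times array.
#' @param montage An `eeg_montage` covering all channels (dimension 1 of
#'   `mask`, in montage channel order).
#' @return The filtered logical array.
#' @export
spatial_neighbor_filter <- function(mask, montage) {
  d <- dim(mask)
  if (d[1] != length(montage$channels))
    abort("mask channel dimension does not match the montage")
  A <- .adjacency_matrix(montage)
  m <- matrix(mask, nrow = d[1])                  # channels x (freq*time)
  keep <- m & ((A %*% m) > 0)
  array(keep, dim = d)
}

# unordered neighbouring channel index pairs (c1 < c2), 2-column matrix
.neighbor_pairs <- function(montage) {
  ch <- montage$channels
  out <- matrix(0L, 0, 2)
  for (i in seq_along(ch)) {
    j <- match(montage$neighbors[[ch[i]]], ch)
    j <- j[j > i]
    if (length(j)) out <- rbind(out, cbind(i, j))
  }
  out
}

# 0/1 channel adjacency matrix in montage channel order
.adjacency_matrix <- function(montage) {
  ch <- montage$channels
  n <- length(ch)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- match(montage$neighbors[[ch[i]]], ch)
    if (length(j)) A[i, j] <- 1
  }
  A
}

# connected components of a filtered mask under (c,f+-1,t), (c,f,t+-1),
# (neighbour(c),f,t) adjacency; returns list of integer vectors of linear
# indices into the full array
.mask_components <- function(mask, montage) {
  d <- dim(mask)
  ids <- which(mask)
  if (!length(ids)) return(list())
  nc <- d[1]; nf <- d[2]; nt <- d[3]
  vmap <- integer(nc * nf * nt)
  vmap[ids] <- seq_along(ids)
  edges_a <- integer(0); edges_b <- integer(0)
  if (nf > 1) {
    both <- mask[, -nf, , drop = FALSE] & mask[, -1, , drop = FALSE]
    w <- which(both)
    if (length(w)) {
      ci <- arrayInd(w, c(nc, nf - 1, nt))
      a <- ci[, 1] + (ci[, 2] - 1L) * nc + (ci[, 3] - 1L) * nc * nf
      edges_a <- c(edges_a, a); edges_b <- c(edges_b, a + nc)
    }
  }
  if (nt > 1) {
    both <- mask[, , -nt, drop = FALSE] & mask[, , -1, drop = FALSE]
    w <- which(both)
    if (length(w)) {
      ci <- arrayInd(w, c(nc, nf, nt - 1))
      a <- ci[, 1] + (ci[, 2] - 1L) * nc + (ci[, 3] - 1L) * nc * nf
      edges_a <- c(edges_a, a); edges_b <- c(edges_b, a + nc * nf)
    }
  }
  pairs <- .neighbor_pairs(montage)              # 2-column, c1 < c2
  if (nrow(pairs)) {
    m2 <- matrix(mask, nrow = nc)                # channels x (freq*time)
    both <- m2[pairs[, 1], , drop = FALSE] & m2[pairs[, 2], , drop = FALSE]
    w <- which(both)
    if (length(w)) {
      pi_ <- (w - 1L) %% nrow(pairs) + 1L        # pair index
      ft <- (w - 1L) %/% nrow(pairs)             # 0-based freq*time index
      base <- ft * nc
      edges_a <- c(edges_a, pairs[pi_, 1] + base)
      edges_b <- c(edges_b, pairs[pi_, 2] + base)
    }
  }
  if (length(edges_a)) {
    g <- igraph::make_graph(rbind(vmap[edges_a], vmap[edges_b]),
                            n = length(ids), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(ids)
  }
  split(ids, memb)
}

#' Form sign-pure supra-threshold clusters
#'
#' Splits the supra-threshold mask (`F > threshold`, strictly) by the sign
#' of the group-mean slope, applies the spatial-neighbour restriction to
#' each sign's mask, and finds connected components under temporal (adjacent
#' time points), spectral (+-1 frequency step) and spatial (montage
#' neighbours) adjacency. Each cluster's value is the sum of its members' F
#' statistics.
#'
#' @param F_map Numeric channels x freqs x times array of F values.
#' @param slope_map Same-shape array of group-mean slopes.
#' @param threshold Cluster-forming threshold (F value, > 0).
#' @param montage An `eeg_montage`.
#' @return List of clusters, each a list with `sign` (`"positive"` or
#'   `"negative"`), `value` (summed F), `n_members`, and `members` (matrix
#'   with columns channel, freq, time index). Ordered by decreasing value.
#' @export
form_clusters <- function(F_map, slope_map, threshold, montage) {
  if (threshold <= 0) abort("threshold must be > 0")
  d <- dim(F_map)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- (F_map > threshold) & (sign(slope_map) == sgn)
    mask[is.na(mask)] <- FALSE
    mask <- spatial_neighbor_filter(mask, montage)
    comps <- .mask_components(mask, montage)
    for (ids in comps) {
      out[[length(out) + 1L]] <- list(
        sign = if (sgn > 0) "positive" else "negative",
        value = sum(F_map[ids]),
        n_members = length(ids),
        members = arrayInd(ids, d))
    }
  }
  if (length(out))
    out <- out[order(vapply(out, function(cl) cl$value, 0),
                     decreasing = TRUE)]
  out
}

#' Cluster-based Monte-Carlo permutation test
#'
#' The full inference procedure for one factor: per-sample linear-trend F
#' maps from the subject x 9-cell values, sign-pure cluster formation at the
#' cluster-forming threshold with the spatial-neighbour restriction, and a
#' permutation null built by independently permuting, per subject, the
#' assignment of the three factor-level means to the level codes. For each
#' permutation the identical threshold/filter/clustering is applied and the
#' maximum positive and maximum negative cluster values are recorded. A
#' cluster's tail probability is the plain proportion of permutation maxima
#' (same sign) reaching its value; with `tail = "two-sided"` (default) the
#' reported p doubles the tail probability (capped at 1) so that the overall
#' two-tailed level equals `alpha`; `tail = "per-tail"` reports the raw tail
#' proportion.
#'
#' @param cell_values Numeric subjects x 9 x channels x freqs x times array
#'   (a matrix `subjects x 9 x channels` is promoted to a singleton grid),
#'   e.g. the `power` of a [stack_subjects()] result after [subset_tfr()].
#' @param factor `"INT"`, `"EXP"` or `"PE"`.
#' @param montage An `eeg_montage`.
#' @param n_perm Number of random permutations (default 1000).
#' @param alpha Significance level for clusters (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @param threshold Cluster-forming threshold; default
#'   `f_critical(1, n_subjects - 1, cluster_alpha)`.
#' @param cluster_alpha Per-sample alpha defining the default threshold.
#' @param tail `"two-sided"` (default) or `"per-tail"`.
#' @param add_one If `TRUE`, use the `(b + 1) / (n + 1)` permutation p-value
#'   instead of the plain proportion `b / n`.
#' @param freqs,times Optional axis labels for reporting.
#' @param channels Optional channel names (default from montage).
#' @return An object of class `cluster_test`: list with `clusters` (each
#'   with `sign`, `value`, `n_members`, `members`, `p`, `significant`),
#'   `F_map`, `slope_map`, `threshold`, `df`, `null_max_pos`,
#'   `null_max_neg`, `factor`, `alpha`, `tail`, `n_perm`, `seed` and axis
#'   metadata.
#' @export
permutation_test <- function(cell_values, factor, montage, n_perm = 1000,
                             alpha = 0.05, seed = 1L, threshold = NULL,
                             cluster_alpha = 0.05,
                             tail = c("two-sided", "per-tail"),
                             add_one = FALSE, freqs = NULL, times = NULL,
                             channels = NULL) {
  tail <- match.arg(tail)
  d <- dim(cell_values)
  if (length(d) == 3) {
    dim(cell_values) <- c(d, 1, 1)
    d <- dim(cell_values)
  }
  if (length(d) != 5 || d[2] != 9)
    abort("cell_values must be subjects x 9 x channels x freqs x times")
  n <- d[1]
  if (n < 2) abort("need at least 2 subjects")
  grid_dim <- d[3:5]
  if (grid_dim[1] != length(montage$channels))
    abort("channel dimension does not match the montage")
  if (is.null(threshold)) threshold <- f_critical(1, n - 1, cluster_alpha)

  L <- factor_level_means(cell_values, factor)     # n x 3 x grid
  codes <- attr(L, "codes")
  n_lev <- length(codes)
  obs <- .trend_stat_map(L, codes)
  F_map <- array(obs$F, dim = grid_dim)
  slope_map <- array(obs$slope, dim = grid_dim)
  clusters <- form_clusters(F_map, slope_map, threshold, montage)

  # permutation null: per subject, relabel the level means
  cc <- codes - mean(codes)
  w <- cc / sum(cc^2)
  all_perms <- .permutations(n_lev)                # n_lev! x n_lev
  m <- prod(grid_dim)
  Lm <- matrix(L, nrow = n * n_lev)                # (n*n_lev) x m
  null_max_pos <- numeric(n_perm)
  null_max_neg <- numeric(n_perm)
  with_seed(seed, {
    for (pp in seq_len(n_perm)) {
      pick <- sample.int(nrow(all_perms), n, replace = TRUE)
      slopes <- matrix(0, n, m)
      for (j in seq_len(n_lev)) {
        wj <- w[all_perms[cbind(pick, j)]]
        slopes <- slopes + wj * Lm[(j - 1) * n + seq_len(n), , drop = FALSE]
      }
      mb <- colMeans(slopes)
      vb <- (colSums(slopes^2) - n * mb^2) / (n - 1)
      vb[vb < 0] <- 0
      Fv <- ifelse(vb == 0, ifelse(mb == 0, 0, Inf), n * mb^2 / vb)
      cl <- form_clusters(array(Fv, grid_dim), array(mb, grid_dim),
                          threshold, montage)
      vals <- vapply(cl, function(x) x$value, 0)
      sgns <- vapply(cl, function(x) x$sign, "")
      null_max_pos[pp] <- if (any(sgns == "positive"))
        max(vals[sgns == "positive"]) else 0
      null_max_neg[pp] <- if (any(sgns == "negative"))
        max(vals[sgns == "negative"]) else 0
    }
  })

  pval <- function(value, sgn) {
    nullv <- if (sgn == "positive") null_max_pos else null_max_neg
    b <- sum(nullv >= value)
    p <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
    if (tail == "two-sided") p <- min(1, 2 * p)
    p
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- pval(clusters[[i]]$value, clusters[[i]]$sign)
    clusters[[i]]$significant <- clusters[[i]]$p < alpha
  }

  structure(list(clusters = clusters, F_map = F_map, slope_map = slope_map,
                 threshold = threshold, df = c(1, n - 1),
                 null_max_pos = null_max_pos, null_max_neg = null_max_neg,
                 factor = factor, alpha = alpha, tail = tail,
                 n_perm = n_perm, seed = seed, add_one = add_one,
                 freqs = freqs, times = times,
                 channels = if (is.null(channels)) montage$channels
                            else channels,
                 n_subjects = n),
            class = "cluster_test")
}

# all permutations of 1..n as rows
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> factor %s, %d subjects, threshold F(%d,%d) > %.3f, %d permutations (%s)\n",
    x$factor, x$n_subjects, x$df[1], x$df[2], x$threshold, x$n_perm, x$tail))
  if (!length(x$clusters)) {
    cat("no supra-threshold clusters\n")
    return(invisible(x))
  }
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %s, value %.1f, %d samples, p = %.4g%s\n",
                i, cl$sign, cl$value, cl$n_members, cl$p,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' @export
summary.cluster_test <- function(object, ...) {
  cl <- object$clusters
  df <- data.frame(
    sign = vapply(cl, function(x) x$sign, ""),
    value = vapply(cl, function(x) x$value, 0),
    n_members = vapply(cl, function(x) x$n_members, 0L),
    p = vapply(cl, function(x) x$p, 0),
    significant = vapply(cl, function(x) x$significant, TRUE))
  if (!is.null(object$freqs) && nrow(df)) {
    df$freq_lo <- vapply(cl, function(x) min(object$freqs[x$members[, 2]]), 0)
    df$freq_hi <- vapply(cl, function(x) max(object$freqs[x$members[, 2]]), 0)
  }
  if (!is.null(object$times) && nrow(df)) {
    df$time_lo <- vapply(cl, function(x) min(object$times[x$members[, 3]]), 0)
    df$time_hi <- vapply(cl, function(x) max(object$times[x$members[, 3]]), 0)
  }
  df
}

#' Bonferroni-corrected pairwise post-hoc tests for a cluster
#'
#' For every subject, values are averaged over all channel-frequency-time
#' samples in the cluster, separately per factor level; the three level
#' pairs are then compared with paired t-tests and Bonferroni correction
#' (adjusted p = min(1, 3 * raw p)).
#'
#' @param cluster One element of a `cluster_test`'s `clusters` (or any list
#'   with a `members` index matrix), or `NULL` to use all samples.
#' @param cell_values Subjects x 9 x channels x freqs x times array (or
#'   subjects x 9 matrix for ratings-style data).
#' @param factor `"INT"`, `"EXP"` or `"PE"`.
#' @return List of class `posthoc_table` with `pairs` (data frame: levels
#'   compared, mean difference, t, raw and Bonferroni-adjusted p) and
#'   `levels` (data frame: level code, mean M and SD of the cluster-averaged
#'   values).
#' @export
posthoc_pairwise <- function(cluster, cell_values, factor) {
  d <- dim(cell_values)
  if (length(d) == 2) {
    cellmeans <- cell_values
  } else {
    if (is.null(cluster) || !nrow(cluster$members))
      abort("cluster must be non-empty")
    mem <- cluster$members
    n <- d[1]
    cellmeans <- matrix(NA_real_, n, 9)
    grid <- d[3:5]
    lin <- (mem[, 1] - 1L) + (mem[, 2] - 1L) * grid[1] +
      (mem[, 3] - 1L) * grid[1] * grid[2]
    pw <- matrix(cell_values, nrow = n * 9)        # (n*9) x grid
    sel <- pw[, lin + 1L, drop = FALSE]
    cellmeans <- matrix(rowMeans(sel), n, 9)
  }
  L <- factor_level_means(cellmeans, factor)
  codes <- attr(L, "codes")
  pairs <- utils::combn(seq_along(codes), 2)
  res <- data.frame()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dvec <- L[, b] - L[, a]
    if (all(dvec == 0)) {
      # identical level values: no evidence either way
      tt <- list(statistic = 0, p.value = 1)
    } else if (sd(dvec) == 0) {
      abort("degenerate paired t-test: zero within-pair variance for levels %g vs %g",
            codes[a], codes[b])
    } else {
      tt <- t.test(L[, b], L[, a], paired = TRUE)
    }
    res <- rbind(res, data.frame(
      level_a = codes[a], level_b = codes[b],
      mean_diff = mean(dvec), t = unname(tt$statistic),
      p_raw = tt$p.value,
      p_bonferroni = min(1, ncol(pairs) * tt$p.value)))
  }
  levels_df <- data.frame(level = codes, M = colMeans(L),
                          SD = apply(L, 2, sd))
  structure(list(pairs = res, levels = levels_df, factor = factor),
            class = "posthoc_table")
}

#' @export
print.posthoc_table <- function(x, ...) {
  cat(sprintf("<posthoc_table> factor %s (Bonferroni x%d)\n", x$factor,
              nrow(x$pairs)))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Linear-trend tests of behavioural ratings
#'
#' Applies the repeated-measures linear-trend F test to the subject x 9-cell
#' mean ratings for each of the three factors, with Bonferroni-corrected
#' pairwise post-hoc tests on the level means.
#'
#' @param cell_means Subjects x 9 matrix of per-condition mean ratings.
#' @param alpha Significance level.
#' @return Object of class `ratings_anova`: per factor, `F`, `df`, `p`,
#'   `slope_mean` and a `posthoc` table.
#' @export
ratings_tests <- function(cell_means, alpha = 0.05) {
  cell_means <- as.matrix(cell_means)
  if (ncol(cell_means) != 9) abort("cell_means must be subjects x 9")
  if (anyNA(cell_means)) abort("incomplete 9-cell table")
  out <- list()
  for (f in c("INT", "EXP", "PE")) {
    L <- factor_level_means(cell_means, f)
    res <- linear_trend_F(L, attr(L, "codes"))
    res$posthoc <- tryCatch(posthoc_pairwise(NULL, cell_means, f),
                            error = function(e) NULL)
    res$significant <- res$p < alpha
    out[[f]] <- res
  }
  structure(list(factors = out, alpha = alpha,
                 n_subjects = nrow(cell_means)),
            class = "ratings_anova")
}

#' @export
print.ratings_anova <- function(x, ...) {
  cat(sprintf("<ratings_anova> %d subjects, linear-trend F(1,%d)\n",
              x$n_subjects, x$n_subjects - 1))
  for (f in names(x$factors)) {
    r <- x$factors[[f]]
    cat(sprintf("  %s: F = %.2f, p = %.4g%s\n", f, r$F, r$p,
                if (r$significant) " *" else ""))
  }
  invisible(x)
}
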