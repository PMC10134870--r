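# Two-condition metabolite time-series robustness statistics.
#
# Metabolome data are long-format data.frames with columns
#   metabolite_id, condition, time_h, replicate, value
# (value in arbitrary NMR units, > 0). Trend statistics are computed on
# per-time replicate means (one trajectory per condition).

#' Per-time replicate means of a metabolome table
#' @param series long-format metabolome data.frame.
#' @return data.frame metabolite_id, condition, time_h, value (mean).
#' @keywords internal
#' @noRd
series_means <- function(series) {
  agg <- stats::aggregate(value ~ metabolite_id + condition + time_h,
                          data = series, FUN = mean)
  agg[order(agg$metabolite_id, agg$condition, agg$time_h), ]
}

#' Normalize trajectories to the first time point
#'
#' Divides every value by the metabolite's condition-specific mean at the
#' first sampled time, so each trajectory starts at 1 (fold over baseline).
#' Scale normalization leaves all correlation statistics unchanged.
#'
#' @param series long-format metabolome data.frame.
#' @return the table with `value` rescaled.
#' @export
normalize_trajectory <- function(series) {
  out <- series
  for (m in unique(series$metabolite_id)) {
    for (cond in unique(series$condition)) {
      sel <- series$metabolite_id == m & series$condition == cond
      if (!any(sel)) next
      t0 <- min(series$time_h[sel])
      base <- mean(series$value[sel & abs(series$time_h - t0) < 1e-9])
      if (!is.finite(base) || base <= 0) {
        stop("metabolite '", m, "' (", cond, "): zero baseline at first time point")
      }
      out$value[sel] <- series$value[sel] / base
    }
  }
  out
}

# Exact permutation null of Spearman's rho. Permutation matrices are cached
# per n; n = 5 (the study's time-grid size) gives the 120-permutation null.
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    out <- NULL
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- rbind(out, cbind(v[i], rest))
    }
    out
  }
  p <- perms(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

#' Two-sided Spearman p-value
#'
#' Exact permutation null for n <= 9 (all n! rank permutations), Student-t
#' approximation above. At n = 5 the exact p takes only the values k/120.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (!is.finite(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (n <= 9) {
    P <- all_permutations(n)
    null_rho <- apply(P, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Cross-condition trend correlation for one metabolite
#'
#' Pearson product-moment correlation between the two conditions'
#' per-time mean trajectories, with Spearman rho and its two-sided
#' (exact for n <= 9) p-value as statistical support. Constant
#' trajectories make the correlation undefined: the result carries
#' `defined = FALSE` instead of propagating NaN.
#'
#' @param series_a,series_b single-metabolite single-condition tables
#'   (long format) on the same time grid.
#' @return list with `pearson_r`, `spearman_rho`, `spearman_p`, `n`,
#'   `defined`.
#' @export
trend_correlation <- function(series_a, series_b) {
  ma <- series_means(series_a)
  mb <- series_means(series_b)
  if (nrow(ma) != nrow(mb)) stop("trajectories have different numbers of time points")
  n <- nrow(ma)
  if (n < 3) stop("need at least 3 time points")
  a <- ma$value[order(ma$time_h)]
  b <- mb$value[order(mb$time_h)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                spearman_p = NA_real_, n = n, defined = FALSE))
  }
  sp <- spearman_test(a, b)
  list(pearson_r = stats::cor(a, b), spearman_rho = sp$rho,
       spearman_p = sp$p, n = n, defined = TRUE)
}

#' All-against-all metabolite correlation matrix
#'
#' Pearson correlations between per-time mean trajectories of all
#' metabolite pairs. With both conditions selected the two condition
#' trajectories are concatenated (pooled); with one, restricted to it.
#'
#' @param series long-format metabolome table (>= 2 metabolites).
#' @param conditions conditions to pool (default: all present).
#' @return list with symmetric matrices `r` and `p` (Pearson two-sided)
#'   and `n`, the points per trajectory.
#' @export
correlation_matrix <- function(series, conditions = NULL) {
  if (is.null(conditions)) conditions <- sort(unique(series$condition))
  series <- series[series$condition %in% conditions, ]
  mets <- sort(unique(series$metabolite_id))
  if (length(mets) < 2) stop("need at least 2 metabolites")
  mm <- series_means(series)
  traj <- lapply(mets, function(m) {
    sub <- mm[mm$metabolite_id == m, ]
    unlist(lapply(conditions, function(cc) {
      s <- sub[sub$condition == cc, ]
      s$value[order(s$time_h)]
    }))
  })
  npts <- unique(vapply(traj, length, integer(1)))
  if (length(npts) != 1) stop("metabolites measured on different time grids")
  if (npts < 2) stop("need more than a single time point")
  X <- do.call(cbind, traj)
  colnames(X) <- mets
  r <- stats::cor(X)
  p <- matrix(1, length(mets), length(mets), dimnames = dimnames(r))
  for (i in seq_along(mets)) {
    for (j in seq_len(i - 1L)) {
      pij <- tryCatch(stats::cor.test(X[, i], X[, j])$p.value,
                      error = function(e) NA_real_)
      p[i, j] <- p[j, i] <- pij
    }
  }
  list(r = r, p = p, n = npts, conditions = conditions)
}

#' Compare two correlation matrices
#'
#' Welch two-sample t-test on the upper-triangle entries (diagonal
#' excluded) of the two matrices; tests whether the mean pairwise
#' correlation structure differs between conditions.
#'
#' @param m0,m15 outputs of [correlation_matrix()] (or plain matrices)
#'   with identical metabolite ordering.
#' @return list with `statistic`, `p`, `mean_0`, `mean_15`.
#' @export
compare_matrices <- function(m0, m15) {
  r0 <- if (is.list(m0)) m0$r else m0
  r15 <- if (is.list(m15)) m15$r else m15
  if (!all(dim(r0) == dim(r15))) stop("correlation matrices have different dimensions")
  if (!is.null(rownames(r0)) && !identical(rownames(r0), rownames(r15))) {
    stop("correlation matrices have different metabolite orderings")
  }
  u0 <- r0[upper.tri(r0)]
  u15 <- r15[upper.tri(r15)]
  if (isTRUE(all.equal(u0, u15))) {
    return(list(statistic = 0, p = 1, mean_0 = mean(u0), mean_15 = mean(u15)))
  }
  tt <- stats::t.test(u0, u15)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       mean_0 = mean(u0), mean_15 = mean(u15))
}

#' Per-metabolite mean-concentration tests between conditions
#'
#' Welch t-test per metabolite on all values pooled over time points and
#' replicates (average concentration across the growth experiment),
#' Bonferroni-adjusted over the metabolites tested.
#'
#' @param series long-format metabolome table with two conditions.
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame metabolite_id, p_raw, p_bonferroni,
#'   significant_raw, significant.
#' @export
mean_difference_tests <- function(series, alpha = 0.05) {
  conds <- sort(unique(series$condition))
  if (length(conds) != 2) stop("exactly two conditions required")
  mets <- sort(unique(series$metabolite_id))
  rows <- lapply(mets, function(m) {
    x <- series$value[series$metabolite_id == m & series$condition == conds[1]]
    y <- series$value[series$metabolite_id == m & series$condition == conds[2]]
    if (length(x) < 2 || length(y) < 2) {
      warning("metabolite '", m, "' skipped: fewer than 2 values in a group")
      return(NULL)
    }
    data.frame(metabolite_id = m, p_raw = stats::t.test(x, y)$p.value)
  })
  out <- do.call(rbind, rows)
  m_tested <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_raw * m_tested)
  out$significant_raw <- out$p_raw < alpha
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Metabolite log2 fold-change contrast at one time point
#'
#' log2(mean alt / mean ref) on replicate values at the named time point,
#' with a Welch t-test per metabolite. Metabolites with |log2FC| >= the
#' threshold are flagged; the summary reports the count and integer-rounded
#' percentage below threshold.
#'
#' The two conditions are sampled on their own time grids (the colder
#' culture grows far slower), so the contrast point is named by sampling
#' index: `time_index = 2` is the second sampled time of each condition
#' (the start of exponential growth, "T1" in a T0-T4 labeling).
#'
#' @param series long-format metabolome table.
#' @param time_index position of the contrast point in each condition's
#'   sorted time grid (default 2).
#' @param condition_ref,condition_alt condition labels (ref = denominator,
#'   the colder condition in the two-temperature design).
#' @param lfc_threshold flag threshold on |log2FC| (default 1).
#' @param alpha significance level for the per-metabolite test.
#' @return data.frame metabolite_id, log2fc, p_raw, p_adjusted, significant,
#'   flagged; attributes `n_flagged`, `pct_below` (integer percent).
#' @export
contrast_log2fc <- function(series, time_index = 2,
                            condition_ref = "0C", condition_alt = "15C",
                            lfc_threshold = 1, alpha = 0.05) {
  pick <- function(cond) {
    tt <- sort(unique(series$time_h[series$condition == cond]))
    if (time_index > length(tt)) {
      stop("condition '", cond, "' has no sampling point ", time_index)
    }
    series$condition == cond & abs(series$time_h - tt[time_index]) < 1e-9
  }
  sub <- series[pick(condition_ref) | pick(condition_alt), ]
  if (!nrow(sub)) stop("no measurements at sampling index ", time_index)
  mets <- sort(unique(sub$metabolite_id))
  rows <- lapply(mets, function(m) {
    x <- sub$value[sub$metabolite_id == m & sub$condition == condition_ref]
    y <- sub$value[sub$metabolite_id == m & sub$condition == condition_alt]
    if (!length(x) || !length(y)) stop("metabolite '", m, "' missing in one condition")
    if (mean(x) <= 0 || mean(y) <= 0) stop("metabolite '", m, "': zero mean")
    p <- if (length(x) > 1 && length(y) > 1 &&
             (stats::sd(x) > 0 || stats::sd(y) > 0)) {
      stats::t.test(x, y)$p.value
    } else if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_
    data.frame(metabolite_id = m, log2fc = log2(mean(y) / mean(x)), p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out$flagged <- abs(out$log2fc) >= lfc_threshold
  attr(out, "n_flagged") <- sum(out$flagged)
  attr(out, "pct_below") <- round(100 * sum(!out$flagged) / nrow(out))
  out
}
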