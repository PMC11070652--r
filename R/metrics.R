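# Ranking and regression metrics for docking pose scoring. Lower score =
# better pose (scores are predicted RMSDs). All ranking metrics are
# rank-based, hence invariant under strictly monotone transforms of the
# scores; ties are broken by stable input order and counted.

rank_table <- function(rankings) {
  stopifnot(is.data.frame(rankings))
  need <- c("complex_id", "pose_id", "score", "rmsd")
  miss <- setdiff(need, names(rankings))
  if (length(miss)) stop2("ranking table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(rankings) == 0L) stop2("empty ranking table")
  if (any(rankings$rmsd < 0, na.rm = TRUE)) stop2("negative true RMSD")
  rankings
}

# per-complex list, each sorted ascending by score with stable tie order
# (+Inf scores keep their input order at the bottom); tie counts attached
split_sorted <- function(rankings) {
  grp <- split(seq_len(nrow(rankings)), rankings$complex_id)
  lapply(grp, function(idx) {
    sc <- rankings$score[idx]
    ord <- order(sc, seq_along(idx))   # stable
    out <- rankings[idx[ord], , drop = FALSE]
    attr(out, "n_ties") <- sum(duplicated(sc[is.finite(sc)]))
    out
  })
}

#' Regression metrics between predicted and true RMSD
#'
#' @param predicted,truth Equal-length finite numeric vectors (length >= 2
#'   for the correlations).
#' @return List with `rmse`, `pearson_r` and `spearman_rho` (average ranks on
#'   ties). A constant vector makes the correlations undefined; they are
#'   returned as `NaN` with a warning.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 3, 2))$spearman_rho  # 0.5
#' @export
regression_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop2("length mismatch")
  if (any(!is.finite(predicted)) || any(!is.finite(truth)))
    stop2("regression metrics require finite values")
  rmse <- sqrt(mean((predicted - truth)^2))
  constant <- stats::var(predicted) == 0 || stats::var(truth) == 0
  if (constant || length(predicted) < 2L) {
    warning("correlation undefined for constant or length-1 input")
    return(list(rmse = rmse, pearson_r = NaN, spearman_rho = NaN))
  }
  list(rmse = rmse,
       pearson_r = stats::cor(predicted, truth, method = "pearson"),
       spearman_rho = stats::cor(predicted, truth, method = "spearman"))
}

#' Docking power: fraction of complexes with a near-native pose in the top k
#'
#' `m(k) / M`, where `m(k)` counts complexes having at least one pose with
#' true RMSD below `threshold` among their k best-scored poses and `M` is the
#' number of complexes.
#'
#' @param rankings data.frame with columns `complex_id`, `pose_id`, `score`,
#'   `rmsd` (one row per pose; lower score = better).
#' @param k Number of top-ranked poses inspected (default 1).
#' @param threshold Near-native RMSD cutoff in Angstrom (default 2, strict
#'   `<`).
#' @return Fraction in `[0, 1]`.
#' @export
docking_power <- function(rankings, k = 1L, threshold = 2.0) {
  stopifnot(k >= 1L, threshold > 0)
  per <- split_sorted(rank_table(rankings))
  hit <- vapply(per, function(tb)
    any(tb$rmsd[seq_len(min(k, nrow(tb)))] < threshold), TRUE)
  mean(hit)
}

#' Hit rate: mean recovered fraction of near-native poses in the top k
#'
#' Per complex, `h(k) / P`: the number of near-native poses among the k
#' best-scored, over the number of near-native poses in the whole pose set.
#' Complexes with no near-native pose at all (`P = 0`) are excluded from the
#' mean and reported in a warning.
#'
#' @inheritParams docking_power
#' @param k Top-ranked poses inspected (default 10).
#' @return Mean fraction in `[0, 1]` (`NaN` with a warning when every
#'   complex has `P = 0`).
#' @export
hit_rate <- function(rankings, k = 10L, threshold = 2.0) {
  stopifnot(k >= 1L, threshold > 0)
  per <- split_sorted(rank_table(rankings))
  fr <- hitrate_fractions(per, k, threshold)
  if (!length(fr$keep)) {
    warning("all complexes have zero near-native poses; hit rate undefined")
    return(NaN)
  }
  mean(fr$h[fr$keep] / fr$P[fr$keep])
}

hitrate_fractions <- function(per, k, threshold) {
  P <- vapply(per, function(tb) sum(tb$rmsd < threshold), 1L)
  h <- vapply(per, function(tb)
    sum(tb$rmsd[seq_len(min(k, nrow(tb)))] < threshold), 1L)
  keep <- which(P > 0L)
  if (length(keep) < length(P))
    warning(sprintf("%d complex(es) with no near-native pose excluded",
                    length(P) - length(keep)))
  list(P = P, h = h, keep = keep,
       n_poses = vapply(per, nrow, 1L))
}

#' Enrichment factor of the top-k selection
#'
#' Per complex, `h(k) / (P * alpha(k))` with `alpha(k) = k / n_poses`: the
#' recovered fraction of near-native poses relative to the fraction of poses
#' inspected. A random ranking gives an expected value of 1; a perfect
#' scorer approaches `1 / alpha(k)`.
#'
#' @inheritParams hit_rate
#' @return Mean enrichment factor over complexes with `P > 0`.
#' @export
enrichment_factor <- function(rankings, k = 10L, threshold = 2.0) {
  stopifnot(k >= 1L, threshold > 0)
  per <- split_sorted(rank_table(rankings))
  fr <- hitrate_fractions(per, k, threshold)
  if (!length(fr$keep)) {
    warning("all complexes have zero near-native poses; enrichment undefined")
    return(NaN)
  }
  alpha <- k / fr$n_poses
  mean(fr$h[fr$keep] / (fr$P[fr$keep] * alpha[fr$keep]))
}

#' Jensen-Shannon divergence between two binned distributions
#'
#' Computed with base-2 logarithms, so the value lies in `[0, 1]`: 0 for
#' identical distributions and 1 for distributions with disjoint support.
#' Used to compare RMSD histograms of different pose sets over a common
#' binning (e.g. restricted to RMSD below 2 A or below 10 A).
#'
#' @param p,q Non-negative histogram vectors over identical bins (normalised
#'   internally).
#' @return Divergence in `[0, 1]`.
#' @examples
#' js_divergence(c(0.5, 0.5), c(1, 0))  # ~0.3113
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop2("histograms must share their bins")
  if (any(p < 0) || any(q < 0)) stop2("negative histogram mass")
  if (sum(p) == 0 || sum(q) == 0) stop2("empty histogram")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Histogram of RMSD values over a fixed binning
#'
#' Convenience for [js_divergence()]: bins of `width` Angstrom covering
#' `[0, upper)`; values at or above `upper` are dropped (the comparison is
#' restricted to the stated RMSD range).
#'
#' @param rmsd Numeric RMSD values.
#' @param upper Range limit in Angstrom (e.g. 2 or 10).
#' @param width Bin width in Angstrom.
#' @return Named count vector (one entry per bin).
#' @export
bin_rmsd <- function(rmsd, upper = 10, width = 0.5) {
  breaks <- seq(0, upper, by = width)
  v <- rmsd[is.finite(rmsd) & rmsd >= 0 & rmsd < upper]
  h <- tabulate(findInterval(v, breaks), nbins = length(breaks) - 1L)
  names(h) <- sprintf("[%.2g,%.2g)", utils::head(breaks, -1L), breaks[-1L])
  h
}

#' Full evaluation report for a ranking table
#'
#' @inheritParams docking_power
#' @param k_top Top-k for docking power.
#' @param k_hit Top-k for hit rate and enrichment factor.
#' @return List of class `metrics_report` with all six metrics plus the
#'   parameters and counts used.
#' @export
evaluate_rankings <- function(rankings, k_top = 1L, k_hit = 10L,
                              threshold = 2.0) {
  rankings <- rank_table(rankings)
  fin <- is.finite(rankings$score) & is.finite(rankings$rmsd)
  reg <- if (sum(fin) >= 2L)
    regression_metrics(rankings$score[fin], rankings$rmsd[fin])
  else list(rmse = NA_real_, pearson_r = NA_real_, spearman_rho = NA_real_)
  out <- list(rmse = reg$rmse, pearson_r = reg$pearson_r,
              spearman_rho = reg$spearman_rho,
              docking_power = docking_power(rankings, k_top, threshold),
              hit_rate = suppressWarnings(hit_rate(rankings, k_hit, threshold)),
              enrichment_factor =
                suppressWarnings(enrichment_factor(rankings, k_hit, threshold)),
              k_top = k_top, k_hit = k_hit, threshold = threshold,
              n_complexes = length(unique(rankings$complex_id)),
              n_poses = nrow(rankings),
              n_infinite_scores = sum(is.infinite(rankings$score)))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("evaluation of %d poses / %d complexes (near-native < %.1f A):\n",
              x$n_poses, x$n_complexes, x$threshold))
  cat(sprintf("  RMSE %.3f | Pearson %.3f | Spearman %.3f\n",
              x$rmse, x$pearson_r, x$spearman_rho))
  cat(sprintf("  docking power (k=%d) %.3f | hit rate (k=%d) %.3f | EF %.3f\n",
              x$k_top, x$docking_power, x$k_hit, x$hit_rate,
              x$enrichment_factor))
  invisible(x)
}

#' Read / write pose ranking tables (TSV)
#'
#' Columns: `complex_id`, `pose_id`, `score`, `rmsd`. Infinite scores are
#' written as the string "inf" and read back as `Inf`.
#'
#' @param path TSV file path.
#' @return `read_rankings` returns a data.frame; `write_rankings` the path.
#' @export
read_rankings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$score <- suppressWarnings(ifelse(tolower(df$score) %in% c("inf", "+inf"),
                                      Inf, as.numeric(df$score)))
  rank_table(df)
}

#' @rdname read_rankings
#' @param rankings Ranking data.frame.
#' @export
write_rankings <- function(rankings, path) {
  df <- rank_table(rankings)
  df$score <- ifelse(is.infinite(df$score), "inf",
                     format(df$score, digits = 10, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
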