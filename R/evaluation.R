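# Recovery metrics for the simulation study: lag-0 cross-correlation and
# relative L1-error against ground-truth kinetics, plus dataset summaries.

#' Lagged cross-correlation coefficient
#'
#' Pearson correlation between `x[t]` and `y[t + lag]` over the overlapping
#' range, for two equal-length series on a common uniform grid. `lag` is in
#' grid steps. If either series is constant over the overlap the coefficient
#' is undefined and returned as `NA` (flagged missing, never coerced to 0).
#'
#' @param x,y Equal-length numeric series.
#' @param lag Integer lag in grid steps (default 0).
#' @return Correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
crosscorr <- function(x, y, lag = 0L) {
  stopifnot(length(x) == length(y))
  lag <- as.integer(lag)
  n <- length(x)
  if (n <= abs(lag) + 1) stop("crosscorr: series too short for this lag")
  if (lag >= 0) {
    xs <- x[seq_len(n - lag)]
    ys <- y[seq_len(n - lag) + lag]
  } else {
    xs <- x[seq_len(n + lag) - lag]
    ys <- y[seq_len(n + lag)]
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Maximum cross-correlation within a lag window
#'
#' Scans integer lags in `[-max_lag/grid_step, +max_lag/grid_step]` and
#' returns the maximum coefficient, breaking ties toward smaller `|lag|`
#' (and toward the non-negative lag between `+l` and `-l`).
#'
#' @param x,y Equal-length series on a uniform grid.
#' @param max_lag_minutes Half-width of the lag window in minutes
#'   (default 60).
#' @param grid_step Grid spacing in minutes (default 1).
#' @return List with `best_cc` and `best_lag` (minutes; `NA` if all lags are
#'   undefined).
#' @export
max_lagged_crosscorr <- function(x, y, max_lag_minutes = 60, grid_step = 1) {
  stopifnot(max_lag_minutes >= 0, grid_step > 0)
  lmax <- floor(max_lag_minutes / grid_step)
  # visit lags in order of increasing |lag| so ties resolve to smaller shifts
  lags <- 0L
  if (lmax > 0) lags <- c(0L, as.vector(rbind(seq_len(lmax), -seq_len(lmax))))
  best_cc <- NA_real_
  best_lag <- NA_real_
  for (l in lags) {
    cc <- crosscorr(x, y, l)
    if (!is.na(cc) && (is.na(best_cc) || cc > best_cc)) {
      best_cc <- cc
      best_lag <- l * grid_step
    }
  }
  list(best_cc = best_cc, best_lag = best_lag)
}

#' Relative L1-error
#'
#' Total absolute deviation between estimate and truth normalized by the
#' total magnitude of the truth: `sum(|est - truth|) / sum(|truth|)`.
#'
#' @param est,truth Equal-length numeric series; `truth` must not be
#'   identically zero.
#' @return Non-negative scalar.
#' @export
relative_l1 <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  denom <- sum(abs(truth))
  if (denom == 0) stop("relative_l1: truth is identically zero")
  sum(abs(est - truth)) / denom
}

#' Evaluate one trained gene against its simulated ground truth
#'
#' Computes the lag-0 cross-correlation of the estimated transcription and
#' degradation rate trajectories with the truth and the relative L1-error of
#' the estimated splicing rate, on a common dense grid over the observation
#' period.
#'
#' @param model A `trained_gene_model` (or any object with a
#'   `mean_trajectory` data frame holding `time`, `alpha`, `beta`, `gamma`).
#' @param truth_grid `data.frame` with `time`, `alpha`, `beta`, `gamma` on
#'   the same grid (as produced by [simulate_scenario()]).
#' @param tags Optional named list of dataset tags (scenario, SI,
#'   noise_frac, ...) copied into the record.
#' @return One-row `data.frame`: `gene_id`, `cc_alpha`, `cc_gamma`,
#'   `rel_l1_beta`, plus any tags.
#' @export
evaluate_gene <- function(model, truth_grid, tags = NULL) {
  est <- model$mean_trajectory
  idx <- match(est$time, truth_grid$time)
  if (anyNA(idx)) stop("evaluate_gene: truth grid does not cover the estimate grid")
  tr <- truth_grid[idx, ]
  rec <- data.frame(gene_id = model$gene_id,
                    cc_alpha = crosscorr(est$alpha, tr$alpha, 0L),
                    cc_gamma = crosscorr(est$gamma, tr$gamma, 0L),
                    rel_l1_beta = relative_l1(est$beta, tr$beta),
                    stringsAsFactors = FALSE)
  if (!is.null(tags)) for (nm in names(tags)) rec[[nm]] <- tags[[nm]]
  rec
}

#' Summarize evaluation records by dataset configuration
#'
#' Per group, the medians and interquartile ranges of the recovery metrics.
#' Records with flagged-missing (NA) correlations are excluded from the
#' corresponding statistic and counted.
#'
#' @param records `data.frame` of rows from [evaluate_gene()].
#' @param group_by Character vector of tag columns to group on (default:
#'   none, one overall summary).
#' @return `data.frame` with one row per group: `n_genes`, medians and IQRs
#'   of `cc_alpha`, `cc_gamma`, `rel_l1_beta`, and `n_na_cc` (flagged
#'   correlations excluded).
#' @export
summarize_evaluations <- function(records, group_by = character()) {
  stopifnot(nrow(records) > 0)
  split_key <- if (length(group_by) == 0) {
    rep("all", nrow(records))
  } else {
    interaction(records[group_by], drop = TRUE)
  }
  out <- lapply(split(records, split_key), function(df) {
    base <- if (length(group_by) > 0) df[1, group_by, drop = FALSE] else data.frame(row.names = 1)
    cbind(base, data.frame(
      n_genes = nrow(df),
      median_cc_alpha = stats::median(df$cc_alpha, na.rm = TRUE),
      iqr_cc_alpha = stats::IQR(df$cc_alpha, na.rm = TRUE),
      median_cc_gamma = stats::median(df$cc_gamma, na.rm = TRUE),
      iqr_cc_gamma = stats::IQR(df$cc_gamma, na.rm = TRUE),
      median_rel_l1_beta = stats::median(df$rel_l1_beta, na.rm = TRUE),
      iqr_rel_l1_beta = stats::IQR(df$rel_l1_beta, na.rm = TRUE),
      n_na_cc = sum(is.na(df$cc_alpha)) + sum(is.na(df$cc_gamma))
    ))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
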