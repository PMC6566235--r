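#' Observed-vs-predicted agreement report
#'
#' Summarises how well predictions agree with observations: Pearson
#' correlation, means and sample SDs of both vectors, the median absolute
#' residual, and Bland-Altman limits of agreement on the per-item
#' differences (observed minus predicted) at `mean +/- sd_multiplier * SD`.
#' Items strictly outside the limits are reported as outliers.
#'
#' Conventions: sample (n-1) standard deviations throughout; the median uses
#' the mid-point convention for even n; the limits default to a literal 2
#' SDs (`sd_multiplier = 1.96` gives the classical 95% limits). The sign
#' convention observed - predicted makes an under-predicted item's
#' difference positive.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 3).
#' @param ids optional item identifiers for the outlier list; defaults to
#'   indices.
#' @param sd_multiplier width of the limits of agreement in SDs of the
#'   differences (default 2).
#' @return A `glyco_agreement`: `n`, `pearson_r`, `mean_observed`,
#'   `sd_observed`, `mean_predicted`, `sd_predicted`,
#'   `median_abs_residual`, `ba_mean_diff`, `ba_sd_diff`, `ba_lower`,
#'   `ba_upper`, `outlier_ids`.
#' @examples
#' b <- load_benchmark()
#' agreement_report(b$gi_obs, b$gi_pred, b$product_id)
#' @export
agreement_report <- function(observed, predicted, ids = NULL,
                             sd_multiplier = 2) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same length")
  n <- length(observed)
  if (n < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("observed and predicted must be finite")
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(ids) == n)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("correlation undefined: a vector has zero variance")

  diffs <- observed - predicted
  m <- mean(diffs); s <- stats::sd(diffs)
  lower <- m - sd_multiplier * s
  upper <- m + sd_multiplier * s
  out <- diffs < lower | diffs > upper
  structure(list(
    n = n,
    pearson_r = stats::cor(observed, predicted),
    mean_observed = mean(observed), sd_observed = stats::sd(observed),
    mean_predicted = mean(predicted), sd_predicted = stats::sd(predicted),
    median_abs_residual = stats::median(abs(diffs)),
    ba_mean_diff = m, ba_sd_diff = s,
    ba_lower = lower, ba_upper = upper,
    sd_multiplier = sd_multiplier,
    outlier_ids = ids[out]
  ), class = "glyco_agreement")
}

#' @export
print.glyco_agreement <- function(x, ...) {
  cat(sprintf("Agreement over %d items\n", x$n))
  cat(sprintf("  Pearson r: %.3f\n", x$pearson_r))
  cat(sprintf("  observed  mean %.2f, SD %.2f\n", x$mean_observed,
              x$sd_observed))
  cat(sprintf("  predicted mean %.2f, SD %.2f\n", x$mean_predicted,
              x$sd_predicted))
  cat(sprintf("  median |residual|: %.2f\n", x$median_abs_residual))
  cat(sprintf("  Bland-Altman limits (mean %+.2f, %.4g SD): [%.2f, %.2f]\n",
              x$ba_mean_diff, x$sd_multiplier, x$ba_lower, x$ba_upper))
  if (length(x$outlier_ids))
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  else cat("  no outliers\n")
  invisible(x)
}

#' Agreement plots
#'
#' `plot_agreement()` draws observed vs predicted with the identity line;
#' `plot_bland_altman()` draws per-item differences against per-item means
#' with the mean difference and limits of agreement.
#'
#' @param observed,predicted numeric vectors.
#' @param report optionally a precomputed [agreement_report()]; recomputed
#'   otherwise.
#' @param units axis-label units (e.g. `"GI"` or `"GL (g)"`).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the agreement report used.
#' @export
plot_agreement <- function(observed, predicted, units = "GI",
                           report = NULL, ...) {
  if (is.null(report)) report <- agreement_report(observed, predicted)
  rng <- range(observed, predicted)
  graphics::plot(predicted, observed, xlim = rng, ylim = rng,
                 xlab = paste("Predicted", units),
                 ylab = paste("Observed", units),
                 main = sprintf("r = %.2f", report$pearson_r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(report)
}

#' @rdname plot_agreement
#' @export
plot_bland_altman <- function(observed, predicted, units = "GI",
                              report = NULL, ...) {
  if (is.null(report)) report <- agreement_report(observed, predicted)
  means <- (observed + predicted) / 2
  diffs <- observed - predicted
  graphics::plot(means, diffs,
                 xlab = paste("Mean of observed and predicted", units),
                 ylab = paste("Observed - predicted", units),
                 main = sprintf("mean %+.2f, limits [%.2f, %.2f]",
                                report$ba_mean_diff, report$ba_lower,
                                report$ba_upper), ...)
  graphics::abline(h = report$ba_mean_diff, lty = 1)
  graphics::abline(h = c(report$ba_lower, report$ba_upper), lty = 2)
  invisible(report)
}
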