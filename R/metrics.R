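# Summary metrics: fold changes, robustness scores, relative error,
# CV(RMSE), DNA-copy-number adaptation and accumulated change.

#' Fold change of a median output under perturbation
#'
#' The fold change is the median output level under a perturbation (e.g. a
#' resource-loading activator) divided by the nominal median (the same
#' module with no perturbation). When several replicate fold changes are
#' combined, their log2 values are averaged (the mean of log2 fold changes,
#' not the log2 of the mean), so that dispersion can be computed directly
#' on the log2 scale.
#'
#' @param output_perturbed Median output under perturbation, > 0
#'   (vectorised over replicates).
#' @param output_nominal Nominal median output, > 0.
#' @return An object of class `fold_change` with `fold_change`,
#'   `log2_fold_change` (per replicate) and, when there are replicates,
#'   `mean_log2` and `mean_fold_change = 2^mean_log2`.
#' @examples
#' fc <- fold_change(50, 100)
#' fc$log2_fold_change  # -1
#' @export
fold_change <- function(output_perturbed, output_nominal) {
  if (any(!is.finite(output_nominal)) || any(output_nominal <= 0))
    stop("nominal output must be finite and positive")
  if (any(!is.finite(output_perturbed)) || any(output_perturbed <= 0))
    stop("perturbed output must be finite and positive")
  fc <- output_perturbed / output_nominal
  l2 <- log2(fc)
  structure(list(fold_change = fc, log2_fold_change = l2,
                 mean_log2 = mean(l2), mean_fold_change = 2^mean(l2)),
            class = "fold_change")
}

#' Robustness score of a fold change
#'
#' `100 * (1 - |1 - fold_change|)`: 100% when the output is unchanged,
#' falling linearly as the fold change departs from 1 in either direction.
#' The score is formula-faithful and may be negative for fold changes above
#' 2 (or below 0, which cannot occur for positive medians); it is never
#' above 100.
#'
#' @param fc A [fold_change()] object or a numeric fold-change value
#'   (vectorised).
#' @return Robustness score(s) in percent.
#' @examples
#' robustness_score(1)    # 100
#' robustness_score(0.5)  # 50
#' @export
robustness_score <- function(fc) {
  v <- if (inherits(fc, "fold_change")) fc$fold_change else fc
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("fold change must be finite numeric")
  100 * (1 - abs(1 - v))
}

#' Relative error of a mean on the log scale
#'
#' `(1 / ln 10) * sigma / mu`: the standard deviation propagated to the
#' log10 scale, used to represent error bars of log-displayed quantities
#' more faithfully than a linear-scale s.d.
#'
#' @param mu Mean, > 0.
#' @param sigma Standard deviation, >= 0.
#' @return Dimensionless relative error.
#' @export
relative_error_log <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive")
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' must be non-negative")
  (1 / log(10)) * sigma / mu
}

#' Coefficient-of-variation of the RMSE
#'
#' Goodness of fit normalised by the data scale:
#' `sqrt(mean((y - f)^2)) / mean(y)`. Invariant under a common rescaling of
#' data and fit.
#'
#' @param observed Observed values.
#' @param predicted Model values, same length.
#' @return Dimensionless CV(RMSE).
#' @export
cv_rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (!length(observed)) stop("need at least one observation")
  ybar <- mean(observed)
  if (!is.finite(ybar) || ybar == 0)
    stop("mean of 'observed' must be finite and non-zero")
  sqrt(mean((observed - predicted)^2)) / ybar
}

#' DNA-copy-number adaptation report
#'
#' A marker-delineated bin is adapted to DNA copy-number variation if the
#' log10 of its median output is within `tolerance` (default 5%) of
#' `log10(Y_max)` — i.e. the log-scale robustness score exceeds
#' `100 * (1 - tolerance)`. The adaptation range is the largest sum of the
#' log10 widths (in decades) of contiguous adapted bins.
#'
#' @param bins A [bin_medians()] table (columns `low`, `high`, `median`),
#'   ordered by marker level.
#' @param y_max_fit Fitted output plateau `Y_max`, > 0.
#' @param tolerance Fractional tolerance on `log10(Y_max)` (default 0.05).
#' @return A list of class `adaptation_report` with `bins` (the input plus
#'   an `adapted` flag) and `adaptation_range` (decades).
#' @export
adaptation_report <- function(bins, y_max_fit, tolerance = 0.05) {
  stopifnot(is.data.frame(bins),
            all(c("low", "high", "median") %in% names(bins)))
  if (!is.finite(y_max_fit) || y_max_fit <= 0)
    stop("'y_max_fit' must be positive")
  keep <- is.finite(bins$median) & bins$median > 0
  if (!all(keep)) {
    warning("bins with missing or non-positive medians were skipped")
    bins <- bins[keep, , drop = FALSE]
  }
  lY <- log10(y_max_fit)
  adapted <- abs(log10(bins$median) - lY) <= tolerance * abs(lY)
  widths <- log10(bins$high / bins$low)
  range_dec <- 0
  if (nrow(bins)) {
    runs <- rle(adapted)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (i in which(runs$values))
      range_dec <- max(range_dec, sum(widths[starts[i]:ends[i]]))
  }
  bins$adapted <- adapted
  structure(list(bins = bins, adaptation_range = range_dec),
            class = "adaptation_report")
}

#' Absolute accumulated change of a median time course
#'
#' The sum of absolute log2 changes in median expression between
#' consecutive time points inside a window (default 12-120 h): zero for a
#' perfectly constant output, large for outputs that drift as plasmid
#' dilutes.
#'
#' @param medians Positive medians, time-ordered.
#' @param times Time points (h), same length, increasing.
#' @param t_start,t_end Window bounds (h), defaults 12 and 120.
#' @return Accumulated |log2| change (dimensionless).
#' @export
accumulated_change <- function(medians, times, t_start = 12, t_end = 120) {
  if (length(medians) != length(times)) stop("length mismatch")
  if (any(!is.finite(medians)) || any(medians <= 0))
    stop("medians must be finite and positive")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  inside <- times >= t_start & times <= t_end
  if (sum(inside) < 2)
    stop("need at least 2 time points inside the window")
  m <- medians[inside]
  sum(abs(diff(log2(m))))
}
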