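# Event-level cytometry processing: MEFL calibration, compensation,
# gating, binning, summaries, density estimation and cell-density
# estimation.

channel_check <- function(events, channels) {
  missing <- setdiff(channels, names(events))
  if (length(missing))
    stop("channel(s) not found in the event table: ",
         paste(missing, collapse = ", "))
  invisible(events)
}

#' Locate bead peaks by 1-D clustering
#'
#' Clusters positive bead intensities on the log10 scale with k-means,
#' `k` = number of known peaks, initialised at evenly spaced quantiles
#' (a deterministic surrogate for manual peak identification). Clusters
#' are ordered by centre and matched to the known peak list by rank.
#'
#' @param values Raw bead intensities (positive values used).
#' @param k Number of peaks expected, >= 2.
#' @return Numeric vector of cluster medians (raw units), increasing.
#' @keywords internal
locate_bead_peaks <- function(values, k) {
  if (k < 2) stop("calibration requires at least 2 bead peaks")
  lv <- log10(values[is.finite(values) & values > 0])
  if (length(lv) < 2 * k) stop("too few positive bead events")
  centers <- stats::quantile(lv, probs = seq(0.5, k - 0.5) / k, names = FALSE)
  if (anyDuplicated(centers)) stop("bead peaks are not resolvable")
  km <- stats::kmeans(lv, centers = matrix(centers, ncol = 1))
  med <- vapply(seq_len(k),
                function(i) stats::median(lv[km$cluster == i]), numeric(1))
  sort(10^med)
}

#' Calibrate fluorescence channels to MEFL units with bead standards
#'
#' Fits an affine map on the log10 scale, `log10(MEFL) = slope *
#' log10(raw) + intercept`, between bead cluster medians located by 1-D
#' clustering and the known peak intensities, then transforms the requested
#' channels of the event table.
#'
#' @param events Event table to calibrate.
#' @param beads Bead event table with a `value` column (raw units).
#' @param known_peaks Known MEFL intensities, strictly increasing, length
#'   >= 2.
#' @param channels Channels of `events` to transform (default: all
#'   fluorescence channels, i.e. everything except `sample_id`, `time_s`,
#'   `fsc`, `ssc`).
#' @return A list with `model` (class `calibration_model`: `slope`,
#'   `intercept`, `peak_medians_raw`) and `events` (calibrated table).
#'   Non-positive raw values are left unchanged (they carry no log-scale
#'   information and are discarded downstream).
#' @export
calibrate_mefl <- function(events, beads, known_peaks, channels = NULL) {
  if (!is.data.frame(beads) || !"value" %in% names(beads))
    stop("'beads' must be an event table with a 'value' column")
  if (length(known_peaks) < 2 || is.unsorted(known_peaks, strictly = TRUE) ||
      any(known_peaks <= 0))
    stop("'known_peaks' must be >= 2 strictly increasing positive values")
  k <- length(known_peaks)
  peak_raw <- locate_bead_peaks(beads$value, k)
  fit <- stats::lm(log10(known_peaks) ~ log10(peak_raw))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration failed: non-positive fitted slope")
  model <- structure(list(slope = slope, intercept = intercept,
                          peak_medians_raw = peak_raw),
                     class = "calibration_model")
  if (is.null(channels))
    channels <- setdiff(names(events),
                        c("sample_id", "time_s", "fsc", "ssc", "bin", "peak"))
  channel_check(events, channels)
  for (ch in channels) {
    v <- events[[ch]]
    pos <- is.finite(v) & v > 0
    v[pos] <- 10^(slope * log10(v[pos]) + intercept)
    events[[ch]] <- v
  }
  list(model = model, events = events)
}

#' Build an autofluorescence + spectral-bleed compensation model
#'
#' Autofluorescence is the per-channel mean of wild-type (untransfected)
#' cells. Bleed slopes are least-squares slopes of each secondary channel
#' against the expressed channel in background-subtracted single-colour
#' controls; they form the columns of a unit-diagonal mixing matrix
#' `observed = M %*% true`.
#'
#' @param wild_type Event table of untransfected cells.
#' @param single_colors Named list mapping each channel name to an event
#'   table of cells expressing only that channel.
#' @return An object of class `compensation_model` with `autofluorescence`
#'   (named vector) and `mixing` (matrix).
#' @export
build_compensation <- function(wild_type, single_colors) {
  channels <- names(single_colors)
  if (is.null(channels) || !length(channels))
    stop("'single_colors' must be a named list of event tables")
  channel_check(wild_type, channels)
  af <- vapply(channels, function(ch) mean(wild_type[[ch]]), numeric(1))
  M <- diag(length(channels))
  dimnames(M) <- list(channels, channels)
  for (src in channels) {
    tab <- channel_check(single_colors[[src]], channels)
    x <- tab[[src]] - af[[src]]
    # expression must spread well beyond the background, or the slope is
    # fit to autofluorescence noise
    if (!is.finite(stats::var(x)) || stats::var(x) <= 0 ||
        stats::var(x) <= 4 * stats::var(wild_type[[src]]))
      stop("degenerate single-colour data for channel '", src,
           "': no expression variance above background")
    for (dst in setdiff(channels, src)) {
      yv <- tab[[dst]] - af[[dst]]
      M[dst, src] <- max(0, sum(x * yv) / sum(x * x))
    }
  }
  if (abs(det(M)) < .Machine$double.eps^0.5)
    stop("fitted mixing matrix is singular")
  structure(list(autofluorescence = af, mixing = M),
            class = "compensation_model")
}

#' Apply compensation to an event table
#'
#' Subtracts the autofluorescence vector, then solves the linear mixing
#' system per event (matrix-based signal deconvolution), recovering the
#' true per-channel signals up to measurement noise.
#'
#' @param events Event table containing the model's channels.
#' @param model A [build_compensation()] model.
#' @return The event table with compensated channel values.
#' @export
compensate <- function(events, model) {
  stopifnot(inherits(model, "compensation_model"))
  channels <- names(model$autofluorescence)
  channel_check(events, channels)
  obs <- t(as.matrix(events[channels])) -
    model$autofluorescence  # recycles by row: channels x events
  truev <- solve(model$mixing, obs)
  for (i in seq_along(channels)) events[[channels[i]]] <- truev[i, ]
  events
}

#' Threshold gating against an untransfected control
#'
#' Per-channel thresholds are a quantile (default 99.9%) of the
#' untransfected control's values — a reproducible surrogate for manually
#' drawn gates. With `mode = "any"` an event passes if it exceeds the
#' threshold in at least one listed channel (the "output-positive OR
#' marker-positive" gate); with `mode = "all"` it must exceed every
#' threshold.
#'
#' @param events Event table to gate.
#' @param untransfected Control event table defining the thresholds.
#' @param channels Channels to gate on.
#' @param mode `"any"` or `"all"`.
#' @param quantile Threshold quantile in (0, 1); default 0.999.
#' @return The subset of `events` passing the gate, with the thresholds in
#'   attribute `"thresholds"`. Warns if no event passes.
#' @export
threshold_gate <- function(events, untransfected, channels,
                           mode = c("any", "all"), quantile = 0.999) {
  mode <- match.arg(mode)
  if (!is.data.frame(untransfected) || nrow(untransfected) == 0)
    stop("'untransfected' must be a non-empty event table")
  channel_check(events, channels); channel_check(untransfected, channels)
  stopifnot(quantile > 0, quantile < 1)
  thr <- vapply(channels, function(ch)
    stats::quantile(untransfected[[ch]], probs = quantile, names = FALSE),
    numeric(1))
  pass <- vapply(channels, function(ch) events[[ch]] > thr[[ch]],
                 logical(nrow(events)))
  pass <- if (length(channels) == 1L) as.matrix(pass) else pass
  keep <- if (mode == "any") rowSums(pass) > 0 else rowSums(pass) == length(channels)
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no events pass the threshold gate")
  attr(out, "thresholds") <- thr
  out
}

#' Half-log-decade bin edges
#'
#' Bin edges spanning the positive values of a channel in half-decade steps
#' on the log10 scale, the default binning used for marker-delineated
#' analyses.
#'
#' @param values Channel values (positive values used).
#' @param width Bin width in decades (default 0.5).
#' @return Strictly increasing numeric vector of edges (linear scale).
#' @export
half_log_edges <- function(values, width = 0.5) {
  v <- values[is.finite(values) & values > 0]
  if (!length(v)) stop("no positive values to bin")
  lo <- floor(log10(min(v)) / width) * width
  hi <- ceiling(log10(max(v)) / width) * width
  if (hi <= lo) hi <- lo + width
  10^seq(lo, hi, by = width)
}

#' Assign events to bins on a channel
#'
#' An event with value `v` falls in bin `i` iff
#' `edges[i] < v <= edges[i + 1]` (low edge exclusive, high edge
#' inclusive). Values at or below the lowest edge, or above the highest,
#' are unassigned (`NA`).
#'
#' @param events Event table.
#' @param channel Channel to bin on.
#' @param edges Strictly increasing numeric vector, length >= 2.
#' @return `events` with an integer `bin` column added.
#' @export
assign_bins <- function(events, channel, edges) {
  channel_check(events, channel)
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE))
    stop("'edges' must be >= 2 strictly increasing values")
  events$bin <- as.integer(cut(events[[channel]], breaks = edges,
                               right = TRUE, labels = FALSE))
  attr(events, "bin_edges") <- edges
  events
}

#' Median of the positive values of a channel
#'
#' Median fluorescence is the standard summary statistic; non-positive
#' values (background-subtraction artefacts) are discarded first so that
#' fold changes cannot go negative.
#'
#' @param events Event table.
#' @param channel Channel to summarise.
#' @return Median of the strictly positive values.
#' @export
median_summary <- function(events, channel) {
  channel_check(events, channel)
  v <- events[[channel]]
  v <- v[is.finite(v) & v > 0]
  if (!length(v))
    stop("no positive values in channel '", channel,
         "': median summary undefined")
  stats::median(v)
}

#' Per-bin median summaries
#'
#' Applies [median_summary()] within each marker bin of a binned event
#' table; bins with no positive values are dropped with a warning.
#'
#' @param events Event table with a `bin` column (see [assign_bins()]).
#' @param channel Channel to summarise per bin.
#' @return A data.frame of class `bin_summary` with columns `bin`, `low`,
#'   `high` (bin edges), `n` (events in bin) and `median`.
#' @export
bin_medians <- function(events, channel) {
  if (!"bin" %in% names(events)) stop("events must be binned first")
  edges <- attr(events, "bin_edges")
  if (is.null(edges)) stop("missing 'bin_edges' attribute")
  bins <- sort(unique(events$bin[!is.na(events$bin)]))
  rows <- lapply(bins, function(b) {
    sub <- events[!is.na(events$bin) & events$bin == b, , drop = FALSE]
    med <- tryCatch(median_summary(sub, channel), error = function(e) NA_real_)
    data.frame(bin = b, low = edges[b], high = edges[b + 1],
               n = nrow(sub), median = med)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$median))) {
    warning("bins with no positive values were dropped")
    out <- out[!is.na(out$median), , drop = FALSE]
  }
  structure(out, class = c("bin_summary", "data.frame"))
}

#' Per-event scatterplot density
#'
#' Estimates a 2-D density for plotting by sorting events into a 25 x 25
#' histogram on the transformed scale, with outer bounds at the data range
#' extended by 5% of the range on each side, then assigning each event a
#' density by bilinear interpolation between bin centres. A zero-range
#' axis collapses to a single bin.
#'
#' @param events Event table.
#' @param ch_x,ch_y Channel names.
#' @param transform Transformation applied before binning (default
#'   [log10()]; events non-finite after transformation are returned NA).
#' @param nbins Bins per dimension (default 25).
#' @return Numeric vector of per-event densities (counts per unit area on
#'   the transformed scale).
#' @export
scatter_density <- function(events, ch_x, ch_y, transform = log10,
                            nbins = 25) {
  channel_check(events, c(ch_x, ch_y))
  tx <- transform(events[[ch_x]])
  ty <- transform(events[[ch_y]])
  ok <- is.finite(tx) & is.finite(ty)
  if (sum(ok) < 2) stop("need >= 2 events with finite transformed values")
  axis_setup <- function(v) {
    r <- range(v)
    if (diff(r) == 0)
      return(list(edges = c(r[1] - 0.5, r[1] + 0.5), centers = r[1], n = 1L))
    pad <- 0.05 * diff(r)
    edges <- seq(r[1] - pad, r[2] + pad, length.out = nbins + 1)
    list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
         n = nbins)
  }
  ax <- axis_setup(tx[ok]); ay <- axis_setup(ty[ok])
  ix <- findInterval(tx[ok], ax$edges, rightmost.closed = TRUE)
  iy <- findInterval(ty[ok], ay$edges, rightmost.closed = TRUE)
  counts <- matrix(0, ax$n, ay$n)
  tb <- table(factor(ix, levels = seq_len(ax$n)),
              factor(iy, levels = seq_len(ay$n)))
  counts[] <- as.numeric(tb)
  area <- diff(ax$edges)[1] * diff(ay$edges)[1]
  dens_grid <- counts / (sum(ok) * area)
  interp1 <- function(centers, v) {
    if (length(centers) == 1L)
      return(list(i0 = rep(1L, length(v)), i1 = rep(1L, length(v)),
                  w = rep(0, length(v))))
    i0 <- pmin(pmax(findInterval(v, centers), 1L), length(centers) - 1L)
    w <- (v - centers[i0]) / (centers[i0 + 1] - centers[i0])
    list(i0 = i0, i1 = i0 + 1L, w = pmin(pmax(w, 0), 1))
  }
  gx <- interp1(ax$centers, tx[ok]); gy <- interp1(ay$centers, ty[ok])
  d <- (1 - gx$w) * (1 - gy$w) * dens_grid[cbind(gx$i0, gy$i0)] +
    gx$w * (1 - gy$w) * dens_grid[cbind(gx$i1, gy$i0)] +
    (1 - gx$w) * gy$w * dens_grid[cbind(gx$i0, gy$i1)] +
    gx$w * gy$w * dens_grid[cbind(gx$i1, gy$i1)]
  out <- rep(NA_real_, nrow(events))
  out[ok] <- d
  out
}

#' Estimate cell density from event timestamps
#'
#' Inter-event gaps are approximately exponential; the maximum-likelihood
#' rate is the inverse of their mean. Gaps above the `trim_q` quantile
#' (default 99.9%) are removed first to prevent biasing by large outliers
#' (fluidics pauses). Cell density is the event rate divided by the
#' volumetric flow rate.
#'
#' @param events Event table with a `time_s` column, or a numeric vector of
#'   timestamps (seconds).
#' @param flow_rate Volumetric flow rate (uL/s), > 0.
#' @param trim_q Quantile above which gaps are discarded (default 0.999).
#' @return A list with `event_rate` (events/s), `cells_per_ul`,
#'   `mean_gap_s` and `n_gaps_used`.
#' @export
estimate_cell_density <- function(events, flow_rate, trim_q = 0.999) {
  ts <- if (is.data.frame(events)) {
    channel_check(events, "time_s")
    events$time_s
  } else as.numeric(events)
  stopifnot(flow_rate > 0, trim_q > 0, trim_q <= 1)
  if (length(ts) < 10) stop("need at least 10 events to estimate density")
  gaps <- diff(sort(ts))
  if (length(gaps) < 2) stop("fewer than 2 inter-event gaps: rate undefined")
  cutoff <- stats::quantile(gaps, probs = trim_q, names = FALSE)
  used <- gaps[gaps <= cutoff]
  mean_gap <- mean(used)  # exponential MLE of the mean
  rate <- 1 / mean_gap
  list(event_rate = rate, cells_per_ul = rate / flow_rate,
       mean_gap_s = mean_gap, n_gaps_used = length(used))
}
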