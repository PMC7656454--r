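# Event-table I/O and the end-to-end pipeline: simulate -> calibrate ->
# compensate -> gate -> bin -> fit -> metrics.

#' Read an event table from CSV
#'
#' The canonical event format is plain CSV with columns `sample_id`,
#' `time_s`, `fsc`, `ssc` and one column per fluorescence channel. A
#' `channel_map` renames instrument channel names to the canonical ones.
#'
#' @param path Path to a CSV file.
#' @param channel_map Optional named character vector
#'   `c(canonical = "file_column")`.
#' @param required Channels that must be present after mapping.
#' @return An event table (data.frame).
#' @export
read_events <- function(path, channel_map = NULL, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(channel_map)) {
    for (canonical in names(channel_map)) {
      src <- channel_map[[canonical]]
      if (!src %in% names(events))
        stop("mapped channel column not found: ", src)
      names(events)[names(events) == src] <- canonical
    }
  }
  missing <- setdiff(required, names(events))
  if (length(missing))
    stop("required channel(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  events
}

#' Write an event table to CSV
#'
#' @param events Event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

pipeline_log <- function(verbose, stage, n_in, n_out) {
  if (verbose)
    message(sprintf("[%s] %d events in -> %d events out", stage, n_in, n_out))
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Executes the stages of the cytometry analysis in order: simulate (or
#' load) events, bead-calibrate to MEFL (skipped with a "raw" units flag if
#' no beads), compensate, threshold-gate against an untransfected control,
#' bin on the marker, fit the configured model and compute bin medians and
#' the adaptation report. Each stage logs event counts in/out. With a fixed
#' seed the outputs are bit-identical across runs.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{transfection}{a [transfection_config()] (used when `events` is
#'       NULL).}
#'     \item{beads}{optional [bead_config()]; when absent, calibration is
#'       skipped and units are flagged `"raw"`.}
#'     \item{known_peaks}{MEFL peak list for calibration (default: the bead
#'       config's true peaks).}
#'     \item{gate_channels, gate_mode, gate_quantile}{gating setup
#'       (defaults: `c("tx_marker", "output")`, `"any"`, 0.999).}
#'     \item{model}{`"iffl"` or `"ur"` — which model to fit (default: the
#'       transfection config's model).}
#'     \item{subsample}{equalise bins before fitting (default FALSE).}
#'   }
#' @param events Optional pre-generated event table (skips simulation).
#' @param untransfected Optional control table; by default one is generated
#'   from the transfection config with `transfected_fraction = 0`.
#' @param seed Seed applied to all stochastic stages.
#' @param verbose Log per-stage event counts (default TRUE).
#' @return A list of class `pipeline_result`: `events` (processed table),
#'   `calibration`, `compensation`, `fit`, `bin_medians`, `adaptation`,
#'   `units`, `counts` (per-stage event counts), `seed`.
#' @export
run_pipeline <- function(config, events = NULL, untransfected = NULL,
                         seed = NULL, verbose = TRUE) {
  stopifnot(is.list(config))
  tcfg <- config$transfection
  if (is.null(events)) {
    if (is.null(tcfg)) stop("config$transfection required to simulate events")
    if (!is.null(seed)) tcfg$seed <- seed
    events <- generate_transfection(tcfg)
    pipeline_log(verbose, "simulate", tcfg$n_cells, nrow(events))
  }
  counts <- c(input = nrow(events))
  channels <- c("tx_marker", "output", "competitor_marker")

  if (is.null(untransfected)) {
    if (is.null(tcfg)) stop("supply 'untransfected' or config$transfection")
    ucfg <- tcfg
    ucfg$transfected_fraction <- 0
    ucfg$n_cells <- max(2000L, tcfg$n_cells %/% 10L)
    ucfg$seed <- if (!is.null(seed)) seed + 1L else NULL
    ucfg$sample_id <- "untransfected"
    untransfected <- generate_transfection(ucfg)
  }

  calibration <- NULL
  units <- "raw"
  if (!is.null(config$beads)) {
    bcfg <- config$beads
    if (!is.null(seed)) bcfg$seed <- seed + 2L
    beads <- generate_beads(bcfg)
    known <- config$known_peaks
    if (is.null(known)) known <- bcfg$peak_mefl_values
    cal <- calibrate_mefl(events, beads, known, channels)
    events <- cal$events
    calibration <- cal$model
    untransfected <- calibrate_mefl(untransfected, beads, known,
                                    channels)$events
    units <- "MEFL"
    pipeline_log(verbose, "calibrate", counts[["input"]], nrow(events))
  }

  # autofluorescence is always subtracted (from the untransfected control);
  # bleed deconvolution additionally needs single-colour controls
  if (!is.null(config$single_colors)) {
    compensation <- build_compensation(untransfected, config$single_colors)
  } else {
    af <- vapply(channels, function(ch) mean(untransfected[[ch]]),
                 numeric(1))
    compensation <- structure(
      list(autofluorescence = af,
           mixing = diag(length(channels))),
      class = "compensation_model")
    dimnames(compensation$mixing) <- list(channels, channels)
  }
  events <- compensate(events, compensation)
  untransfected <- compensate(untransfected, compensation)
  pipeline_log(verbose, "compensate", nrow(events), nrow(events))

  gate_channels <- config$gate_channels
  if (is.null(gate_channels)) gate_channels <- c("tx_marker", "output")
  gate_mode <- if (is.null(config$gate_mode)) "any" else config$gate_mode
  gate_q <- if (is.null(config$gate_quantile)) 0.999 else config$gate_quantile
  gated <- threshold_gate(events, untransfected, gate_channels,
                          mode = gate_mode, quantile = gate_q)
  counts["gated"] <- nrow(gated)
  pipeline_log(verbose, "gate", nrow(events), nrow(gated))

  binned <- assign_bins(gated, "tx_marker",
                        half_log_edges(gated$tx_marker))
  bins <- bin_medians(binned, "output")
  pipeline_log(verbose, "bin", nrow(gated), sum(bins$n))

  model <- config$model
  if (is.null(model)) model <- if (!is.null(tcfg)) tcfg$model else "iffl"
  subsample <- isTRUE(config$subsample)
  fit <- if (model == "iffl") {
    fit_iffl(binned, subsample = subsample,
             seed = if (!is.null(seed)) seed + 3L else NULL)
  } else {
    fit_ur(binned)
  }
  pipeline_log(verbose, "fit", nrow(binned), fit$n_events)

  adaptation <- if (model == "iffl")
    adaptation_report(bins, fit$Y_max) else NULL

  structure(list(events = binned, calibration = calibration,
                 compensation = compensation, fit = fit,
                 bin_medians = bins, adaptation = adaptation,
                 units = units, counts = counts, seed = seed),
            class = "pipeline_result")
}

#' Robustness comparison of two populations
#'
#' Convenience wrapper for the resource-loading experiment: given gated
#' event tables for a module at nominal and loaded resource levels,
#' computes the median fold change and robustness score of the output.
#'
#' @param nominal,loaded Event tables (already gated).
#' @param output_ch Output channel (default `"output"`).
#' @return A list with `fold_change` ([fold_change()]) and `robustness`
#'   (percent).
#' @export
loading_robustness <- function(nominal, loaded, output_ch = "output") {
  fc <- fold_change(median_summary(loaded, output_ch),
                    median_summary(nominal, output_ch))
  list(fold_change = fc, robustness = robustness_score(fc))
}
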