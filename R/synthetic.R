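# Synthetic transient-transfection cytometry: per-cell event tables, bead
# standards and event-timestamp streams with the statistical structure the
# downstream pipeline assumes.

#' Configuration of a synthetic transient transfection
#'
#' Describes the measurement model used to emulate per-cell flow cytometry
#' of a transiently transfected population: a fraction of cells takes up
#' plasmid with log10-normal copy numbers spanning several decades; each
#' transfected cell expresses a TX marker `z = V_z * D * R` and an output
#' from the configured steady-state model (`iffl` or `ur`); channels receive
#' multiplicative log-normal measurement noise, linear spectral bleed and
#' additive normal autofluorescence (which may push values non-positive, as
#' in real data after background subtraction).
#'
#' @param n_cells Number of events to generate.
#' @param transfected_fraction Fraction of cells receiving plasmid, in
#'   \[0, 1\].
#' @param log10_copy_mean,log10_copy_sd Mean and s.d. of log10 plasmid
#'   copies per transfected cell. The defaults (1.5, 1.0) span roughly three
#'   decades of uptake, the spread seen in transient transfection.
#' @param noise_sd_log10 S.d. of multiplicative measurement noise on the
#'   log10 scale (default 0.2).
#' @param autofluor_mean,autofluor_sd Additive per-channel background
#'   (MEFL); defaults 100 and 30.
#' @param bleed_matrix Square channel-mixing matrix with unit diagonal and
#'   non-negative entries; `observed = bleed_matrix %*% true`. Default
#'   identity.
#' @param model `"iffl"` or `"ur"`.
#' @param params An [iffl_params()] or [ur_params()] object matching
#'   `model`. For the UR model, marker levels still require a `V_z`, taken
#'   from `V_z`.
#' @param V_z Marker capacity used to form `z = V_z * D * R` (for
#'   `model = "ur"`; for `"iffl"` the value inside `params` is used).
#' @param R Lumped free-resource level of the condition (default 1); lower
#'   it to emulate resource loading by a co-transfected activator.
#' @param loading Optional TA marker level recorded per cell in the
#'   `competitor_marker` channel, scaled per cell by `D / 10^log10_copy_mean`
#'   (co-transfected plasmids share uptake).
#' @param event_rate Mean event rate of the acquisition (events/s).
#' @param seed Optional RNG seed for reproducibility.
#' @param sample_id Sample label attached to every event.
#' @return A list of class `transfection_config`.
#' @export
transfection_config <- function(n_cells = 20000,
                                transfected_fraction = 0.7,
                                log10_copy_mean = 1.5,
                                log10_copy_sd = 1.0,
                                noise_sd_log10 = 0.2,
                                autofluor_mean = 100,
                                autofluor_sd = 30,
                                bleed_matrix = diag(3),
                                model = c("iffl", "ur"),
                                params = iffl_params(V_y = 1000,
                                                     epsilon = 10,
                                                     V_z = 5),
                                V_z = 5,
                                R = 1,
                                loading = 0,
                                event_rate = 500,
                                seed = NULL,
                                sample_id = "sample1") {
  model <- match.arg(model)
  stopifnot(n_cells >= 1, transfected_fraction >= 0,
            transfected_fraction <= 1, is.finite(log10_copy_mean),
            log10_copy_sd >= 0, noise_sd_log10 >= 0, autofluor_sd >= 0,
            R >= 0, loading >= 0, event_rate > 0)
  if (!is.matrix(bleed_matrix) || nrow(bleed_matrix) != 3 ||
      ncol(bleed_matrix) != 3 || any(bleed_matrix < 0) ||
      any(diag(bleed_matrix) != 1))
    stop("'bleed_matrix' must be a 3x3 non-negative matrix with unit diagonal")
  if (model == "iffl" && !inherits(params, "iffl_params"))
    stop("model 'iffl' requires iffl_params")
  if (model == "ur" && !inherits(params, "ur_params"))
    stop("model 'ur' requires ur_params")
  structure(as.list(environment()), class = "transfection_config")
}

#' Generate a synthetic transfection event table
#'
#' Draws per-cell plasmid copies, evaluates the configured steady-state
#' model, and applies the measurement model of [transfection_config()].
#' Channels are `tx_marker`, `output` and `competitor_marker` (in that
#' order for the bleed matrix). Forward/side scatter are filled with
#' log-normal values so scatter-based operations have realistic input.
#' The generating truth (copies, true channel values) is attached in the
#' `"truth"` attribute for use as a test oracle.
#'
#' @param cfg A [transfection_config()].
#' @return An event table: data.frame with columns `sample_id`, `time_s`,
#'   `fsc`, `ssc`, `tx_marker`, `output`, `competitor_marker`.
#' @examples
#' ev <- generate_transfection(transfection_config(n_cells = 500, seed = 1))
#' head(ev)
#' @export
generate_transfection <- function(cfg) {
  stopifnot(inherits(cfg, "transfection_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_cells
  transfected <- stats::runif(n) < cfg$transfected_fraction
  D <- numeric(n)
  D[transfected] <- 10^stats::rnorm(sum(transfected), cfg$log10_copy_mean,
                                    cfg$log10_copy_sd)
  if (cfg$model == "iffl") {
    V_z <- cfg$params$V_z
    y_true <- iffl_output(D, cfg$R, cfg$params)
  } else {
    V_z <- cfg$V_z
    y_true <- ur_output(V_z * D * cfg$R, cfg$params)
  }
  z_true <- V_z * D * cfg$R
  comp_true <- cfg$loading * D / 10^cfg$log10_copy_mean
  true_mat <- cbind(tx_marker = z_true, output = y_true,
                    competitor_marker = comp_true)
  noisy <- true_mat * 10^matrix(stats::rnorm(3L * n, 0, cfg$noise_sd_log10),
                                n, 3L)
  mixed <- noisy %*% t(cfg$bleed_matrix)
  af <- matrix(stats::rnorm(3L * n, cfg$autofluor_mean, cfg$autofluor_sd),
               n, 3L)
  observed <- mixed + af
  events <- data.frame(
    sample_id = cfg$sample_id,
    time_s = cumsum(stats::rexp(n, rate = cfg$event_rate)),
    fsc = 10^stats::rnorm(n, 5, 0.1),
    ssc = 10^stats::rnorm(n, 4.5, 0.15),
    tx_marker = observed[, 1],
    output = observed[, 2],
    competitor_marker = observed[, 3]
  )
  attr(events, "truth") <- data.frame(
    copies = D, transfected = transfected,
    tx_marker = z_true, output = y_true, competitor_marker = comp_true)
  attr(events, "config") <- cfg
  events
}

#' Configuration of a synthetic bead standard
#'
#' Calibration beads carry several sub-populations ("peaks") with known MEFL
#' intensities. Each generated event is a peak value with log-normal
#' within-peak scatter of the stated coefficient of variation, optionally
#' mapped to raw instrument units by an affine map on the log10 scale
#' (`log10(raw) = (log10(MEFL) - intercept) / slope`), so that calibration
#' must recover `slope`/`intercept`.
#'
#' @param peak_mefl_values Strictly increasing positive MEFL intensities.
#' @param peak_cv Within-peak coefficient of variation, >= 0.
#' @param events_per_peak Events generated per peak.
#' @param slope,intercept Affine map from log10(raw) to log10(MEFL)
#'   (defaults 1 and 0: raw units already MEFL).
#' @param seed Optional RNG seed.
#' @return A list of class `bead_config`.
#' @export
bead_config <- function(peak_mefl_values = c(1e2, 1e3, 1e4, 1e5, 1e6),
                        peak_cv = 0.05, events_per_peak = 2000,
                        slope = 1, intercept = 0, seed = NULL) {
  stopifnot(all(peak_mefl_values > 0),
            !is.unsorted(peak_mefl_values, strictly = TRUE),
            peak_cv >= 0, events_per_peak >= 1, slope > 0)
  structure(as.list(environment()), class = "bead_config")
}

#' Generate a synthetic bead event table
#'
#' @param cfg A [bead_config()].
#' @return A data.frame with columns `sample_id`, `time_s`, `value` (raw
#'   units), and `peak` (true peak index, for test oracles).
#' @export
generate_beads <- function(cfg) {
  stopifnot(inherits(cfg, "bead_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- length(cfg$peak_mefl_values)
  n <- k * cfg$events_per_peak
  peak <- rep(seq_len(k), each = cfg$events_per_peak)
  # log-normal with sdlog chosen so the CV matches peak_cv
  sdlog <- sqrt(log(1 + cfg$peak_cv^2))
  mefl <- cfg$peak_mefl_values[peak] *
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  raw <- 10^((log10(mefl) - cfg$intercept) / cfg$slope)
  ord <- sample.int(n)
  data.frame(sample_id = "beads",
             time_s = cumsum(stats::rexp(n, rate = 1000)),
             value = raw[ord], peak = peak[ord])
}

#' Generate exponential inter-event timestamps
#'
#' Event arrival in a flow cytometer is approximately Poisson, so gaps
#' between consecutive events are i.i.d. exponential with mean `1/rate`.
#'
#' @param rate Mean event rate (events/s), > 0.
#' @param n Number of events.
#' @param seed Optional RNG seed.
#' @return Non-decreasing numeric vector of `n` timestamps (seconds).
#' @export
generate_timestamps <- function(rate, n, seed = NULL) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cumsum(stats::rexp(n, rate = rate))
}
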