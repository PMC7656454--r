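# Least-squares estimation of iFFL, UR and resource-competition model
# parameters from event tables.

#' Equalise bin occupancy by subsampling
#'
#' Bins an event table into half-log-decade marker bins and draws the same
#' number of events from every non-empty bin (the size of the smallest
#' non-empty bin, capped at `max_per_bin`), preventing the fit from being
#' dominated by the heavily populated low-marker (untransfected) bins.
#'
#' Sparse bins at the extremes of the marker range (fewer than
#' `min_bin_events` events) are dropped before the equalisation count is
#' computed, so a handful of outlier cells cannot collapse the subsample.
#'
#' @param events Event table.
#' @param channel Marker channel to bin on.
#' @param max_per_bin Cap on events kept per bin (default 3000).
#' @param min_bin_events Bins with fewer events are dropped (default 50).
#' @param seed Optional RNG seed for the subsample.
#' @return The subsampled event table (binned, with `bin_edges` attribute).
#' @export
subsample_bins <- function(events, channel, max_per_bin = 3000,
                           min_bin_events = 50, seed = NULL) {
  channel_check(events, channel)
  if (!is.null(seed)) set.seed(seed)
  pos <- events[is.finite(events[[channel]]) & events[[channel]] > 0, ,
                drop = FALSE]
  binned <- assign_bins(pos, channel, half_log_edges(pos[[channel]]))
  counts <- table(binned$bin)
  counts <- counts[counts >= min_bin_events]
  if (!length(counts)) stop("no bin reaches 'min_bin_events' events")
  binned <- binned[!is.na(binned$bin) &
                     binned$bin %in% as.integer(names(counts)), , drop = FALSE]
  n_take <- min(min(counts), max_per_bin)
  idx <- unlist(lapply(names(counts), function(b) {
    rows <- which(!is.na(binned$bin) & binned$bin == as.integer(b))
    if (length(rows) > n_take) sample(rows, n_take) else rows
  }))
  out <- binned[sort(idx), , drop = FALSE]
  attr(out, "bin_edges") <- attr(binned, "bin_edges")
  attr(out, "n_per_bin") <- n_take
  out
}

#' Fit the iFFL marker-vs-output model to an event table
#'
#' Fits `y = a * z / (1 + z / Z_50)` (the marker form of the iFFL
#' steady-state model, with `a = V_y / V_z` the low-marker slope) by
#' bounded Levenberg-Marquardt least squares on log10-transformed output,
#' using log10 parameters internally. Only the lumped combinations
#' `Y_max = a * Z_50`, `Z_50` and the slope `a` are identifiable from this
#' curve; the returned [iffl_params()] uses the `V_z = 1` normalisation
#' (`V_y = a`, `epsilon = Z_50`).
#'
#' Starting values come from data quantiles (`Y_max`: 90th-percentile
#' output; `Z_50`: median marker). If the fitted `Z_50` escapes beyond the
#' observed marker range the data show no saturation (e.g. an unregulated
#' module) and the report flags it (`z50_escaped`).
#'
#' @param events Event table.
#' @param marker_ch,output_ch Channel names (default `"tx_marker"`,
#'   `"output"`).
#' @param subsample Equalise half-log marker bins before fitting via
#'   [subsample_bins()].
#' @param max_per_bin,min_bin_events,seed Passed to [subsample_bins()].
#' @return A list of class `iffl_fit`: `params` ([iffl_params()], `V_z = 1`
#'   convention), `Y_max`, `Z_50`, `slope0`, `cv_rmse` (on the log10
#'   fitting scale), `n_events`, `converged`, `z50_escaped`.
#' @export
fit_iffl <- function(events, marker_ch = "tx_marker", output_ch = "output",
                     subsample = FALSE, max_per_bin = 3000,
                     min_bin_events = 50, seed = NULL) {
  channel_check(events, c(marker_ch, output_ch))
  if (subsample)
    events <- subsample_bins(events, marker_ch, max_per_bin,
                             min_bin_events, seed)
  z <- events[[marker_ch]]; y <- events[[output_ch]]
  ok <- is.finite(z) & is.finite(y) & z > 0 & y > 0
  if (sum(ok) < 100)
    stop("need >= 100 events with positive marker and output (have ",
         sum(ok), ")")
  z <- z[ok]; y <- y[ok]
  ly <- log10(y); lz <- log10(z)
  z50_hi <- max(z) * 1e4
  start <- c(lYmax = log10(stats::quantile(y, 0.9, names = FALSE)),
             lZ50 = log10(stats::median(z)))
  lower <- c(min(ly) - 6, min(lz) - 6)
  upper <- c(max(ly) + 6, log10(z50_hi))
  model_ly <- function(p, lz) {
    # log10 of a*z/(1+z/Z50) with a = Ymax/Z50
    p[["lYmax"]] + lz - p[["lZ50"]] - log10(1 + 10^(lz - p[["lZ50"]]))
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) ly - model_ly(p, lz),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    stop("iFFL fit did not converge (info = ", fit$info,
         "): start = ", paste(signif(10^start, 3), collapse = ", "),
         "; bounds Z_50 <= ", signif(z50_hi, 3))
  p <- fit$par
  Y_max <- 10^p[["lYmax"]]; Z_50 <- 10^p[["lZ50"]]
  # saturation must be reached within the bulk of the data for the plateau
  # to be measured; a Z_50 beyond the 90th marker percentile means the
  # curve is effectively linear over the data (unregulated behaviour)
  escaped <- Z_50 > stats::quantile(z, 0.9, names = FALSE)
  if (escaped)
    warning("fitted Z_50 lies beyond the bulk of the marker distribution: ",
            "no saturation detected (data may be unregulated)")
  params <- iffl_params(V_y = Y_max / Z_50, epsilon = Z_50, V_z = 1)
  structure(list(params = params, Y_max = Y_max, Z_50 = Z_50,
                 slope0 = Y_max / Z_50,
                 cv_rmse = cv_rmse(ly, model_ly(p, lz)),
                 n_events = length(z), converged = TRUE,
                 z50_escaped = escaped),
            class = "iffl_fit")
}

#' @export
print.iffl_fit <- function(x, ...) {
  cat("iFFL marker-vs-output fit (V_z = 1 normalisation)\n")
  cat(sprintf("  Y_max  = %g\n  Z_50   = %g%s\n  slope0 = %g (V_y/V_z)\n",
              x$Y_max, x$Z_50,
              if (x$z50_escaped) "  [beyond data range: no saturation]" else "",
              x$slope0))
  cat(sprintf("  CV(RMSE) on log10 scale = %.4g  (n = %d events)\n",
              x$cv_rmse, x$n_events))
  invisible(x)
}

#' Fit the unregulated linear model to an event table
#'
#' The UR model is `output = m * marker`; on the log10 scale this is a
#' unit-slope line with offset `log10(m)`, so the least-squares estimate is
#' `m = 10^mean(log10(output) - log10(marker))` over events positive in
#' both channels.
#'
#' @inheritParams fit_iffl
#' @return A list of class `ur_fit`: `params` ([ur_params()]), `m`,
#'   `cv_rmse` (log10 scale), `n_events`.
#' @export
fit_ur <- function(events, marker_ch = "tx_marker", output_ch = "output") {
  channel_check(events, c(marker_ch, output_ch))
  z <- events[[marker_ch]]; y <- events[[output_ch]]
  ok <- is.finite(z) & is.finite(y) & z > 0 & y > 0
  if (sum(ok) < 100)
    stop("need >= 100 events with positive marker and output")
  lz <- log10(z[ok]); ly <- log10(y[ok])
  if (stats::var(lz) == 0) stop("zero-variance marker: slope undefined")
  lm_off <- mean(ly - lz)
  structure(list(params = ur_params(10^lm_off), m = 10^lm_off,
                 cv_rmse = cv_rmse(ly, lz + lm_off),
                 n_events = sum(ok)),
            class = "ur_fit")
}

#' Fit the resource-competition dose-response model across activators
#'
#' Simultaneous bounded least squares over one or more Gal4-TA dose-response
#' curves, with a user-designated subset of parameters shared across
#' activators, the rest fit per activator, and any parameter optionally held
#' fixed. Residuals are computed on the raw medians (replicate medians
#' should be pooled into `dose_tables` beforehand). The loading law is the
#' competitive-sequestration form; because the resource scale is arbitrary,
#' `R_tot` is fixed to 1 by default (only ratios such as `R_TX / k12` are
#' identifiable).
#'
#' Parameters are optimised on the log10 scale with +/- 6 decade bounds
#' around their starting values, keeping them positive and finite.
#'
#' @param dose_tables Named list, one element per activator, each a
#'   data.frame with columns `u2`, `output1`, `output2` (pooled replicate
#'   medians).
#' @param shared Character vector of parameter names shared across
#'   activators, chosen from `alpha1`, `alpha2`, `k12`, `k21`, `k22`,
#'   `R_tot`, `k_sq`. Default: amplitudes and resource constants global;
#'   `k21` and `k_sq` per activator.
#' @param fixed Named numeric vector of parameters held constant (default
#'   `c(R_tot = 1)`, the resource unit convention). Fixed parameters apply
#'   to all activators.
#' @param start Optional named numeric vector overriding the data-driven
#'   starting values.
#' @return A list of class `resource_fit`: `params` (named list of
#'   [resource_params()] per activator), `estimates` (data.frame of fitted
#'   values), `cv_rmse` (per curve and output), `converged`.
#' @export
fit_resource_model <- function(dose_tables,
                               shared = c("alpha1", "alpha2", "k12", "k22"),
                               fixed = c(R_tot = 1),
                               start = NULL) {
  if (!is.list(dose_tables) || is.null(names(dose_tables)) ||
      !length(dose_tables))
    stop("'dose_tables' must be a named list of dose-response tables")
  all_par <- c("alpha1", "alpha2", "k12", "k21", "k22", "R_tot", "k_sq")
  if (!all(shared %in% all_par))
    stop("unknown shared parameter(s): ",
         paste(setdiff(shared, all_par), collapse = ", "))
  if (length(fixed) && (is.null(names(fixed)) ||
                        !all(names(fixed) %in% all_par) || any(fixed <= 0)))
    stop("'fixed' must be a named vector of positive values from: ",
         paste(all_par, collapse = ", "))
  tas <- names(dose_tables)
  for (ta in tas) {
    tab <- dose_tables[[ta]]
    if (!is.data.frame(tab) ||
        !all(c("u2", "output1", "output2") %in% names(tab)))
      stop("dose table '", ta, "' needs columns u2, output1, output2")
    if (nrow(tab) < 4)
      stop("dose table '", ta, "' needs >= 4 dose points")
  }
  shared <- setdiff(shared, names(fixed))
  per_ta <- setdiff(all_par, c(shared, names(fixed)))
  n_free <- length(shared) + length(per_ta) * length(tas)
  n_obs <- sum(vapply(dose_tables, nrow, integer(1))) * 2L
  if (n_free >= n_obs)
    stop("under-determined sharing spec: ", n_free, " free parameters for ",
         n_obs, " observations")

  par_names <- c(shared,
                 unlist(lapply(tas, function(ta) paste(per_ta, ta, sep = "."))))
  default_start <- function() {
    u_all <- unlist(lapply(dose_tables, `[[`, "u2"))
    o1 <- unlist(lapply(dose_tables, `[[`, "output1"))
    o2 <- unlist(lapply(dose_tables, `[[`, "output2"))
    u_pos <- u_all[u_all > 0]
    c(alpha1 = max(o1), alpha2 = 2 * max(o2), k12 = 1, k22 = 1,
      k21 = stats::median(u_pos), R_tot = 1, k_sq = stats::median(u_pos))
  }
  s0 <- default_start()
  if (!is.null(start)) s0[names(start)] <- start
  p0 <- stats::setNames(numeric(length(par_names)), par_names)
  for (nm in par_names) p0[nm] <- s0[[sub("\\..*$", "", nm)]]
  get_par <- function(p, base, ta) {
    if (base %in% names(fixed)) return(fixed[[base]])
    if (base %in% shared) p[[base]] else p[[paste(base, ta, sep = ".")]]
  }
  params_for <- function(p, ta)
    resource_params(
      alpha1 = get_par(p, "alpha1", ta), alpha2 = get_par(p, "alpha2", ta),
      k12 = get_par(p, "k12", ta), k21 = get_par(p, "k21", ta),
      k22 = get_par(p, "k22", ta),
      loading_law = loading_law_competitive(
        R_tot = get_par(p, "R_tot", ta), k_sq = get_par(p, "k_sq", ta)))
  residuals_fn <- function(lp) {
    p <- 10^lp  # parameters fit on the log10 scale to stay positive
    unlist(lapply(tas, function(ta) {
      tab <- dose_tables[[ta]]
      pred <- resource_dose_response(tab$u2, params_for(p, ta))
      c(tab$output1 - pred$output1, tab$output2 - pred$output2)
    }))
  }
  # the deviance surface has local minima along the alpha/k ridges, so the
  # Levenberg-Marquardt search is restarted from a small grid of scale
  # offsets on the dissociation constants and the best fit kept
  offsets <- expand.grid(k12 = c(-1, 0, 1), k_sq = c(-1, 0, 1))
  fit <- NULL
  for (i in seq_len(nrow(offsets))) {
    pi0 <- log10(p0)
    pi0[grep("^k12", names(pi0))] <- pi0[grep("^k12", names(pi0))] +
      offsets$k12[i]
    pi0[grep("^k_sq", names(pi0))] <- pi0[grep("^k_sq", names(pi0))] +
      offsets$k_sq[i]
    cand <- tryCatch(
      minpack.lm::nls.lm(par = pi0, fn = residuals_fn,
                         lower = log10(p0) - 6, upper = log10(p0) + 6,
                         control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info != 0 &&
        (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  if (is.null(fit))
    stop("resource-model fit failed from every start; start = ",
         paste(signif(p0, 3), collapse = ", "),
         "; bounds +/- 6 decades around start")
  converged <- fit$info %in% c(1:4, 6, 7)
  if (!converged)
    warning("resource-model fit stopped at the iteration limit; ",
            "estimates may sit in a flat likelihood region")
  p_hat <- 10^fit$par
  params <- stats::setNames(lapply(tas, function(ta) params_for(p_hat, ta)),
                            tas)
  cv <- do.call(rbind, lapply(tas, function(ta) {
    tab <- dose_tables[[ta]]
    pred <- resource_dose_response(tab$u2, params[[ta]])
    data.frame(ta = ta,
               cv_rmse_output1 = cv_rmse(tab$output1, pred$output1),
               cv_rmse_output2 = cv_rmse(tab$output2, pred$output2))
  }))
  estimates <- data.frame(parameter = names(p_hat), value = unname(p_hat))
  structure(list(params = params, estimates = estimates, cv_rmse = cv,
                 converged = converged),
            class = "resource_fit")
}
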