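# Mass-action ODE simulation of the iFFL during transient transfection.

#' Dynamic simulation parameters
#'
#' Bundles the mechanistic rate constants with the conditions of a transient
#' transfection: free transcriptional (`R_TX`) and translational (`R_TL`)
#' resource levels, the dilution rate `mu` (1/h) from cell growth and
#' division (acting on plasmid, mRNA and protein), and the initial plasmid
#' copy number `D0`. The TX-marker gene is co-simulated with its own
#' constants (`phi_z`, `delta_z`, `beta_z`, `kappa_z`, `gamma_z`), which
#' default to the output gene's values; the marker mRNA is not cleaved by
#' the endoRNase.
#'
#' @param constants A [mechanistic_constants()] object.
#' @param R_TX,R_TL Free-resource levels, >= 0.
#' @param mu Dilution rate (1/h), >= 0.
#' @param D0 Initial plasmid copies per cell, >= 0.
#' @param phi_z,delta_z,beta_z,kappa_z,gamma_z Marker-gene constants
#'   (default: the output gene's values).
#' @return An object of class `dynamic_params`.
#' @export
dynamic_params <- function(constants = mechanistic_constants(),
                           R_TX = 1, R_TL = 1, mu = 0, D0 = 1,
                           phi_z = constants$phi_y,
                           delta_z = constants$delta_y,
                           beta_z = constants$beta_y,
                           kappa_z = constants$kappa_y,
                           gamma_z = constants$gamma_y) {
  stopifnot(inherits(constants, "mechanistic_constants"))
  for (nm in c("R_TX", "R_TL", "mu", "D0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single finite non-negative number", nm))
  }
  for (nm in c("phi_z", "delta_z", "beta_z", "kappa_z", "gamma_z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm))
  }
  structure(list(constants = constants, R_TX = R_TX, R_TL = R_TL, mu = mu,
                 D0 = D0, phi_z = phi_z, delta_z = delta_z, beta_z = beta_z,
                 kappa_z = kappa_z, gamma_z = gamma_z),
            class = "dynamic_params")
}

iffl_rhs <- function(t, state, parms) {
  cc <- parms$constants
  R_TX <- parms$R_TX_fun(t)
  R_TL <- parms$R_TL
  mu <- parms$mu
  with(as.list(state), {
    tx <- D * R_TX / cc$k  # sub-saturation transcription drive
    dD <- -mu * D
    dm_x <- cc$phi_x * tx - cc$delta_x * m_x - mu * m_x
    dm_y <- cc$phi_y * tx - cc$delta_y * m_y - mu * m_y -
      cc$theta * x * m_y / (cc$K_M + m_y)
    dm_z <- parms$phi_z * tx - parms$delta_z * m_z - mu * m_z
    dx <- cc$beta_x * R_TL * m_x / cc$kappa_x - (cc$gamma_x + mu) * x
    dy <- cc$beta_y * R_TL * m_y / cc$kappa_y - (cc$gamma_y + mu) * y
    dz <- parms$beta_z * R_TL * m_z / parms$kappa_z - (parms$gamma_z + mu) * z
    list(c(dD, dm_x, dm_y, dm_z, dx, dy, dz))
  })
}

run_ode <- function(params, t_grid, R_TX_fun, rtol, atol) {
  parms <- c(unclass(params), list(R_TX_fun = R_TX_fun))
  y0 <- c(D = params$D0, m_x = 0, m_y = 0, m_z = 0, x = 0, y = 0, z = 0)
  sol <- try(deSolve::ode(y = y0, times = t_grid, func = iffl_rhs,
                          parms = parms, method = "lsoda",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol)))
    stop("stiff integration failed for D0 = ", params$D0, ", mu = ",
         params$mu, ", R_TX = ", params$R_TX, ": ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "non-finite trajectory")
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  # lsoda can undershoot 0 by ~atol near absorbing states; clamp.
  out[-1][out[-1] < 0] <- 0
  structure(out, class = c("time_course", "data.frame"))
}

#' Simulate iFFL dynamics during transient transfection
#'
#' Integrates the mass-action model of the iFFL with exponential plasmid
#' dilution: `dD/dt = -mu*D`; mRNA production at rate `phi_i * D * R_TX / k`
#' (sub-saturation regime), first-order mRNA decay plus dilution, and
#' Michaelis-Menten cleavage of the output mRNA by the endoRNase
#' (`theta * x * m_y / (K_M + m_y)`); protein production at
#' `beta_i * R_TL * m_i / kappa_i` with decay plus dilution. With `mu = 0`
#' and `m_y << K_M`, the steady-state output equals the closed form of
#' [iffl_output()] evaluated at `D0` and `R = R_TX * R_TL`.
#'
#' @param params A [dynamic_params()] object.
#' @param t_grid Strictly increasing time points (hours); default 0-120 h at
#'   0.5 h steps.
#' @param rtol,atol Integration tolerances (relative default 1e-8).
#' @return A `time_course` data.frame with columns `time`, `D`, `m_x`,
#'   `m_y`, `m_z`, `x` (endoRNase), `y` (output), `z` (TX marker).
#' @examples
#' tc <- simulate_iffl(dynamic_params(D0 = 5), t_grid = seq(0, 50, 1))
#' tail(tc$y, 1)
#' @export
simulate_iffl <- function(params, t_grid = seq(0, 120, by = 0.5),
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "dynamic_params"))
  if (length(t_grid) < 1L || is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be non-empty and strictly increasing")
  run_ode(params, t_grid, R_TX_fun = function(t) params$R_TX,
          rtol = rtol, atol = atol)
}

#' Simulate a step drop in transcriptional resources
#'
#' Runs the iFFL to (quasi) steady state, multiplies `R_TX` by `fold_drop`
#' at `t_step`, and continues the simulation. Reports the adaptation time:
#' the first time after the step at which the output re-enters a band of
#' `+/- band` around its pre-step level and stays inside it for the rest of
#' the simulated window.
#'
#' @param params A [dynamic_params()] object (use `mu = 0` for a clean
#'   steady-state experiment).
#' @param t_step Time of the resource drop (h), >= 0.
#' @param fold_drop Multiplier applied to `R_TX` at `t_step`, in (0, 1].
#' @param t_end End of the simulation (h); must exceed `t_step`.
#' @param dt Output grid resolution (h).
#' @param band Half-width of the recovery band as a fraction of the
#'   pre-step output (default 0.05).
#' @param rtol,atol Integration tolerances.
#' @return A list with elements `time_course`, `y_pre` (pre-step output),
#'   `y_post` (final output), `adaptation_time` (h after `t_step`; 0 if the
#'   output never leaves the band) and `recovered` (logical).
#' @export
simulate_resource_step <- function(params, t_step = 48, fold_drop = 1/3,
                                   t_end = max(240, 2 * t_step), dt = 0.25,
                                   band = 0.05, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "dynamic_params"))
  if (!is.numeric(t_step) || t_step < 0) stop("'t_step' must be >= 0")
  if (!is.numeric(fold_drop) || fold_drop <= 0 || fold_drop > 1)
    stop("'fold_drop' must be in (0, 1]")
  if (t_end <= t_step) stop("'t_end' must exceed 't_step'")
  t_grid <- sort(unique(c(seq(0, t_end, by = dt), t_step)))
  R_fun <- function(t) params$R_TX * ifelse(t < t_step, 1, fold_drop)
  tc <- run_ode(params, t_grid, R_TX_fun = R_fun, rtol = rtol, atol = atol)
  y_pre <- tc$y[which.min(abs(tc$time - t_step))]
  post <- tc$time > t_step
  inside <- abs(tc$y[post] - y_pre) <= band * y_pre
  if (all(inside)) {
    adapt_t <- 0
    recovered <- TRUE
  } else {
    # first index after which the trajectory stays inside the band
    stay <- rev(cumprod(rev(inside))) > 0
    if (any(stay)) {
      adapt_t <- tc$time[post][which(stay)[1]] - t_step
      recovered <- TRUE
    } else {
      adapt_t <- NA_real_
      recovered <- FALSE
    }
  }
  list(time_course = tc, y_pre = y_pre, y_post = tc$y[nrow(tc)],
       adaptation_time = adapt_t, recovered = recovered)
}

#' Closed-form steady state implied by dynamic parameters
#'
#' Convenience wrapper: lumps the mechanistic constants and evaluates
#' [iffl_output()] at `D0` and `R = R_TX * R_TL`. Valid in the regime
#' `mu = 0`, `m_y << K_M` in which the closed form is the exact steady
#' state of [simulate_iffl()].
#'
#' @param params A [dynamic_params()] object.
#' @return The closed-form steady-state output level.
#' @export
steady_state_output <- function(params) {
  stopifnot(inherits(params, "dynamic_params"))
  p <- lump(params$constants)
  iffl_output(params$D0, params$R_TX * params$R_TL, p)
}
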