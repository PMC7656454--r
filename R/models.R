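# Closed-form steady-state models of the endoRNase-based iFFL, the
# unregulated (UR) control, and the Gal4-TA resource-competition
# dose-response.

#' Lumped steady-state parameters of the iFFL
#'
#' Container for the three lumped constants that determine the steady-state
#' behaviour of an endoRNase-based incoherent feedforward loop (iFFL):
#' `V_y` (output capacity, fluorescence per unit of plasmid dose times free
#' resource, D*R), `epsilon` (feedforward impedance, units of D*R) and `V_z`
#' (transfection-marker capacity). Two derived quantities characterise the
#' marker-vs-output curve: the output plateau `Y_max = V_y * epsilon` and the
#' marker level `Z_50 = V_z * epsilon` at which the output reaches half of
#' `Y_max`. Smaller `epsilon` means stronger feedforward repression, earlier
#' saturation and better adaptation, at the cost of a lower plateau.
#'
#' @param V_y Output capacity constant, > 0.
#' @param epsilon Feedforward impedance, > 0.
#' @param V_z Transfection-marker capacity constant, > 0.
#' @return An object of class `iffl_params` with elements `V_y`, `epsilon`,
#'   `V_z`, `Y_max` and `Z_50`.
#' @examples
#' p <- iffl_params(V_y = 1000, epsilon = 10, V_z = 5)
#' p$Y_max  # 10000
#' p$Z_50   # 50
#' @export
iffl_params <- function(V_y, epsilon, V_z = 1) {
  for (nm in c("V_y", "epsilon", "V_z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm))
  }
  structure(
    list(V_y = V_y, epsilon = epsilon, V_z = V_z,
         Y_max = V_y * epsilon, Z_50 = V_z * epsilon),
    class = "iffl_params"
  )
}

#' @export
print.iffl_params <- function(x, ...) {
  cat("iFFL steady-state parameters\n")
  cat(sprintf("  V_y     = %g\n  epsilon = %g\n  V_z     = %g\n",
              x$V_y, x$epsilon, x$V_z))
  cat(sprintf("  Y_max   = %g (V_y * epsilon)\n  Z_50    = %g (V_z * epsilon)\n",
              x$Y_max, x$Z_50))
  invisible(x)
}

#' Mechanistic rate constants of the iFFL
#'
#' Mass-action rate constants for the endoRNase gene (subscript `x`) and the
#' output gene (subscript `y`): transcription initiation (`phi_*`, 1/h per
#' promoter-resource), translation initiation (`beta_*`, 1/h per
#' ribosome-mRNA), mRNA decay (`delta_*`, 1/h), protein decay (`gamma_*`,
#' 1/h), ribosome-mRNA dissociation constants (`kappa_*`), the endoRNase
#' catalytic rate (`theta`, 1/h), its Michaelis constant (`K_M`) and the
#' promoter-resource dissociation constant (`k`). All must be strictly
#' positive.
#'
#' @param phi_x,phi_y Transcription initiation rate constants.
#' @param beta_x,beta_y Translation initiation rate constants.
#' @param delta_x,delta_y mRNA decay rate constants.
#' @param gamma_x,gamma_y Protein decay rate constants.
#' @param kappa_x,kappa_y Ribosome-mRNA dissociation constants.
#' @param theta EndoRNase catalytic rate constant.
#' @param K_M Michaelis constant of endoRNase cleavage.
#' @param k Promoter-resource dissociation constant.
#' @return An object of class `mechanistic_constants`.
#' @seealso [lump()] to reduce these to [iffl_params()].
#' @export
mechanistic_constants <- function(phi_x = 1, phi_y = 1, beta_x = 1, beta_y = 1,
                                  delta_x = 1, delta_y = 1, gamma_x = 1,
                                  gamma_y = 1, kappa_x = 1, kappa_y = 1,
                                  theta = 1, K_M = 1, k = 1) {
  vals <- list(phi_x = phi_x, phi_y = phi_y, beta_x = beta_x, beta_y = beta_y,
               delta_x = delta_x, delta_y = delta_y, gamma_x = gamma_x,
               gamma_y = gamma_y, kappa_x = kappa_x, kappa_y = kappa_y,
               theta = theta, K_M = K_M, k = k)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("mechanistic constants must be single finite positive numbers: ",
         paste(bad, collapse = ", "))
  structure(vals, class = "mechanistic_constants")
}

#' Reduce mechanistic constants to lumped iFFL parameters
#'
#' Computes the lumped steady-state parameters from the mass-action rate
#' constants:
#' `V_y = phi_y * beta_y / (gamma_y * k * kappa_y * delta_y)` and
#' `epsilon = gamma_x * k * delta_x * delta_y * K_M * kappa_x /
#' (phi_x * beta_x * theta)`. The free-resource level enters the model only
#' through the product `R = R_TX * R_TL`, which the caller forms when
#' evaluating [iffl_output()]. The marker lump `V_z` is not determined by
#' these constants and is supplied by the caller.
#'
#' @param constants A [mechanistic_constants()] object.
#' @param V_z Marker capacity to attach to the result (default 1).
#' @return An [iffl_params()] object.
#' @examples
#' lump(mechanistic_constants())  # V_y = 1, epsilon = 1
#' @export
lump <- function(constants, V_z = 1) {
  stopifnot(inherits(constants, "mechanistic_constants"))
  c_ <- constants
  V_y <- c_$phi_y * c_$beta_y / (c_$gamma_y * c_$k * c_$kappa_y * c_$delta_y)
  epsilon <- c_$gamma_x * c_$k * c_$delta_x * c_$delta_y * c_$K_M * c_$kappa_x /
    (c_$phi_x * c_$beta_x * c_$theta)
  iffl_params(V_y = V_y, epsilon = epsilon, V_z = V_z)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and non-negative", name))
  invisible(x)
}

#' Steady-state iFFL output versus plasmid dose and free resources
#'
#' Evaluates `y = V_y * D * R / (1 + D * R / epsilon)`, the steady-state
#' output of the iFFL as a function of plasmid dose `D` and the lumped free
#' resource level `R` (the product of transcriptional and translational
#' resources). The output increases monotonically in `D * R` and saturates
#' at `Y_max = V_y * epsilon`; when `D * R >> epsilon` the output becomes
#' independent of both dose and resources — the adaptation regime.
#'
#' @param D Plasmid dose (copies per cell), non-negative, vectorised.
#' @param R Lumped free-resource level, non-negative, vectorised.
#' @param params An [iffl_params()] object.
#' @return Output level(s), same length as `D * R` after recycling.
#' @examples
#' p <- iffl_params(V_y = 2, epsilon = 4)
#' iffl_output(2, 2, p)  # D*R = epsilon -> V_y*epsilon/2 = 4
#' @export
iffl_output <- function(D, R, params) {
  stopifnot(inherits(params, "iffl_params"))
  check_nonneg(D, "D"); check_nonneg(R, "R")
  u <- D * R
  # Written as Y_max / (epsilon/u + 1) for large u to avoid overflow.
  out <- ifelse(u > params$epsilon,
                params$Y_max / (params$epsilon / u + 1),
                params$V_y * u / (1 + u / params$epsilon))
  out[u == 0] <- 0
  out
}

#' Steady-state iFFL output versus transfection-marker level
#'
#' The experimentally measurable form of the iFFL dose-response: with the
#' marker level `z = V_z * D * R` proportional to delivered plasmid dose,
#' `y = V_y * (z / V_z) / (1 + z / (V_z * epsilon))`. The curve rises with
#' initial slope `V_y / V_z`, passes half of `Y_max` at `z = Z_50` and
#' plateaus at `Y_max`.
#'
#' @param z Marker level (MEFL), non-negative, vectorised.
#' @param params An [iffl_params()] object.
#' @return Output level(s) in the same units as `V_y * epsilon`.
#' @examples
#' p <- iffl_params(V_y = 1000, epsilon = 10, V_z = 5)
#' iffl_output_vs_marker(p$Z_50, p) / p$Y_max  # 0.5
#' @export
iffl_output_vs_marker <- function(z, params) {
  stopifnot(inherits(params, "iffl_params"))
  check_nonneg(z, "z")
  zz <- z / params$Z_50  # dimensionless; stable for z up to 1e12 and beyond
  out <- params$Y_max * zz / (1 + zz)
  out[z == 0] <- 0
  out
}

#' Unregulated (UR) control module parameters
#'
#' The UR module replaces the endoRNase with an inert gene, breaking the
#' feedforward path, so its steady-state output is simply proportional to
#' the transfection marker: `output = m * z`.
#'
#' @param m Proportionality slope on the MEFL scale, > 0.
#' @return An object of class `ur_params`.
#' @export
ur_params <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("'m' must be a single finite positive number")
  structure(list(m = m), class = "ur_params")
}

#' Unregulated output versus marker level
#'
#' @param z Marker level (MEFL), non-negative, vectorised.
#' @param params A [ur_params()] object.
#' @return `m * z`.
#' @export
ur_output <- function(z, params) {
  stopifnot(inherits(params, "ur_params"))
  check_nonneg(z, "z")
  params$m * z
}

#' uORF tuning series for the feedforward impedance
#'
#' Table mapping the number of upstream open reading frames (uORFs) placed
#' in the endoRNase 5' UTR to the relative fold-increase of the
#' ribosome-mRNA dissociation constant `kappa_x` (and hence of `epsilon`,
#' `Y_max` and `Z_50`, all proportional to `kappa_x`). The default series is
#' a synthetic set of plausible values shipped for testing only; supply
#' measured values for real analyses.
#'
#' @param n Integer vector of uORF counts; must include 0.
#' @param relative_kappa Fold-change of `kappa_x` relative to `n = 0`;
#'   `relative_kappa[n == 0]` must equal 1 and the series must be
#'   non-decreasing in `n`.
#' @return A data.frame of class `uorf_series` with columns `n` and
#'   `relative_kappa`.
#' @export
uorf_series <- function(n = c(0L, 1L, 2L, 4L, 8L, 12L),
                        relative_kappa = c(1, 2, 4, 10, 40, 150)) {
  stopifnot(length(n) == length(relative_kappa), !anyDuplicated(n))
  ord <- order(n)
  n <- as.integer(n[ord]); relative_kappa <- relative_kappa[ord]
  if (!any(n == 0L) || relative_kappa[n == 0L] != 1)
    stop("the series must contain n = 0 with relative_kappa = 1")
  if (any(relative_kappa <= 0) || is.unsorted(relative_kappa))
    stop("'relative_kappa' must be positive and non-decreasing in n")
  structure(data.frame(n = n, relative_kappa = relative_kappa),
            class = c("uorf_series", "data.frame"))
}

#' Scale the feedforward impedance by a uORF count
#'
#' Adding `n` uORFs to the endoRNase transcript multiplies `kappa_x` — and
#' therefore `epsilon`, `Y_max` and `Z_50` — by `relative_kappa(n)`, while
#' `V_y` and `V_z` are untouched (they involve only output- and marker-gene
#' constants).
#'
#' @param params An [iffl_params()] object (the `n = 0` reference).
#' @param n A uORF count present in `series`.
#' @param series A [uorf_series()] table.
#' @return An [iffl_params()] object with scaled `epsilon`.
#' @export
scale_epsilon_by_uorf <- function(params, n, series = uorf_series()) {
  stopifnot(inherits(params, "iffl_params"), inherits(series, "uorf_series"))
  i <- match(n, series$n)
  if (is.na(i))
    stop(sprintf("uORF count %s is not in the series (have: %s)",
                 n, paste(series$n, collapse = ", ")))
  iffl_params(V_y = params$V_y,
              epsilon = params$epsilon * series$relative_kappa[i],
              V_z = params$V_z)
}

#' Free-resource loading laws
#'
#' A loading law maps the Gal4 transcriptional-activator (TA) marker level
#' `u2` to the free transcriptional resource level `R_TX`. Strong TAs
#' sequester shared coactivators ("squelching"), depleting `R_TX` as `u2`
#' rises. `loading_law_competitive()` is a conservation-style competitive
#' sequestration law `R_TX(u2) = R_tot / (1 + (u2 / k_sq)^h)`;
#' `loading_law_constant()` ignores `u2` (useful for tests and for the
#' no-competitor limit).
#'
#' @param R_tot Total resource level, > 0.
#' @param k_sq Sequestration half-point on the `u2` scale, > 0.
#' @param h Hill coefficient of sequestration, > 0 (default 1).
#' @return A function of `u2` returning `R_TX`.
#' @export
loading_law_competitive <- function(R_tot = 1, k_sq = 1, h = 1) {
  stopifnot(R_tot > 0, k_sq > 0, h > 0)
  function(u2) {
    check_nonneg(u2, "u2")
    R_tot / (1 + (u2 / k_sq)^h)
  }
}

#' @rdname loading_law_competitive
#' @param R Constant resource level returned for any `u2`.
#' @export
loading_law_constant <- function(R = 1) {
  stopifnot(R > 0)
  function(u2) {
    check_nonneg(u2, "u2")
    rep_len(R, length(u2))
  }
}

#' Resource-competition dose-response parameters
#'
#' Parameters of the two-module resource-competition model: a constitutive
#' promoter driving `output1` and a Gal4-TA-activated promoter driving
#' `output2`, both drawing on a shared transcriptional resource `R_TX` that
#' the TA depletes. `alpha1`, `alpha2` are saturating amplitudes; `k12`,
#' `k22` resource dissociation constants; `k21` the TA activation constant
#' (Hill coefficient 2); `loading_law` maps the TA marker `u2` to `R_TX`.
#'
#' @param alpha1,alpha2 Saturating amplitudes (MEFL), > 0.
#' @param k12,k22 Resource dissociation constants, > 0.
#' @param k21 TA activation constant (TA marker units), > 0.
#' @param loading_law A function of `u2` returning `R_TX`; see
#'   [loading_law_competitive()].
#' @return An object of class `resource_params`.
#' @export
resource_params <- function(alpha1, alpha2, k12, k21, k22,
                            loading_law = loading_law_competitive()) {
  vals <- list(alpha1 = alpha1, alpha2 = alpha2, k12 = k12, k21 = k21,
               k22 = k22)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("resource parameters must be single finite positive numbers: ",
         paste(bad, collapse = ", "))
  stopifnot(is.function(loading_law))
  structure(c(vals, list(loading_law = loading_law)),
            class = "resource_params")
}

#' Resource-competition dose-response
#'
#' Evaluates the steady-state levels of the non-target constitutive output
#' (`output1`) and the TA-activated output (`output2`) as functions of the
#' TA marker level `u2`:
#' `output1 = alpha1 * (R_TX / k12) / (1 + R_TX / k12)` and
#' `output2 = alpha2 * (R_TX / k22) * (u2 / k21)^2 /
#' (1 + (u2 / k21)^2 * (1 + R_TX / k22))`, with `R_TX = loading_law(u2)`.
#' With a depleting loading law, `output1` falls with `u2` (off-target
#' knockdown) and `output2` rises then falls (self-squelching).
#'
#' @param u2 TA marker level(s), non-negative.
#' @param params A [resource_params()] object.
#' @return A data.frame with columns `u2`, `R_TX`, `output1`, `output2`.
#' @export
resource_dose_response <- function(u2, params) {
  stopifnot(inherits(params, "resource_params"))
  check_nonneg(u2, "u2")
  R_TX <- params$loading_law(u2)
  r1 <- R_TX / params$k12
  out1 <- params$alpha1 * r1 / (1 + r1)
  hill <- (u2 / params$k21)^2
  r2 <- R_TX / params$k22
  out2 <- params$alpha2 * r2 * hill / (1 + hill * (1 + r2))
  data.frame(u2 = u2, R_TX = R_TX, output1 = out1, output2 = out2)
}
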