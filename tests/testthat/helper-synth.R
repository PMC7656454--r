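# Shared fixtures: processed synthetic populations for recovery and
# robustness tests.

# Generate a transfection, subtract the autofluorescence estimated from a
# matched untransfected control, and gate transfected cells. Returns the
# gated table (plus the raw pieces for tests that need them).
gated_population <- function(cfg, control_seed = cfg$seed + 1L,
                             gate_channels = c("tx_marker", "output"),
                             gate_mode = "any") {
  events <- generate_transfection(cfg)
  ucfg <- cfg
  ucfg$transfected_fraction <- 0
  ucfg$n_cells <- 5000L
  ucfg$seed <- control_seed
  ucfg$sample_id <- "untransfected"
  un <- generate_transfection(ucfg)
  chs <- c("tx_marker", "output", "competitor_marker")
  af <- colMeans(un[chs])
  for (ch in chs) {
    events[[ch]] <- events[[ch]] - af[[ch]]
    un[[ch]] <- un[[ch]] - af[[ch]]
  }
  gated <- threshold_gate(events, un, gate_channels, mode = gate_mode)
  list(gated = gated, events = events, untransfected = un)
}

# iFFL population with a given impedance at fixed plateau Y_max = V_y0:
# V_y is rescaled so robustness differences come from epsilon alone.
iffl_population <- function(epsilon, Y_max = 1e4, V_z = 5, R = 1,
                            n_cells = 15000, noise = 0.2, seed = 1) {
  transfection_config(
    n_cells = n_cells, transfected_fraction = 1,
    noise_sd_log10 = noise, autofluor_mean = 0, autofluor_sd = 0,
    model = "iffl",
    params = iffl_params(V_y = Y_max / epsilon, epsilon = epsilon,
                         V_z = V_z),
    R = R, seed = seed)
}

# Single-colour compensation controls consistent with a bleed matrix and
# additive autofluorescence.
single_color_tables <- function(bleed, af_mean = 100, af_sd = 30,
                                n = 4000, seed = 1) {
  set.seed(seed)
  chs <- c("tx_marker", "output", "competitor_marker")
  make_one <- function(i) {
    true_mat <- matrix(0, n, 3)
    true_mat[, i] <- 10^stats::rnorm(n, 3.5, 0.6)
    obs <- true_mat %*% t(bleed) +
      matrix(stats::rnorm(3 * n, af_mean, af_sd), n, 3)
    out <- as.data.frame(obs)
    names(out) <- chs
    cbind(sample_id = paste0("sc_", chs[i]),
          time_s = seq_len(n) / 500, fsc = 1e5, ssc = 3e4, out)
  }
  stats::setNames(lapply(1:3, make_one), chs)
}

wild_type_table <- function(af_mean = 100, af_sd = 30, n = 4000, seed = 2) {
  set.seed(seed)
  chs <- c("tx_marker", "output", "competitor_marker")
  out <- as.data.frame(matrix(stats::rnorm(3 * n, af_mean, af_sd), n, 3))
  names(out) <- chs
  cbind(sample_id = "wt", time_s = seq_len(n) / 500, fsc = 1e5, ssc = 3e4,
        out)
}
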