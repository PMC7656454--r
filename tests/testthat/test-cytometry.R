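test_that("bead calibration recovers a known affine map", {
  # beads written in raw units via slope 0.9 / intercept 0.5
  bcfg <- bead_config(slope = 0.9, intercept = 0.5, events_per_peak = 2000,
                      seed = 31)
  beads <- generate_beads(bcfg)
  ev <- data.frame(sample_id = "s", time_s = 1:100 / 500, fsc = 1, ssc = 1,
                   tx_marker = 10^seq(1, 5, length.out = 100))
  cal <- calibrate_mefl(ev, beads, bcfg$peak_mefl_values, "tx_marker")
  expect_equal(cal$model$slope, 0.9, tolerance = 0.01)
  expect_equal(cal$model$intercept, 0.5, tolerance = 0.05)
  # round-trip: calibrated bead cluster medians match the known peaks
  bev <- data.frame(sample_id = "b", time_s = beads$time_s, fsc = 1, ssc = 1,
                    tx_marker = beads$value)
  bcal <- calibrate_mefl(bev, beads, bcfg$peak_mefl_values, "tx_marker")
  med <- tapply(bcal$events$tx_marker, beads$peak, median)
  rel <- abs(med - bcfg$peak_mefl_values) / bcfg$peak_mefl_values
  expect_true(all(rel < 0.02))
  # identity beads give an identity map
  b1 <- generate_beads(bead_config(events_per_peak = 1000, seed = 32))
  cal1 <- calibrate_mefl(ev, b1, c(1e2, 1e3, 1e4, 1e5, 1e6), "tx_marker")
  expect_equal(cal1$model$slope, 1, tolerance = 0.01)
  expect_lt(abs(cal1$model$intercept), 0.05)
  # under-determined with one peak
  expect_error(
    calibrate_mefl(ev, generate_beads(bead_config(peak_mefl_values = 1e3,
                                                  seed = 1)),
                   1e3, "tx_marker"),
    ">= 2")
})

test_that("compensation recovers bleed slopes and inverts the mixing", {
  bleed <- diag(3)
  bleed[2, 1] <- 0.1  # tx_marker bleeds into output
  bleed[3, 2] <- 0.05
  wt <- wild_type_table(seed = 33)
  sc <- single_color_tables(bleed, seed = 34)
  model <- build_compensation(wt, sc)
  expect_equal(unname(model$mixing[2, 1]), 0.1, tolerance = 0.01)
  expect_equal(unname(model$mixing[3, 2]), 0.05, tolerance = 0.01)
  expect_lt(max(abs(model$mixing - bleed)), 0.01)

  # compensation of generator-mixed events recovers the true signals
  # (measurement noise off so the mixing inversion itself is tested)
  cfg <- transfection_config(n_cells = 10000, bleed_matrix = bleed,
                             noise_sd_log10 = 0, seed = 35)
  ev <- generate_transfection(cfg)
  truth <- attr(ev, "truth")
  comp <- compensate(ev, model)
  on <- truth$tx_marker > 1000  # well above background
  rel_err <- abs(comp$tx_marker[on] - truth$tx_marker[on]) /
    truth$tx_marker[on]
  expect_lt(median(rel_err), 0.02)
  rel_err_y <- abs(comp$output[on] - truth$output[on]) /
    pmax(truth$output[on], 1)
  expect_lt(median(rel_err_y), 0.02)
  # algebraic inverse: compensating then re-mixing reproduces the input
  remixed <- t(model$mixing %*% t(as.matrix(comp[names(
    model$autofluorescence)]))) +
    rep(model$autofluorescence, each = nrow(ev))
  expect_lt(max(abs(remixed - as.matrix(ev[names(
    model$autofluorescence)]))), 1e-6)
  # identity model only subtracts background
  id_model <- build_compensation(wt, single_color_tables(diag(3), seed = 36))
  ev2 <- compensate(ev, id_model)
  expect_equal(ev2$tx_marker,
               ev$tx_marker - id_model$autofluorescence[["tx_marker"]],
               tolerance = 0.02)
  expect_error(build_compensation(wt, list(tx_marker = wt)), "degenerate")
})

test_that("threshold gating behaves like its defining quantile", {
  cfg <- transfection_config(n_cells = 20000, transfected_fraction = 0,
                             seed = 37)
  un <- generate_transfection(cfg)
  self_gated <- threshold_gate(un, un, "output", mode = "all",
                               quantile = 0.999)
  expect_equal(nrow(self_gated) / nrow(un), 0.001, tolerance = 0.5)
  # union gate passes at least as many as each single-channel gate
  g_any <- threshold_gate(un, un, c("tx_marker", "output"), mode = "any")
  g_tx <- threshold_gate(un, un, "tx_marker")
  g_out <- threshold_gate(un, un, "output")
  expect_gte(nrow(g_any), nrow(g_tx))
  expect_gte(nrow(g_any), nrow(g_out))
  # raising the quantile never admits more events
  ns <- vapply(c(0.9, 0.99, 0.999),
               function(q) nrow(threshold_gate(un, un, "output",
                                               quantile = q)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  # all below threshold -> empty result with warning
  low <- un; low$output <- -abs(low$output)
  expect_warning(res <- threshold_gate(low, un, "output"), "no events")
  expect_equal(nrow(res), 0)
  expect_error(threshold_gate(un, un[0, ], "output"), "non-empty")
})

test_that("binning uses (low, high] intervals and partitions the range", {
  ev <- data.frame(sample_id = "s", time_s = 1:5, fsc = 1, ssc = 1,
                   x = c(10, 1, 100, 0.5, 40))
  b <- assign_bins(ev, "x", c(1, 10, 100))
  # value equal to a high edge falls in the lower bin
  expect_identical(b$bin, c(1L, NA_integer_, 2L, NA_integer_, 2L))
  # partition: every in-range event lands in exactly one bin
  set.seed(38)
  v <- 10^runif(5000, -1, 5)
  ev2 <- data.frame(sample_id = "s", time_s = seq_along(v), fsc = 1, ssc = 1,
                    x = v)
  edges <- half_log_edges(v)
  b2 <- assign_bins(ev2, "x", edges)
  in_range <- v > edges[1] & v <= edges[length(edges)]
  expect_equal(sum(!is.na(b2$bin)), sum(in_range))
  expect_equal(sum(table(b2$bin)), sum(in_range))
  expect_error(assign_bins(ev, "x", c(10, 1)), "strictly increasing")
})

test_that("median summaries discard non-positive values", {
  ev <- data.frame(sample_id = "s", time_s = 1:5, fsc = 1, ssc = 1,
                   y = c(-1, 0, 2, 4, 6))
  expect_equal(median_summary(ev, "y"), 4)
  ev_neg <- ev; ev_neg$y <- c(-1, 0, -2, -4, -6)
  expect_error(median_summary(ev_neg, "y"), "no positive values")
  ev1 <- ev; ev1$y <- c(-2, -1, 0, 0, 7)
  expect_equal(median_summary(ev1, "y"), 7)
})

test_that("bin medians summarise each marker bin", {
  set.seed(39)
  v <- 10^runif(2000, 0.1, 3.9)
  ev <- data.frame(sample_id = "s", time_s = seq_along(v), fsc = 1, ssc = 1,
                   x = v, y = 2 * v)
  b <- assign_bins(ev, "x", 10^seq(0, 4, 0.5))
  bm <- bin_medians(b, "y")
  expect_s3_class(bm, "bin_summary")
  expect_equal(sum(bm$n), 2000)
  expect_true(all(bm$low < bm$high))
  # per-bin medians track the linear relation
  expect_equal(bm$median / tapply(v, b$bin, median)[as.character(bm$bin)],
               rep(2, nrow(bm)), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("scatter density is uniform on a grid and peaks on a cluster", {
  g <- expand.grid(x = 10^seq(1, 3, length.out = 100),
                   y = 10^seq(1, 3, length.out = 100))
  ev <- data.frame(sample_id = "s", time_s = seq_len(nrow(g)), fsc = 1,
                   ssc = 1, x = g$x, y = g$y)
  d <- scatter_density(ev, "x", "y")
  expect_true(all(is.finite(d)) && all(d >= 0))
  # away from the padded boundary the density is near-uniform
  lx <- log10(g$x); lyv <- log10(g$y)
  interior <- lx > quantile(lx, 0.1) & lx < quantile(lx, 0.9) &
    lyv > quantile(lyv, 0.1) & lyv < quantile(lyv, 0.9)
  expect_lt(max(d[interior]) / min(d[interior]), 2)
  # tight cluster on a sparse background attains maximal density
  set.seed(40)
  bg_x <- 10^runif(500, 1, 5); bg_y <- 10^runif(500, 1, 5)
  cl_x <- 10^rnorm(500, 3, 0.01); cl_y <- 10^rnorm(500, 3, 0.01)
  ev2 <- data.frame(sample_id = "s", time_s = 1:1000, fsc = 1, ssc = 1,
                    x = c(bg_x, cl_x), y = c(bg_y, cl_y))
  d2 <- scatter_density(ev2, "x", "y")
  expect_true(which.max(d2) > 500)
  # degenerate axis falls back to a single bin
  ev3 <- ev2; ev3$y <- 100
  expect_true(all(is.finite(scatter_density(ev3, "x", "y"))))
})

test_that("cell density estimation matches rate / flow", {
  # constructed constant gaps: exact rate before trimming
  ts <- seq(0, by = 0.01, length.out = 1000)
  est <- estimate_cell_density(ts, flow_rate = 2, trim_q = 1)
  expect_equal(est$event_rate, 100)
  expect_equal(est$cells_per_ul, 50)
  # exponential gaps: MLE recovery within 2% at n = 1e4
  ts2 <- generate_timestamps(100, 1e4, seed = 41)
  est2 <- estimate_cell_density(ts2, flow_rate = 1)
  expect_lt(abs(est2$event_rate - 100) / 100, 0.02)
  # invariant to a global time shift
  est3 <- estimate_cell_density(ts2 + 500, flow_rate = 1)
  expect_equal(est3$event_rate, est2$event_rate)
  # agreement with an independent exponential fit (fitdistrplus MLE)
  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    gaps <- diff(ts2)
    gaps <- gaps[gaps <= quantile(gaps, 0.999)]
    oracle <- fitdistrplus::fitdist(gaps, "exp")$estimate[["rate"]]
    expect_equal(est2$event_rate, oracle, tolerance = 1e-6)
  }
  expect_error(estimate_cell_density(1:5, flow_rate = 1), "at least 10")
})
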