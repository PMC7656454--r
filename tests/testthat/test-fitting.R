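test_that("noise-free iFFL data are recovered essentially exactly", {
  cfg <- transfection_config(n_cells = 5000, transfected_fraction = 1,
                             noise_sd_log10 = 0, autofluor_mean = 0,
                             autofluor_sd = 0, seed = 9)
  fit <- fit_iffl(generate_transfection(cfg))
  expect_lt(abs(fit$Y_max - cfg$params$Y_max) / cfg$params$Y_max, 0.001)
  expect_lt(abs(fit$Z_50 - cfg$params$Z_50) / cfg$params$Z_50, 0.001)
  expect_lt(fit$cv_rmse, 1e-6)
  # identifiable lumps are exposed consistently
  expect_equal(fit$params$Y_max, fit$Y_max)
  expect_equal(fit$params$Z_50, fit$Z_50)
  expect_equal(fit$slope0, fit$Y_max / fit$Z_50)
})

test_that("noisy iFFL recovery through background subtraction and gating", {
  pop <- gated_population(transfection_config(seed = 42))
  fit <- fit_iffl(pop$gated)
  expect_lt(abs(fit$Y_max - 1e4) / 1e4, 0.10)
  expect_lt(abs(fit$Z_50 - 50) / 50, 0.10)
  expect_false(fit$z50_escaped)
  # fitting is invariant to event order
  shuffled <- pop$gated[sample(nrow(pop$gated)), ]
  fit2 <- fit_iffl(shuffled)
  expect_equal(fit2$Y_max, fit$Y_max)
  expect_equal(fit2$Z_50, fit$Z_50)
})

test_that("bias of the fitted plateau shrinks as the sample grows", {
  err_at_n <- function(n, seed) {
    cfg <- transfection_config(n_cells = n, transfected_fraction = 1,
                               noise_sd_log10 = 0.2, autofluor_mean = 0,
                               autofluor_sd = 0, seed = seed)
    fit <- fit_iffl(generate_transfection(cfg))
    abs(fit$Y_max - cfg$params$Y_max) / cfg$params$Y_max
  }
  # residual error at large n reflects marker measurement noise
  # (errors-in-variables), not sampling error
  errs <- vapply(c(1e3, 1e4, 1e5), err_at_n, numeric(1), seed = 10)
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1] + 0.02)
})

test_that("bin-equalised subsampling is seeded and capped", {
  pop <- gated_population(transfection_config(seed = 42))
  s1 <- subsample_bins(pop$gated, "tx_marker", seed = 3)
  s2 <- subsample_bins(pop$gated, "tx_marker", seed = 3)
  expect_identical(s1, s2)
  expect_lte(attr(s1, "n_per_bin"), 3000)
  counts <- table(s1$bin)
  expect_true(all(counts == attr(s1, "n_per_bin")))
  fit <- fit_iffl(pop$gated, subsample = TRUE, seed = 3)
  expect_lt(abs(fit$Y_max - 1e4) / 1e4, 0.25)
})

test_that("unregulated fits recover the slope; mismatched fits are flagged", {
  cfg0 <- transfection_config(n_cells = 2000, transfected_fraction = 1,
                              noise_sd_log10 = 0, autofluor_mean = 0,
                              autofluor_sd = 0, model = "ur",
                              params = ur_params(0.5), seed = 11)
  expect_equal(fit_ur(generate_transfection(cfg0))$m, 0.5, tolerance = 1e-9)
  cfg <- transfection_config(n_cells = 10000, transfected_fraction = 1,
                             noise_sd_log10 = 0.2, autofluor_mean = 0,
                             autofluor_sd = 0, model = "ur",
                             params = ur_params(0.5), seed = 12)
  ev <- generate_transfection(cfg)
  expect_lt(abs(fit_ur(ev)$m - 0.5) / 0.5, 0.05)
  # zero-variance marker
  flat <- ev; flat$tx_marker <- 1000
  expect_error(fit_ur(flat), "zero-variance")
  # UR data pushed through the saturating fit shows no saturation
  expect_warning(fit_mis <- fit_iffl(ev), "no saturation")
  expect_true(fit_mis$z50_escaped)
})

test_that("fitted Z_50 and Y_max scale linearly with the uORF kappa series", {
  s <- uorf_series()
  base <- iffl_params(V_y = 1000, epsilon = 1, V_z = 5)
  fits <- lapply(s$n, function(n) {
    p <- scale_epsilon_by_uorf(base, n, s)
    cfg <- transfection_config(n_cells = 4000, transfected_fraction = 1,
                               noise_sd_log10 = 0, autofluor_mean = 0,
                               autofluor_sd = 0, params = p,
                               seed = 100 + n)
    fit_iffl(generate_transfection(cfg))
  })
  z50 <- vapply(fits, `[[`, numeric(1), "Z_50")
  ymax <- vapply(fits, `[[`, numeric(1), "Y_max")
  r2_origin <- function(y, x) {
    b <- sum(x * y) / sum(x^2)
    1 - sum((y - b * x)^2) / sum(y^2)
  }
  expect_gt(r2_origin(z50, s$relative_kappa), 0.99)
  expect_gt(r2_origin(ymax, s$relative_kappa), 0.99)
})

test_that("resource model: single activator is recovered from clean doses", {
  u2 <- c(0, 10^seq(0, 4, length.out = 9))
  truth <- resource_params(alpha1 = 5000, alpha2 = 20000, k12 = 0.5,
                           k21 = 300, k22 = 2,
                           loading_law = loading_law_competitive(
                             R_tot = 1, k_sq = 500))
  obs <- resource_dose_response(u2, truth)
  fit <- fit_resource_model(list(
    VPR = data.frame(u2 = u2, output1 = obs$output1,
                     output2 = obs$output2)))
  est <- setNames(fit$estimates$value, fit$estimates$parameter)
  expect_equal(est[["alpha1"]], 5000, tolerance = 0.05)
  expect_equal(est[["alpha2"]], 20000, tolerance = 0.05)
  expect_equal(est[["k12"]], 0.5, tolerance = 0.05)
  expect_equal(est[["k21.VPR"]], 300, tolerance = 0.05)
  expect_equal(est[["k_sq.VPR"]], 500, tolerance = 0.05)
  expect_true(all(fit$cv_rmse$cv_rmse_output1 < 1e-6))
  # zero-dose point is honoured exactly (no offset parameter)
  pred0 <- resource_dose_response(0, fit$params$VPR)
  expect_equal(pred0$output2, 0)
})

test_that("sharing amplitudes across activators improves their estimate", {
  # doses deep into resource depletion so output1 spans its saturation
  # (alpha1 and k12 are separately identifiable only then)
  u2 <- 10^seq(0, 4, length.out = 7)
  gen <- function(k21, k_sq, seed) {
    truth <- resource_params(alpha1 = 5000, alpha2 = 20000, k12 = 0.1,
                             k21 = k21, k22 = 2,
                             loading_law = loading_law_competitive(
                               R_tot = 1, k_sq = k_sq))
    obs <- resource_dose_response(c(0, u2), truth)
    set.seed(seed)
    data.frame(u2 = c(0, u2),
               output1 = obs$output1 * exp(rnorm(8, 0, 0.1)),
               output2 = obs$output2 * exp(rnorm(8, 0, 0.1)))
  }
  err_shared <- err_single <- numeric(8)
  for (i in 1:8) {
    tabs <- list(VPR = gen(300, 300, 2 * i), Rta = gen(1000, 1000, 2 * i + 1))
    shared_fit <- fit_resource_model(tabs)
    a1 <- shared_fit$estimates$value[shared_fit$estimates$parameter ==
                                       "alpha1"]
    err_shared[i] <- abs(a1 - 5000) / 5000
    singles <- vapply(tabs, function(tb) {
      f <- suppressWarnings(fit_resource_model(list(x = tb)))
      f$estimates$value[f$estimates$parameter == "alpha1"]
    }, numeric(1))
    err_single[i] <- mean(abs(singles - 5000) / 5000)
  }
  expect_lt(sqrt(mean(err_shared^2)), sqrt(mean(err_single^2)))
})

test_that("degenerate fitting inputs are rejected", {
  expect_error(fit_resource_model(list(a = data.frame(u2 = 1:3,
                                                      output1 = 1:3,
                                                      output2 = 1:3))),
               ">= 4 dose points")
  expect_error(fit_resource_model(list(data.frame(u2 = 1:5, output1 = 1:5,
                                                  output2 = 1:5))),
               "named list")
  small <- data.frame(sample_id = "s", time_s = 1:10, fsc = 1, ssc = 1,
                      tx_marker = 1:10, output = 1:10)
  expect_error(fit_iffl(small), ">= 100 events")
})
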