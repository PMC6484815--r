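test_that("moving-average smoothing matches a brute-force window loop", {
  set.seed(1)
  pc <- perfusion_curve(0:49 / 10, rnorm(50), frame_rate = 10)
  for (w in c(0.5, 1, 2.5)) {
    h <- floor(w / (2 * 0.1) + 1e-9)
    expect_equal(smooth_curve(pc, w)$intensity,
                 naive_moving_average(pc$intensity, h))
  }
})

test_that("smoothing fixed points: constant curves and sub-sample windows", {
  const <- perfusion_curve(0:19, rep(4, 20))
  expect_equal(smooth_curve(const, 5)$intensity, rep(4, 20))
  set.seed(2)
  pc <- perfusion_curve(0:19, rnorm(20))
  expect_equal(smooth_curve(pc, 0.5)$intensity, pc$intensity)  # < one interval
  # interior of a ramp is preserved (linear-phase property)
  ramp <- perfusion_curve(0:29, 2 * (0:29) + 1)
  sm <- smooth_curve(ramp, 6)
  expect_equal(sm$intensity[5:26], ramp$intensity[5:26])
})

test_that("onset of a noiseless 5 s-onset curve is found within one frame", {
  pc <- simulate_curve(linear_truth(), 10, 60)
  ons <- detect_onset(pc)
  expect_gte(ons$t_onset, 5.0)
  expect_lte(ons$t_onset, 5.1)
  expect_equal(ons$f_min, 10)
})

test_that("flat curves raise a no-perfusion error", {
  flat <- simulate_curve(kinetic_truth(amplitude_a = 0, onset_t0 = 5,
                                       rise_duration = 10), 10, 60)
  expect_error(fit_perfusion(flat), class = "icg_no_perfusion")
  noisy_flat <- simulate_curve(kinetic_truth(amplitude_a = 0, onset_t0 = 5,
                                             rise_duration = 10, noise_sd = 2),
                               10, 60, seed = 9)
  expect_error(fit_perfusion(noisy_flat), class = "icg_no_perfusion")
})

test_that("noisy onsets are recovered within 3 inter-frame intervals in >= 95% of runs", {
  # linear rise at the pipeline's 5 fps sampling; noise 2% of amplitude
  hits <- vapply(1:200, function(s) {
    kt <- linear_truth(noise_sd = 1.2, onset_t0 = 10)
    f <- suppressWarnings(fit_perfusion(simulate_curve(kt, 5, 60, seed = s)))
    abs(f$params$t_onset - 10) <= 3 / 5
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("closed-form parameters of a noiseless linear rise are recovered", {
  fit <- fit_perfusion(simulate_curve(linear_truth(), 10, 60))
  p <- fit$params
  expect_equal(p$t_max, 30, tolerance = 0.1)
  expect_equal(p$t_half_max, 15, tolerance = 0.1)
  expect_equal(p$tr, 0.5, tolerance = 0.005)
  expect_equal(p$slope, 2, tolerance = 0.01)
  expect_equal(p$delta_f, 60, tolerance = 0.1)
  expect_equal(p$f_min, 10)
  expect_false(p$censored)
})

test_that("a 64 s rise shaped for TR 0.6 reproduces the slow-group time ratio", {
  g <- log(0.5) / log(0.6)
  kt <- kinetic_truth(baseline_f0 = 11.5, amplitude_a = 44.8, onset_t0 = 10,
                      rise_duration = 64, shape_gamma = g)
  fit <- fit_perfusion(simulate_curve(kt, 10, 120))
  expect_equal(fit$params$tr, 0.6, tolerance = 0.01)
  expect_equal(fit$params$t_max, 64, tolerance = 0.1)
})

test_that("recovered parameters converge to analytic truth with frame rate", {
  errs <- vapply(c(1, 10, 100), function(fps) {
    kt <- kinetic_truth(amplitude_a = 60, onset_t0 = 15, rise_duration = 30,
                        shape_gamma = 1.5)
    fit <- fit_perfusion(simulate_curve(kt, fps, 70))
    tp <- true_params(kt)
    max(abs(fit$params$t_max - tp$t_max),
        abs(fit$params$t_half_max - tp$t_half_max))
  }, 0)
  expect_true(all(errs <= 1 / c(1, 10, 100) + 1e-9))
  expect_true(all(diff(errs) < 0))
})

test_that("the fitted half-max crossing equals an exhaustive upsampled scan", {
  for (s in 1:5) {
    kt <- kinetic_truth(amplitude_a = 60, onset_t0 = 8, rise_duration = 25,
                        shape_gamma = c(0.7, 1, 1.4, 2, 0.5)[s], noise_sd = 2)
    pc <- simulate_curve(kt, 10, 50, seed = 100 + s)
    fit <- suppressWarnings(fit_perfusion(pc))
    p <- fit$params
    oracle <- scan_half_crossing(fit$smoothed$time, fit$smoothed$intensity,
                                 p$f_min + 0.5 * p$delta_f, p$t_onset)
    expect_equal(p$t_onset + p$t_half_max, oracle, tolerance = 1e-6)
  }
})

test_that("time factors are invariant under affine intensity transforms", {
  kt <- kinetic_truth(amplitude_a = 60, onset_t0 = 10, rise_duration = 30,
                      shape_gamma = 1.2, noise_sd = 1.5)
  pc <- simulate_curve(kt, 10, 60, seed = 42)
  base <- suppressWarnings(fit_perfusion(pc))$params
  dt <- 0.1
  for (alpha in c(0.2, 1, 5)) {
    for (beta in c(0, 40)) {
      tr_pc <- perfusion_curve(pc$time, alpha * pc$intensity + beta,
                               frame_rate = 10)
      p <- suppressWarnings(fit_perfusion(tr_pc))$params
      expect_lt(abs(p$t_max - base$t_max), dt + 1e-9)
      expect_lt(abs(p$t_half_max - base$t_half_max), dt + 1e-9)
      expect_lt(abs(p$tr - base$tr), 0.01)
      # intensity factors scale, as expected for uncalibrated fluorescence
      expect_equal(p$delta_f, alpha * base$delta_f, tolerance = 1e-6)
    }
  }
})

test_that("parameter invariants hold across random noisy fits", {
  for (s in 1:10) {
    kt <- kinetic_truth(amplitude_a = runif(1, 20, 80),
                        onset_t0 = runif(1, 5, 15),
                        rise_duration = runif(1, 10, 60),
                        shape_gamma = runif(1, 0.6, 2),
                        noise_sd = runif(1, 0.5, 3))
    pc <- simulate_curve(kt, 10, kt$onset_t0 + kt$rise_duration + 30,
                         seed = 200 + s)
    p <- suppressWarnings(fit_perfusion(pc))$params
    expect_equal(p$slope * p$t_max, p$delta_f, tolerance = 1e-9)
    expect_gt(p$tr, 0)
    expect_lte(p$tr, 1)
    expect_lte(p$t_half_max, p$t_max + 1e-9)
    expect_gt(p$delta_f, 0)
  }
})

test_that("a curve still rising at the window end is censored with a warning", {
  kt <- linear_truth()
  t <- 0:249 / 10
  pc <- perfusion_curve(t, kinetic_intensity(kt, t), frame_rate = 10)  # cut at 25 s
  expect_warning(fit <- fit_perfusion(pc), class = "icg_peak_censored")
  expect_true(fit$params$censored)
  expect_equal(fit$params$t_max, max(t) - fit$params$t_onset, tolerance = 1e-9)
  # censoring forces the risk zone to at least dangerous
  st <- perfusion_status(fit)
  expect_gte(as.integer(st$risk_zone), 3L)
})

test_that("the regression slope variant reports a fitted slope alongside the ratio", {
  pc <- simulate_curve(linear_truth(), 10, 60)
  fit <- fit_perfusion(pc, perfusion_control(slope_method = "regression"))
  expect_equal(fit$slope_fitted, 2, tolerance = 0.05)
  expect_equal(fit$params$slope * fit$params$t_max, fit$params$delta_f)
})

test_that("model-object methods are coherent", {
  pc <- simulate_curve(linear_truth(noise_sd = 1), 10, 60, seed = 5)
  fit <- suppressWarnings(fit_perfusion(pc))
  expect_named(coef(fit), c("f_min", "delta_f", "slope", "t_onset", "t_max",
                            "t_half_max", "tr"))
  expect_length(fitted(fit), length(pc))
  expect_equal(residuals(fit), pc$intensity - fitted(fit))
  expect_lt(mean(abs(residuals(fit))), 3)  # reconstruction tracks the data
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "perfusion_curve")
  expect_equal(predict(fit, newdata = c(0, 100)),
               c(fit$params$f_min, fit$params$f_min + fit$params$delta_f),
               tolerance = 1e-6)
})

test_that("too-short curves and bad controls are rejected", {
  expect_error(fit_perfusion(perfusion_curve(0:8, c(rep(1, 5), 2:5))),
               "at least 10")
  expect_error(perfusion_control(plateau_epsilon = 0.3), "plateau_epsilon")
  expect_error(perfusion_control(onset_k = -1), "positive")
})
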