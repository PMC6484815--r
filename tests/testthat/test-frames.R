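test_that("TIFF round trip with a one-pixel ROI reproduces the generated curve", {
  kt <- linear_truth()
  roi <- matrix(FALSE, 8, 8); roi[4, 5] <- TRUE
  spec <- frame_stack_spec(height = 8, width = 8, frame_rate = 10,
                           duration = 40, roi_mask = roi,
                           background_level = 3, pixel_noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".tif")
  simulate_frame_stack(kt, spec, f)
  stack <- read_frames(f)
  expect_equal(length(stack$frames), 400L)
  expect_equal(stack$frame_rate, 10)
  expect_s3_class(stack$truth, "kinetic_truth")
  pc <- extract_curve(stack, roi)
  ref <- simulate_curve(kt, 10, 40)
  expect_equal(pc$time, ref$time)
  # storage is 32-bit float, so agreement is to float precision
  expect_equal(pc$intensity, ref$intensity, tolerance = 1e-6)
})

test_that("PNG directory round trip recovers the curve up to 8-bit quantization", {
  kt <- linear_truth()
  roi <- matrix(TRUE, 6, 6)
  spec <- frame_stack_spec(height = 6, width = 6, frame_rate = 5,
                           duration = 40, roi_mask = roi, pixel_noise_sd = 0)
  d <- withr::local_tempdir()
  simulate_frame_stack(kt, spec, d, format = "png")
  stack <- read_frames(d)
  expect_equal(length(stack$frames), 200L)
  pc <- extract_curve(stack, roi)
  ref <- simulate_curve(kt, 5, 40)
  q <- (max(ref$intensity) - min(ref$intensity)) / 255
  expect_equal(pc$intensity, ref$intensity, tolerance = q)
})

test_that("a noisy 64x64 stack recovers TR within 0.02 of the analytic truth", {
  kt <- kinetic_truth(baseline_f0 = 10, amplitude_a = 60, onset_t0 = 5,
                      rise_duration = 30, shape_gamma = 1.357, noise_sd = 0)
  spec <- frame_stack_spec(height = 64, width = 64, frame_rate = 10,
                           duration = 60, pixel_noise_sd = 2)
  f <- withr::local_tempfile(fileext = ".tif")
  simulate_frame_stack(kt, spec, f, seed = 21)
  stack <- read_frames(f)
  pc <- extract_curve(stack, spec$roi_mask)
  fit <- suppressWarnings(fit_perfusion(pc))
  expect_lt(abs(fit$params$tr - 0.5^(1 / 1.357)), 0.02)
})

test_that("a flat stack yields a flat curve and a no-perfusion error downstream", {
  kt <- kinetic_truth(amplitude_a = 0, onset_t0 = 5, rise_duration = 10)
  spec <- frame_stack_spec(height = 6, width = 6, frame_rate = 10,
                           duration = 30, background_level = 10,
                           pixel_noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".tif")
  simulate_frame_stack(kt, spec, f)
  pc <- extract_curve(read_frames(f), spec$roi_mask)
  expect_lt(diff(range(pc$intensity)), 1e-6)
  expect_error(fit_perfusion(pc), class = "icg_no_perfusion")
})

test_that("RGB PNG frames reduce to the requested channel", {
  d <- withr::local_tempdir()
  set.seed(4)
  imgs <- lapply(1:3, function(i) array(runif(5 * 4 * 3), c(5, 4, 3)))
  for (i in 1:3) {
    png::writePNG(imgs[[i]], file.path(d, sprintf("frame_%06d.png", i - 1L)))
  }
  stack <- read_frames(d, frame_rate = 2, channel = "green")
  q <- 1 / 255  # PNG files are 8-bit
  for (i in 1:3) {
    expect_equal(stack$frames[[i]], imgs[[i]][, , 2], tolerance = q)
    expect_equal(dim(stack$frames[[i]]), c(5L, 4L))
  }
  red <- read_frames(d, frame_rate = 2, channel = "red")
  expect_equal(red$frames[[2]], imgs[[2]][, , 1], tolerance = q)
})

test_that("ROI means agree with an explicit pixel-sum oracle and are linear", {
  grad <- outer(1:7, 1:9, function(r, c) r + 10 * c)
  frames <- list(grad, 2 * grad, grad + 5)
  roi <- matrix((seq_len(7 * 9) %% 2) == 0, 7, 9)  # checkerboard
  pc <- extract_curve(frames, roi, frame_rate = 1)
  manual <- vapply(frames, function(f) {
    s <- 0; k <- 0
    for (r in 1:7) for (c in 1:9) if (roi[r, c]) { s <- s + f[r, c]; k <- k + 1 }
    s / k
  }, 0)
  expect_equal(pc$intensity, manual)
  # linearity in pixel intensities: alpha * frames + beta
  scaled <- lapply(frames, function(f) 3 * f + 2)
  pc2 <- extract_curve(scaled, roi, frame_rate = 1)
  expect_equal(pc2$intensity, 3 * pc$intensity + 2)
})

test_that("uniform frames give a constant curve", {
  frames <- replicate(5, matrix(7, 4, 4), simplify = FALSE)
  pc <- extract_curve(frames, matrix(TRUE, 4, 4), frame_rate = 10)
  expect_true(all(pc$intensity == 7))
})

test_that("degenerate and malformed inputs raise format/configuration errors", {
  expect_error(extract_curve(list(matrix(1, 2, 2)), matrix(TRUE, 2, 2), 1),
               "format error")
  expect_error(extract_curve(replicate(3, matrix(1, 2, 2), simplify = FALSE),
                             matrix(FALSE, 2, 2), 1), "invalid ROI")
  expect_error(extract_curve(replicate(3, matrix(1, 2, 2), simplify = FALSE),
                             matrix(TRUE, 3, 3), 1), "invalid ROI")
  expect_error(read_frames(file.path(tempdir(), "nope-missing")), "format error")
  d <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 3, 3), file.path(d, "frame_000000.png"))
  png::writePNG(matrix(0.5, 4, 4), file.path(d, "frame_000001.png"))
  expect_error(read_frames(d, frame_rate = 1), "mixed dimensions")
  d2 <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 3, 3), file.path(d2, "frame_000000.png"))
  expect_error(read_frames(d2), "configuration error")
})

test_that("frame_stack_spec and roi_rect validate geometry", {
  expect_error(frame_stack_spec(roi_mask = matrix(FALSE, 64, 64)),
               "at least one TRUE")
  expect_error(frame_stack_spec(height = 8, roi_mask = matrix(TRUE, 4, 4)),
               "match height")
  expect_error(roi_rect(3, 0, 2, 2, 8, 8), "invalid ROI")
  m <- roi_rect(1, 2, 4, 5, 8, 8)  # half-open: columns 2..4, rows 3..5
  expect_equal(sum(m), 9)
  expect_true(m[3, 2] && m[5, 4])
  expect_false(m[2, 2] || m[6, 4] || m[3, 5])
})
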