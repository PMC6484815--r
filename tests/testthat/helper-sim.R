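# Shared fixtures and independent oracles for the test suite.

# canonical linear-rise ground truth: baseline 10 AU, amplitude 60 AU,
# onset 5 s, rise 30 s => slope 2 AU/s, T_MAX 30 s, T_1/2MAX 15 s, TR 0.5
linear_truth <- function(noise_sd = 0, onset_t0 = 5) {
  kinetic_truth(baseline_f0 = 10, amplitude_a = 60, onset_t0 = onset_t0,
                rise_duration = 30, shape_gamma = 1, noise_sd = noise_sd)
}

# brute-force tie-aware Mann-Whitney AUC: explicit pairwise comparison loop,
# independent of any ranking shortcut
pairwise_auc <- function(values, outcomes) {
  pos <- values[outcomes == 1]
  neg <- values[outcomes == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# brute-force centred moving average: direct window loop
naive_moving_average <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, 0)
}

# brute-force half-max crossing: exhaustive scan over an upsampled linear
# interpolation of the trace
scan_half_crossing <- function(t, y, level, after, upsample = 1000L) {
  tt <- seq(t[1], t[length(t)], length.out = upsample * length(t))
  yy <- stats::approx(t, y, xout = tt)$y
  ok <- which(tt > after & yy >= level)
  if (length(ok) == 0L) return(NA_real_)
  i <- ok[1L]
  if (i == 1L || yy[i - 1L] >= level) return(tt[i])
  tt[i - 1L] + (level - yy[i - 1L]) / (yy[i] - yy[i - 1L]) * (tt[i] - tt[i - 1L])
}

# numeric half-max time of the noiseless kinetic model on a 1 ms grid
grid_half_time <- function(truth, step = 1e-3) {
  tt <- seq(truth$onset_t0, truth$onset_t0 + truth$rise_duration, by = step)
  yy <- kinetic_intensity(truth, tt)
  level <- truth$baseline_f0 + truth$amplitude_a / 2
  tt[which(yy >= level)[1L]] - truth$onset_t0
}
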