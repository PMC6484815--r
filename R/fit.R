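#' Control parameters for perfusion curve analysis
#'
#' Numerical knobs of the curve estimator. Defaults are conservative,
#' field-standard choices; all are per-analysis configurable.
#'
#' @param smooth_window Width of the centred moving-average smoother in
#'   seconds (default 0.5 s). Smoothing is noise-adaptive: a trace whose
#'   baseline standard deviation is numerically zero is analysed unsmoothed,
#'   since on clean data the moving average only biases the onset and
#'   peak-attainment times around slope discontinuities.
#' @param onset_k Baseline-SD multiplier of the onset detector (default 3):
#'   the bolus arrival is detected at the first sample exceeding the running
#'   baseline mean plus `onset_k` running SDs.
#' @param onset_sustain Seconds the exceedance must be sustained (default
#'   0.5 s) before it counts as the fluorescence increase, guarding against
#'   isolated noise spikes.
#' @param plateau_epsilon Plateau tolerance as a fraction of the amplitude
#'   (default 0.02, must lie in (0, 0.2)): T_MAX is the first attainment of
#'   `(1 - plateau_epsilon)` of the peak above baseline, so a noisy plateau
#'   does not inflate it. On noise-free traces the effective tolerance is 0
#'   (exact maximum).
#' @param analysis_window Seconds after onset searched for the peak (default
#'   300 s, the 5-minute intraoperative observation cap).
#' @param min_baseline_frames Minimum number of pre-rise samples required to
#'   estimate the baseline (default 10).
#' @param slope_method `"ratio"` (default) defines the slope as
#'   `delta_f / t_max`; `"regression"` additionally reports an ordinary
#'   least-squares slope fitted over the rise segment (field `slope_fitted`
#'   of the fit; the `slope` parameter itself always stays the ratio so that
#'   `slope * t_max = delta_f` holds).
#' @return An object of class `perfusion_control`.
#' @export
perfusion_control <- function(smooth_window = 0.5, onset_k = 3,
                              onset_sustain = 0.5, plateau_epsilon = 0.02,
                              analysis_window = 300,
                              min_baseline_frames = 10,
                              slope_method = c("ratio", "regression")) {
  slope_method <- match.arg(slope_method)
  vals <- c(smooth_window = smooth_window, onset_k = onset_k,
            onset_sustain = onset_sustain, plateau_epsilon = plateau_epsilon,
            analysis_window = analysis_window,
            min_baseline_frames = min_baseline_frames)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all control parameters must be positive and finite", call. = FALSE)
  }
  if (plateau_epsilon >= 0.2) {
    stop("`plateau_epsilon` must lie in (0, 0.2)", call. = FALSE)
  }
  structure(
    list(smooth_window = smooth_window, onset_k = onset_k,
         onset_sustain = onset_sustain, plateau_epsilon = plateau_epsilon,
         analysis_window = analysis_window,
         min_baseline_frames = as.integer(min_baseline_frames),
         slope_method = slope_method),
    class = "perfusion_control"
  )
}

#' Centred moving-average smoothing of a perfusion curve
#'
#' Length-preserving centred moving average with truncated windows at the
#' endpoints. The half-width in samples is `floor(window_s / (2 * dt))` for
#' inter-sample interval `dt`; a window shorter than one interval is the
#' identity.
#'
#' @param curve A [perfusion_curve()].
#' @param window_s Window width in seconds (>= one inter-sample interval to
#'   have any effect).
#' @return A smoothed [perfusion_curve()].
#' @export
smooth_curve <- function(curve, window_s) {
  stopifnot(inherits(curve, "perfusion_curve"))
  x <- curve$intensity
  # epsilon guards against 0.1-style binary representation of the sampling
  # interval flooring 5.0 down to 4
  h <- floor(window_s / (2 * curve_dt(curve)) + 1e-9)
  if (h < 1) return(curve)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  perfusion_curve(curve$time, sm, frame_rate = curve$frame_rate)
}

stop_no_perfusion <- function(msg) {
  stop(errorCondition(msg, class = c("icg_no_perfusion", "error", "condition")))
}

#' Detect the onset of the fluorescence increase
#'
#' Two-stage bolus-arrival detector. Stage 1 (detection): scanning the
#' working trace forward, a sample is flagged when it exceeds the running
#' baseline mean plus `onset_k` running baseline SDs; the threshold is frozen
#' at the first exceedance (whose prefix is still uncontaminated by the rise)
#' and the exceedance must then hold for `onset_sustain` seconds. Stage 2
#' (refinement): the flagged sample overestimates the true arrival by the
#' time the signal needs to climb out of the noise floor, so the onset is
#' back-projected onto the baseline level — for noise-free traces by direct
#' interpolation of the baseline crossing; for noisy traces by a least-squares
#' fit of a piecewise power-law rise (flat baseline, then
#' `c * (t - t0)^gamma`) to the raw samples of the early rise, initialised
#' from a linear back-projection, which removes the shape-dependent
#' noise-floor-crossing bias.
#'
#' @param curve A [perfusion_curve()].
#' @param control A [perfusion_control()].
#' @return A list with `t_onset` (s), `f_min` (mean of samples strictly
#'   before `t_onset`, AU), `baseline_sd` (AU), and `detect_index` (the
#'   sample index of the sustained exceedance).
#' @section Errors: when no sustained exceedance occurs within
#'   `analysis_window`, a `"no perfusion detected"` error of condition class
#'   `icg_no_perfusion` is raised.
#' @export
detect_onset <- function(curve, control = perfusion_control()) {
  stopifnot(inherits(curve, "perfusion_curve"))
  x <- curve$intensity
  t <- curve$time
  n <- length(x)
  mb <- control$min_baseline_frames
  if (n < mb + 2L) {
    stop(sprintf("need at least %d samples for onset detection", mb + 2L),
         call. = FALSE)
  }
  dt <- curve_dt(curve)
  ns <- max(1L, ceiling(control$onset_sustain / dt))

  s0 <- stats::sd(x[seq_len(mb)])
  rng <- max(x) - min(x)
  noisy <- s0 > 1e-8 * max(rng, .Machine$double.xmin)
  # the working trace: smoothed when the baseline carries measurable noise,
  # raw otherwise (smoothing a clean trace only smears the onset corner)
  w_ <- if (noisy) smooth_curve(curve, control$smooth_window)$intensity else x

  cs <- cumsum(w_)
  css <- cumsum(w_ * w_)
  csr <- cumsum(x)
  cssr <- cumsum(x * x)
  h <- floor(control$smooth_window / (2 * dt) + 1e-9)
  base_stats <- function(j) {
    m <- cs[j] / j
    s <- sqrt(max((css[j] - cs[j]^2 / j) / (j - 1L), 0))
    if (noisy) {
      # the smoothed prefix is serially correlated, so its empirical SD
      # underestimates the smoothed-noise level on short prefixes; floor it
      # by the raw-prefix SD scaled down by the averaging-window length
      raw_sd <- sqrt(max((cssr[j] - csr[j]^2 / j) / (j - 1L), 0))
      s <- max(s, raw_sd / sqrt(2 * h + 1))
    }
    c(m, s)
  }

  # rolling minimum over the sustain window (truncated at the end)
  rmin <- w_
  if (ns > 1L) {
    for (s in 1L:(ns - 1L)) {
      shifted <- c(w_[-seq_len(s)], rep(Inf, s))
      rmin <- pmin(rmin, shifted)
    }
    rmin[(n - ns + 2L):n] <- vapply((n - ns + 2L):n,
                                    function(i) min(w_[i:n]), 0)
  }

  # baseline statistics must come from pre-rise samples only: running
  # statistics over an ever-growing prefix absorb the rise itself and the
  # threshold then outruns a slow convex inflow. Start from the guaranteed
  # pre-rise prefix, detect, re-estimate the baseline from all samples before
  # the detected rise, and iterate to a fixed point.
  t_limit <- t[1L] + control$analysis_window
  j <- mb
  d <- NA_integer_
  for (iter in 1:6) {
    st <- base_stats(j)
    tau <- st[1L] + control$onset_k * st[2L]
    cand <- which(rmin > tau & seq_len(n) > j & t <= t_limit)
    if (length(cand) == 0L) {
      stop_no_perfusion(
        "no perfusion detected: no sustained fluorescence increase within the analysis window")
    }
    d_new <- cand[1L]
    below <- which(w_[seq_len(d_new - 1L)] <= st[1L])
    b <- if (length(below)) max(below) else d_new - 1L
    j_new <- max(b, mb)
    if (!is.na(d) && d_new == d && j_new == j) break
    d <- d_new
    j <- j_new
  }
  st <- base_stats(j)
  m_d <- st[1L]
  below <- which(w_[seq_len(d - 1L)] <= m_d)
  b <- if (length(below)) max(below) else d - 1L

  if (!noisy) {
    # exact baseline crossing between the last sub-baseline sample and its
    # successor
    if (w_[b] >= m_d || w_[b + 1L] <= w_[b]) {
      t_onset <- t[b]
    } else {
      t_onset <- t[b] + (m_d - w_[b]) / (w_[b + 1L] - w_[b]) * (t[b + 1L] - t[b])
    }
  } else {
    # linear back-projection of the early rise onto the baseline level gives
    # a cheap initial onset
    w <- b:min(d + ns - 1L, n)
    t0i <- t[min(b + 1L, d)]
    if (length(w) >= 3L) {
      lf <- stats::lm.fit(cbind(1, t[w]), w_[w])
      beta <- lf$coefficients[2L]
      if (is.finite(beta) && beta > 0) {
        t0i <- (m_d - lf$coefficients[1L]) / beta
      }
    }
    t0i <- min(max(t0i, t[b] - control$smooth_window, 0), t[d])
    t_onset <- refine_onset_power(t, x, w_, b, d, m_d, t0i,
                                  control$analysis_window)
  }
  t_onset <- max(t_onset, t[2L])
  f_min <- mean(x[t < t_onset])
  bsd <- stats::sd(x[t < t_onset])
  if (is.na(bsd)) bsd <- s0  # onset refined to the very start of the trace
  list(t_onset = t_onset, f_min = f_min,
       baseline_sd = bsd,
       baseline_mean = m_d,
       detect_index = d, noisy = noisy)
}

# Least-squares refinement of a noisy onset: fit the piecewise model
# baseline + c * max(0, t - t0)^gamma to the raw samples between ~3 s before
# the last sub-baseline sample and the 70%-amplitude crossing. Unbiased
# across rise shapes where the linear back-projection under-shoots convex
# rises. Falls back to the initial value when the fit is implausible.
refine_onset_power <- function(t, x, w_, b, d, m_d, t0i, analysis_window) {
  n <- length(t)
  after <- which(t > t[b] & t <= t[b] + analysis_window)
  if (length(after) < 3L) return(t0i)
  peak0 <- max(w_[after])
  a0 <- peak0 - m_d
  if (a0 <= 0) return(t0i)
  cross <- function(frac) {
    i <- after[which(w_[after] >= m_d + frac * a0)[1L]]
    if (is.na(i)) NA_real_ else t[i]
  }
  t70 <- cross(0.7)
  t50 <- cross(0.5)
  if (is.na(t70) || is.na(t50) || t50 <= t0i) return(t0i)
  seg <- which(t >= t[b] - 5 & t <= t70)
  if (length(seg) < 5L) return(t0i)
  obj <- function(p) {
    mu <- m_d + exp(p[3L]) * pmax(0, t[seg] - p[1L])^exp(p[2L])
    sum((x[seg] - mu)^2)
  }
  init <- c(t0i, 0, log(max(0.5 * a0 / (t50 - t0i), 1e-9)))
  op <- tryCatch(
    stats::optim(init, obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10)),
    error = function(e) NULL
  )
  dt <- stats::median(diff(t))
  # a convex rise can hide below the noise floor for many seconds before the
  # last sub-baseline sample, so allow the refined onset well before it; the
  # upper bound keeps it below the half-amplitude crossing (a spuriously
  # early detection must not cap a sound model fit)
  lo <- max(0, t[b] - 10)
  hi <- t50 - 2 * dt
  if (!is.null(op) && is.finite(op$par[1L]) &&
      op$par[1L] > lo && op$par[1L] < hi) {
    op$par[1L]
  } else {
    min(max(t0i, lo), max(hi, lo))
  }
}

#' Fit inflow-phase perfusion parameters to a time-intensity curve
#'
#' The core estimator: given a fluorescence time-intensity curve, it detects
#' the bolus-arrival onset ([detect_onset()]), locates the peak, and measures
#' the six perfusion parameters of the inflow phase (see
#' [perfusion_params()]): baseline `f_min`, amplitude `delta_f`, average
#' `slope`, and the onset-referenced times `t_max`, `t_half_max` and their
#' ratio `tr`.
#'
#' Measurement rules:
#' * The working trace is the raw curve when the baseline is noise-free,
#'   otherwise the `smooth_window` moving average (the raw curve is always
#'   retained for plotting).
#' * The peak value is the maximum of the working trace within
#'   `analysis_window` after onset; `t_max` is the first time the trace
#'   attains `(1 - plateau_epsilon)` of the peak above baseline (tolerance 0
#'   on noise-free traces), measured from onset.
#' * `t_half_max` is the first crossing of `f_min + delta_f / 2`, located by
#'   linear interpolation between the bracketing samples (sub-frame
#'   resolution), measured from onset.
#' * A curve still rising at the window end gets `t_max` right-censored at
#'   the window end, a `"peak not reached"` warning, and `censored = TRUE`.
#'
#' @param curve A [perfusion_curve()] with at least 10 samples.
#' @param control A [perfusion_control()].
#' @return An object of class `perfusion_fit` with components `params`
#'   (a [perfusion_params()]), `curve`, `smoothed`, `onset`, `censored`,
#'   `slope_fitted` (when `slope_method = "regression"`) and `control`.
#'   Supports `print()`, `summary()`, `coef()`, `plot()`, `fitted()`,
#'   `residuals()`, `predict()` and `simulate()`.
#' @examples
#' kt <- kinetic_truth(amplitude_a = 60, onset_t0 = 5, rise_duration = 30)
#' fit <- fit_perfusion(simulate_curve(kt, 10, 60))
#' coef(fit)
#' @export
fit_perfusion <- function(curve, control = perfusion_control()) {
  stopifnot(inherits(curve, "perfusion_curve"))
  if (length(curve$time) < 10L) {
    stop("a perfusion curve needs at least 10 samples for analysis",
         call. = FALSE)
  }
  fit <- fit_perfusion_pass(curve, control,
                            w_smooth = control$smooth_window,
                            w_plateau = 4 * control$smooth_window,
                            warn = FALSE)
  # second pass with a noise-matched bandwidth: on shallow, noisy rises the
  # half/peak crossing times have standard deviation ~ noise_sd / local slope,
  # so the window is widened until the smoothed noise is ~2.5% of the
  # amplitude, capped at an eighth of the measured rise so the crossing
  # geometry is preserved
  p1 <- fit$params
  sd1 <- fit$onset$baseline_sd
  fps <- 1 / curve_dt(curve)
  if (fit$onset$noisy && sd1 > 0) {
    n_needed <- (sd1 / (0.025 * p1$delta_f))^2
    w2 <- min(max(control$smooth_window, n_needed / fps), p1$t_max / 8)
    wp <- min(max(4 * control$smooth_window, 4 * w2), p1$t_max / 4, 10)
    wp <- max(wp, w2)
    if (w2 > 1.5 * control$smooth_window || wp < 2 * control$smooth_window) {
      fit <- fit_perfusion_pass(curve, control, w_smooth = w2,
                                w_plateau = wp, warn = FALSE)
    }
  }
  # a rise indistinguishable from the baseline noise band is not a measurable
  # perfusion signal
  if (fit$onset$noisy &&
      fit$params$delta_f < control$onset_k * fit$onset$baseline_sd) {
    stop_no_perfusion(
      "no perfusion detected: fluorescence rise not distinguishable from baseline noise")
  }
  if (fit$censored) {
    warning(warningCondition(
      "peak not reached: curve still rising at the analysis window end; t_max censored",
      class = c("icg_peak_censored", "warning", "condition")))
  }
  fit
}

fit_perfusion_pass <- function(curve, control, w_smooth, w_plateau,
                               warn = TRUE) {
  t <- curve$time
  x <- curve$intensity
  dt <- curve_dt(curve)

  ctl <- control
  ctl$smooth_window <- w_smooth
  ons <- detect_onset(curve, ctl)
  smoothed <- smooth_curve(curve, w_smooth)
  work <- if (ons$noisy) smoothed$intensity else x

  t_end <- min(ons$t_onset + control$analysis_window, t[length(t)])
  win <- which(t > ons$t_onset & t <= t_end)
  if (length(win) < 2L) {
    stop("internal-consistency error: no samples after onset", call. = FALSE)
  }
  # the peak is read from a plateau-grade (wider) smoother when noise is
  # present: the maximum of the lightly smoothed trace overshoots the true
  # plateau by the extreme value of its noise, inflating delta_f and delaying
  # the (1 - eps) attainment
  peak_trace <- if (ons$noisy) {
    smooth_curve(curve, w_plateau)$intensity
  } else {
    work
  }
  f_peak <- max(peak_trace[win])
  delta_f <- f_peak - ons$f_min
  if (delta_f <= 0) {
    stop_no_perfusion("no perfusion detected: no intensity rise above baseline")
  }
  # the plateau tolerance adapts to the residual noise of the peak trace:
  # the measured peak overshoots the true plateau by the extreme value of the
  # smoothed noise, and an attainment level above the true plateau would wait
  # for a late noise excursion and inflate t_max
  eps_eff <- if (ons$noisy) {
    np <- 2 * floor(w_plateau / (2 * dt) + 1e-9) + 1
    sigma_p <- ons$baseline_sd / sqrt(np)
    min(max(control$plateau_epsilon, 2.5 * sigma_p / delta_f), 0.25)
  } else {
    0
  }
  tol <- 1e-9 * max(1, abs(delta_f))
  level_max <- ons$f_min + (1 - eps_eff) * delta_f - tol
  attain <- win[which(work[win] >= level_max)[1L]]
  if (is.na(attain)) attain <- win[which.max(work[win])]
  t_attain <- t[attain]

  # peak attained only at the very edge of the window => still rising
  censored <- (t_end - t_attain) <= max(2 * w_smooth, 2 * dt)
  if (censored) {
    if (warn) {
      warning(warningCondition(
        "peak not reached: curve still rising at the analysis window end; t_max censored",
        class = c("icg_peak_censored", "warning", "condition")))
    }
    t_max <- t_end - ons$t_onset
  } else {
    t_max <- t_attain - ons$t_onset
  }

  lev_half <- ons$f_min + 0.5 * delta_f
  j_all <- which(t > ons$t_onset & work >= lev_half)
  j_all <- j_all[j_all <= max(win)]
  if (length(j_all) == 0L) {
    stop("internal-consistency error: half-maximum never reached",
         call. = FALSE)
  }
  j <- j_all[1L]
  if (j > 1L && work[j - 1L] < lev_half && t[j - 1L] >= ons$t_onset) {
    t_half_time <- t[j - 1L] +
      (lev_half - work[j - 1L]) / (work[j] - work[j - 1L]) * (t[j] - t[j - 1L])
  } else {
    t_half_time <- t[j]
  }
  if (t_half_time <= ons$t_onset) {
    stop("internal-consistency error: half-maximum crossing precedes onset",
         call. = FALSE)
  }
  t_half <- min(t_half_time - ons$t_onset, t_max)

  params <- perfusion_params(
    f_min = ons$f_min, delta_f = delta_f, slope = delta_f / t_max,
    t_onset = ons$t_onset, t_max = t_max, t_half_max = t_half,
    tr = t_half / t_max, censored = censored
  )

  slope_fitted <- NULL
  if (control$slope_method == "regression") {
    rise <- which(t >= ons$t_onset & t <= t_attain)
    if (length(rise) >= 2L) {
      slope_fitted <- unname(stats::lm.fit(cbind(1, t[rise]),
                                           work[rise])$coefficients[2L])
    }
  }

  structure(
    list(params = params, curve = curve, smoothed = smoothed, onset = ons,
         censored = censored, slope_fitted = slope_fitted, control = control,
         bandwidth = c(smooth = w_smooth, plateau = w_plateau)),
    class = "perfusion_fit"
  )
}

# Power-law kinetic model implied by a fitted parameter set; used for the
# fitted/residual/simulate methods and diagnostic overlays.
implied_truth <- function(object) {
  p <- object$params
  gamma <- log(0.5) / log(min(max(p$tr, 1e-6), 1 - 1e-6))
  kinetic_truth(baseline_f0 = p$f_min, amplitude_a = p$delta_f,
                onset_t0 = p$t_onset, rise_duration = p$t_max,
                shape_gamma = gamma, washout_rate = 0,
                noise_sd = object$onset$baseline_sd)
}

#' @export
print.perfusion_fit <- function(x, ...) {
  cat("Perfusion curve fit\n")
  print(x$params)
  if (!is.null(x$slope_fitted)) {
    cat(sprintf("  slope (regression over rise): %.4f AU/s\n", x$slope_fitted))
  }
  invisible(x)
}

#' @export
summary.perfusion_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.perfusion_fit")
}

#' @export
print.summary.perfusion_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  samples: %d at %.4g s spacing\n", length(f$curve$time),
              curve_dt(f$curve)))
  cat(sprintf("  baseline sd: %.4g AU (%s trace analysed)\n",
              f$onset$baseline_sd,
              if (f$onset$noisy) "smoothed" else "raw"))
  cat(sprintf("  onset detected at sample %d, refined to %.3f s\n",
              f$onset$detect_index, f$params$t_onset))
  invisible(x)
}

#' @export
coef.perfusion_fit <- function(object, ...) coef(object$params)

#' @export
fitted.perfusion_fit <- function(object, ...) {
  kinetic_intensity(implied_truth(object), object$curve$time)
}

#' @export
residuals.perfusion_fit <- function(object, ...) {
  object$curve$intensity - fitted(object)
}

#' @param object,x A `perfusion_fit`.
#' @param newdata Numeric vector of times (s); defaults to the fitted curve's
#'   sample times.
#' @rdname fit_perfusion
#' @export
predict.perfusion_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$curve$time
  kinetic_intensity(implied_truth(object), as.numeric(newdata))
}

#' @param nsim Number of curves to simulate.
#' @param seed Optional integer seed.
#' @rdname fit_perfusion
#' @export
simulate.perfusion_fit <- function(object, nsim = 1, seed = NULL, ...) {
  truth <- implied_truth(object)
  duration <- max(object$curve$time) + curve_dt(object$curve)
  fr <- object$curve$frame_rate %||% (1 / curve_dt(object$curve))
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    simulate_curve(truth, frame_rate = fr, duration = duration)
  }))
}

#' @rdname fit_perfusion
#' @export
plot.perfusion_fit <- function(x, ...) {
  p <- x$params
  graphics::plot(x$curve$time, x$curve$intensity, type = "l", col = "grey60",
                 xlab = "Time (s)", ylab = "Fluorescence intensity (AU)", ...)
  graphics::lines(x$smoothed$time, x$smoothed$intensity, col = "black")
  graphics::abline(h = p$f_min, lty = 3)
  graphics::abline(v = p$t_onset, lty = 2, col = "blue")
  graphics::abline(v = p$t_onset + p$t_half_max, lty = 2, col = "orange")
  graphics::abline(v = p$t_onset + p$t_max, lty = 2, col = "red")
  graphics::segments(p$t_onset, p$f_min, p$t_onset + p$t_max,
                     p$f_min + p$delta_f, col = "red")
  graphics::legend("bottomright",
                   legend = c("raw", "smoothed", "onset", "T_1/2MAX", "T_MAX"),
                   col = c("grey60", "black", "blue", "orange", "red"),
                   lty = c(1, 1, 2, 2, 2), bty = "n", cex = 0.8)
  invisible(x)
}
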