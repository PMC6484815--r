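#' Ground-truth kinetic model for a synthetic perfusion curve
#'
#' The simulator represents an ICG inflow curve as a flat baseline, a
#' power-law rise, and a plateau (optionally decaying):
#' \deqn{I(t) = F_0 \quad (t < t_0)}
#' \deqn{I(t) = F_0 + A\,((t - t_0)/d)^{\gamma} \quad (t_0 \le t \le t_0 + d)}
#' \deqn{I(t) = F_0 + A\,e^{-w (t - t_0 - d)} \quad (t > t_0 + d)}
#' with baseline \eqn{F_0}, amplitude \eqn{A}, onset \eqn{t_0}, rise duration
#' \eqn{d}, shape exponent \eqn{\gamma} and washout rate \eqn{w}.
#'
#' The inflow-phase perfusion parameters are then available in closed form:
#' `t_max = d`, `t_half_max = d * 0.5^(1/gamma)`, hence
#' `tr = 0.5^(1/gamma)` (always in (0, 1)), `slope = A / d`, `delta_f = A`.
#' The shape exponent is therefore a direct dial for the time ratio TR:
#' `gamma = log(0.5) / log(tr)`; a linear rise (`gamma = 1`) has TR = 0.5,
#' convex rises (`gamma > 1`, sluggish start) push TR toward 1, concave rises
#' (`gamma < 1`, brisk start) push it toward 0.
#'
#' @param baseline_f0 Baseline fluorescence before dye arrival (AU).
#' @param amplitude_a Rise amplitude above baseline (AU, > 0; 0 is allowed and
#'   produces a flat no-perfusion curve).
#' @param onset_t0 Onset time of the first fluorescence increase (s, >= 0).
#' @param rise_duration Duration of the rise from onset to maximum (s, > 0);
#'   equals the analytic T_MAX.
#' @param shape_gamma Dimensionless rise-shape exponent (> 0).
#' @param washout_rate Post-peak exponential decay rate (1/s, >= 0; 0 keeps a
#'   flat plateau).
#' @param noise_sd Standard deviation of additive Gaussian sample noise (AU,
#'   >= 0).
#' @return An object of class `kinetic_truth`.
#' @seealso [true_params()], [simulate_curve()], [simulate_frame_stack()]
#' @examples
#' kt <- kinetic_truth(amplitude_a = 60, onset_t0 = 5, rise_duration = 30)
#' true_params(kt)$tr  # 0.5 for a linear rise
#' @export
kinetic_truth <- function(baseline_f0 = 10, amplitude_a = 50, onset_t0 = 5,
                          rise_duration = 30, shape_gamma = 1,
                          washout_rate = 0, noise_sd = 0) {
  num1 <- function(v, nm) {
    if (length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    as.numeric(v)
  }
  baseline_f0 <- num1(baseline_f0, "baseline_f0")
  amplitude_a <- num1(amplitude_a, "amplitude_a")
  onset_t0 <- num1(onset_t0, "onset_t0")
  rise_duration <- num1(rise_duration, "rise_duration")
  shape_gamma <- num1(shape_gamma, "shape_gamma")
  washout_rate <- num1(washout_rate, "washout_rate")
  noise_sd <- num1(noise_sd, "noise_sd")
  if (amplitude_a < 0) stop("`amplitude_a` must be >= 0", call. = FALSE)
  if (onset_t0 < 0) stop("`onset_t0` must be >= 0", call. = FALSE)
  if (rise_duration <= 0) stop("`rise_duration` must be > 0", call. = FALSE)
  if (shape_gamma <= 0) stop("`shape_gamma` must be > 0", call. = FALSE)
  if (washout_rate < 0) stop("`washout_rate` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(baseline_f0 = baseline_f0, amplitude_a = amplitude_a,
         onset_t0 = onset_t0, rise_duration = rise_duration,
         shape_gamma = shape_gamma, washout_rate = washout_rate,
         noise_sd = noise_sd),
    class = "kinetic_truth"
  )
}

#' @export
print.kinetic_truth <- function(x, ...) {
  cat("Kinetic ground truth (baseline -> power-law rise -> plateau)\n")
  cat(sprintf("  F0 = %g AU, A = %g AU, t0 = %g s, rise = %g s, gamma = %g\n",
              x$baseline_f0, x$amplitude_a, x$onset_t0, x$rise_duration,
              x$shape_gamma))
  cat(sprintf("  washout = %g /s, noise sd = %g AU\n",
              x$washout_rate, x$noise_sd))
  tp <- true_params(x)
  cat(sprintf("  analytic: T_MAX = %g s, T_1/2MAX = %.4g s, TR = %.4g, slope = %.4g AU/s\n",
              tp$t_max, tp$t_half_max, tp$tr, tp$slope))
  invisible(x)
}

#' Evaluate the noiseless kinetic model
#'
#' @param truth A [kinetic_truth()].
#' @param t Numeric vector of times (s).
#' @return Noiseless intensities (AU) at `t`.
#' @export
kinetic_intensity <- function(truth, t) {
  stopifnot(inherits(truth, "kinetic_truth"))
  t <- as.numeric(t)
  tt <- t - truth$onset_t0
  y <- rep(truth$baseline_f0, length(t))
  rise <- tt >= 0 & tt <= truth$rise_duration
  y[rise] <- truth$baseline_f0 +
    truth$amplitude_a * (tt[rise] / truth$rise_duration)^truth$shape_gamma
  post <- tt > truth$rise_duration
  y[post] <- truth$baseline_f0 +
    truth$amplitude_a * exp(-truth$washout_rate * (tt[post] - truth$rise_duration))
  y
}

#' Analytic perfusion parameters of a kinetic ground truth
#'
#' Closed-form values of the quantities that [fit_perfusion()] estimates from
#' data: baseline `f_min`, amplitude `delta_f`, `slope`, onset `t_onset`,
#' `t_max`, `t_half_max` and `tr`. The peak occurs at the end of the rise for
#' any washout rate, so `t_max = rise_duration` and
#' `tr = 0.5^(1/shape_gamma)` exactly.
#'
#' @param truth A [kinetic_truth()].
#' @return An object of class `perfusion_params` (a named list).
#' @export
true_params <- function(truth) {
  stopifnot(inherits(truth, "kinetic_truth"))
  tr <- 0.5^(1 / truth$shape_gamma)
  perfusion_params(
    f_min = truth$baseline_f0,
    delta_f = truth$amplitude_a,
    slope = truth$amplitude_a / truth$rise_duration,
    t_onset = truth$onset_t0,
    t_max = truth$rise_duration,
    t_half_max = truth$rise_duration * tr,
    tr = tr,
    censored = FALSE
  )
}

#' Simulate a sampled perfusion curve from a kinetic ground truth
#'
#' Samples the kinetic model at frame times `i / frame_rate` (0-based frame
#' index, covering `[0, duration)`) and adds independent Gaussian noise of
#' standard deviation `truth$noise_sd` to every sample.
#'
#' @param truth A [kinetic_truth()].
#' @param frame_rate Sampling rate (frames/second, > 0).
#' @param duration Recording duration (s); must exceed
#'   `onset_t0 + rise_duration` so the curve reaches its maximum.
#' @param seed Optional integer seed; when given, the global RNG state is left
#'   untouched and the same seed reproduces the same curve.
#' @return A [perfusion_curve()] with the generating `kinetic_truth` attached
#'   as attribute `"truth"`.
#' @examples
#' kt <- kinetic_truth(amplitude_a = 60, onset_t0 = 5, rise_duration = 30)
#' pc <- simulate_curve(kt, frame_rate = 10, duration = 50, seed = 1)
#' @export
simulate_curve <- function(truth, frame_rate, duration, seed = NULL) {
  stopifnot(inherits(truth, "kinetic_truth"))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("invalid specification: `frame_rate` must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L ||
      duration <= truth$onset_t0 + truth$rise_duration) {
    stop("invalid specification: `duration` must exceed onset_t0 + rise_duration",
         call. = FALSE)
  }
  n <- floor(duration * frame_rate)
  t <- (seq_len(n) - 1L) / frame_rate
  y <- kinetic_intensity(truth, t)
  if (truth$noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(n, sd = truth$noise_sd))
  }
  pc <- perfusion_curve(t, y, frame_rate = frame_rate)
  attr(pc, "truth") <- truth
  pc
}

# Run `expr` under a temporary RNG state when `seed` is non-NULL; otherwise
# use (and advance) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
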