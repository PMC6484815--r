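#' Perfusion parameter set
#'
#' The six inflow-phase quantities of a fluorescence time-intensity curve,
#' plus the absolute onset time:
#' \describe{
#'   \item{f_min}{baseline fluorescence before dye arrival (AU).}
#'   \item{delta_f}{fluorescence difference between maximum and baseline (AU).}
#'   \item{slope}{average rate of rise, `delta_f / t_max` (AU/s).}
#'   \item{t_onset}{absolute time of the first fluorescence increase (s).}
#'   \item{t_max}{time from onset to maximum fluorescence (s).}
#'   \item{t_half_max}{time from onset to the first crossing of half of
#'     `delta_f` above baseline (s).}
#'   \item{tr}{time ratio `t_half_max / t_max` (dimensionless, in (0, 1]); a
#'     shape descriptor of the inflow — values near 1 mean a sluggish early
#'     rise (slow perfusion).}
#' }
#'
#' Users normally obtain one from [fit_perfusion()] (estimated from data) or
#' [true_params()] (analytic, from a simulated ground truth) rather than
#' calling this constructor directly.
#'
#' @param f_min,delta_f,slope,t_onset,t_max,t_half_max,tr See Details.
#' @param censored Logical; `TRUE` when the curve was still rising at the end
#'   of the analysis window and `t_max` is right-censored there.
#' @return An object of class `perfusion_params` (named list).
#' @export
perfusion_params <- function(f_min, delta_f, slope, t_onset, t_max,
                             t_half_max, tr, censored = FALSE) {
  p <- list(f_min = as.numeric(f_min), delta_f = as.numeric(delta_f),
            slope = as.numeric(slope), t_onset = as.numeric(t_onset),
            t_max = as.numeric(t_max), t_half_max = as.numeric(t_half_max),
            tr = as.numeric(tr), censored = isTRUE(censored))
  if (p$delta_f <= 0) stop("`delta_f` must be > 0", call. = FALSE)
  if (p$t_max <= 0 || p$t_half_max <= 0) {
    stop("`t_max` and `t_half_max` must be > 0", call. = FALSE)
  }
  if (p$t_half_max > p$t_max + 1e-9) {
    stop("`t_half_max` must not exceed `t_max`", call. = FALSE)
  }
  if (p$tr <= 0 || p$tr > 1 + 1e-9) stop("`tr` must lie in (0, 1]", call. = FALSE)
  if (abs(p$slope * p$t_max - p$delta_f) > 1e-6 * max(1, abs(p$delta_f))) {
    stop("inconsistent parameters: slope * t_max must equal delta_f",
         call. = FALSE)
  }
  class(p) <- "perfusion_params"
  p
}

#' @export
print.perfusion_params <- function(x, ...) {
  cat("Perfusion parameters\n")
  cat(sprintf("  F_MIN    %8.3f AU%s\n", x$f_min, ""))
  cat(sprintf("  dF       %8.3f AU\n", x$delta_f))
  cat(sprintf("  slope    %8.4f AU/s\n", x$slope))
  cat(sprintf("  t_onset  %8.3f s\n", x$t_onset))
  cat(sprintf("  T_MAX    %8.3f s%s\n", x$t_max,
              if (x$censored) "  (censored at window end)" else ""))
  cat(sprintf("  T_1/2MAX %8.3f s\n", x$t_half_max))
  cat(sprintf("  TR       %8.4f\n", x$tr))
  invisible(x)
}

#' @export
coef.perfusion_params <- function(object, ...) {
  c(f_min = object$f_min, delta_f = object$delta_f, slope = object$slope,
    t_onset = object$t_onset, t_max = object$t_max,
    t_half_max = object$t_half_max, tr = object$tr)
}

#' @export
as.data.frame.perfusion_params <- function(x, ...) {
  data.frame(f_min = x$f_min, delta_f = x$delta_f, slope = x$slope,
             t_onset = x$t_onset, t_max = x$t_max, t_half_max = x$t_half_max,
             tr = x$tr, censored = x$censored)
}
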