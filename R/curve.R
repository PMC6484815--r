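#' Construct a perfusion time-intensity curve
#'
#' A `perfusion_curve` is a sampled fluorescence time-intensity trace: the raw
#' material of quantitative ICG angiography. Times are in seconds and strictly
#' increasing; intensities are in arbitrary units (AU), the uncalibrated scale
#' of a fluorescence laparoscope.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing,
#'   non-negative.
#' @param intensity Numeric vector of fluorescence intensities (AU), same
#'   length as `time`.
#' @param frame_rate Optional frames/second; recorded when the curve was
#'   derived from a video frame stack (sample times are then `i / frame_rate`
#'   for 0-based frame index `i`).
#' @return An object of class `perfusion_curve`: a list with elements `time`,
#'   `intensity` and `frame_rate`.
#' @seealso [simulate_curve()], [extract_curve()], [fit_perfusion()]
#' @examples
#' pc <- perfusion_curve(seq(0, 9, by = 0.5), c(rep(10, 10), 10 + 1:10))
#' print(pc)
#' @export
perfusion_curve <- function(time, intensity, frame_rate = NULL) {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity)) {
    stop("`time` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a perfusion curve needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(time) || anyNA(intensity)) {
    stop("`time` and `intensity` must not contain NA", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (time[1L] < 0) {
    stop("`time` must be non-negative", call. = FALSE)
  }
  if (!is.null(frame_rate)) {
    frame_rate <- as.numeric(frame_rate)
    if (length(frame_rate) != 1L || !is.finite(frame_rate) || frame_rate <= 0) {
      stop("`frame_rate` must be a single positive number", call. = FALSE)
    }
  }
  structure(
    list(time = time, intensity = intensity, frame_rate = frame_rate),
    class = "perfusion_curve"
  )
}

#' @export
print.perfusion_curve <- function(x, ...) {
  cat("Perfusion time-intensity curve\n")
  cat(sprintf("  %d samples over %.2f .. %.2f s", length(x$time),
              x$time[1L], x$time[length(x$time)]))
  if (!is.null(x$frame_rate)) cat(sprintf(" (%g fps)", x$frame_rate))
  cat("\n")
  cat(sprintf("  intensity range %.3g .. %.3g AU\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
as.data.frame.perfusion_curve <- function(x, ...) {
  data.frame(time_s = x$time, intensity_au = x$intensity)
}

#' @export
length.perfusion_curve <- function(x) length(x$time)

#' @param x A `perfusion_curve`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @rdname perfusion_curve
#' @export
plot.perfusion_curve <- function(x, ...) {
  graphics::plot(x$time, x$intensity, type = "l",
                 xlab = "Time (s)", ylab = "Fluorescence intensity (AU)", ...)
  invisible(x)
}

#' Read / write a perfusion curve as CSV
#'
#' The on-disk exchange format is a two-column CSV with header
#' `time_s,intensity_au`.
#'
#' @param path File path.
#' @param frame_rate Optional frame rate to attach on read (frames/second).
#' @return `read_curve_csv()` returns a [perfusion_curve()];
#'   `write_curve_csv()` returns `path` invisibly.
#' @export
read_curve_csv <- function(path, frame_rate = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "intensity_au") %in% names(d))) {
    stop("curve CSV must have columns `time_s` and `intensity_au`",
         call. = FALSE)
  }
  perfusion_curve(d$time_s, d$intensity_au, frame_rate = frame_rate)
}

#' @param curve A [perfusion_curve()].
#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "perfusion_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

# Median inter-sample interval; curves from frame stacks are uniform so this
# is just 1/fps, but CSV input may be irregular.
curve_dt <- function(curve) {
  stats::median(diff(curve$time))
}
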