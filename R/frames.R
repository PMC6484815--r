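#' Specify a synthetic fluorescence frame stack
#'
#' Geometry and noise model for rendering a [kinetic_truth()] as a video-like
#' stack of single-channel frames: pixels inside the region of interest (ROI)
#' follow the noiseless kinetic trajectory plus independent per-pixel Gaussian
#' noise; pixels outside stay at a constant background level plus noise.
#'
#' @param height,width Frame dimensions in pixels.
#' @param frame_rate Frames per second (> 0).
#' @param duration Recording duration (s).
#' @param roi_mask Logical `height x width` matrix with at least one `TRUE`
#'   pixel; default is a centred square covering half of each dimension.
#' @param background_level Intensity outside the ROI (AU).
#' @param pixel_noise_sd Per-pixel additive Gaussian noise SD (AU).
#' @return An object of class `frame_stack_spec`.
#' @seealso [simulate_frame_stack()]
#' @export
frame_stack_spec <- function(height = 64, width = 64, frame_rate = 10,
                             duration = 60, roi_mask = NULL,
                             background_level = 10, pixel_noise_sd = 0) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1 || width < 1) {
    stop("invalid specification: frame dimensions must be positive",
         call. = FALSE)
  }
  if (frame_rate <= 0 || duration <= 0) {
    stop("invalid specification: `frame_rate` and `duration` must be positive",
         call. = FALSE)
  }
  if (is.null(roi_mask)) {
    roi_mask <- matrix(FALSE, height, width)
    rows <- seq.int(floor(height / 4) + 1L, floor(3 * height / 4))
    cols <- seq.int(floor(width / 4) + 1L, floor(3 * width / 4))
    roi_mask[rows, cols] <- TRUE
  }
  roi_mask <- as.matrix(roi_mask)
  storage.mode(roi_mask) <- "logical"
  if (!identical(dim(roi_mask), c(height, width))) {
    stop("invalid specification: `roi_mask` must match height x width",
         call. = FALSE)
  }
  if (!any(roi_mask)) {
    stop("invalid specification: `roi_mask` must contain at least one TRUE pixel",
         call. = FALSE)
  }
  structure(
    list(height = height, width = width, frame_rate = as.numeric(frame_rate),
         duration = as.numeric(duration), roi_mask = roi_mask,
         background_level = as.numeric(background_level),
         pixel_noise_sd = as.numeric(pixel_noise_sd)),
    class = "frame_stack_spec"
  )
}

#' Render a kinetic ground truth as a frame stack on disk
#'
#' Writes the stack either as a single multi-page grayscale TIFF
#' (32-bit float samples, the lossless default) or as a directory of
#' zero-padded grayscale PNG frames (8-bit, i.e. quantized storage). Intensities are min-max normalised to `[0, 1]` for storage; a
#' sidecar JSON file (`<path>.json` for TIFF, `metadata.json` inside a PNG
#' directory) records `frame_rate_fps`, the affine storage transform
#' (`intensity_offset`, `intensity_scale`; AU = offset + scale * stored) and
#' the generating truth parameters, so [read_frames()] can restore intensities
#' in AU.
#'
#' @param truth A [kinetic_truth()].
#' @param spec A [frame_stack_spec()].
#' @param path Output path: a `.tif`/`.tiff` file name for TIFF, otherwise a
#'   directory name for PNG frames.
#' @param format `"tiff"` or `"png"`.
#' @param seed Optional integer seed for the pixel noise.
#' @return `path`, invisibly.
#' @export
simulate_frame_stack <- function(truth, spec, path, format = c("tiff", "png"),
                                 seed = NULL) {
  stopifnot(inherits(truth, "kinetic_truth"), inherits(spec, "frame_stack_spec"))
  format <- match.arg(format)
  n <- floor(spec$duration * spec$frame_rate)
  if (n < 1) stop("invalid specification: no frames to render", call. = FALSE)
  t <- (seq_len(n) - 1L) / spec$frame_rate
  traj <- kinetic_intensity(truth, t)
  npx <- spec$height * spec$width
  frames <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      f <- matrix(spec$background_level, spec$height, spec$width)
      f[spec$roi_mask] <- traj[i]
      if (spec$pixel_noise_sd > 0) {
        f <- f + matrix(stats::rnorm(npx, sd = spec$pixel_noise_sd),
                        spec$height, spec$width)
      }
      f
    })
  })
  lo <- min(vapply(frames, min, 0))
  hi <- max(vapply(frames, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  stored <- lapply(frames, function(f) (f - lo) / scale)
  meta <- list(frame_rate_fps = spec$frame_rate, intensity_offset = lo,
               intensity_scale = scale, n_frames = n,
               truth = unclass(truth))
  ok <- tryCatch({
    if (format == "tiff") {
      tiff::writeTIFF(stored, path, bits.per.sample = 32)
      jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                           digits = NA)
    } else {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      for (i in seq_len(n)) {
        png::writePNG(stored[[i]],
                      file.path(path, sprintf("frame_%06d.png", i - 1L)))
      }
      jsonlite::write_json(meta, file.path(path, "metadata.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    TRUE
  }, error = function(e) e)
  if (inherits(ok, "error")) {
    stop("I/O error writing frame stack: ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

# Reduce one decoded frame (matrix or h x w x ch array) to a single channel.
select_channel <- function(img, channel) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) != 3L) {
    stop("format error: unsupported frame layout", call. = FALSE)
  }
  nc <- dim(img)[3L]
  if (channel == "mean") {
    out <- apply(img[, , seq_len(min(nc, 3L)), drop = FALSE], c(1, 2), mean)
    return(out)
  }
  idx <- switch(channel, red = 1L, green = 2L, blue = 3L)
  if (nc < idx) idx <- 1L  # grayscale+alpha stacks: first plane is intensity
  img[, , idx]
}

#' Read a fluorescence frame stack
#'
#' Accepts a multi-page TIFF file or a directory of PNG/TIFF frames (sorted by
#' file name). When a sidecar JSON written by [simulate_frame_stack()] is
#' present, the frame rate and the affine intensity transform are taken from
#' it; otherwise `frame_rate` must be supplied. Multi-channel frames are
#' reduced by a channel selector, defaulting to the green channel (the usual
#' display channel of fluorescence emission overlays).
#'
#' @param path TIFF file or frame directory.
#' @param frame_rate Frames/second; required when no sidecar metadata exists.
#' @param channel One of `"green"`, `"red"`, `"blue"`, `"mean"`.
#' @return An object of class `frame_stack`: a list with `frames` (list of
#'   numeric matrices in AU), `frame_rate`, and `truth` (a [kinetic_truth()]
#'   when recorded in the sidecar, else `NULL`).
#' @export
read_frames <- function(path, frame_rate = NULL,
                        channel = c("green", "red", "blue", "mean")) {
  channel <- match.arg(channel)
  meta <- NULL
  if (dir.exists(path)) {
    mf <- file.path(path, "metadata.json")
    if (file.exists(mf)) meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      stop("format error: no frame files found in ", path, call. = FALSE)
    }
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      select_channel(img, channel)
    })
  } else if (file.exists(path)) {
    mf <- paste0(path, ".json")
    if (file.exists(mf)) meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.array(pages) || is.matrix(pages)) pages <- list(pages)
    frames <- lapply(pages, select_channel, channel = channel)
  } else {
    stop("format error: ", path, " does not exist", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: frames have mixed dimensions", call. = FALSE)
  }
  if (!is.null(meta)) {
    off <- meta$intensity_offset %||% 0
    sc <- meta$intensity_scale %||% 1
    frames <- lapply(frames, function(f) off + sc * f)
    if (is.null(frame_rate)) frame_rate <- meta$frame_rate_fps
  }
  if (is.null(frame_rate)) {
    stop("configuration error: `frame_rate` missing (no sidecar metadata)",
         call. = FALSE)
  }
  truth <- NULL
  if (!is.null(meta$truth)) truth <- do.call(kinetic_truth, as.list(meta$truth))
  structure(list(frames = frames, frame_rate = as.numeric(frame_rate),
                 truth = truth),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %d x %d px at %g fps\n",
              length(x$frames), d[1], d[2], x$frame_rate))
  invisible(x)
}

#' Rectangular region-of-interest mask
#'
#' Builds a logical mask from pixel coordinates `(x0, y0)` (top-left,
#' inclusive) to `(x1, y1)` (exclusive): 0-based, half-open on the upper
#' bounds, with `x` indexing columns and `y` rows.
#'
#' @param x0,y0,x1,y1 Rectangle bounds (0-based pixels, half-open upper).
#' @param height,width Frame dimensions.
#' @return A logical `height x width` matrix.
#' @export
roi_rect <- function(x0, y0, x1, y1, height, width) {
  if (x1 <= x0 || y1 <= y0 || x0 < 0 || y0 < 0 || x1 > width || y1 > height) {
    stop("invalid ROI rectangle", call. = FALSE)
  }
  m <- matrix(FALSE, height, width)
  m[(y0 + 1L):y1, (x0 + 1L):x1] <- TRUE
  m
}

#' Extract the ROI-mean time-intensity curve from a frame stack
#'
#' The intensity at frame `i` is the arithmetic mean of the pixel values
#' inside the ROI; sample times are `i / frame_rate` for 0-based `i`. This is
#' the measurement step that turns a fluorescence video into the perfusion
#' graph analysed by [fit_perfusion()].
#'
#' @param frames A `frame_stack` from [read_frames()], or a list of numeric
#'   matrices.
#' @param roi Logical mask matrix matching the frame dimensions, or a numeric
#'   rectangle `c(x0, y0, x1, y1)` as in [roi_rect()].
#' @param frame_rate Frames/second; defaults to the stack's recorded rate.
#' @return A [perfusion_curve()].
#' @export
extract_curve <- function(frames, roi, frame_rate = NULL) {
  if (inherits(frames, "frame_stack")) {
    if (is.null(frame_rate)) frame_rate <- frames$frame_rate
    frames <- frames$frames
  }
  if (is.null(frame_rate)) {
    stop("configuration error: `frame_rate` missing", call. = FALSE)
  }
  if (length(frames) < 2L) {
    stop("format error: need at least 2 frames", call. = FALSE)
  }
  d <- dim(frames[[1]])
  if (is.numeric(roi) && length(roi) == 4L) {
    roi <- roi_rect(roi[1], roi[2], roi[3], roi[4], d[1], d[2])
  }
  roi <- as.matrix(roi)
  storage.mode(roi) <- "logical"
  if (!identical(dim(roi), d)) {
    stop("invalid ROI: mask does not match frame dimensions", call. = FALSE)
  }
  if (!any(roi)) stop("invalid ROI: empty mask", call. = FALSE)
  y <- vapply(frames, function(f) mean(f[roi]), 0)
  t <- (seq_along(frames) - 1L) / frame_rate
  perfusion_curve(t, y, frame_rate = frame_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
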