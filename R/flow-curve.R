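# The flow curve: bright-pixel area of a fixed vertical image slice as a
# function of time, sampled on the uniform camera grid t_k = k / fps.

#' Construct a flow curve
#'
#' A flow curve is the central measured object of the cone-growth method:
#' the bright-area time series of one vertical slice of the recording.
#'
#' @param areas numeric vector of bright areas (pixels), non-negative.
#' @param times optional numeric vector of times in seconds, strictly
#'   increasing, same length as `areas`. Defaults to the uniform grid
#'   `(0:(n-1)) / fps`.
#' @param fps frames per second of the recording (default 25).
#' @return An object of class `"flow_curve"`: a list with elements
#'   `times`, `areas` and `fps`.
#' @examples
#' fc <- flow_curve(10 * (0:99)^(1/3))
#' print(fc)
#' @export
flow_curve <- function(areas, times = NULL, fps = 25) {
  if (!is.numeric(areas) || length(areas) < 2 || any(!is.finite(areas))) {
    stop("`areas` must be a finite numeric vector of length >= 2",
         call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (is.null(times)) {
    times <- (seq_along(areas) - 1) / fps
  }
  if (length(times) != length(areas)) {
    stop("`times` and `areas` must have the same length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), areas = as.numeric(areas),
                 fps = fps),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("Flow curve: %d frames at %g fps (%.2f s)\n",
              length(x$areas), x$fps, max(x$times)))
  cat(sprintf("  area range: %.1f .. %.1f px\n",
              min(x$areas), max(x$areas)))
  invisible(x)
}

#' @export
as.data.frame.flow_curve <- function(x, ...) {
  data.frame(frame = seq_along(x$areas) - 1L, time_s = x$times,
             area_px = x$areas)
}

#' @export
length.flow_curve <- function(x) length(x$areas)

#' @export
plot.flow_curve <- function(x, xlab = "time (s)", ylab = "bright area (px)",
                            type = "l", ...) {
  graphics::plot(x$times, x$areas, xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

#' Read and write flow curves as CSV
#'
#' The on-disk format is a comma-separated file with a mandatory header.
#' `write_flow_curve()` writes columns `frame,time_s,area_px`;
#' `read_flow_curve()` accepts that schema or any file with recognizable
#' time (`time`, `time_s`, `t`) and area (`area`, `area_px`, `y`)
#' columns.
#'
#' @param curve a [flow_curve()] object.
#' @param path path of the CSV file.
#' @param fps frames per second used when the file carries no time column;
#'   also stored on the returned curve (default 25).
#' @return `read_flow_curve()` returns a `"flow_curve"`;
#'   `write_flow_curve()` returns `path` invisibly.
#' @export
write_flow_curve <- function(curve, path) {
  stopifnot(inherits(curve, "flow_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_curve
#' @export
read_flow_curve <- function(path, fps = 25) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  a_col <- match(TRUE, nm %in% c("area_px", "area", "y"))
  if (is.na(a_col)) stop("no area column (area_px/area/y) in ", path,
                         call. = FALSE)
  t_col <- match(TRUE, nm %in% c("time_s", "time", "t"))
  times <- if (!is.na(t_col)) df[[t_col]] else NULL
  if (!is.null(times) && length(times) > 1) {
    dt <- diff(times)
    if (all(abs(dt - dt[1]) < 1e-9) && dt[1] > 0) fps <- 1 / dt[1]
  }
  flow_curve(df[[a_col]], times = times, fps = fps)
}
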