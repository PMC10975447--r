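# Frame-level image analysis: binarization, vertical slicing into bands,
# bright-area measurement, static angle of repose from the final pile,
# flow time from the plateau of the curve, and Crofton-perimeter shape
# measures.
#
# Coordinates: frames are matrices with row 1 = top of the image and
# columns 1..W left to right. Column bands are half-open in 0-based pixel
# coordinates; pile height is counted upward from the bottom row.

#' Construct an image stack
#'
#' An ordered sequence of equally sized grayscale frames at a fixed frame
#' rate, as produced by the recording rig (25 fps, 128 x 160 px in the
#' reference setup) or by [simulate_pile_stack()].
#'
#' @param frames list of numeric matrices (grayscale intensities), all of
#'   identical dimensions; at least 2 frames.
#' @param fps frames per second (default 25).
#' @return Object of class `"image_stack"`.
#' @export
image_stack <- function(frames, fps = 25) {
  if (!is.list(frames) || length(frames) < 2) {
    stop("`frames` must be a list of at least 2 matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) stop("`fps` must be positive",
                                         call. = FALSE)
  structure(list(frames = frames, fps = fps,
                 dim = c(rows = dims[1, 1], cols = dims[2, 1])),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Image stack: %d frames of %d x %d px at %g fps\n",
              length(x$frames), x$dim[1], x$dim[2], x$fps))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read an image stack from a directory of frames
#'
#' Reads all PNG (and, if the tiff package is available, TIFF) files in
#' `dir` in numeric filename order and returns an [image_stack()].
#' Multi-channel images are collapsed to grayscale by channel averaging;
#' intensities are scaled to 0..255.
#'
#' @param dir directory containing the extracted frames.
#' @param fps frames per second of the recording (default 25).
#' @return An `"image_stack"`.
#' @export
read_image_stack <- function(dir, fps = 25) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) < 2) stop("need at least 2 frame files in ", dir,
                              call. = FALSE)
  # numeric sort on the digits embedded in the file name
  key <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  files <- files[order(key, basename(files))]
  read_one <- function(f) {
    ext <- tolower(tools::file_ext(f))
    img <- if (ext == "png") {
      png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF frames",
             call. = FALSE)
      }
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3) img <- rowMeans(img, dims = 2)
    img * 255
  }
  image_stack(lapply(files, read_one), fps = fps)
}

#' Binarize a grayscale frame
#'
#' Separates bright space (particles) from the dark background. With
#' `method = "otsu"` (default) the global threshold is chosen by Otsu's
#' criterion, appropriate for the bimodal histograms produced by forward
#' illumination against a black pane; `method = "fixed"` uses the
#' supplied `threshold`.
#'
#' @param frame numeric matrix of grayscale intensities (0..255).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity cut for `method = "fixed"`; pixels strictly
#'   above it are bright.
#' @param range intensity range of the frames (default `c(0, 255)`).
#' @return Logical matrix the size of `frame` (TRUE = bright).
#' @export
binarize_frame <- function(frame, method = c("otsu", "fixed"),
                           threshold = NULL, range = c(0, 255)) {
  method <- match.arg(method)
  if (!is.matrix(frame) || length(frame) == 0) {
    stop("`frame` must be a non-empty matrix", call. = FALSE)
  }
  if (method == "fixed") {
    if (is.null(threshold) || !is.numeric(threshold) ||
        threshold < range[1] || threshold > range[2]) {
      stop("`threshold` must lie within the intensity range for method ",
           "\"fixed\"", call. = FALSE)
    }
  } else {
    if (diff(base::range(frame)) == 0) {
      warning("constant frame: Otsu threshold undefined, returning ",
              "all-background mask", call. = FALSE)
      return(matrix(FALSE, nrow(frame), ncol(frame)))
    }
    threshold <- EBImage::otsu(frame, range = range, levels = 256L)
  }
  frame > threshold
}

#' Default analysis slice
#'
#' The analysed band should sit as close to the middle of the frame as
#' possible without being crossed by the falling bulk jet under the
#' nozzle. The rule used here places it `max(1, n_slices/8)` bands
#' off-center toward lower column indices (index 11 for the standard 32
#' slices), clamped to the valid range; it can always be overridden.
#'
#' @param n_slices number of vertical bands the frame is cut into
#'   (>= 4; default 32).
#' @return 0-based slice index.
#' @export
default_slice_index <- function(n_slices = 32) {
  if (!is.numeric(n_slices) || n_slices < 4) {
    stop("`n_slices` must be at least 4", call. = FALSE)
  }
  n_slices <- as.integer(n_slices)
  off <- max(1L, as.integer(round(n_slices / 8)))
  max(0L, n_slices %/% 2L - 1L - off)
}

.slice_cols <- function(width, n_slices, slice_index) {
  if (slice_index < 0 || slice_index >= n_slices) {
    stop("`slice_index` must be in [0, n_slices)", call. = FALSE)
  }
  lo <- floor(slice_index * width / n_slices)        # 0-based half-open
  hi <- floor((slice_index + 1) * width / n_slices)
  if (hi - lo < 1) stop("slice band narrower than 1 px", call. = FALSE)
  (lo + 1):hi                                        # 1-based columns
}

#' Extract a flow curve from an image stack by vertical slicing
#'
#' Cuts each frame vertically into `n_slices` equal bands, binarizes the
#' chosen band and counts its bright pixels, yielding the bright-area
#' time series (the flow curve) on the grid `t_k = k / fps`.
#'
#' @param stack an [image_stack()].
#' @param n_slices number of equal vertical bands (default 32).
#' @param slice_index 0-based index of the analysed band; default
#'   [default_slice_index()].
#' @param method,threshold binarization settings, see [binarize_frame()].
#' @return A [flow_curve()] with areas in pixels. The analysed column
#'   range is attached as attribute `"cols"`.
#' @export
slice_area_series <- function(stack, n_slices = 32,
                              slice_index = default_slice_index(n_slices),
                              method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  cols <- .slice_cols(stack$dim[["cols"]], n_slices, slice_index)
  # threshold each full frame, then count bright pixels inside the band
  areas <- vapply(stack$frames, function(fr) {
    mask <- binarize_frame(fr, method = method, threshold = threshold)
    sum(mask[, cols])
  }, numeric(1))
  out <- flow_curve(areas, fps = stack$fps)
  attr(out, "cols") <- base::range(cols)
  out
}

# Upper envelope of the pile: height (px above the bottom row) of the
# topmost bright pixel of each column; 0 for empty columns.
.pile_profile <- function(mask) {
  nr <- nrow(mask)
  apply(mask, 2, function(col) {
    top <- match(TRUE, col)
    if (is.na(top)) 0 else nr - top + 1
  })
}

#' Static angle of repose from the final pile silhouette
#'
#' Fits a least-squares line through the upper envelope of each flank of
#' the settled pile and returns the mean absolute slope angle of the two
#' sides, in degrees. To avoid bias from apex rounding and base
#' spreading, envelope points above 90% of the pile height and within
#' the bottom 2 rows are excluded from the fits.
#'
#' @param final_mask logical matrix (TRUE = particle) of the last frame,
#'   containing a single pile resting on the bottom row.
#' @return Static angle of repose in degrees. Per-side angles are
#'   attached as attribute `"sides"`.
#' @export
measure_static_angle <- function(final_mask) {
  if (!is.logical(final_mask) || !is.matrix(final_mask)) {
    stop("`final_mask` must be a logical matrix", call. = FALSE)
  }
  if (!any(final_mask)) stop("empty mask: no pile to measure", call. = FALSE)
  if (!any(final_mask[nrow(final_mask), ])) {
    stop("pile does not touch the bottom row", call. = FALSE)
  }
  h <- .pile_profile(final_mask)
  filled <- which(h > 0)
  if (length(filled) < 5) stop("pile narrower than 5 px", call. = FALSE)
  apex <- filled[which.max(h[filled])]
  hmax <- max(h)
  side_angle <- function(cols) {
    keep <- cols[h[cols] > 2 & h[cols] < 0.9 * hmax]
    if (length(keep) < 3) {
      stop("flank too short to fit a slope; pile too small or truncated",
           call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, keep), h[keep])
    unname(atan(abs(fit$coefficients[2])) * 180 / pi)
  }
  left <- filled[filled < apex]
  right <- filled[filled > apex]
  sides <- c(left = side_angle(left), right = side_angle(right))
  out <- mean(sides)
  attr(out, "sides") <- sides
  out
}

#' Flow time from the plateau of a flow curve
#'
#' The flow time is the moment the pile stops growing: the first time
#' `t*` from which the bright area stays within `plateau_tol` (as a
#' fraction of the final area) of the final area for at least
#' `plateau_len` consecutive frames.
#'
#' @param curve a [flow_curve()].
#' @param plateau_tol relative tolerance around the final area
#'   (default 0.005, i.e. 0.5%).
#' @param plateau_len required plateau length in frames (default 25,
#'   one second at 25 fps).
#' @return Flow time `t*` in seconds.
#' @export
measure_flow_time <- function(curve, plateau_tol = 0.005, plateau_len = 25) {
  stopifnot(inherits(curve, "flow_curve"))
  n <- length(curve$areas)
  if (n <= plateau_len) {
    stop("curve shorter than `plateau_len`", call. = FALSE)
  }
  final <- curve$areas[n]
  within <- abs(curve$areas - final) <= plateau_tol * abs(final)
  # run length of TRUEs starting at each index
  run <- integer(n)
  cnt <- 0L
  for (k in n:1) {
    cnt <- if (within[k]) cnt + 1L else 0L
    run[k] <- cnt
  }
  k <- match(TRUE, run >= plateau_len)
  if (is.na(k)) {
    stop("no plateau found: recording appears truncated before flow ended",
         call. = FALSE)
  }
  curve$times[k]
}

#' Crofton perimeter of a binary mask
#'
#' Integral-geometry perimeter estimate from boundary intercept counts
#' along four line directions (0, 45, 90, 135 degrees):
#' `P = (pi/8) * (t0 + t90 + (t45 + t135) / sqrt(2))`, where `t` are the
#' total foreground/background transition counts along the line families
#' (axis-aligned line spacing 1 px, diagonal spacing `sqrt(2)/2` px).
#' For a single pixel this yields the constant `pi/8 * (4 + 2*sqrt(2))`
#' (about 2.68 px).
#'
#' The four-direction estimate is accurate on isotropic shapes (a digital
#' disk converges to `2*pi*r`) but carries a small anisotropy bias on
#' axis-aligned shapes: for a `w x h` rectangle its limit is
#' `(pi/4) * (1 + sqrt(2)) * (w + h)`, about 5% below the true
#' `2 * (w + h)`.
#'
#' @param mask logical matrix with at least one TRUE pixel.
#' @return Perimeter estimate in pixels (> 0).
#' @export
crofton_perimeter <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  nr <- nrow(mask) + 2L
  nc <- ncol(mask) + 2L
  p <- matrix(FALSE, nr, nc)
  p[2:(nr - 1), 2:(nc - 1)] <- mask
  t_h  <- sum(p[, -1] != p[, -nc])                      # along rows (0 deg)
  t_v  <- sum(p[-1, ] != p[-nr, ])                      # along columns (90)
  t_d1 <- sum(p[-1, -1] != p[-nr, -nc])                 # 45 deg
  t_d2 <- sum(p[-1, -nc] != p[-nr, -1])                 # 135 deg
  (pi / 8) * (t_h + t_v + (t_d1 + t_d2) / sqrt(2))
}

#' Sphericity of a single-particle mask
#'
#' Combines the pixel count of the silhouette with its Crofton perimeter
#' into the sphericity index `4 * pi * A / P^2` (see
#' [sphericity_index()]). The mask must contain exactly one connected
#' particle; label fields with multiple particles upstream (e.g. with
#' `EBImage::bwlabel()`) and pass them one at a time.
#'
#' @param mask logical matrix holding one 8-connected component.
#' @return Sphericity in (0, 1].
#' @export
particle_sphericity <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask) || !any(mask)) {
    stop("`mask` must be a logical matrix with at least one TRUE pixel",
         call. = FALSE)
  }
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 1) {
    stop("mask contains ", max(lab), " connected components; label and ",
         "pass particles individually", call. = FALSE)
  }
  sphericity_index(sum(mask), crofton_perimeter(mask))
}

#' Classify a particle as pellet or granule by sphericity
#'
#' Pellets are near-spherical multiparticulates with sphericity above
#' 0.91; particles at or below 0.90 are granules. Values in the
#' unassigned gap (0.90, 0.91] are resolved as granules with a boundary
#' warning rather than an error.
#'
#' @param psi sphericity in (0, 1].
#' @return `"pellet"` or `"granule"`.
#' @export
classify_particle <- function(psi) {
  if (!is.numeric(psi) || length(psi) != 1 || is.na(psi) ||
      psi <= 0 || psi > 1) {
    stop("`psi` must be a single sphericity value in (0, 1]", call. = FALSE)
  }
  if (psi > 0.91) return("pellet")
  if (psi > 0.90) {
    warning("sphericity ", format(psi), " falls in the unassigned ",
            "(0.90, 0.91] band; classified as granule", call. = FALSE)
  }
  "granule"
}
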