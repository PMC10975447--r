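# Ground-truth synthetic data for every stage of the pipeline: flow
# curves with known (a, b, c) and avalanche structure, pile-growth image
# stacks, particle silhouettes of controlled sphericity, and CCD response
# columns with known coefficients.
#
# The emulated rig: a funnel discharges at constant volumetric rate onto
# a plane; the pile is an ideal cone with flank angle alpha, recorded at
# 25 fps on 128 x 160 px frames, bright particles on a black background.

.require_seed <- function(seed, what) {
  if (is.null(seed)) {
    stop("`seed` is required for ", what, " (stochastic output)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
}

# Piecewise-linear stick-slip term: the local slope steepens until a slip
# event sheds a wedge, so the residual ramps up over each inter-event
# interval and drops at the event. Gaps are min_gap + Poisson.
.avalanche_series <- function(n, amplitude_px, mean_period_frames,
                              min_gap = 5) {
  if (mean_period_frames <= min_gap) {
    stop("`mean_period_frames` must exceed the minimum gap (", min_gap, ")",
         call. = FALSE)
  }
  events <- integer(0)
  pos <- 0L
  while (pos < n) {
    gap <- min_gap + stats::rpois(1, mean_period_frames - min_gap)
    pos <- pos + gap
    events <- c(events, pos)
  }
  s <- numeric(n)
  start <- 1L
  for (ev in events) {
    stop_at <- min(ev, n)
    len <- stop_at - start + 1L
    if (len > 0) s[start:stop_at] <- amplitude_px * seq_len(len) / (ev - start + 1L)
    start <- stop_at + 1L
    if (start > n) break
  }
  list(series = s, events = events[events <= n])
}

#' Simulate a flow curve with known ground truth
#'
#' Generates the bright-area series of an ideally growing cone: volume
#' `V(t) = feed_rate * t`, height `h(t) = cone_height(V, alpha)`, and a
#' slice area proportional to the height,
#' `y(t) = area_offset + area_scale * h(t)`, which is exactly
#' `a + b * t^(1/3)` with `a = area_offset` and
#' `b = area_scale * ((3 / pi) * tan(alpha)^2 * feed_rate)^(1/3)`.
#' Alternatively pass `abc` to prescribe the power law directly.
#' Optional additions: a stick-slip avalanche sawtooth and Gaussian
#' pixel noise.
#'
#' @param alpha static angle of repose in degrees (default 35).
#' @param feed_rate volumetric feed in px^3/s (default 2e4).
#' @param abc optional `c(a, b, c)` overriding the geometric
#'   construction.
#' @param duration recording length in seconds (default 20).
#' @param fps frames per second (default 25).
#' @param area_scale px of slice area per px of pile height (default 5,
#'   a typical band width).
#' @param area_offset intercept in px (default 0; negative on real
#'   off-center slices).
#' @param avalanche `NULL`, or a list with `amplitude_px` (drop size),
#'   `mean_period_frames` (mean event spacing) and optionally `min_gap`
#'   (default 5 frames).
#' @param noise_sigma Gaussian pixel-noise standard deviation
#'   (default 0).
#' @param seed RNG seed; mandatory when `avalanche` or `noise_sigma > 0`
#'   makes the output stochastic.
#' @return Object of class `"flow_sim"`: list with `curve` (a
#'   [flow_curve()]) and `truth` (list with `a`, `b`, `c`, `alpha`,
#'   `feed_rate`, `avalanche_events`, `noise_sigma`, `seed`).
#' @examples
#' sim <- simulate_flow_curve(alpha = 35, duration = 10)
#' coef(fit_power_law(sim$curve))  # recovers c = 1/3
#' @export
simulate_flow_curve <- function(alpha = 35, feed_rate = 2e4, abc = NULL,
                                duration = 20, fps = 25, area_scale = 5,
                                area_offset = 0, avalanche = NULL,
                                noise_sigma = 0, seed = NULL) {
  n <- floor(duration * fps) + 1L
  if (n < 10) stop("duration * fps must give at least 10 frames",
                   call. = FALSE)
  stochastic <- !is.null(avalanche) || noise_sigma > 0
  if (stochastic) .require_seed(seed, "simulate_flow_curve")
  t <- (seq_len(n) - 1) / fps
  if (is.null(abc)) {
    .check_alpha(alpha)
    .check_positive(feed_rate, "feed_rate")
    b <- area_scale * ((3 / pi) * tan(deg2rad(alpha))^2 * feed_rate)^(1 / 3)
    abc <- c(area_offset, b, 1 / 3)
  }
  y <- abc[1] + abc[2] * ifelse(t > 0, t^abc[3], 0)
  events <- integer(0)
  if (!is.null(avalanche)) {
    min_gap <- if (is.null(avalanche$min_gap)) 5 else avalanche$min_gap
    av <- .avalanche_series(n, avalanche$amplitude_px,
                            avalanche$mean_period_frames, min_gap)
    y <- y + av$series
    events <- av$events
  }
  if (noise_sigma > 0) y <- y + stats::rnorm(n, sd = noise_sigma)
  structure(list(
    curve = flow_curve(y, times = t, fps = fps),
    truth = list(a = abc[1], b = abc[2], c = abc[3], alpha = alpha,
                 feed_rate = feed_rate, avalanche_events = events,
                 noise_sigma = noise_sigma, seed = seed)),
    class = "flow_sim")
}

#' Simulate a pile-growth image stack
#'
#' Renders, frame by frame, the 2-D silhouette of a cone growing under a
#' nozzle: a triangle with apex under `apex_col`, flank slope
#' `alpha` and height `h(t) = cone_height(feed_rate * t, alpha)`.
#' Rendering is binary (intensities 0/255) with no anti-aliasing, so
#' slice areas are exactly reproducible. Optionally a central jet band
#' (the falling bulk stream) is rendered fully bright to exercise slice
#' selection.
#'
#' @param alpha static angle of repose in degrees.
#' @param duration recording length in seconds.
#' @param fps frames per second (default 25).
#' @param frame_shape `c(rows, cols)`, default `c(128, 160)`.
#' @param final_height_frac target final pile height as a fraction of
#'   the frame height (default 0.85); sets the feed rate unless
#'   `feed_rate` is given.
#' @param feed_rate volumetric feed in px^3/s; overrides
#'   `final_height_frac`.
#' @param apex_col apex column (default frame center).
#' @param jet_width width in px of the bright central jet (default 0 =
#'   no jet).
#' @return Object of class `"pile_sim"`: list with `stack` (an
#'   [image_stack()]) and `truth` (list with `alpha`, `feed_rate`,
#'   `apex_col`, `final_height`, `frame_shape`).
#' @export
simulate_pile_stack <- function(alpha, duration, fps = 25,
                                frame_shape = c(128, 160),
                                final_height_frac = 0.85, feed_rate = NULL,
                                apex_col = NULL, jet_width = 0) {
  .check_alpha(alpha)
  n <- floor(duration * fps) + 1L
  if (n < 2) stop("duration too short: need at least 2 frames",
                  call. = FALSE)
  nr <- frame_shape[1]
  nc <- frame_shape[2]
  if (is.null(apex_col)) apex_col <- (nc + 1) / 2
  t_end <- (n - 1) / fps
  if (is.null(feed_rate)) {
    h_final <- final_height_frac * nr
    feed_rate <- cone_volume(h_final, alpha) / t_end
  }
  h_end <- cone_height(feed_rate * t_end, alpha)
  if (h_end > nr) {
    stop("pile would exceed the frame height before the end of the run; ",
         "use a shorter duration or lower feed rate", call. = FALSE)
  }
  tn <- tan(deg2rad(alpha))
  d <- abs(seq_len(nc) - apex_col)
  frames <- lapply(seq_len(n) - 1L, function(k) {
    fr <- matrix(0, nr, nc)
    if (k > 0) {
      h <- cone_height(feed_rate * k / fps, alpha)
      prof <- pmax(0, h - d * tn)
      npx <- pmin(nr, floor(prof + 0.5))
      for (x in which(npx > 0)) fr[(nr - npx[x] + 1):nr, x] <- 255
    }
    if (jet_width > 0) {
      jet <- which(d <= jet_width / 2)
      fr[, jet] <- 255
    }
    fr
  })
  structure(list(
    stack = image_stack(frames, fps = fps),
    truth = list(alpha = alpha, feed_rate = feed_rate, apex_col = apex_col,
                 final_height = h_end, frame_shape = c(nr, nc))),
    class = "pile_sim")
}

#' Write an image stack as numbered PNG frames
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_image_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[k]] / 255,
                  file.path(dir, sprintf("frame_%05d.png", k - 1L)))
  }
  invisible(dir)
}

#' Generate a particle silhouette of controlled sphericity
#'
#' Produces binary masks emulating microscope projections: a digital
#' disk (pellet-like, sphericity near 1), an axis-aligned ellipse, or a
#' radially perturbed blob (granule-like, sphericity well below 0.9).
#' The continuous-geometry ground-truth sphericity is returned alongside
#' the rasterized mask.
#'
#' @param kind `"disk"`, `"ellipse"` or `"rough"`.
#' @param size_px particle diameter (major axis) in pixels, >= 8.
#' @param aspect major/minor axis ratio for `"ellipse"` (default 2).
#' @param roughness relative amplitude of the radial perturbation for
#'   `"rough"` (default 0.3).
#' @param seed RNG seed, required for `"rough"`.
#' @return List with `mask` (logical matrix), `psi_true`
#'   (continuous-geometry sphericity), `kind`.
#' @export
generate_particle_mask <- function(kind = c("disk", "ellipse", "rough"),
                                   size_px = 101, aspect = 2,
                                   roughness = 0.3, seed = NULL) {
  kind <- match.arg(kind)
  if (size_px < 8) stop("`size_px` must be at least 8", call. = FALSE)
  r0 <- (size_px - 1) / 2
  # rough blobs need head-room for outward perturbation
  s <- if (kind == "rough") as.integer(ceiling(size_px * 1.9))
       else as.integer(size_px + 5)
  ctr <- (s + 1) / 2
  xs <- matrix(rep(seq_len(s) - ctr, each = s), s, s)   # column offsets
  ys <- matrix(rep(seq_len(s) - ctr, times = s), s, s)  # row offsets
  if (kind == "disk") {
    mask <- (xs^2 + ys^2) <= r0^2
    psi_true <- 1
  } else if (kind == "ellipse") {
    b0 <- r0 / aspect
    mask <- (xs / r0)^2 + (ys / b0)^2 <= 1
    # Ramanujan's second approximation for the ellipse perimeter
    h <- ((r0 - b0) / (r0 + b0))^2
    per <- pi * (r0 + b0) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    psi_true <- 4 * pi * (pi * r0 * b0) / per^2
  } else {
    .require_seed(seed, "generate_particle_mask(kind = \"rough\")")
    m_h <- 2:7
    a_m <- stats::rnorm(length(m_h))
    b_m <- stats::rnorm(length(m_h))
    norm <- sqrt(sum(a_m^2 + b_m^2) / 2)   # unit-RMS perturbation
    a_m <- a_m / norm
    b_m <- b_m / norm
    radial <- function(theta) {
      pert <- rowSums(vapply(seq_along(m_h), function(i) {
        a_m[i] * cos(m_h[i] * theta) + b_m[i] * sin(m_h[i] * theta)
      }, numeric(length(theta))))
      pmax(0.2 * r0, r0 * (1 + roughness * pert) * 0.8)
    }
    theta_px <- atan2(ys, xs)
    mask <- sqrt(xs^2 + ys^2) <= radial(as.numeric(theta_px))
    dim(mask) <- c(s, s)
    # continuous ground truth from a fine polar grid
    th <- seq(0, 2 * pi, length.out = 20001)[-1]
    rr <- radial(th)
    drr <- c(diff(rr), rr[1] - rr[length(rr)]) / (th[2] - th[1])
    A <- sum(rr^2) / 2 * (th[2] - th[1])
    P <- sum(sqrt(rr^2 + drr^2)) * (th[2] - th[1])
    psi_true <- 4 * pi * A / P^2
  }
  list(mask = mask, psi_true = psi_true, kind = kind)
}

#' Simulate responses for a coded design with known coefficients
#'
#' Evaluates a response-surface polynomial on the coded factors of a
#' design and adds Gaussian noise:
#' `y_run = sum(coef * term(x)) + N(0, sigma)`. Term names follow R
#' model syntax on the coded columns: `"(Intercept)"`, `"x1"`,
#' `"x1:x2"`, `"I(x1^2)"`.
#'
#' @param design a design data frame with coded columns `x1`..`x4`
#'   (e.g. from [build_ccd()] or [read_design_table()]).
#' @param coefficients named numeric vector of true coefficients.
#' @param sigma response noise standard deviation (default 0).
#' @param seed RNG seed, required when `sigma > 0`.
#' @return Numeric response vector, one value per run.
#' @examples
#' d <- build_ccd()
#' y <- simulate_design_responses(d, c("(Intercept)" = 21.15, x4 = -1.82))
#' coef(fit_response_surface(d, y, terms = "x4"))
#' @export
simulate_design_responses <- function(design, coefficients, sigma = 0,
                                      seed = NULL) {
  X <- .term_matrix(design, names(coefficients))
  y <- as.numeric(X %*% coefficients)
  if (sigma > 0) {
    .require_seed(seed, "simulate_design_responses")
    y <- y + stats::rnorm(length(y), sd = sigma)
  }
  y
}
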