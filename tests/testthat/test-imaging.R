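# Binarization, slicing, angle-of-repose and shape measurement on
# constructed frames.

test_that("fixed-threshold binarization is exact on constructed frames", {
  z <- matrix(0, 20, 20)
  expect_false(any(binarize_frame(z, method = "fixed", threshold = 10)))
  fr <- matrix(0, 20, 20)
  fr[1:8, ] <- 100                      # bright above row 8
  mask <- binarize_frame(fr, method = "fixed", threshold = 50)
  expect_true(all(mask[1:8, ]))
  expect_false(any(mask[9:20, ]))
  expect_error(binarize_frame(fr, method = "fixed", threshold = 500),
               "intensity range")
})

test_that("Otsu binarization splits a bimodal frame like any mid cut", {
  set.seed(7)
  fr <- matrix(sample(c(30, 200), 400, replace = TRUE), 20, 20)
  # brute-force sweep oracle: maximize between-class variance
  counts <- tabulate(as.integer(fr) + 1L, nbins = 256)
  lev <- 0:255
  best <- -Inf; tcut <- NA
  for (t in 0:254) {
    w0 <- sum(counts[lev <= t]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(lev[lev <= t] * counts[lev <= t]) / w0
    m1 <- sum(lev[lev > t] * counts[lev > t]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; tcut <- t }
  }
  expect_true(tcut >= 30 && tcut < 200)   # any cut in [30, 200) splits
  otsu_mask <- binarize_frame(fr, method = "otsu")
  expect_identical(otsu_mask,
                   binarize_frame(fr, method = "fixed", threshold = tcut))
  expect_identical(otsu_mask,
                   binarize_frame(fr, method = "fixed", threshold = 100))
  expect_warning(m <- binarize_frame(matrix(5, 4, 4), method = "otsu"),
                 "constant frame")
  expect_false(any(m))
})

test_that("slice bands partition the reference frame width evenly", {
  stack <- image_stack(list(matrix(0, 128, 160), matrix(255, 128, 160)))
  for (idx in c(0, 11, 31)) {
    fc <- slice_area_series(stack, n_slices = 32, slice_index = idx,
                            method = "fixed", threshold = 128)
    cols <- attr(fc, "cols")
    expect_identical(diff(cols) + 1L, 5L)       # 160 / 32
    expect_equal(fc$areas, c(0, 5 * 128))
  }
  expect_error(slice_area_series(stack, n_slices = 32, slice_index = 32),
               "slice_index")
})

test_that("slice areas count exactly and an empty band stays zero", {
  nr <- 40; nc <- 64                    # 8 slices of 8 px
  frames <- lapply(0:9, function(k) {
    fr <- matrix(0, nr, nc)
    if (k > 0) fr[(nr - k + 1):nr, 17:24] <- 255   # band index 2 fills
    fr
  })
  stack <- image_stack(frames)
  fc <- slice_area_series(stack, n_slices = 8, slice_index = 2,
                          method = "fixed", threshold = 128)
  expect_equal(fc$areas, 8 * (0:9))              # k rows * 8 px
  dark <- slice_area_series(stack, n_slices = 8, slice_index = 6,
                            method = "fixed", threshold = 128)
  expect_true(all(dark$areas == 0))
  expect_equal(fc$times, (0:9) / 25)
})

test_that("default slice sits off-center, clear of the bulk jet", {
  expect_identical(default_slice_index(32), 11L)
  expect_identical(default_slice_index(8), 2L)
  expect_identical(default_slice_index(4), 0L)
  expect_error(default_slice_index(2), "at least 4")
  # validated against the simulator: the default band is outside a
  # 12-px central jet on the reference frame geometry
  sim <- simulate_pile_stack(35, duration = 2, jet_width = 12)
  fc <- slice_area_series(sim$stack)
  expect_lt(fc$areas[1], 128 * 5)   # first frame not saturated by jet
})

test_that("static angle of repose is recovered from wedge silhouettes", {
  expect_lt(abs(measure_static_angle(make_wedge(45)) - 45), 0.5)
  expect_lt(abs(measure_static_angle(make_wedge(34.41)) - 34.41), 0.5)
  asym <- measure_static_angle(make_wedge(30, 40))
  expect_lt(abs(asym - 35), 0.5)
  sides <- attr(asym, "sides")
  expect_lt(abs(sides[["left"]] - 30), 0.5)
  expect_lt(abs(sides[["right"]] - 40), 0.5)
  expect_error(measure_static_angle(matrix(FALSE, 10, 10)), "empty")
  narrow <- matrix(FALSE, 10, 10); narrow[10, 4:6] <- TRUE
  expect_error(measure_static_angle(narrow), "narrower")
})

test_that("flow time finds the first durable plateau", {
  areas <- c(seq(0, 99, length.out = 100), rep(100, 100))
  fc <- flow_curve(areas, fps = 25)
  expect_equal(measure_flow_time(fc, plateau_tol = 0.005,
                                 plateau_len = 25), 100 / 25)
  mono <- flow_curve(seq(0, 199), fps = 25)
  expect_error(measure_flow_time(mono), "plateau")
  # mass balance: feed stops once volume V is delivered -> FT = V / Q
  sim <- simulate_flow_curve(alpha = 35, feed_rate = 2e4, duration = 8)
  V <- 2e4 * 5                          # stop feeding at t = 5 s
  y <- sim$curve$areas
  stop_k <- which(sim$curve$times >= 5)[1]
  y[stop_k:length(y)] <- y[stop_k]
  ft <- measure_flow_time(flow_curve(y, fps = 25))
  expect_equal(ft, V / 2e4, tolerance = 0.05)
})

test_that("Crofton perimeter matches analytic lengths", {
  disk <- digital_disk(50)
  expect_equal(crofton_perimeter(disk), 2 * pi * 50, tolerance = 0.02)
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(crofton_perimeter(single), (pi / 8) * (4 + 2 * sqrt(2)))
  # axis-aligned rectangle: matches the four-direction analytic limit
  # (pi/4)(1+sqrt(2))(w+h), itself about 5% under the true 2(w+h)
  rect <- digital_rect(40, 20)
  expect_equal(crofton_perimeter(rect), (pi / 4) * (1 + sqrt(2)) * 60,
               tolerance = 0.015)
  expect_equal(crofton_perimeter(rect), 2 * (40 + 20), tolerance = 0.07)
  expect_error(crofton_perimeter(matrix(FALSE, 4, 4)), "empty")
})

test_that("Crofton disk error shrinks as the radius grows", {
  rel_err <- vapply(c(10, 20, 40, 80), function(r)
    abs(crofton_perimeter(digital_disk(r)) / (2 * pi * r) - 1), numeric(1))
  expect_true(all(diff(rel_err) < 0))
})

test_that("particle sphericity separates disks, ellipses and bars", {
  expect_equal(as.numeric(suppressWarnings(
    particle_sphericity(digital_disk(50)))), 1, tolerance = 0.02)
  ell <- generate_particle_mask("ellipse", 101, aspect = 2)
  expect_equal(suppressWarnings(particle_sphericity(ell$mask)), 0.84,
               tolerance = 0.03)
  bar <- digital_rect(50, 4)
  expect_lt(particle_sphericity(bar), 0.5)
  two <- digital_rect(5, 5, pad = 2)
  two[1, 1] <- TRUE                      # second component
  expect_error(particle_sphericity(two), "components")
})

test_that("pellet/granule classification applies the 0.91 / 0.90 rule", {
  expect_identical(classify_particle(0.95), "pellet")
  expect_identical(classify_particle(0.85), "granule")
  expect_identical(classify_particle(0.910001), "pellet")
  expect_warning(cls <- classify_particle(0.905), "unassigned")
  expect_identical(cls, "granule")
  expect_error(classify_particle(1.2), "sphericity")
  expect_error(classify_particle(0), "sphericity")
})

test_that("bright-area counts are invariant under horizontal mirroring", {
  sim <- simulate_pile_stack(33, duration = 3, apex_col = 70)
  mirrored <- image_stack(lapply(sim$stack$frames,
                                 function(fr) fr[, ncol(fr):1]),
                          fps = sim$stack$fps)
  tot <- function(st) vapply(st$frames, function(fr) sum(fr > 128),
                             numeric(1))
  expect_identical(tot(sim$stack), tot(mirrored))
  # a band and its mirror image cover the same pixels
  fc <- slice_area_series(sim$stack, n_slices = 32, slice_index = 11,
                          method = "fixed", threshold = 128)
  fc_m <- slice_area_series(mirrored, n_slices = 32, slice_index = 20,
                            method = "fixed", threshold = 128)
  expect_identical(fc$areas, fc_m$areas)
})
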