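# Avalanche statistics on the detrended flow curve. An avalanche is a
# discrete slip of the pile: on the residual series it appears as a local
# maximum followed by a drop to a trough. The detector operationalizes
# this as peaks whose peak-to-trough drop reaches a prominence threshold,
# with a minimum peak-to-peak spacing.

#' Detect avalanches on a detrended flow curve
#'
#' Scans the residual series for local maxima, measures each candidate's
#' drop to the following trough (the minimum before the next candidate
#' peak, or to the series end), and keeps drops of at least
#' `min_prominence` pixels whose peak lies at least `min_gap` frames
#' after the previously accepted peak.
#'
#' The avalanche amplitude is the peak-to-trough drop in pixels; the
#' wavelength is the frame spacing between successive accepted peaks
#' (1 frame = 0.04 s at 25 fps) and is defined only when at least two
#' events are found.
#'
#' @param residuals numeric residual series (length >= 10), e.g. from
#'   [detrend()].
#' @param min_prominence minimum peak-to-trough drop in pixels
#'   (default 2).
#' @param min_gap minimum spacing between accepted peaks in frames
#'   (default 5).
#' @return Object of class `"avalanche_stats"`: list with `count`,
#'   `amplitude_mean` (px), `wavelength_mean` (frames; `NA` when
#'   `count < 2`) and `events`, a data frame with one row per event
#'   (`peak_frame`, `trough_frame`, `amplitude`, `gap_frames`; frames
#'   0-based, `gap_frames` is `NA` for the first event).
#' @examples
#' saw <- 6 * ((0:200) %% 20) / 19          # 10 sawtooth collapses
#' detect_avalanches(saw)
#' @export
detect_avalanches <- function(residuals, min_prominence = 2, min_gap = 5) {
  r <- as.numeric(residuals)
  n <- length(r)
  if (n < 10) stop("residual series shorter than 10 frames", call. = FALSE)
  # candidate peaks: strictly above the next sample, not below the previous
  cand <- which(r[2:(n - 1)] > r[3:n] & r[2:(n - 1)] >= r[1:(n - 2)]) + 1L
  peaks <- integer(0)
  troughs <- integer(0)
  amps <- numeric(0)
  for (i in seq_along(cand)) {
    pk <- cand[i]
    upto <- if (i < length(cand)) cand[i + 1] - 1L else n
    seg <- pk:upto
    tr <- seg[which.min(r[seg])]
    amp <- r[pk] - r[tr]
    if (amp < min_prominence) next
    if (length(peaks) > 0 && pk - peaks[length(peaks)] < min_gap) next
    peaks <- c(peaks, pk)
    troughs <- c(troughs, tr)
    amps <- c(amps, amp)
  }
  count <- length(peaks)
  gaps <- if (count >= 2) c(NA_real_, diff(peaks)) else
    rep(NA_real_, count)
  events <- data.frame(peak_frame = peaks - 1L, trough_frame = troughs - 1L,
                       amplitude = amps, gap_frames = gaps)
  structure(list(count = count,
                 amplitude_mean = if (count > 0) mean(amps) else NA_real_,
                 wavelength_mean = if (count >= 2) mean(diff(peaks))
                                   else NA_real_,
                 events = events),
            class = "avalanche_stats")
}

#' @export
print.avalanche_stats <- function(x, ...) {
  cat(sprintf("Avalanches: %d", x$count))
  if (x$count > 0) {
    cat(sprintf("   mean amplitude %.2f px", x$amplitude_mean))
  }
  if (!is.na(x$wavelength_mean)) {
    cat(sprintf("   mean wavelength %.2f frames", x$wavelength_mean))
  }
  cat("\n")
  invisible(x)
}
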