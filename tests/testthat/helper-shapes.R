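# Small geometric fixtures built in code: wedge silhouettes, digital
# shapes and sawtooth residual series used across the test files.

make_wedge <- function(alpha_left, alpha_right = alpha_left, height = 90,
                       shape = c(128, 160), apex_col = 80.5) {
  nr <- shape[1]; nc <- shape[2]
  x <- seq_len(nc)
  slope <- ifelse(x < apex_col, tan(alpha_left * pi / 180),
                  tan(alpha_right * pi / 180))
  prof <- pmax(0, height - abs(x - apex_col) * slope)
  npx <- pmin(nr, floor(prof + 0.5))
  mask <- matrix(FALSE, nr, nc)
  for (j in which(npx > 0)) mask[(nr - npx[j] + 1):nr, j] <- TRUE
  mask
}

digital_disk <- function(r, pad = 3) {
  s <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  xs <- matrix(rep(seq_len(s) - ctr, each = s), s, s)
  ys <- matrix(rep(seq_len(s) - ctr, times = s), s, s)
  (xs^2 + ys^2) <= r^2
}

digital_rect <- function(w, h, pad = 3) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

# n_periods full sawtooth cycles (rise to `amp`, collapse to 0), closed
# by the final trough sample: peaks are `period` frames apart.
sawtooth <- function(amp = 6, period = 20, n_periods = 10) {
  k <- 0:(n_periods * period)
  amp * (k %% period) / (period - 1)
}
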