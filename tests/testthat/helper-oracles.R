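# Independent brute-force oracles used by several test files.

brute_weighted_hsv <- function(block) {
  # per-pixel double loop over the stated weighting formula
  d <- dim(block)
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  dmax <- sqrt((d[1] / 2)^2 + (d[2] / 2)^2)
  num_h <- 0; num_v <- 0; den <- 0
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      hsv <- grDevices::rgb2hsv(block[i, j, 1], block[i, j, 2],
                                block[i, j, 3], maxColorValue = 1)
      w <- 1 - sqrt((i - ci)^2 + (j - cj)^2) / dmax
      num_h <- num_h + w * hsv[1] * 255
      num_v <- num_v + w * hsv[3] * 255
      den <- den + w
    }
  }
  list(wH = num_h / den, wV = num_v / den)
}
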