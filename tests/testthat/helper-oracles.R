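# Independent oracles and fixture builders shared across the suite.

# Brute-force mean per-row foreground width (run-length count), in um.
# Deliberately loop-based and independent of segment_thickness().
row_width_oracle <- function(mask, segment) {
  widths <- numeric(0)
  for (r in (segment$row_start + 1L):segment$row_end) {
    cnt <- 0L
    for (cc in (segment$col_start + 1L):segment$col_end) {
      if (mask$pixels[r, cc] == 1) cnt <- cnt + 1L
    }
    widths <- c(widths, cnt)
  }
  mean(widths) * mask$pixel_size
}

# Sample one element of a vector (safe for length-1 vectors, unlike sample()).
pick1 <- function(v) v[sample.int(length(v), 1L)]

# Random sparse binary mask.
random_mask <- function(nr, nc, p = 0.3, pixel_size = 1) {
  binary_mask(matrix(rbinom(nr * nc, 1L, p), nr, nc), pixel_size)
}

# Vertical band mask: per-row foreground widths `widths`, left edge at
# `col0` (1-based), canvas cols `nc`.
band_mask <- function(widths, nc, col0 = 3L, pixel_size = 1) {
  m <- matrix(0, length(widths), nc)
  for (i in seq_along(widths)) {
    if (widths[i] > 0) m[i, col0:(col0 + widths[i] - 1L)] <- 1
  }
  binary_mask(m, pixel_size)
}

# Group-sharing relation implied by a compact letter display
# (single-character labels assumed, i.e. at most 26 letter sets).
share_from_letters <- function(lets) {
  k <- length(lets)
  ch <- lapply(lets, function(s) strsplit(s, "")[[1]])
  out <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- length(intersect(ch[[i]], ch[[j]])) > 0
    }
  }
  out
}

# Random symmetric p-value matrix with unit diagonal.
random_pmat <- function(k) {
  p <- matrix(0, k, k)
  p[upper.tri(p)] <- runif(k * (k - 1) / 2)
  p <- p + t(p)
  diag(p) <- 1
  dimnames(p) <- list(paste0("g", seq_len(k)), paste0("g", seq_len(k)))
  p
}

# Slice records whose cell means are exactly the stated values: two
# records per cell placed symmetrically about the mean.
records_with_exact_means <- function(ref, spread = 10) {
  ref <- ref[!is.na(ref$mean_um), ]
  do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    data.frame(
      tissue = ref$tissue[i], step_size = ref$step_size[i],
      speed = ref$speed[i],
      thickness = ref$mean_um[i] + c(-spread, spread),
      stringsAsFactors = FALSE
    )
  }))
}
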