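# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the most literal formulation of
# each definition (explicit sums and per-pixel scans), not the package's
# code paths.

# OLS slope via explicit normal-equation sums, accumulated point by point
slope_oracle <- function(t, y) {
  n <- length(t)
  sx <- 0; sy <- 0; sxx <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + t[i]
    sy <- sy + y[i]
    sxx <- sxx + t[i]^2
    sxy <- sxy + t[i] * y[i]
  }
  (n * sxy - sx * sy) / (n * sxx - sx^2)
}

# Euclidean-disk dilation via per-pixel distance scan over all true pixels
dilate_oracle <- function(mask, radius) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  tr <- which(mask, arr.ind = TRUE)
  if (nrow(tr) == 0) return(out)
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      d2 <- (tr[, 1] - i)^2 + (tr[, 2] - j)^2
      out[i, j] <- min(d2) <= radius^2
    }
  }
  out
}

# rolling-ball subtraction via literal per-pixel erosion-then-dilation with
# the ball structuring element
rb_oracle <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  off <- expand.grid(dx = -floor(radius):floor(radius),
                     dy = -floor(radius):floor(radius))
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  h <- sqrt(radius^2 - off$dx^2 - off$dy^2)
  er <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- Inf
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dx[k]; jj <- j + off$dy[k]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        v <- img[ii, jj] - h[k]
        if (v < best) best <- v
      }
    }
    er[i, j] <- best
  }
  bg <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- -Inf
    for (k in seq_len(nrow(off))) {
      ii <- i - off$dx[k]; jj <- j - off$dy[k]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        v <- er[ii, jj] + h[k]
        if (v > best) best <- v
      }
    }
    bg[i, j] <- best
  }
  pmax(img - bg, 0)
}

# densely sampled noise-free logistic curve, for slope cross-checks
dense_log2_curve <- function(initial_od, carrying_capacity, rate,
                             lag_h = 0, t_max = 40, dt = 0.005) {
  t <- seq(0, t_max, by = dt)
  te <- pmax(t - lag_h, 0)
  od <- initial_od * carrying_capacity /
    (initial_od + (carrying_capacity - initial_od) *
       exp(-rate * log(2) * te))
  data.frame(time_h = t, log2_od = log2(od))
}

# slope of the dense curve restricted to a log2-OD window, via the oracle
dense_window_slope <- function(..., window = c(-3, -2)) {
  d <- dense_log2_curve(...)
  keep <- d$log2_od >= window[1] & d$log2_od <= window[2]
  slope_oracle(d$time_h[keep], d$log2_od[keep])
}
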