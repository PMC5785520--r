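# Independent analytic CDFs used as oracles for the sampling machinery.

cdf_uniform <- function(q, lo, hi) pmin(pmax((q - lo) / (hi - lo), 0), 1)

cdf_triangular <- function(q, a, m, b) {
  out <- numeric(length(q))
  left <- q > a & q <= m
  right <- q > m & q < b
  out[left] <- (q[left] - a)^2 / ((b - a) * (m - a))
  out[right] <- 1 - (b - q[right])^2 / ((b - a) * (b - m))
  out[q >= b] <- 1
  out
}

cdf_trapezoidal <- function(q, a, b, c, d) {
  h <- 2 / (d + c - b - a)
  out <- numeric(length(q))
  i1 <- q > a & q <= b
  i2 <- q > b & q <= c
  i3 <- q > c & q < d
  out[i1] <- h * (q[i1] - a)^2 / (2 * (b - a))
  out[i2] <- h * (b - a) / 2 + h * (q[i2] - b)
  out[i3] <- 1 - h * (d - q[i3])^2 / (2 * (d - c))
  out[q >= d] <- 1
  out
}

ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  f <- cdf(x)
  max(abs(f - (seq_len(n) - 1) / n), abs(f - seq_len(n) / n))
}

# Brute-force reference for the cohort series: literal summation of the
# defining sums, one year at a time.
ref_use_release <- function(I, m) {
  n <- length(I)
  vapply(seq_len(n), function(t)
    sum(I[max(1, t - m + 1):t]) / m, 0)
}

ref_use_stock <- function(I, m) {
  n <- length(I)
  vapply(seq_len(n), function(t) {
    js <- seq_len(n)
    js <- js[js > t - m + 1 & js <= t]
    if (!length(js)) return(0)
    sum(I[js] * (m + js - t - 1) / m)
  }, 0)
}

ref_eol_release <- function(I, m) {
  n <- length(I)
  vapply(seq_len(n), function(t) if (t > m) I[t - m] else 0, 0)
}

ref_eol_stock <- function(I, m) {
  n <- length(I)
  vapply(seq_len(n), function(t) sum(I[max(1, t - m + 1):t]), 0)
}
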