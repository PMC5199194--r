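# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals. Used to freeze expected values and
# for oracle-equivalence checks.

# running median, window w (odd), reflect padding
brute_median_filter <- function(x, w) {
  half <- (w - 1) %/% 2
  n <- length(x)
  padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  vapply(seq_len(n), function(i) median(padded[i:(i + w - 1)]), 0)
}

# running mean, window w, left half floor((w-1)/2), reflect padding
brute_mean_filter <- function(x, w) {
  hl <- (w - 1) %/% 2
  hr <- w - 1 - hl
  n <- length(x)
  padded <- c(x[(hl + 1):2], x, x[(n - 1):(n - hr)])
  vapply(seq_len(n), function(i) mean(padded[i:(i + w - 1)]), 0)
}

# cycle extraction + both candidate averages, straight from the definition
brute_cycle_average <- function(trace, rate, onset, tf, n_cycles,
                                w0 = 0.05, w1 = 0.55) {
  len <- round((w1 - w0) * rate)
  wins <- lapply(seq_len(n_cycles) - 1, function(k) {
    i0 <- round((onset + k / tf + w0) * rate) + 1
    trace[i0:(i0 + len - 1)]
  })
  list(windows = wins,
       avg3 = Reduce(`+`, wins) / n_cycles,
       avg2 = (wins[[1]] + wins[[2]]) / 2)
}

# two-sample KS statistic by ECDF enumeration
brute_ks2_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(x) mean(a <= x), 0)
  Fb <- vapply(xs, function(x) mean(b <= x), 0)
  max(abs(Fa - Fb))
}

# one-sample KS statistic against Uniform(0, 90)
brute_ks_unif_D <- function(x) {
  x <- sort(x)
  n <- length(x)
  Fx <- x / 90
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
}

# paired t from the textbook formula
brute_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Pearson r from the covariance formula, p from the t transform
brute_pearson <- function(a, b) {
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# orientation vector straight from the formula, no clipping logic
brute_orientation <- function(dirs_deg, R) {
  z <- sum(R * exp(2i * dirs_deg * pi / 180)) / sum(R)
  half <- Arg(z) / 2 * 180 / pi
  pref <- half - 90
  if (pref < -90) pref <- pref + 180
  if (pref >= 90) pref <- pref - 180
  list(gOSI = Mod(z), pref = pref)
}
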