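# Independent oracles used across the suite. These are deliberately naive,
# definition-level implementations, kept separate from the package's code
# paths they check.

# Brute-force peak finder: local maxima (first sample of a plateau bounded
# below on both sides), topographic prominence computed by walking outward
# to the nearest strictly higher sample, then min-separation pruning by
# prominence (earlier peak on exact ties).
oracle_detect <- function(x, t, min_prominence, min_separation) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next
    # walk right over any plateau of equal values
    j <- i + 1
    while (j <= n && x[j] == x[i]) j <- j + 1
    if (j <= n && x[j] < x[i]) peaks <- c(peaks, i)
  }
  prom <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    h <- x[i]
    lmin <- h
    j <- i - 1
    while (j >= 1 && x[j] <= h) {
      lmin <- min(lmin, x[j])
      j <- j - 1
    }
    rmin <- h
    j <- i + 1
    while (j <= n && x[j] <= h) {
      rmin <- min(rmin, x[j])
      j <- j + 1
    }
    prom[k] <- h - max(lmin, rmin)
  }
  keep <- prom >= min_prominence
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) > 1 && min_separation > 0) {
    ord <- order(-prom, t[peaks])
    acc <- integer(0)
    for (k in ord) {
      if (length(acc) == 0 || all(abs(t[peaks[acc]] - t[peaks[k]]) >= min_separation)) {
        acc <- c(acc, k)
      }
    }
    peaks <- sort(peaks[acc])
  }
  peaks
}

# Closed-form two-parameter OLS.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Exhaustive minimum-total-|dt| bipartite matching of min(n1, n2) pairs.
oracle_min_cost_pairs <- function(t1, t2) {
  n1 <- length(t1)
  n2 <- length(t2)
  if (n1 > n2) {
    sw <- oracle_min_cost_pairs(t2, t1)
    return(list(cost = sw$cost))
  }
  best <- Inf
  subsets <- utils::combn(n2, n1, simplify = FALSE)
  for (sub in subsets) {
    perms <- perm_all(sub)
    for (pm in perms) {
      cost <- sum(abs(t2[pm] - t1))
      if (cost < best) best <- cost
    }
  }
  list(cost = best)
}

perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_all(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# A minimal valid trace with taps injected on one axis.
make_pulse_trace <- function(tap_times, axis = "z", amp = 2, fs = 120,
                             duration = 10, noise = 0, seed = 1,
                             finger_label = "index_dom") {
  set.seed(seed)
  n <- round(duration * fs)
  tm <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  for (tau in tap_times) {
    sig <- sig + amp * exp(-((tm - tau) / 0.01)^2)
  }
  mk <- function(has_sig) {
    (if (has_sig) sig else 0) + if (noise > 0) rnorm(n, 0, noise) else 0
  }
  accel_trace(
    timestamps = tm,
    ax = mk(axis == "x"), ay = mk(axis == "y"), az = mk(axis == "z"),
    sampling_rate = fs, finger_label = finger_label
  )
}
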