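# Independent oracles used to validate the implementations.

# Brute-force full-matrix dynamic programming DTW with squared local cost;
# deliberately written as the textbook O(nm) table, independent of the
# package's rolling-array implementation.
dtw_oracle <- function(a, b) {
  n <- length(a)
  m <- length(b)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- (a[i] - b[j])^2
      D[i + 1L, j + 1L] <- cost + min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L]
}

# Literal step-up definition of Benjamini-Hochberg rejection
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(pass)) rej[o[seq_len(max(pass))]] <- TRUE
  rej
}

# recall and precision of detected event times against ground truth
match_times <- function(detected_s, truth_s, tol_s = 1e-3) {
  if (length(truth_s) == 0L) {
    return(c(recall = NA_real_, precision = as.numeric(length(detected_s) == 0L)))
  }
  hit <- vapply(truth_s, function(s) any(abs(detected_s - s) <= tol_s), logical(1))
  fp <- vapply(detected_s, function(s) all(abs(truth_s - s) > tol_s), logical(1))
  c(recall = mean(hit),
    precision = if (length(detected_s)) 1 - mean(fp) else NA_real_)
}

# closed-form response of the probe to a constant force from given initial
# conditions (underdamped regime)
probe_step_oracle <- function(t_ms, probe, F_uN, x0 = 0, v0 = 0) {
  xeq <- F_uN / probe$k
  y0 <- x0 - xeq
  tau <- probe$tau_ms
  wd <- probe$omega_d
  xeq + exp(-t_ms / tau) *
    (y0 * cos(wd * t_ms) + ((v0 + y0 / tau) / wd) * sin(wd * t_ms))
}
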