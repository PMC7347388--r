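# Internal helpers shared across modules.

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Indices of strict local maxima of `x` above `threshold`, thinned so that
# retained peaks are at least `min_sep` samples apart (greedy, tallest first).
local_maxima <- function(x, threshold = -Inf, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer())
  core <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  core <- core[x[core] > threshold]
  if (length(core) <= 1L || min_sep <= 1L) return(core)
  ord <- core[order(x[core], decreasing = TRUE)]
  keep <- logical(length(x))
  taken <- logical(length(x))
  for (i in ord) {
    lo <- max(1L, i - min_sep + 1L)
    hi <- min(length(x), i + min_sep - 1L)
    if (!any(taken[lo:hi])) {
      keep[i] <- TRUE
      taken[lo:hi] <- TRUE
    }
  }
  which(keep)
}

# Separable Gaussian smoothing of a 2-D image with zero padding outside the
# frame and a kernel normalised to unit sum, so a solid region smooths to 1
# in its interior and decays towards boundaries. The exact boundary semantics
# matter for the neighbourhood-support rule in refine_cluster_map().
gaussian_smooth2d <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  pad_conv <- function(v) {
    n <- length(v)
    padded <- c(rep(0, r), v, rep(0, r))
    out <- numeric(n)
    for (j in seq_along(kern)) {
      out <- out + kern[j] * padded[j:(j + n - 1L)]
    }
    out
  }
  tmp <- apply(img, 2L, pad_conv)
  t(apply(t(tmp), 2L, pad_conv))
}

# Savitzky-Golay smoothed derivative on a uniform grid (units of x per unit
# of `dt`). Thin wrapper over signal::sgolayfilt.
sg_derivative <- function(x, p, n, dt) {
  signal::sgolayfilt(x, p = p, n = n, m = 1L, ts = dt)
}

# Linear-system convolution of a sampled event train with a kernel, keeping
# the input length (causal: kernel applied forward in time). Zero-padded to a
# power of two so the FFT length is never near-prime.
causal_conv <- function(train, kernel) {
  n <- length(train)
  m <- length(kernel)
  N <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(train, rep(0, N - n)))
  K <- stats::fft(c(kernel, rep(0, N - m)))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / N
}

# Difference-of-exponentials kernel on grid `dt` (same time units as the
# constants), normalised to unit peak.
doe_kernel <- function(rise, decay, dt, length_factor = 6) {
  stopifnot(decay > rise)
  tt <- seq(0, decay * length_factor, by = dt)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

# contiguous runs of TRUE as a two-column matrix of (start, end) indices
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
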