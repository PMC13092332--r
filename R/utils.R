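# Internal helpers: circular-track geometry, rolling statistics, kernels.

# wrap a bin index onto 1..n_bins
wrap_bin <- function(b, n_bins) ((b - 1L) %% n_bins) + 1L

# circular distance between two positions in cm on a track of length L
circ_dist_cm <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

# signed circular offset a - b mapped to (-L/2, L/2]
circ_offset_cm <- function(a, b, L) {
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

# bin centers in cm for 1-based bins
bin_centers_cm <- function(n_bins, bin_size_cm) (seq_len(n_bins) - 0.5) * bin_size_cm

# trailing (causal) running mean with truncated windows at the start
roll_mean_trailing <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  cs <- cumsum(x)
  out <- cs / seq_len(n)
  if (n > w) {
    i <- (w + 1L):n
    out[i] <- (cs[i] - cs[i - w]) / w
    out[w] <- cs[w] / w
  }
  out
}

# trailing rolling minimum over a window of w samples (truncated at the start),
# monotonic-deque algorithm, O(n)
roll_min_trailing <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  dq <- integer(n)
  head <- 1L
  tail <- 0L
  for (i in seq_len(n)) {
    while (tail >= head && x[dq[tail]] >= x[i]) tail <- tail - 1L
    tail <- tail + 1L
    dq[tail] <- i
    while (dq[head] <= i - w) head <- head + 1L
    out[i] <- x[dq[head]]
  }
  out
}

# raised-cosine (Hann-family) kernel of length L with nonzero endpoints,
# normalized to unit sum; L = 2 degenerates to c(0.5, 0.5)
hanning_kernel <- function(L) {
  stopifnot(L >= 1)
  k <- sin(pi * seq_len(L) / (L + 1))^2
  k / sum(k)
}

# impute NAs in a circular series by linear interpolation between the nearest
# observed neighbors around the circle
circ_interp_na <- function(x) {
  n <- length(x)
  obs <- which(!is.na(x))
  if (length(obs) == n) return(x)
  if (length(obs) == 0L) stop("all values are NA; cannot interpolate")
  if (length(obs) == 1L) {
    x[] <- x[obs]
    return(x)
  }
  idx <- c(obs - n, obs, obs + n)
  val <- rep(x[obs], 3L)
  x[-obs] <- stats::approx(idx, val, xout = which(is.na(x)))$y
  x
}

# dense circulant smoothing matrix for a centered kernel; y_smoothed = y %*% K
circulant_smoother <- function(n_bins, window_bins) {
  k <- hanning_kernel(window_bins)
  centre <- ceiling(window_bins / 2)
  K <- matrix(0, n_bins, n_bins)
  for (j in seq_len(window_bins)) {
    shift <- j - centre
    idx <- wrap_bin(seq_len(n_bins) + shift, n_bins)
    K[cbind(seq_len(n_bins), idx)] <- K[cbind(seq_len(n_bins), idx)] + k[j]
  }
  t(K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
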