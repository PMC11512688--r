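# FIR design and zero-phase application helpers (internal).
#
# Linear-phase FIR filters are designed with signal::fir1 (Hamming window,
# ~53 dB stopband) at an even order, so the group delay is an integer number
# of samples and can be removed exactly. Application is FFT overlap-free
# convolution on reflection-padded data, which keeps long recordings cheap
# and avoids filter transients bleeding in from zero edges.

# split an integer decimation factor into stages of at most 5
.decim_stages <- function(q) {
  stages <- integer()
  while (q > 1) {
    k <- max(Filter(function(d) q %% d == 0, 2:min(5, q)))
    stages <- c(stages, k)
    q <- q / k
  }
  stages
}

.fir_design_lowpass <- function(cutoff, rate, trans) {
  stopifnot(cutoff + trans / 2 < rate / 2)
  n <- ceiling(3.3 * rate / trans)      # Hamming transition-width rule
  if (n %% 2 == 1) n <- n + 1           # even order -> odd, symmetric taps
  h <- signal::fir1(n, (cutoff + trans / 2) / (rate / 2), type = "low")
  h / sum(h)                            # unit DC gain
}

# Apply a symmetric odd-length FIR to each row of `mat` with zero net delay.
# Short kernels run as direct compiled convolution; long ones via FFT.
# Edges are reflection-padded either way.
.fir_filter_rows <- function(mat, h) {
  L <- length(h)
  stopifnot(L %% 2 == 1)
  d <- (L - 1) / 2
  n <- ncol(mat)
  if (d >= n) stop("signal shorter than filter delay")
  if (L <= 512) return(.fir_rows_cpp(mat, h))
  # reflection padding at both ends
  left <- mat[, (d + 1):2, drop = FALSE]
  right <- mat[, (n - 1):(n - d), drop = FALSE]
  xp <- cbind(left, mat, right)
  np <- ncol(xp)
  nfft <- stats::nextn(np + L - 1, c(2, 3, 5))
  H <- stats::fft(c(h, rep(0, nfft - L)))
  out <- matrix(0, nrow(mat), n)
  block <- max(1L, floor(4e7 / nfft))   # cap working memory per chunk
  for (i0 in seq(1, nrow(mat), by = block)) {
    idx <- i0:min(i0 + block - 1L, nrow(mat))
    X <- t(xp[idx, , drop = FALSE])
    X <- rbind(X, matrix(0, nfft - np, length(idx)))
    Y <- Re(stats::mvfft(stats::mvfft(X) * H, inverse = TRUE)) / nfft
    # full convolution index k corresponds to sum of lags; after stripping
    # the pad and the delay, samples (2d+1):(2d+n) are the aligned output
    out[idx, ] <- t(Y[(2 * d + 1):(2 * d + n), , drop = FALSE])
  }
  out
}

# Zero-phase Butterworth high-pass on each row (forward-backward).
.butter_highpass_rows <- function(mat, cutoff, rate, order = 2) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "high")
  t(apply(mat, 1, function(x) signal::filtfilt(bf, x)))
}
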