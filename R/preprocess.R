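#' Resample a recording to a lower rate
#'
#' Anti-alias low-pass FIR filtering (zero net delay) followed by integer
#' decimation. Events are remapped to the nearest sample at the new rate.
#'
#' @param rec a `recording`.
#' @param target_rate new sampling rate; must divide `rec$rate` and be lower.
#' @return the resampled `recording`.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "recording"))
  if (target_rate >= rec$rate) stop("`target_rate` must be below the current rate")
  q <- rec$rate / target_rate
  if (abs(q - round(q)) > 1e-9) stop("`target_rate` must divide the current rate")
  q <- round(q)
  # multistage decimation: each stage protects the final passband
  # (0 .. 0.5 * target_rate) from aliasing; earlier stages can then use wide
  # transition bands and short filters
  x <- rec$data
  rate <- rec$rate
  for (k in .decim_stages(q)) {
    r_out <- rate / k
    pass <- 0.4 * target_rate
    stopb <- r_out - 0.5 * target_rate
    h <- .fir_design_lowpass(cutoff = pass, rate = rate, trans = stopb - pass)
    x <- .fir_filter_rows(x, h)
    x <- x[, seq(1, ncol(x), by = k), drop = FALSE]
    rate <- r_out
  }
  ev <- rec$events
  if (nrow(ev)) ev$sample <- pmin(round((ev$sample - 1) / q) + 1L, ncol(x))
  new_recording(x, target_rate, rec$channel_names, rec$reference, ev)
}

#' Zero-phase band-pass filter
#'
#' High-pass: second-order Butterworth applied forward-backward (removes DC
#' and slow drift without the impractically long FIR a 0.1 Hz edge would
#' need). Low-pass: linear-phase FIR with delay compensation. Intended for
#' continuous data, before epoching, so filter edge effects do not sit at
#' epoch boundaries.
#'
#' @param rec a `recording`.
#' @param lo,hi band edges in Hz, `0 < lo < hi < rate / 2`.
#' @return the filtered `recording`.
#' @export
bandpass_recording <- function(rec, lo = 0.1, hi = 100) {
  stopifnot(inherits(rec, "recording"))
  if (!(0 < lo && lo < hi && hi < rec$rate / 2)) {
    stop("need 0 < lo < hi < rate/2")
  }
  x <- rec$data - rowMeans(rec$data)
  x <- .butter_highpass_rows(x, lo, rec$rate)
  trans <- min(0.25 * hi, rec$rate / 2 - hi)
  x <- .fir_filter_rows(x, .fir_design_lowpass(hi, rec$rate, trans))
  new_recording(x, rec$rate, rec$channel_names, rec$reference, rec$events)
}

#' Remove power-line noise by windowed sinusoidal regression
#'
#' Within consecutive time windows, each channel is regressed on a sine and
#' cosine at the line frequency (and optional harmonics) and the fitted
#' sinusoid is subtracted. Windowing lets a slowly drifting line amplitude
#' be tracked; broadband activity is essentially untouched because only the
#' projection onto the line-frequency pair is removed.
#'
#' @param rec a `recording`.
#' @param line_freq line frequency in Hz (below Nyquist).
#' @param window window length in seconds.
#' @param harmonics integer multiples of `line_freq` to remove (all below
#'   Nyquist are kept).
#' @return the cleaned `recording`.
#' @export
remove_line_noise <- function(rec, line_freq = 60, window = 4, harmonics = 1) {
  stopifnot(inherits(rec, "recording"))
  if (line_freq >= rec$rate / 2) stop("line frequency at or above Nyquist")
  freqs <- line_freq * seq_len(harmonics)
  freqs <- freqs[freqs < rec$rate / 2]
  n <- ncol(rec$data)
  win_n <- round(window * rec$rate)
  starts <- seq(1, n, by = win_n)
  x <- rec$data
  for (s in starts) {
    e <- min(s + win_n - 1L, n)
    if (e - s + 1L < rec$rate / line_freq * 2) next  # < 2 cycles: skip
    tt <- (s:e - 1) / rec$rate
    X <- do.call(cbind, lapply(freqs, function(f) {
      cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    }))
    Y <- t(x[, s:e, drop = FALSE])
    beta <- solve(crossprod(X), crossprod(X, Y))
    x[, s:e] <- x[, s:e] - t(X %*% beta)
  }
  new_recording(x, rec$rate, rec$channel_names, rec$reference, rec$events)
}

#' Extract fixed-length epochs from each trial
#'
#' Cuts `n_epochs` consecutive non-overlapping epochs of `epoch_len` seconds
#' from each trial onset. Epochs extending past the end of the recording are
#' flagged `absent` (their data is zero-filled and never used) and a warning
#' reports the truncated trials.
#'
#' @param rec a `recording` with trial events.
#' @param epoch_len epoch length in seconds.
#' @param n_epochs epochs per trial.
#' @return an object of class `epochset`: epochs array
#'   (epoch x channel x sample), `meta` (trial, condition, second),
#'   per-epoch `flags` in retained/rejected/selected/absent, `rate`,
#'   `channel_names`, and a stage `log`.
#' @export
extract_epochs <- function(rec, epoch_len = 1, n_epochs = 16) {
  stopifnot(inherits(rec, "recording"))
  if (!nrow(rec$events)) stop("recording has no trial events")
  L <- round(epoch_len * rec$rate)
  ev <- rec$events[order(rec$events$sample), ]
  n_total <- nrow(ev) * n_epochs
  epochs <- array(0, dim = c(n_total, nrow(rec$data), L))
  meta <- data.frame(trial = rep(ev$trial, each = n_epochs),
                     condition = rep(ev$condition, each = n_epochs),
                     second = rep(seq_len(n_epochs), nrow(ev)))
  flags <- rep("retained", n_total)
  k <- 0L
  truncated <- integer()
  for (i in seq_len(nrow(ev))) {
    for (j in seq_len(n_epochs)) {
      k <- k + 1L
      a <- ev$sample[i] + (j - 1L) * L
      b <- a + L - 1L
      if (b > ncol(rec$data)) {
        flags[k] <- "absent"
        truncated <- union(truncated, ev$trial[i])
      } else {
        epochs[k, , ] <- rec$data[, a:b]
      }
    }
  }
  if (length(truncated)) {
    warning("trials truncated before ", n_epochs, " epochs: ",
            paste(sort(truncated), collapse = ", "))
  }
  structure(list(epochs = epochs, meta = meta, flags = flags,
                 rate = rec$rate, channel_names = rec$channel_names,
                 reference = rec$reference, interpolated = character(),
                 excluded = FALSE,
                 log = list(list(stage = "extract_epochs",
                                 epochs_in = n_total,
                                 epochs_out = sum(flags == "retained")))),
            class = "epochset")
}

#' @export
print.epochset <- function(x, ...) {
  cat(sprintf("<epochset> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$rate))
  cat("  flags:", paste(sprintf("%s=%d", names(table(x$flags)),
                                table(x$flags)), collapse = " "), "\n")
  invisible(x)
}

# Perrin-style spherical-spline interpolation operator: estimates the bad
# channels as a fixed linear combination of the good ones (stiffness 4,
# 50 Legendre terms).
.spline_interp_matrix <- function(pos_good, pos_bad, stiffness = 4,
                                  n_terms = 50) {
  gfun <- function(cosang) {
    p_nm1 <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
    p_n <- cosang                                   # P_1
    acc <- (2 * 1 + 1) / (1 * 2)^stiffness * p_n
    for (n in 2:n_terms) {
      p_np1 <- ((2 * n - 1) * cosang * p_n - (n - 1) * p_nm1) / n
      acc <- acc + (2 * n + 1) / (n * (n + 1))^stiffness * p_np1
      p_nm1 <- p_n; p_n <- p_np1
    }
    acc / (4 * pi)
  }
  G <- gfun(tcrossprod(pos_good))
  Gb <- gfun(tcrossprod(pos_bad, pos_good))
  k <- nrow(pos_good)
  C <- rbind(cbind(G, 1), c(rep(1, k), 0))
  M <- cbind(Gb, 1) %*% solve(C)
  M[, seq_len(k), drop = FALSE]
}

#' Spherically interpolate bad channels
#'
#' A channel whose peak absolute amplitude exceeds `amp_thresh` in more than
#' `frac_thresh` of the (non-absent) epochs is replaced, in every epoch, by
#' spherical-spline interpolation from the remaining channels on the
#' idealized head sphere. Interpolated channel names are recorded in the
#' epoch set's `interpolated` field and the QC log.
#'
#' @param es an `epochset`.
#' @param montage a `montage` with positions for all channels.
#' @param amp_thresh peak amplitude criterion in microvolts.
#' @param frac_thresh proportion of epochs that must exceed it.
#' @param max_bad_frac when more than this fraction of channels is bad the
#'   subject is flagged unusable (`es$excluded`) rather than interpolated.
#' @return the `epochset` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(es, montage, amp_thresh = 500,
                                     frac_thresh = 0.5, max_bad_frac = 0.25) {
  stopifnot(inherits(es, "epochset"), inherits(montage, "montage"))
  use <- which(es$flags != "absent")
  nc <- length(es$channel_names)
  peak <- apply(abs(es$epochs[use, , , drop = FALSE]), c(1, 2), max)
  frac_exceed <- colMeans(peak > amp_thresh)
  bad <- which(frac_exceed > frac_thresh)
  es$log <- c(es$log, list(list(stage = "interpolate_bad_channels",
                                channels_interpolated = es$channel_names[bad])))
  if (!length(bad)) return(es)
  if (length(bad) > max_bad_frac * nc) {
    es$excluded <- TRUE
    warning(sprintf("%d of %d channels bad; subject flagged unusable",
                    length(bad), nc))
    return(es)
  }
  good <- setdiff(seq_len(nc), bad)
  if (length(good) < 4) stop("fewer than 4 good channels; spline unsolvable")
  idx <- match(es$channel_names, rownames(montage$pos))
  if (anyNA(idx)) stop("montage lacks positions for some channels")
  pos <- montage$pos[idx, , drop = FALSE]
  M <- .spline_interp_matrix(pos[good, , drop = FALSE],
                             pos[bad, , drop = FALSE])
  ne <- dim(es$epochs)[1]; ns <- dim(es$epochs)[3]
  X <- aperm(es$epochs, c(2, 1, 3))
  dim(X) <- c(nc, ne * ns)
  X[bad, ] <- M %*% X[good, , drop = FALSE]
  dim(X) <- c(nc, ne, ns)
  es$epochs <- aperm(X, c(2, 1, 3))
  es$interpolated <- es$channel_names[bad]
  es
}

# moving-window standard deviation maxima per epoch x channel
.max_window_sd <- function(epochs, win_n, step_n) {
  ns <- dim(epochs)[3]
  starts <- seq(1, ns - win_n + 1, by = step_n)
  if (ns - (starts[length(starts)] + win_n - 1L) > 0) {
    starts <- c(starts, ns - win_n + 1L)  # cover the tail
  }
  mx <- matrix(-Inf, dim(epochs)[1], dim(epochs)[2])
  for (s in starts) {
    seg <- epochs[, , s:(s + win_n - 1L), drop = FALSE]
    m1 <- rowMeans(seg, dims = 2)
    m2 <- rowMeans(seg^2, dims = 2)
    v <- pmax(m2 - m1^2, 0) * win_n / (win_n - 1)
    mx <- pmax(mx, sqrt(v))
  }
  mx
}

#' Reject epochs with excessive windowed amplitude variability
#'
#' An epoch is flagged `rejected` when, on any channel, the sample standard
#' deviation within any sliding window exceeds `sd_thresh`. Windows are
#' `win_len` seconds long and slide by `step` seconds (50% overlap at the
#' defaults), with a final window flush to the epoch end.
#'
#' @param es an `epochset`.
#' @param sd_thresh threshold in microvolts.
#' @param win_len,step window length and hop in seconds.
#' @return the `epochset` with updated flags and log.
#' @export
reject_epochs <- function(es, sd_thresh = 80, win_len = 0.2, step = 0.1) {
  stopifnot(inherits(es, "epochset"))
  win_n <- round(win_len * es$rate)
  if (win_n >= dim(es$epochs)[3]) stop("window longer than epoch")
  step_n <- max(1L, round(step * es$rate))
  mx <- .max_window_sd(es$epochs, win_n, step_n)
  bad <- which(apply(mx, 1, max) > sd_thresh & es$flags == "retained")
  es$flags[bad] <- "rejected"
  es$log <- c(es$log, list(list(stage = "reject_epochs",
                                epochs_in = sum(es$flags != "absent"),
                                epochs_out = sum(es$flags %in% c("retained", "selected")),
                                rejected = length(bad))))
  es
}

#' Re-reference epochs to the scalp average
#'
#' Subtracts, at every sample, the mean across all channels, so the spatial
#' mean is zero. Idempotent; differences between channel pairs are
#' unaffected.
#'
#' @param es an `epochset`.
#' @return the re-referenced `epochset`.
#' @export
rereference_average <- function(es) {
  stopifnot(inherits(es, "epochset"))
  ne <- dim(es$epochs)[1]; nc <- dim(es$epochs)[2]; ns <- dim(es$epochs)[3]
  mu <- colMeans(aperm(es$epochs, c(2, 1, 3)))            # epoch x sample
  es$epochs <- es$epochs - aperm(array(mu, c(ne, ns, nc)), c(1, 3, 2))
  es$reference <- "average"
  es
}

#' Total global field power per epoch
#'
#' GFP at a sample is the standard deviation across channels; the total GFP
#' of an epoch sums it over the epoch's samples.
#'
#' @param es an `epochset`.
#' @return numeric vector, one value per epoch (microvolts).
#' @export
epoch_gfp <- function(es) {
  stopifnot(inherits(es, "epochset"))
  nc <- dim(es$epochs)[2]
  perm <- aperm(es$epochs, c(2, 1, 3))
  m1 <- colMeans(perm)        # epoch x sample means over channels
  m2 <- colMeans(perm^2)
  v <- pmax(m2 - m1^2, 0) * nc / (nc - 1)
  rowSums(sqrt(v))
}

#' Select the epochs with total GFP closest to the condition median
#'
#' Within each condition, ranks the retained epochs by the absolute distance
#' of their total global field power from that condition's median GFP and
#' marks the `n_select` closest as `selected` (ties broken by temporal
#' order), so every subject contributes the same amount of data downstream.
#' A subject with fewer than `n_select` retained epochs in either condition
#' is flagged excluded and nothing is selected for that condition.
#'
#' @param es an `epochset` (after rejection and re-referencing).
#' @param n_select epochs to keep per condition.
#' @return the `epochset` with `selected` flags, a `gfp_table` data frame
#'   (epoch, condition, gfp, dist_to_median, selected) and `excluded` set
#'   when a condition has too few retained epochs.
#' @export
select_epochs_gfp <- function(es, n_select = 10) {
  stopifnot(inherits(es, "epochset"))
  g <- epoch_gfp(es)
  retained <- which(es$flags == "retained")
  tab <- data.frame(epoch = retained,
                    condition = es$meta$condition[retained],
                    gfp = g[retained])
  tab$dist_to_median <- NA_real_
  tab$selected <- FALSE
  for (cond in unique(tab$condition)) {
    rows <- which(tab$condition == cond)
    if (length(rows) < n_select) {
      es$excluded <- TRUE
      next
    }
    d <- abs(tab$gfp[rows] - stats::median(tab$gfp[rows]))
    tab$dist_to_median[rows] <- d
    pick <- rows[order(d, tab$epoch[rows])][seq_len(n_select)]
    tab$selected[pick] <- TRUE
    es$flags[tab$epoch[pick]] <- "selected"
  }
  es$gfp_table <- tab
  es$log <- c(es$log, list(list(stage = "select_epochs_gfp",
                                epochs_in = length(retained),
                                epochs_out = sum(tab$selected),
                                excluded = es$excluded)))
  es
}

#' Run the full preprocessing chain on a continuous recording
#'
#' Fixed stage order: resample, band-pass, line-noise removal, epoch
#' extraction, bad-channel interpolation, epoch rejection, average
#' re-reference, GFP-based epoch selection. Stage counts accumulate in the
#' epoch set's `log`.
#'
#' @param rec a `recording`.
#' @param montage a `montage`.
#' @param config a [pipeline_config()] list (stage parameters).
#' @return the final `epochset`.
#' @export
preprocess_recording <- function(rec, montage = default_montage(),
                                 config = pipeline_config()) {
  p <- config
  rec <- resample_recording(rec, p$target_rate)
  rec <- bandpass_recording(rec, p$band_lo, p$band_hi)
  rec <- remove_line_noise(rec, p$line_freq)
  es <- extract_epochs(rec, p$epoch_len, p$epochs_per_trial)
  es <- interpolate_bad_channels(es, montage, p$interp_amp_thresh,
                                 p$interp_frac_thresh)
  if (es$excluded) return(es)
  es <- reject_epochs(es, p$reject_sd_thresh, p$reject_win_len, p$reject_step)
  es <- rereference_average(es)
  select_epochs_gfp(es, p$n_select)
}
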