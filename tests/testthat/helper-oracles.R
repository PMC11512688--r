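# Independent oracles and small fixture builders used across tests.

# Brute-force sample-entropy counts: enumerate every template pair directly,
# Chebyshev <= tol, templates within segments only, pairs pooled across
# segments. Deliberately naive (no sorting, no pruning).
oracle_sampen <- function(segments, m, tol) {
  if (is.numeric(segments)) segments <- list(segments)
  tpl <- list()
  for (s in segments) {
    for (i in seq_len(max(0, length(s) - m))) {
      tpl[[length(tpl) + 1L]] <- s[i:(i + m)]
    }
  }
  A <- 0; B <- 0
  n <- length(tpl)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (max(abs(tpl[[i]][1:m] - tpl[[j]][1:m])) <= tol) {
        B <- B + 1
        if (abs(tpl[[i]][m + 1] - tpl[[j]][m + 1]) <= tol) A <- A + 1
      }
    }
  }
  list(A = A, B = B, entropy = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# Exhaustive GFP selection oracle: rank by |gfp - median|, ties by epoch order.
oracle_gfp_select <- function(gfp, n_select) {
  d <- abs(gfp - median(gfp))
  sort(order(d, seq_along(gfp))[seq_len(n_select)])
}

# ICC(2,1) via R's own two-way ANOVA decomposition (aov), as an independent
# route to the mean squares.
oracle_icc21 <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  d <- data.frame(y = as.vector(ratings),
                  row = factor(rep(seq_len(n), k)),
                  col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ row + col, data = d))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Minimal epochset builder for unit tests: data is epoch x channel x sample.
make_epochset <- function(epochs, conditions, rate = 500,
                          channel_names = NULL) {
  ne <- dim(epochs)[1]
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(dim(epochs)[2]))
  }
  structure(list(
    epochs = epochs,
    meta = data.frame(trial = seq_len(ne), condition = conditions,
                      second = 1L),
    flags = rep("retained", ne), rate = rate,
    channel_names = channel_names, reference = "FCz",
    interpolated = character(), excluded = FALSE, log = list()
  ), class = "epochset")
}

# Small continuous recording with evenly spaced trial markers.
make_test_recording <- function(n_channels = 4, rate = 500, n_trials = 2,
                                trial_len = 4, gap = 1, lead = 1,
                                data_fun = function(n) rnorm(n, sd = 20)) {
  total <- (lead + n_trials * (trial_len + gap)) * rate
  data <- t(vapply(seq_len(n_channels), function(i) data_fun(total),
                   numeric(total)))
  onsets <- (lead + (seq_len(n_trials) - 1) * (trial_len + gap)) * rate + 1L
  events <- data.frame(sample = onsets,
                       condition = rep(c("joint", "parallel"),
                                       length.out = n_trials),
                       trial = seq_len(n_trials))
  new_recording(data, rate, paste0("ch", seq_len(n_channels)),
                events = events)
}

# Band power around a frequency from a raw periodogram.
band_power <- function(x, rate, freq, halfwidth = 2) {
  p <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  sel <- abs(p$freq * rate - freq) <= halfwidth
  max(p$spec[sel])
}
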