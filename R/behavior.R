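#' Merge abutting same-target looks in a gaze log
#'
#' Sorts the event log by onset and merges consecutive looks at the same
#' target whose gap is at most `gap_tol` seconds, so that how a coder split
#' a single continuous look cannot change downstream metrics.
#'
#' @param log data frame with columns `onset`, `offset` (seconds) and
#'   `target` (one of `"infant"`, `"object"`, `"other"`).
#' @param gap_tol maximum gap merged across, in seconds.
#' @return the merged, sorted log.
#' @export
merge_looks <- function(log, gap_tol = 0) {
  stopifnot(all(c("onset", "offset", "target") %in% names(log)))
  if (!nrow(log)) return(log)
  if (any(log$offset <= log$onset)) stop("each look needs onset < offset")
  log <- log[order(log$onset), , drop = FALSE]
  out <- log[1, , drop = FALSE]
  for (i in seq_len(nrow(log))[-1]) {
    j <- nrow(out)
    if (log$target[i] == out$target[j] &&
        log$onset[i] - out$offset[j] <= gap_tol) {
      out$offset[j] <- max(out$offset[j], log$offset[i])
    } else {
      out <- rbind(out, log[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Parent alternating-gaze duration
#'
#' Scores the total duration of parent alternating gaze from a coded event
#' log: looks to the infant, then an object, then back to the infant. The
#' leading `discard_lead` seconds of the session are dropped first (looks
#' straddling the boundary are truncated), and abutting same-target looks
#' are merged before sequence detection.
#'
#' The 2-second turn rule has two defensible readings, both implemented:
#'
#' * `cap_mode = "qualify"` (default): a constituent look longer than
#'   `max_turn` disqualifies the triple — the cap defines what counts as
#'   alternating gaze. Overlapping chains (infant-object-infant-object-...)
#'   credit each look's time once, however many qualifying triples it
#'   belongs to.
#' * `cap_mode = "credit"`: every infant-object-infant triple qualifies, but
#'   each look is credited at most `max_turn` seconds.
#'
#' @param log gaze event data frame (`onset`, `offset`, `target`).
#' @param max_turn per-look cap in seconds.
#' @param discard_lead leading seconds to discard (acclimation period).
#' @param cap_mode `"qualify"` or `"credit"`.
#' @return list with `duration` (seconds), `n_sequences` (number of
#'   qualifying infant-object-infant triples) and the post-discard `log`.
#' @export
alternating_gaze_duration <- function(log, max_turn = 2, discard_lead = 60,
                                      cap_mode = c("qualify", "credit")) {
  cap_mode <- match.arg(cap_mode)
  if (!nrow(log)) return(list(duration = 0, n_sequences = 0L, log = log))
  log <- log[log$offset > discard_lead, , drop = FALSE]
  if (nrow(log)) log$onset <- pmax(log$onset, discard_lead)
  log <- merge_looks(log)
  n <- nrow(log)
  if (n < 3) return(list(duration = 0, n_sequences = 0L, log = log))
  dur <- log$offset - log$onset
  counted <- rep(FALSE, n)
  credit <- if (cap_mode == "credit") pmin(dur, max_turn) else dur
  n_seq <- 0L
  for (i in seq_len(n - 2)) {
    trip <- i:(i + 2)
    if (!identical(log$target[trip], c("infant", "object", "infant"))) next
    if (cap_mode == "qualify" && any(dur[trip] > max_turn)) next
    n_seq <- n_seq + 1L
    counted[trip] <- TRUE
  }
  list(duration = sum(credit[counted]), n_sequences = n_seq, log = log)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-rater, absolute-agreement ICC from the two-way random-effects
#' ANOVA mean squares, the standard inter-coder reliability index: with
#' `MSR` (between targets), `MSC` (between coders) and `MSE` (residual),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The
#' confidence interval is the usual F-based one (Shrout-Fleiss).
#'
#' @param ratings numeric matrix, targets (dyads) x coders, no missing
#'   values.
#' @param conf_level confidence level for the interval.
#' @return list: `icc`, `lower`, `upper`, mean squares, `n`, `k`, and
#'   `valid` (`FALSE` when between-target variance is zero, where the
#'   coefficient is undefined).
#' @export
icc_two_way_random <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop("need at least 2 coders")
  if (n < 5) warning("fewer than 5 targets; ICC will be unstable")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  MSR <- k * sum((rm_ - grand)^2) / (n - 1)
  MSC <- n * sum((cm - grand)^2) / (k - 1)
  SSE <- sum((ratings - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= .Machine$double.eps * max(1, abs(grand))) {
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k,
                valid = FALSE))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  # Shrout & Fleiss F-based interval for ICC(2,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0) v <- (n - 1) * (k - 1)
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, lower = lower, upper = upper,
       MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k, valid = TRUE)
}

#' Z-score a vector
#'
#' Centers and scales to sample mean 0 and sample SD 1 (n - 1 denominator).
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return standardized vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero standard deviation")
  (x - mean(x)) / s
}
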