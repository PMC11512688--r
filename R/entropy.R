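#' Coarse-grain a time series
#'
#' Replaces consecutive non-overlapping blocks of `scale` samples by their
#' mean, the standard construction of the scale-s series in multiscale
#' entropy. Trailing samples that do not fill a block are dropped.
#'
#' @param x numeric vector.
#' @param scale positive integer coarse-graining factor.
#' @return numeric vector of length `floor(length(x) / scale)`; length zero
#'   when `scale > length(x)`.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1L) stop("`scale` must be a positive integer")
  if (scale == 1L) return(as.numeric(x))
  n <- length(x) %/% scale
  if (n == 0L) return(numeric(0))
  colMeans(matrix(x[seq_len(n * scale)], nrow = scale))
}

#' Sample entropy pooled over discontinuous segments
#'
#' Computes sample entropy when the data come as separate continuous
#' segments (e.g. non-contiguous 1-s epochs). Template vectors never span a
#' segment boundary, but template pairs are compared across all segments and
#' the match counts A (length m + 1) and B (length m) are pooled before the
#' log ratio, so every segment contributes to a single estimate:
#' `entropy = -ln(A / B)` in nats. Matching uses the Chebyshev
#' (maximum-coordinate) distance with a non-strict `<= tolerance` rule;
#' self-matches are excluded.
#'
#' @param segments numeric vector or list of numeric vectors. Segments
#'   shorter than `m + 1` contribute no templates.
#' @param m pattern length (template length for the B count).
#' @param tolerance absolute match tolerance, in the data's units.
#' @return list with `entropy` (nats; `NA` when undefined), integer-valued
#'   counts `A` and `B`, `n_templates`, and `valid` (`FALSE` when A or B is
#'   zero, leaving the log ratio undefined — no value is imputed).
#' @export
sample_entropy_segments <- function(segments, m = 2, tolerance) {
  if (is.numeric(segments)) segments <- list(segments)
  stopifnot(is.list(segments), length(segments) >= 1)
  segments <- lapply(segments, as.numeric)
  cnt <- .sampen_counts(segments, as.integer(m), as.numeric(tolerance))
  valid <- cnt$A > 0 && cnt$B > 0
  list(entropy = if (valid) -log(cnt$A / cnt$B) else NA_real_,
       A = cnt$A, B = cnt$B, n_templates = cnt$n_templates, valid = valid)
}

#' Multiscale sample entropy curve over discontinuous segments
#'
#' For each coarse-graining factor, every segment is coarse-grained, the
#' similarity criterion is converted to an absolute tolerance, and
#' [sample_entropy_segments()] pools template counts across the
#' coarse-grained segments. Two tolerance conventions are provided:
#'
#' * `"per-scale"` (the default, the modification this package centres on):
#'   tolerance at scale s is `r` times the standard deviation of the pooled
#'   coarse-grained points at that scale, so entropy is not conflated with
#'   the variance reduction that coarse-graining induces.
#' * `"fixed"`: tolerance at every scale is `r` times the pooled standard
#'   deviation of the original (scale-1) data, the original convention.
#'
#' The scale-1 SD is computed from the pooled points of all segments, with
#' no per-segment renormalization; a single tolerance per scale keeps the
#' pooled counts commensurable.
#'
#' @param segments numeric vector or list of numeric vectors (e.g. the
#'   selected 1-s epochs of one channel).
#' @param m pattern length.
#' @param r similarity criterion as a fraction of SD.
#' @param scales integer vector of coarse-graining factors, strictly
#'   increasing.
#' @param tolerance_mode `"per-scale"` or `"fixed"`.
#' @return data frame with one row per scale: `scale`, `entropy` (nats),
#'   `A`, `B`, `n_points` (pooled coarse-grained points), `tolerance`,
#'   `valid`. A cell is invalid when the pooled SD at that scale is zero,
#'   when fewer than `m + 1` coarse-grained points remain in every segment,
#'   or when a match count is zero.
#' @export
mse_curve <- function(segments, m = 2, r = 0.5, scales,
                      tolerance_mode = c("per-scale", "fixed")) {
  tolerance_mode <- match.arg(tolerance_mode)
  if (is.numeric(segments)) segments <- list(segments)
  segments <- lapply(segments, as.numeric)
  scales <- as.integer(scales)
  if (any(scales < 1L) || is.unsorted(scales, strictly = TRUE)) {
    stop("`scales` must be strictly increasing positive integers")
  }
  if (r <= 0) stop("`r` must be positive")
  sd1 <- stats::sd(unlist(segments))

  rows <- lapply(scales, function(s) {
    cg <- lapply(segments, coarse_grain, scale = s)
    cg <- cg[vapply(cg, length, 0L) >= m + 1]
    n_pts <- sum(vapply(cg, length, 0L))
    if (!length(cg)) {
      return(data.frame(scale = s, entropy = NA_real_, A = 0, B = 0,
                        n_points = n_pts, tolerance = NA_real_,
                        valid = FALSE))
    }
    sd_s <- if (tolerance_mode == "per-scale") stats::sd(unlist(cg)) else sd1
    if (!is.finite(sd_s) || sd_s == 0) {
      return(data.frame(scale = s, entropy = NA_real_, A = 0, B = 0,
                        n_points = n_pts, tolerance = NA_real_,
                        valid = FALSE))
    }
    tol <- r * sd_s
    se <- sample_entropy_segments(cg, m = m, tolerance = tol)
    data.frame(scale = s, entropy = se$entropy, A = se$A, B = se$B,
               n_points = n_pts, tolerance = tol, valid = se$valid)
  })
  do.call(rbind, rows)
}

#' Coarse-graining factors realizing a frequency band
#'
#' Maps a frequency band to the set of integer timescales whose
#' characteristic frequency falls inside it. Two conventions are offered
#' because the correspondence between a coarse-graining factor s and a
#' frequency is itself a modelling choice: `"cycle"` (default) takes the
#' scale-s series to track fluctuations at `f = rate / s`, while
#' `"halfcycle"` treats a scale-s block as half a period, `f = rate / (2 s)`.
#'
#' @param lo,hi band edges in Hz, `lo < hi <= rate / 2`.
#' @param rate sampling rate in samples/s.
#' @param mapping `"cycle"` or `"halfcycle"`.
#' @return integer vector of scales; errors if the band maps to no integer
#'   scale.
#' @export
scales_for_band <- function(lo, hi, rate, mapping = c("cycle", "halfcycle")) {
  mapping <- match.arg(mapping)
  if (!(lo <= hi)) stop("need lo <= hi")
  if (hi > rate / 2) stop("band edge above Nyquist frequency")
  den <- if (mapping == "cycle") 1 else 2
  # f = rate / (den * s) in [lo, hi]  =>  s in [rate/(den*hi), rate/(den*lo)]
  s_min <- ceiling(rate / (den * hi))
  s_max <- floor(rate / (den * lo))
  if (s_max < s_min) stop("no integer scale maps into the requested band")
  seq.int(s_min, s_max)
}

#' Entropy curves for every channel of a selected epoch set
#'
#' Runs [mse_curve()] per condition and channel on the epochs flagged
#' `selected`, treating each 1-s epoch as one discontinuous segment.
#'
#' @param es an `epochset` (see [extract_epochs()]) after GFP selection.
#' @param m,r,scales,tolerance_mode passed to [mse_curve()].
#' @return long data frame: condition, channel, scale, entropy, A, B,
#'   n_points, valid.
#' @export
entropy_epochset <- function(es, m = 2, r = 0.5, scales,
                             tolerance_mode = "per-scale") {
  stopifnot(inherits(es, "epochset"))
  sel <- which(es$flags == "selected")
  if (!length(sel)) stop("no selected epochs; run select_epochs_gfp() first")
  out <- list()
  for (cond in sort(unique(es$meta$condition[sel]))) {
    idx <- sel[es$meta$condition[sel] == cond]
    for (ch in seq_along(es$channel_names)) {
      segs <- lapply(idx, function(e) es$epochs[e, ch, ])
      cur <- mse_curve(segs, m = m, r = r, scales = scales,
                       tolerance_mode = tolerance_mode)
      cur$condition <- cond
      cur$channel <- es$channel_names[ch]
      out[[length(out) + 1L]] <- cur
    }
  }
  res <- do.call(rbind, out)
  res[, c("condition", "channel", "scale", "entropy", "A", "B",
          "n_points", "tolerance", "valid")]
}

#' Average entropy over a frequency band and regions of interest
#'
#' Averages per-channel, per-scale entropy over the scales realizing a
#' frequency band and over the channels of each ROI. Invalid cells are
#' excluded from the mean (never zero-filled); the number of cells entering
#' each average is reported, and an ROI value is itself invalid when every
#' contributing cell is.
#'
#' @param ent_df long entropy table from [entropy_epochset()] (optionally
#'   with extra id columns such as `subject`, which are preserved as
#'   grouping variables).
#' @param montage a `montage` providing the ROI partition.
#' @param band_scales integer vector of scales to average over.
#' @return data frame: one row per (extra ids x) condition x ROI with
#'   `entropy`, `n_cells`, `valid`.
#' @export
aggregate_band_roi <- function(ent_df, montage, band_scales) {
  if (!length(band_scales)) stop("`band_scales` must be nonempty")
  rois <- roi_of_channel(montage)
  df <- ent_df[ent_df$scale %in% band_scales, , drop = FALSE]
  df$roi <- unname(rois[df$channel])
  if (anyNA(df$roi)) stop("entropy table contains channels not in the montage")
  ids <- intersect(c("subject", "condition", "roi"), names(df))
  key <- interaction(df[ids], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(df, key), function(g) {
    ok <- g$valid & is.finite(g$entropy)
    row <- g[1L, ids, drop = FALSE]
    row$entropy <- if (any(ok)) mean(g$entropy[ok]) else NA_real_
    row$n_cells <- sum(ok)
    row$valid <- any(ok)
    row
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
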