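#' Construct a continuous EEG recording
#'
#' A `recording` is the package's in-memory model of a continuous
#' multi-channel EEG acquisition: an amplitude matrix in microvolts, a
#' sampling rate, ordered channel labels, the reference state, and stimulus
#' events marking trial onsets.
#'
#' @param data numeric matrix, channels x samples, amplitudes in microvolts.
#' @param rate sampling rate in samples per second.
#' @param channel_names character vector of unique channel labels
#'   (10-20 system), one per row of `data`.
#' @param reference reference label (e.g. `"FCz"`) or `"average"`.
#' @param events data frame with columns `sample` (1-based sample index of
#'   the event onset), `condition` (character, e.g. `"joint"`/`"parallel"`)
#'   and `trial` (integer trial number). May have zero rows.
#'
#' @return an object of class `recording`.
#' @export
new_recording <- function(data, rate, channel_names, reference = "FCz",
                          events = empty_events()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) {
    stop("`data` must be a numeric matrix with no missing values")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` must have one entry per data row")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  events <- as.data.frame(events)
  if (!all(c("sample", "condition", "trial") %in% names(events))) {
    stop("`events` needs columns sample, condition, trial")
  }
  if (nrow(events) &&
      (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    stop("event sample indices must lie within the recording")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, rate = rate, channel_names = as.character(channel_names),
         reference = reference,
         events = events[, c("sample", "condition", "trial")]),
    class = "recording"
  )
}

#' An empty stimulus-event table
#'
#' @return zero-row data frame with columns `sample`, `condition`, `trial`.
#' @export
empty_events <- function() {
  data.frame(sample = integer(), condition = character(), trial = integer())
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz, ref %s, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, x$reference, nrow(x$events)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Load the idealized 10-20 montage shipped with the package
#'
#' Electrode positions on a unit head sphere for the 32-channel cap, given as
#' polar angle from the vertex and azimuth from the nose (positive toward the
#' right ear), together with the region-of-interest map used for entropy
#' aggregation: left frontal (Fp1, F3), right frontal (Fp2, F4), left central
#' (FC1, C3), right central (FC2, C4), and all remaining scalp channels as a
#' comparison region.
#'
#' @param path optional path to a montage CSV with columns
#'   `channel, theta_deg, phi_deg`; defaults to the packaged file.
#' @return an object of class `montage`: a list with `channels`, unit
#'   position vectors `pos` (channels x 3), and `roi_map`.
#' @export
default_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage_1020_32.csv", package = "mseeg")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "theta_deg", "phi_deg") %in% names(tab)))
  th <- tab$theta_deg * pi / 180
  ph <- tab$phi_deg * pi / 180
  pos <- cbind(x = sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
  rownames(pos) <- tab$channel
  roi_map <- list(
    LF = c("Fp1", "F3"), RF = c("Fp2", "F4"),
    LC = c("FC1", "C3"), RC = c("FC2", "C4")
  )
  roi_map$other <- setdiff(tab$channel, unlist(roi_map))
  structure(list(channels = tab$channel, pos = pos, roi_map = roi_map),
            class = "montage")
}

#' Map channels to regions of interest
#'
#' @param montage a `montage`.
#' @return named character vector: for each channel, its ROI label in
#'   `{LF, RF, LC, RC, other}`. The five ROIs partition the scalp channels.
#' @export
roi_of_channel <- function(montage) {
  out <- rep(NA_character_, length(montage$channels))
  names(out) <- montage$channels
  for (roi in names(montage$roi_map)) out[montage$roi_map[[roi]]] <- roi
  out
}
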