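#' Pseudorandomized condition schedule
#'
#' Random order of `n_trials` trials split evenly between `"joint"` and
#' `"parallel"`, with no condition repeated more than `max_run` times in a
#' row (rejection sampling).
#'
#' @param n_trials even number of trials.
#' @param max_run longest allowed run of one condition.
#' @return character vector of conditions.
#' @export
schedule_conditions <- function(n_trials = 16, max_run = 2) {
  stopifnot(n_trials %% 2 == 0)
  base <- rep(c("joint", "parallel"), n_trials / 2)
  repeat {
    s <- sample(base)
    runs <- rle(s)$lengths
    if (max(runs) <= max_run) return(s)
  }
}

#' Unit-variance synthetic EEG background
#'
#' The stochastic part of a synthetic channel: a mixture of 1/f ("pink")
#' noise, obtained by spectral shaping of Gaussian white noise with exponent
#' 1, and white noise, weighted by the subject's irregularity parameter
#' `c` in \[0, 1\]. Higher `c` gives a whiter, more irregular signal and
#' therefore higher sample entropy; lower `c` a smoother, more
#' autocorrelated one. The mixture is rescaled to unit empirical SD.
#'
#' @param n number of samples.
#' @param c_irregular white-noise mixing weight in \[0, 1\].
#' @return numeric vector of length `n` with SD 1.
#' @export
synth_background <- function(n, c_irregular) {
  stopifnot(n > 16, c_irregular >= 0, c_irregular <= 1)
  # draw the 1/f spectrum directly: Hermitian-symmetric complex-normal
  # coefficients with amplitude 1/sqrt(k), one inverse FFT
  n2 <- n %/% 2
  k <- seq_len(n2 - 1 + n %% 2)
  Zh <- complex(real = stats::rnorm(length(k)),
                imaginary = stats::rnorm(length(k))) / sqrt(k)
  nyq <- if (n %% 2 == 0) stats::rnorm(1) / sqrt(n2) else NULL
  X <- c(0, Zh, nyq, Conj(rev(Zh)))
  pink <- Re(stats::fft(X, inverse = TRUE))
  pink <- pink / stats::sd(pink)
  white <- stats::rnorm(n)
  x <- (1 - c_irregular) * pink + c_irregular * white
  x / stats::sd(x)
}

# oscillation amplitude topography: strongest over frontal/central sites
.osc_topography <- function(channel_names) {
  w <- rep(0.3, length(channel_names))
  names(w) <- channel_names
  frontal_central <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
                       "FC1", "FC2", "FC5", "FC6", "C3", "C4", "Cz")
  w[intersect(frontal_central, channel_names)] <- 1
  w
}

#' Simulate one subject's continuous EEG recording
#'
#' Emulates the acquisition the pipeline expects: a 32-channel cap sampled
#' at 5000 Hz, 16 trials of 16 s of video viewing (conditions
#' pseudorandomized, never more than two in a row) separated by 1-s gaps.
#' Each channel is `noise_rms` microvolts of 1/f-plus-white background (mix
#' controlled by the subject's irregularity `c_irregular`) plus a shared
#' 6-Hz oscillation weighted toward frontal/central channels, so the ROI
#' structure is non-trivial.
#'
#' Ground-truth artifacts are injected on demand:
#' * `artifact_epochs`: for each listed (trial, second) epoch, a 200-ms
#'   25-Hz burst of `burst_amp` microvolts on `n_burst_channels` random
#'   channels, placed on the 100-ms grid so a sliding rejection window
#'   captures it fully.
#' * `bad_channel`: that channel receives an 8-Hz, `bad_amp`-microvolt
#'   sinusoid during `bad_epoch_frac` of the epochs, exceeding the
#'   interpolation amplitude criterion in those epochs.
#'
#' @param c_irregular irregularity parameter in \[0, 1\].
#' @param montage a `montage` (channel set and order).
#' @param rate sampling rate (samples/s).
#' @param n_trials,trial_len,gap_len,lead_in trial structure in seconds.
#' @param noise_rms background RMS amplitude, microvolts.
#' @param osc_freq,osc_amp shared oscillation frequency (Hz) and peak
#'   amplitude (microvolts) at full topographic weight.
#' @param artifact_epochs data frame (`trial`, `second`) of epochs to
#'   contaminate, or `NULL`.
#' @param n_burst_channels,burst_amp burst channels per artifact and
#'   amplitude.
#' @param bad_channel channel name to corrupt, or `NULL`.
#' @param bad_epoch_frac fraction of epochs in which the bad channel
#'   exceeds the amplitude criterion.
#' @param bad_amp bad-channel sinusoid amplitude, microvolts.
#' @return list: `recording`, `conditions` (per trial), `artifact_epochs`,
#'   `bad_channel`, `bad_epochs` (indices among the trial x second grid).
#' @export
simulate_subject_eeg <- function(c_irregular, montage = default_montage(),
                                 rate = 5000, n_trials = 16, trial_len = 16,
                                 gap_len = 1, lead_in = 2, noise_rms = 25,
                                 osc_freq = 6, osc_amp = 10,
                                 artifact_epochs = NULL,
                                 n_burst_channels = 3, burst_amp = 300,
                                 bad_channel = NULL, bad_epoch_frac = 0.6,
                                 bad_amp = 800) {
  chans <- montage$channels
  nc <- length(chans)
  total_s <- lead_in + n_trials * (trial_len + gap_len)
  n <- total_s * rate
  conditions <- schedule_conditions(n_trials)
  onsets <- lead_in + (seq_len(n_trials) - 1) * (trial_len + gap_len)  # seconds
  tt <- (seq_len(n) - 1) / rate
  phase <- stats::runif(1, 0, 2 * pi)
  osc <- sin(2 * pi * osc_freq * tt + phase)
  topo <- .osc_topography(chans)

  data <- matrix(0, nc, n)
  for (i in seq_len(nc)) {
    data[i, ] <- noise_rms * synth_background(n, c_irregular) +
      osc_amp * topo[i] * osc
  }

  epoch_span <- function(trial, second) {
    a <- round((onsets[trial] + second - 1) * rate) + 1L
    c(a, a + rate - 1L)
  }

  if (!is.null(artifact_epochs) && nrow(artifact_epochs)) {
    for (k in seq_len(nrow(artifact_epochs))) {
      sp <- epoch_span(artifact_epochs$trial[k], artifact_epochs$second[k])
      off <- sample(0:7, 1) * round(0.1 * rate)     # 100-ms grid inside epoch
      a <- sp[1] + off
      b <- a + round(0.2 * rate) - 1L
      tb <- (seq(a, b) - a) / rate
      burst <- burst_amp * sin(2 * pi * 25 * tb)
      for (ch in sample(nc, n_burst_channels)) {
        data[ch, a:b] <- data[ch, a:b] + burst
      }
    }
  }

  bad_epochs <- integer()
  if (!is.null(bad_channel)) {
    ci <- match(bad_channel, chans)
    if (is.na(ci)) stop("unknown bad channel: ", bad_channel)
    grid <- expand.grid(second = seq_len(trial_len), trial = seq_len(n_trials))
    n_bad <- ceiling(bad_epoch_frac * nrow(grid))
    bad_epochs <- sort(sample(nrow(grid), n_bad))
    for (k in bad_epochs) {
      sp <- epoch_span(grid$trial[k], grid$second[k])
      tb <- (seq(sp[1], sp[2]) - 1) / rate
      data[ci, sp[1]:sp[2]] <- data[ci, sp[1]:sp[2]] +
        bad_amp * sin(2 * pi * 8 * tb)
    }
  }

  events <- data.frame(sample = round(onsets * rate) + 1L,
                       condition = conditions, trial = seq_len(n_trials))
  list(recording = new_recording(data, rate, chans, "FCz", events),
       conditions = conditions,
       artifact_epochs = artifact_epochs,
       bad_channel = bad_channel, bad_epochs = bad_epochs)
}

#' Construct a gaze event log with a target alternating-gaze total
#'
#' Builds a coded free-play event log whose alternating-gaze content is
#' known by construction: after the acclimation minute, runs of short
#' (under the 2-s cap) infant-object-infant alternations are emitted until
#' their summed look time reaches `target_duration` (or the session ends),
#' separated by looks elsewhere; some filler looks are placed inside the
#' first minute to exercise the lead discard. The realized total is
#' returned as ground truth.
#'
#' @param target_duration desired alternating-gaze seconds.
#' @param session_length session length in seconds.
#' @param discard_lead acclimation period the metric will drop.
#' @return list: `log` (onset, offset, target), `alternating_duration`
#'   (realized seconds), `n_looks`.
#' @export
simulate_gaze_log <- function(target_duration, session_length = 300,
                              discard_lead = 60) {
  ev <- data.frame(onset = numeric(), offset = numeric(),
                   target = character())
  add <- function(t0, len, target) {
    ev[nrow(ev) + 1L, ] <<- list(t0, t0 + len, target)
    t0 + len
  }
  # filler inside the discarded lead
  t <- 2
  while (t < discard_lead - 5) {
    t <- add(t, stats::runif(1, 0.5, 1.8), sample(c("infant", "object"), 1))
    t <- t + stats::runif(1, 0.2, 1.5)
  }
  t <- discard_lead + 1
  realized <- 0
  while (realized < target_duration - 0.5 && t < session_length - 8) {
    n_looks <- sample(c(3, 5, 7), 1)
    remaining <- target_duration - realized
    lens <- pmin(stats::runif(n_looks, 0.5, 1.8),
                 pmax(remaining / n_looks, 0.4))
    targ <- rep(c("infant", "object"), length.out = n_looks)
    for (j in seq_len(n_looks)) t <- add(t, lens[j], targ[j])
    realized <- realized + sum(lens)
    t <- add(t, stats::runif(1, 1, 3), "other")
    t <- t + stats::runif(1, 0.2, 1)
  }
  list(log = ev, alternating_duration = realized, n_looks = nrow(ev))
}

#' Generate a ground-truth-annotated synthetic cohort
#'
#' Writes, per subject, a BrainVision triplet and a gaze-log CSV emulating
#' the study conditions (32 channels at 5000 Hz, 16 trials of 16 s, two
#' pseudorandomized viewing conditions), together with a manifest that
#' fully determines every downstream test quantity: the irregularity
#' parameter, realized gaze duration, injected-artifact epochs, bad
#' channels, and forced exclusions.
#'
#' The association between gaze and neural complexity is controlled by
#' `effect`, the expected pipeline-level regression coefficient of
#' sqrt-entropy on z-scored gaze. Internally, gaze duration is
#' `gaze_base + b * c + noise`; `b` is solved from `effect` using the
#' shipped calibration constant `entropy_per_c` (the empirically measured
#' slope of sqrt band-ROI entropy on `c`; see [pipeline_config()]):
#' `b = effect * sigma / sqrt(V (kappa^2 V - effect^2))` with `V = var(c)`.
#' `effect = 0` gives gaze independent of the EEG.
#'
#' @param n_subjects cohort size (>= 2).
#' @param dir output directory (created if needed).
#' @param seed integer seed; the manifest plus seed fully determine the
#'   files.
#' @param effect expected pipeline-level gaze coefficient (see above), `0`
#'   for a null cohort, or `"max"` for a noiseless-gaze cohort in which the
#'   association is at its attainable ceiling.
#' @param n_artifacts_range per-subject range of contaminated epochs.
#' @param p_bad probability a subject has one bad (interpolatable) channel.
#' @param n_exclude number of subjects forced below 10 clean epochs per
#'   condition (rejected-epoch overload) and hence excluded downstream.
#' @param gaze_noise_sd gaze noise SD in seconds.
#' @param config a [pipeline_config()] (for the calibration constant and
#'   acquisition parameters).
#' @return the manifest: a list with per-subject entries (`id`, `c`,
#'   `gaze_duration`, `conditions`, `artifact_epochs`, `bad_channel`,
#'   `force_excluded`, file paths) and cohort-level settings. Also written
#'   as `manifest.json` when jsonlite is available.
#' @export
generate_cohort <- function(n_subjects, dir, seed, effect = 0,
                            n_artifacts_range = c(2, 10), p_bad = 0.2,
                            n_exclude = 0, gaze_noise_sd = 6,
                            config = pipeline_config()) {
  stopifnot(n_subjects >= 2)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  montage <- default_montage()

  c_lo <- 0.15; c_hi <- 0.9
  cs <- stats::runif(n_subjects, c_lo, c_hi)
  V <- (c_hi - c_lo)^2 / 12
  kappa <- config$entropy_per_c
  if (identical(effect, "max")) {
    # noiseless gaze: the gaze metric becomes an affine function of c and
    # the pipeline-level coefficient sits at its ceiling, kappa * sd(c)
    gaze_noise_sd <- 0
    b <- 40
  } else if (effect == 0) {
    b <- 0
  } else {
    if (abs(effect) >= abs(kappa) * sqrt(V)) {
      stop(sprintf("effect %.3g unattainable; |effect| must be below %.3g",
                   effect, abs(kappa) * sqrt(V)))
    }
    b <- effect * gaze_noise_sd / sqrt(V * (kappa^2 * V - effect^2))
  }

  excl <- if (n_exclude > 0) sample(n_subjects, n_exclude) else integer()
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%03d", i)
    force_excluded <- i %in% excl
    if (force_excluded) {
      # contaminate so many epochs of one condition that < 10 survive
      n_art <- 120
    } else {
      n_art <- sample(seq(n_artifacts_range[1], n_artifacts_range[2]), 1)
    }
    bad_channel <- if (stats::runif(1) < p_bad) {
      sample(setdiff(montage$channels, unlist(montage$roi_map[1:4])), 1)
    } else NULL

    # conditions are drawn inside simulate_subject_eeg; pick artifact
    # epochs afterwards so condition labels are known
    sub <- simulate_subject_eeg(
      cs[i], montage = montage, rate = config$acq_rate,
      n_trials = config$n_trials, trial_len = config$trial_len,
      noise_rms = config$noise_rms,
      artifact_epochs = NULL, bad_channel = bad_channel
    )
    grid <- expand.grid(second = seq_len(config$trial_len),
                        trial = seq_len(config$n_trials))
    grid$condition <- sub$conditions[grid$trial]
    if (force_excluded) {
      pool <- which(grid$condition == "joint")
      pick <- sample(pool, min(n_art, length(pool)))
    } else {
      pick <- sample(nrow(grid), n_art)
    }
    art <- grid[sort(pick), c("trial", "second")]
    sub2 <- .inject_artifacts(sub$recording, art, config)
    stem <- file.path(dir, id)
    write_brainvision(sub2, stem)

    gz_target <- max(5, 10 + b * cs[i] + stats::rnorm(1, sd = gaze_noise_sd))
    gz <- simulate_gaze_log(gz_target)
    gaze_path <- file.path(dir, paste0(id, "_gaze.csv"))
    utils::write.csv(cbind(dyad_id = id, coder_id = "C1", gz$log),
                     gaze_path, row.names = FALSE)

    subjects[[i]] <- list(
      id = id, c = cs[i], gaze_duration = gz$alternating_duration,
      conditions = sub$conditions,
      artifact_epochs = art, n_artifacts = nrow(art),
      artifact_by_condition = table(grid$condition[sort(pick)]),
      bad_channel = bad_channel, bad_epochs = sub$bad_epochs,
      force_excluded = force_excluded,
      eeg_stem = stem, gaze_file = gaze_path
    )
  }
  manifest <- list(seed = seed, effect = effect, gaze_slope_b = b,
                   n_subjects = n_subjects, subjects = subjects)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    slim <- lapply(subjects, function(s) {
      s$artifact_epochs <- as.list(s$artifact_epochs)
      s$artifact_by_condition <- as.list(s$artifact_by_condition)
      s
    })
    jsonlite::write_json(list(seed = seed, effect = effect,
                              gaze_slope_b = b, subjects = slim),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  manifest
}

# add ground-truth bursts to an already simulated recording
.inject_artifacts <- function(rec, artifact_epochs, config,
                              n_burst_channels = 3, burst_amp = 300) {
  if (!nrow(artifact_epochs)) return(rec)
  rate <- rec$rate
  for (k in seq_len(nrow(artifact_epochs))) {
    onset <- rec$events$sample[rec$events$trial == artifact_epochs$trial[k]]
    a <- onset + (artifact_epochs$second[k] - 1L) * rate +
      sample(0:7, 1) * round(0.1 * rate)
    b <- a + round(0.2 * rate) - 1L
    tb <- (seq(a, b) - a) / rate
    burst <- burst_amp * sin(2 * pi * 25 * tb)
    for (ch in sample(nrow(rec$data), n_burst_channels)) {
      rec$data[ch, a:b] <- rec$data[ch, a:b] + burst
    }
  }
  rec
}

#' Simulate a secondary coder for inter-rater reliability
#'
#' Perturbs every look boundary of the primary coder's log by Gaussian
#' jitter, clipping so each look stays valid (onset < offset) and looks
#' stay non-overlapping. `noise_sd = 0` reproduces the log exactly;
#' increasing jitter lowers the expected ICC of the derived duration
#' metric.
#'
#' @param log a gaze event log (`onset`, `offset`, `target`).
#' @param noise_sd boundary jitter SD in seconds.
#' @return the second coder's log.
#' @export
generate_coder_pair <- function(log, noise_sd) {
  if (noise_sd == 0 || !nrow(log)) return(log)
  on <- log$onset + stats::rnorm(nrow(log), sd = noise_sd)
  off <- log$offset + stats::rnorm(nrow(log), sd = noise_sd)
  bad <- off <= on
  if (any(bad)) {  # collapse to a short look around the midpoint
    mid <- (on[bad] + off[bad]) / 2
    on[bad] <- mid - 0.05
    off[bad] <- mid + 0.05
  }
  ord <- order(on)
  on <- on[ord]; off <- off[ord]
  for (i in seq_along(on)[-1]) {
    if (on[i] < off[i - 1]) on[i] <- off[i - 1] + 1e-3
    if (off[i] <= on[i]) off[i] <- on[i] + 0.05
  }
  data.frame(onset = pmax(on, 0), offset = off, target = log$target[ord])
}
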