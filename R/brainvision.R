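#' Read a BrainVision recording
#'
#' Parses a BrainVision header (`.vhdr`), its marker file (`.vmrk`) and the
#' binary data file into a [new_recording()] object. Only the multiplexed
#' IEEE float32 binary layout is supported; other layouts raise a format
#' error rather than being silently misread. Amplitudes are returned in
#' microvolts (the per-channel resolution from the header is applied).
#'
#' Stimulus markers with descriptions of the form `<condition>_<trial>`
#' (e.g. `joint_03`) become rows of the recording's `events` table.
#'
#' @param header_path path to the `.vhdr` file.
#' @return a `recording`.
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) {
    stop("header file not found: ", header_path)
  }
  hdr <- .parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  chinf <- hdr[["Channel Infos"]]
  if (is.null(ci) || is.null(chinf)) stop("malformed .vhdr: missing sections")

  if (!identical(toupper(ci[["DataFormat"]]), "BINARY")) {
    stop("unsupported data format: ", ci[["DataFormat"]])
  }
  if (!identical(toupper(ci[["DataOrientation"]]), "MULTIPLEXED")) {
    stop("unsupported data orientation: ", ci[["DataOrientation"]])
  }
  if (!identical(toupper(bi[["BinaryFormat"]]), "IEEE_FLOAT_32")) {
    stop("unsupported binary format: ", bi[["BinaryFormat"]])
  }
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(ci[["SamplingInterval"]])  # interval in microseconds

  dir <- dirname(header_path)
  data_file <- file.path(dir, ci[["DataFile"]])
  marker_file <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(data_file)) stop("missing companion data file: ", data_file)
  if (!file.exists(marker_file)) {
    stop("missing companion marker file: ", marker_file)
  }

  # Channel Infos lines: Ch<i>=<name>,<ref>,<resolution>,<unit>
  keys <- names(chinf)
  ord <- order(as.integer(sub("^Ch", "", keys)))
  parts <- strsplit(unlist(chinf[ord]), ",", fixed = TRUE)
  channel_names <- vapply(parts, `[`, "", 1L)
  res <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, 0)

  sz <- file.info(data_file)$size
  n_total <- sz / 4
  if (n_total != floor(n_total) || (n_total %% n_ch) != 0) {
    stop("data file size inconsistent with ", n_ch, " float32 channels")
  }
  raw <- readBin(data_file, what = "numeric", n = n_total, size = 4,
                 endian = "little")
  data <- matrix(raw, nrow = n_ch)  # multiplexed: channels vary fastest
  if (any(res != 1)) data <- data * res
  events <- .parse_vmrk(readLines(marker_file, warn = FALSE))
  new_recording(data, rate, channel_names,
                reference = if (is.null(ci[["Reference"]])) "FCz" else ci[["Reference"]],
                events = events)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` (multiplexed IEEE
#' float32, resolution 1 microvolt) readable by [read_brainvision()].
#'
#' @param rec a `recording`.
#' @param stem output path without extension.
#' @return invisibly, the three file paths.
#' @export
write_brainvision <- function(rec, stem) {
  stopifnot(inherits(rec, "recording"))
  base <- basename(stem)
  paths <- paste0(stem, c(".vhdr", ".vmrk", ".eeg"))
  dir <- dirname(stem)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
    paste0("Reference=", rec$reference),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(rec$channel_names),
            rec$channel_names)
  )
  writeLines(hdr, paths[1], useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    if (nrow(rec$events)) {
      sprintf("Mk%d=Stimulus,%s_%02d,%d,1,0",
              seq_len(nrow(rec$events)) + 1L,
              rec$events$condition, rec$events$trial, rec$events$sample)
    }
  )
  writeLines(mk, paths[2], useBytes = TRUE)

  con <- file(paths[3], "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(paths)
}

# Minimal INI parser for BrainVision header/marker files.
.parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (!is.null(section) && grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      out[[section]][[key]] <- trimws(substr(ln, eq + 1, nchar(ln)))
    }
  }
  out
}

.parse_vmrk <- function(lines) {
  ini <- .parse_ini(lines)
  mi <- ini[["Marker Infos"]]
  if (is.null(mi)) return(empty_events())
  vals <- unlist(mi[order(as.integer(sub("^Mk", "", names(mi))))])
  parts <- strsplit(vals, ",", fixed = TRUE)
  stim <- parts[vapply(parts, `[`, "", 1L) == "Stimulus"]
  if (!length(stim)) return(empty_events())
  desc <- vapply(stim, `[`, "", 2L)
  data.frame(
    sample = as.integer(vapply(stim, `[`, "", 3L)),
    condition = sub("_[0-9]+$", "", desc),
    trial = as.integer(sub("^.*_", "", desc))
  )
}
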