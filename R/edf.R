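#' Write a recording to EDF with a JSON sidecar
#'
#' Writes the standard polysomnography container: European Data Format,
#' 16-bit samples, one 1-s data record per second, one signal per channel,
#' with per-channel physical scaling derived from the signal range. EDF
#' channel labels are too constrained to carry the full role map, so a
#' sidecar JSON (`<path>.json`) records channel roles, lights-on window,
#' sample rate and any animal id/genotype; [read_recording()] uses it when
#' present and falls back to parsing the labels.
#'
#' @param recording A `psg_recording`.
#' @param path Output EDF path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signals
  fs <- recording$sample_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sample rate", call. = FALSE)
  ns <- ncol(sig)
  n_rec <- floor(nrow(sig) / fs)
  sig <- sig[seq_len(n_rec * fs), , drop = FALSE]

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = -w, flag = " ")
  }
  num8 <- function(x) pad(formatC(signif(x, 5), format = "g"), 8)

  # pad the range so the 5-significant-digit header value never rounds
  # below the true maximum (which would overflow int16)
  phys_max <- pmax(apply(abs(sig), 2, max), 1e-6) * 1.001
  # re-read the 8-char header representation so scaling is self-consistent
  phys_max <- as.numeric(num8(phys_max))
  phys_min <- -phys_max
  dig_max <- 32767L; dig_min <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  header_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad("0", 8), pad(recording$id %||% "X", 80),
    pad("Startdate 01.JAN.2000", 80), pad("01.01.00", 8), pad("00.00.00", 8),
    pad(header_bytes, 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4),
    paste(pad(colnames(sig), 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(pad(ifelse(recording$channel_info$type == "eeg", "uV", "g"), 8),
          collapse = ""),
    paste(num8(phys_min), collapse = ""),
    paste(num8(phys_max), collapse = ""),
    paste(rep(pad(dig_min, 8), ns), collapse = ""),
    paste(rep(pad(dig_max, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- sapply(seq_len(ns), function(j) {
    d <- as.integer(round((sig[, j] - phys_min[j]) / scale[j])) + dig_min
    as.integer(pmax(pmin(d, dig_max), dig_min))
  })
  # interleave: per record, all samples of channel 1, then channel 2, ...
  dim(dig) <- NULL
  idx <- as.vector(aperm(array(seq_len(n_rec * fs * ns),
                               dim = c(fs, n_rec, ns)), c(1, 3, 2)))
  writeBin(dig[idx], con, size = 2, endian = "little")

  meta <- list(
    sample_rate = fs, duration_s = n_rec, lights_on = recording$lights_on,
    id = recording$id, genotype = recording$genotype,
    channel_info = recording$channel_info
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the EDF header and 16-bit data records back into a
#' `psg_recording`. Channel roles come from the sidecar JSON written by
#' [write_edf()] when present, otherwise from the channel labels
#' (substrings "frontal"/"parietal" mark EEG sites, "ACC" the
#' accelerometer axes); unparseable labels are an error listing them.
#'
#' @param path EDF file path.
#' @return A `psg_recording`.
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                       # transducer
  for (i in seq_len(ns)) rd(8)                        # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  expected <- header_bytes + 2 * n_rec * sum(spr)
  if (file.size(path) < expected) {
    stop(sprintf("truncated EDF: %d bytes, expected %d", file.size(path),
                 expected), call. = FALSE)
  }
  if (length(unique(spr)) != 1) {
    stop("channels with differing sample rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  arr <- array(raw, dim = c(spr[1], ns, n_rec))
  sig <- sapply(seq_len(ns), function(j) {
    as.vector(arr[, j, ]) * (phys_max[j] - phys_min[j]) /
      (dig_max[j] - dig_min[j]) +
      phys_min[j] - dig_min[j] * (phys_max[j] - phys_min[j]) /
      (dig_max[j] - dig_min[j])
  })
  colnames(sig) <- labels

  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ci <- tibble::as_tibble(meta$channel_info)
    lights_on <- meta$lights_on
    id <- meta$id; genotype <- meta$genotype
  } else {
    role <- dplyr::case_when(
      grepl("frontal", labels, ignore.case = TRUE) ~ "frontal",
      grepl("parietal", labels, ignore.case = TRUE) ~ "parietal",
      grepl("ACC", labels, ignore.case = TRUE) ~ "accel",
      TRUE ~ NA_character_
    )
    if (anyNA(role)) {
      stop("cannot parse channel roles from labels: ",
           paste(labels[is.na(role)], collapse = ", "), call. = FALSE)
    }
    ci <- tibble::tibble(
      channel = labels,
      type = ifelse(role == "accel", "accel", "eeg"),
      role = role, side = NA_character_
    )
    lights_on <- c(0, n_rec * rec_dur)
    id <- NULL; genotype <- NULL
  }
  if (!any(ci$type == "eeg")) stop("no EEG channel in file", call. = FALSE)
  structure(list(signals = sig, channel_info = ci, sample_rate = fs,
                 duration_s = n_rec * rec_dur, lights_on = lights_on,
                 id = id, genotype = genotype),
            class = "psg_recording")
}
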