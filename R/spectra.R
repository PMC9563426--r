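#' Per-second Welch power spectra
#'
#' Cuts each EEG channel into contiguous 1-s epochs and estimates a power
#' spectral density per epoch by Welch's method: `segment_s`-long segments
#' with 50% overlap and a Hann taper, averaged within the epoch. The
#' default 0.5-s segment gives a 2 Hz frequency resolution, so the first
#' usable bin of the delta band (0.5-4 Hz) is the 2 Hz bin; a 1-s segment
#' (one periodogram per epoch) gives 1 Hz resolution and is used by the
#' pipeline for theta-peak estimation.
#'
#' @param recording A `psg_recording`.
#' @param epoch_s Epoch length in seconds (default 1). A trailing partial
#'   epoch is dropped.
#' @param segment_s Welch segment length in seconds (default 0.5).
#' @return A list of class `epoch_spectra`: `times` (epoch start s),
#'   `freqs` (Hz), `power` (epoch x channel x frequency array, EEG
#'   channels only), `channel_info`, `sample_rate`.
#' @export
compute_epoch_spectra <- function(recording, epoch_s = 1, segment_s = 0.5) {
  fs <- recording$sample_rate
  if (fs < 360) {
    affected <- default_bands()$band[default_bands()$hi_hz > fs / 2]
    stop(sprintf(
      "sample rate %.0f Hz cannot resolve band(s) %s (need >= 360 Hz)",
      fs, paste(affected, collapse = ", ")), call. = FALSE)
  }
  eeg <- which(recording$channel_info$type == "eeg")
  n_ep <- floor(nrow(recording$signals) / (fs * epoch_s))
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)

  nper <- as.integer(segment_s * fs)
  step <- nper %/% 2L
  ep_len <- as.integer(epoch_s * fs)
  seg_starts <- seq(1L, ep_len - nper + 1L, by = step)
  n_seg <- length(seg_starts)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  u <- fs * sum(win^2)                       # Welch density normalization
  n_freq <- nper %/% 2L + 1L
  freqs <- (seq_len(n_freq) - 1) * fs / nper

  power <- array(0, dim = c(n_ep, length(eeg), n_freq))
  # all segments of all epochs of one channel in a single matrix FFT
  seg_idx <- as.vector(outer(seq_len(nper) - 1L,
                             as.vector(outer(seg_starts,
                                             (seq_len(n_ep) - 1L) * ep_len,
                                             `+`)), `+`))
  for (jj in seq_along(eeg)) {
    segs <- matrix(recording$signals[seg_idx, eeg[jj]], nrow = nper)
    segs <- (segs - rep(colMeans(segs), each = nper)) * win
    ft <- stats::mvfft(segs)[seq_len(n_freq), , drop = FALSE]
    p <- (Mod(ft)^2) / u
    p[-c(1, n_freq), ] <- 2 * p[-c(1, n_freq), ]   # one-sided
    ep_grp <- rep(seq_len(n_ep), each = n_seg)
    pm <- t(rowsum(t(p), ep_grp)) / n_seg
    power[, jj, ] <- t(pm)
  }
  structure(list(times = (seq_len(n_ep) - 1) * epoch_s, freqs = freqs,
                 power = power,
                 channel_info = recording$channel_info[eeg, ],
                 sample_rate = fs, epoch_s = epoch_s),
            class = "epoch_spectra")
}

#' Integrate epoch spectra into band powers
#'
#' Per epoch, channel and band, the band power is the mean PSD over the
#' frequency bins whose centre lies inside the band's inclusive bounds.
#' Band bounds are checked against the frequency grid; a band that captures
#' no bin is an error naming the band and the grid resolution.
#'
#' @param spectra An `epoch_spectra`.
#' @param bands Band table from [default_bands()].
#' @return A tidy tibble of class `band_power` with columns `epoch_s`,
#'   `channel`, `role`, `band`, `raw`.
#' @export
integrate_bands <- function(spectra, bands = default_bands()) {
  if (any(bands$hi_hz > max(spectra$freqs))) {
    stop("band limits exceed the frequency grid", call. = FALSE)
  }
  res <- spectra$freqs[2] - spectra$freqs[1]
  band_bins <- lapply(seq_len(nrow(bands)), function(i) {
    which(spectra$freqs >= bands$lo_hz[i] & spectra$freqs <= bands$hi_hz[i])
  })
  empty <- lengths(band_bins) == 0
  if (any(empty)) {
    stop(sprintf("band(s) %s contain no frequency bin at %.2f Hz resolution",
                 paste(bands$band[empty], collapse = ", "), res),
         call. = FALSE)
  }
  n_ep <- dim(spectra$power)[1]
  ci <- spectra$channel_info
  out <- purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    bp <- rowMeans(spectra$power[, , band_bins[[i]], drop = FALSE], dims = 2)
    tibble::tibble(
      epoch_s = rep(spectra$times, times = nrow(ci)),
      channel = rep(ci$channel, each = n_ep),
      role = rep(ci$role, each = n_ep),
      band = bands$band[i],
      raw = as.vector(bp)
    )
  })
  out <- dplyr::arrange(out, .data$epoch_s, .data$channel)
  out$band <- factor(out$band, levels = bands$band)
  class(out) <- c("band_power", class(out))
  attr(out, "bands") <- bands
  out
}

#' Flag extreme-outlier epochs by the k x IQR rule
#'
#' For every (channel, band), the lower and upper quartiles Q1/Q3 are taken
#' over all epochs of the recording (linear-interpolation quantiles,
#' `stats::quantile` type 7). An epoch is flagged for a channel when any of
#' that channel's band values that second lies strictly above
#' Q3 + k x IQR or strictly below Q1 - k x IQR; flagging is per channel
#' independently. The default k = 15 removes only extreme artifacts.
#'
#' @param table A `band_power` tibble (raw powers).
#' @param k Positive IQR multiplier.
#' @return The same tibble with a logical `outlier` column.
#' @export
flag_outliers <- function(table, k = 15) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (dplyr::n_distinct(table$epoch_s) < 4) {
    stop("need at least 4 epochs per channel to form quartiles", call. = FALSE)
  }
  out <- table |>
    dplyr::group_by(.data$channel, .data$band) |>
    dplyr::mutate(
      .q1 = stats::quantile(.data$raw, 0.25, type = 7, names = FALSE),
      .q3 = stats::quantile(.data$raw, 0.75, type = 7, names = FALSE),
      .iqr = .data$.q3 - .data$.q1,
      .exceed = .data$raw > .data$.q3 + k * .data$.iqr |
        .data$raw < .data$.q1 - k * .data$.iqr
    ) |>
    dplyr::ungroup() |>
    # an epoch is an outlier for a channel if ANY band value exceeds a fence
    dplyr::group_by(.data$channel, .data$epoch_s) |>
    dplyr::mutate(outlier = any(.data$.exceed)) |>
    dplyr::ungroup() |>
    dplyr::select(-".q1", -".q3", -".iqr", -".exceed")
  class(out) <- c("band_power", class(out))
  attr(out, "bands") <- attr(table, "bands")
  out
}

#' Median-normalize band powers
#'
#' Divides each raw band power by the median of the unflagged raw values of
#' that (channel, band) over the whole lights-on recording, so the median
#' of unflagged normalized values is exactly 1. Flagged epochs receive
#' normalized values too but stay excluded from all downstream summaries.
#'
#' @param table A `band_power` tibble with an `outlier` column (see
#'   [flag_outliers()]).
#' @return The same tibble with a `normalized` column.
#' @export
normalize_power <- function(table) {
  if (!"outlier" %in% names(table)) {
    stop("run flag_outliers() before normalize_power()", call. = FALSE)
  }
  out <- table |>
    dplyr::group_by(.data$channel, .data$band) |>
    dplyr::mutate(.med = stats::median(.data$raw[!.data$outlier])) |>
    dplyr::ungroup()
  bad <- out |>
    dplyr::filter(is.na(.data$.med) | .data$.med <= 0) |>
    dplyr::distinct(.data$channel, .data$band)
  if (nrow(bad)) {
    stop("non-positive or undefined median for: ",
         paste(bad$channel, bad$band, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(normalized = .data$raw / .data$.med) |>
    dplyr::select(-".med")
  class(out) <- c("band_power", class(out))
  attr(out, "bands") <- attr(table, "bands")
  out
}

#' Per-state mean normalized band power
#'
#' Averages normalized band power over the unflagged epochs of each
#' vigilance state, per channel, then averages the left/right channels of
#' the same electrode site (laterality is not analyzed). States with no
#' unflagged epochs yield `NA`, never zero.
#'
#' @param table A normalized `band_power` tibble.
#' @param hypnogram A `hypnogram` on the same 1-s epoch grid.
#' @return Tibble `state`, `role`, `band`, `mean_norm_power`.
#' @export
state_band_summary <- function(table, hypnogram) {
  n_tab <- dplyr::n_distinct(table$epoch_s)
  if (n_tab != nrow(hypnogram)) {
    stop(sprintf("epoch grids differ: %d band-power epochs vs %d hypnogram epochs",
                 n_tab, nrow(hypnogram)), call. = FALSE)
  }
  grid <- expand.grid(state = state_levels(),
                      role = unique(table$role),
                      band = levels(table$band),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per_channel <- table |>
    dplyr::inner_join(hypnogram, by = c(epoch_s = "epoch_start_s")) |>
    dplyr::filter(!.data$outlier) |>
    dplyr::group_by(.data$state, .data$role, .data$channel, .data$band) |>
    dplyr::summarise(m = mean(.data$normalized), .groups = "drop")
  out <- per_channel |>
    dplyr::group_by(.data$state, .data$role, .data$band) |>
    dplyr::summarise(mean_norm_power = mean(.data$m), .groups = "drop") |>
    dplyr::mutate(state = as.character(.data$state),
                  band = as.character(.data$band)) |>
    dplyr::right_join(grid, by = c("state", "role", "band")) |>
    dplyr::arrange(factor(.data$state, state_levels()), .data$role,
                   factor(.data$band, band_levels()))
  tibble::as_tibble(out)
}

#' Peak theta frequency of the state-averaged spectrum
#'
#' Averages the PSD over the epochs of the requested state and the
#' channels of each site, restricts to the theta range and returns the
#' frequency of the maximum with parabolic interpolation around the argmax
#' bin (sub-bin resolution, clamped to half a bin). Ties go to the lower
#' frequency. With no epochs of the state the result is `NA`.
#'
#' By default the raw state-averaged PSD is scanned: dividing by the
#' per-frequency recording median (the display normalization,
#' `normalize = "median"`) imprints the median's own theta structure --
#' dominated by wake theta -- onto the state spectrum and can displace the
#' peak, so the raw spectrum gives the more faithful peak location.
#'
#' @param spectra An `epoch_spectra` (1 Hz resolution recommended).
#' @param hypnogram Aligned `hypnogram`.
#' @param state State whose spectrum is scanned (default "REM").
#' @param range_hz Frequency window searched (default theta, 5-10 Hz).
#' @param normalize `"none"` (raw PSD, default) or `"median"` (each
#'   frequency bin divided by its median over all epochs first).
#' @return Tibble `role`, `peak_hz`.
#' @export
theta_peak_frequency <- function(spectra, hypnogram, state = "REM",
                                 range_hz = c(5, 10),
                                 normalize = c("none", "median")) {
  normalize <- match.arg(normalize)
  n_ep <- dim(spectra$power)[1]
  if (n_ep != nrow(hypnogram)) {
    stop(sprintf("epoch grids differ: %d spectra epochs vs %d hypnogram epochs",
                 n_ep, nrow(hypnogram)), call. = FALSE)
  }
  in_state <- which(hypnogram$state == state)
  roles <- unique(spectra$channel_info$role)
  if (!length(in_state)) {
    return(tibble::tibble(role = roles, peak_hz = NA_real_))
  }
  freqs <- spectra$freqs
  out <- purrr::map_dfr(roles, function(r) {
    ch <- which(spectra$channel_info$role == r)
    spec <- rep(0, length(freqs))
    for (j in ch) {
      p <- spectra$power[, j, ]                       # epochs x freq
      if (normalize == "median") {
        med <- apply(p, 2, stats::median)
        med[med <= 0] <- NA
        p <- sweep(p, 2, med, `/`)
      }
      spec <- spec + colMeans(p[in_state, , drop = FALSE]) / length(ch)
    }
    win <- which(freqs >= range_hz[1] & freqs <= range_hz[2])
    i0 <- win[which.max(spec[win])]
    peak <- freqs[i0]
    if (i0 > 1 && i0 < length(freqs) &&
        all(is.finite(spec[(i0 - 1):(i0 + 1)]))) {
      y1 <- spec[i0 - 1]; y2 <- spec[i0]; y3 <- spec[i0 + 1]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) {
        delta <- 0.5 * (y1 - y3) / denom
        delta <- max(-0.5, min(0.5, delta))
        peak <- freqs[i0] + delta * (freqs[2] - freqs[1])
      }
    }
    tibble::tibble(role = r, peak_hz = peak)
  })
  out
}
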