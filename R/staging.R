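#' Per-epoch staging features
#'
#' Computes the three features used to segregate vigilance states, one row
#' per 1-s epoch: slow-wave activity (`swa`, mean median-normalized
#' delta-band power over the frontal channels, the canonical NREM marker),
#' the theta ratio (`theta_ratio`, theta / (delta + theta) power from the
#' parietal channels, bounded in 0-1; parietal sites carry volume-conducted
#' hippocampal theta in mice), and `movement` (within-epoch variance of
#' each accelerometer axis, summed over the three axes). All three are
#' smoothed with a centred 5-epoch running median.
#'
#' @param spectra An `epoch_spectra` of the recording.
#' @param recording The `psg_recording` the spectra came from (provides the
#'   accelerometer channels).
#' @return Tibble `epoch_s`, `swa`, `theta_ratio`, `movement`.
#' @export
extract_features <- function(spectra, recording) {
  acc <- which(recording$channel_info$type == "accel")
  if (!length(acc)) {
    stop("recording has no accelerometer channels; movement is required to separate wake",
         call. = FALSE)
  }
  n_ep <- dim(spectra$power)[1]
  fs <- recording$sample_rate
  bands <- default_bands()
  dl <- bands[bands$band == "delta", ]
  th <- bands[bands$band == "theta", ]
  d_bins <- which(spectra$freqs >= dl$lo_hz & spectra$freqs <= dl$hi_hz)
  t_bins <- which(spectra$freqs >= th$lo_hz & spectra$freqs <= th$hi_hz)

  frontal <- which(spectra$channel_info$role == "frontal")
  parietal <- which(spectra$channel_info$role == "parietal")
  delta_p <- rowMeans(spectra$power[, , d_bins, drop = FALSE], dims = 2)
  theta_p <- rowMeans(spectra$power[, , t_bins, drop = FALSE], dims = 2)

  swa <- rowMeans(sapply(frontal, function(j) {
    delta_p[, j] / stats::median(delta_p[, j])
  }))
  theta_ratio <- rowMeans(sapply(parietal, function(j) {
    theta_p[, j] / (theta_p[, j] + delta_p[, j])
  }))
  ep_len <- as.integer(fs * spectra$epoch_s)
  idx <- seq_len(n_ep * ep_len)
  movement <- rowSums(sapply(acc, function(j) {
    m <- matrix(recording$signals[idx, j], nrow = ep_len)
    colMeans(m^2) - colMeans(m)^2
  }))

  smooth5 <- function(x) as.numeric(stats::runmed(x, 5, endrule = "median"))
  tibble::tibble(
    epoch_s = spectra$times,
    swa = smooth5(swa),
    theta_ratio = smooth5(theta_ratio),
    movement = smooth5(movement)
  )
}

#' Otsu threshold of a 1-D sample
#'
#' Histogram-based two-class split maximizing the between-class variance;
#' the deterministic workhorse of the staging cascade. Returns `NA` for a
#' (near-)constant sample, which callers treat as "no epoch above
#' threshold".
#'
#' @param x Numeric vector.
#' @param nbins Number of histogram bins.
#' @return The threshold value, or `NA` if `x` is degenerate.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  rng <- range(x)
  if (diff(rng) < 1e-12) return(NA_real_)
  brk <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  brk[k + 1]
}

#' Score vigilance states from staging features
#'
#' Deterministic threshold cascade: (1) epochs whose log movement exceeds
#' its Otsu threshold are wake; (2) among the still (low-movement) epochs,
#' log slow-wave activity above its Otsu threshold marks NREM; (3) the
#' remaining still, low-SWA epochs are REM when their theta ratio exceeds
#' its Otsu threshold, otherwise quiet wake. Runs shorter than `min_bout_s`
#' are then absorbed into the longer flanking state (tie: the preceding
#' state; the first and last run of the recording are never absorbed), and
#' REM bouts not preceded by NREM within 10 s are relabelled wake
#' (wake-to-REM transitions do not occur in healthy rodents). All
#' thresholds are attached to the result as the `thresholds` attribute for
#' audit. A degenerate (near-constant) feature disables its split with a
#' warning rather than failing, so constant input yields a single-state
#' hypnogram.
#'
#' An Otsu split is only accepted when the two classes it produces are
#' genuinely separated (difference of class medians at least `min_sep`,
#' about a 4.5-fold ratio on the log features); otherwise the feature is
#' treated as unimodal -- the population contains only one of the two
#' states -- and a physiological fallback assigns it whole: still epochs
#' whose slow-wave activity is unimodal are all NREM when their pooled
#' theta ratio is delta-dominant (median < 0.5), and a unimodal theta
#' ratio sends the remaining epochs to REM only when theta dominates.
#' This prevents the cascade from slicing noise in recordings that lack a
#' state (e.g. no REM in a short recording).
#'
#' @param features Tibble from [extract_features()].
#' @param min_bout_s Minimum bout duration enforced by smoothing (s).
#' @param forbid_wake_rem Apply the rodent convention that REM must be
#'   entered from NREM (relabelling offending REM bouts as wake); disable
#'   only for diagnostics.
#' @return A `hypnogram` (provenance "automatic").
#' @export
score_states <- function(features, min_bout_s = 3, forbid_wake_rem = TRUE) {
  if (nrow(features) < 60) stop("need at least 60 epochs to score", call. = FALSE)
  eps <- 1e-12
  log_mov <- log(features$movement + eps)
  log_swa <- log(features$swa + eps)
  theta <- features$theta_ratio
  theta[!is.finite(theta)] <- 0

  # (1) movement: high -> WAKE
  mov <- otsu_split(log_mov, min_sep = 1.5)
  if (!mov$ok) {
    warning("movement is unimodal; treating all epochs as still")
  }
  still <- if (mov$ok) log_mov <= mov$thr else rep(TRUE, length(log_mov))
  lab <- rep("WAKE", nrow(features))

  # (2) among still epochs, high slow-wave activity -> NREM
  swa <- otsu_split(log_swa[still], min_sep = 1.5)
  if (swa$ok) {
    nrem <- still & log_swa > swa$thr
  } else if (any(still) && stats::median(theta[still]) < 0.5) {
    warning("slow-wave activity is unimodal among still epochs; labelling them all NREM")
    nrem <- still
  } else {
    nrem <- rep(FALSE, length(still))
  }
  lab[nrem] <- "NREM"

  # (3) still, low-SWA epochs: theta-dominant -> REM, else quiet wake
  rest <- still & !nrem
  th <- otsu_split(theta[rest], min_sep = 0.2)
  if (th$ok) {
    lab[rest & theta > th$thr] <- "REM"
  } else if (any(rest) && stats::median(theta[rest]) > 0.5) {
    lab[rest] <- "REM"
  }

  lab <- enforce_min_bout(lab, min_bout_s)
  if (forbid_wake_rem) lab <- forbid_wake_to_rem(lab, lookback_s = 10)

  h <- new_hypnogram(lab, start_s = features$epoch_s[1], provenance = "automatic")
  attr(h, "thresholds") <- c(log_movement = mov$thr, log_swa = swa$thr,
                             theta_ratio = th$thr)
  attr(h, "splits_accepted") <- c(movement = mov$ok, swa = swa$ok,
                                  theta = th$ok)
  h
}

# Otsu threshold plus an acceptance check: the split is kept only when the
# medians of the two classes differ by at least min_sep.
otsu_split <- function(x, min_sep) {
  thr <- otsu_threshold(x)
  if (is.na(thr)) return(list(ok = FALSE, thr = NA_real_))
  lo <- x[x <= thr]; hi <- x[x > thr]
  if (!length(lo) || !length(hi)) return(list(ok = FALSE, thr = thr))
  list(ok = (stats::median(hi) - stats::median(lo)) >= min_sep, thr = thr)
}

# Absorb interior runs shorter than min_bout_s into the longer flanking
# state (tie: preceding). First and last runs are left untouched.
enforce_min_bout <- function(lab, min_bout_s) {
  if (min_bout_s <= 1) return(lab)
  repeat {
    r <- rle(lab)
    k <- length(r$lengths)
    if (k <= 2) return(lab)
    short <- setdiff(which(r$lengths < min_bout_s), c(1, k))
    if (!length(short)) return(lab)
    i <- short[which.min(r$lengths[short])]
    winner <- if (r$lengths[i + 1] > r$lengths[i - 1]) {
      r$values[i + 1]
    } else {
      r$values[i - 1]
    }
    r$values[i] <- winner
    lab <- inverse.rle(r)
  }
}

# Relabel REM runs not preceded by NREM within lookback_s seconds as wake.
forbid_wake_to_rem <- function(lab, lookback_s = 10) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values == "REM")) {
    win <- max(1, starts[i] - lookback_s):(starts[i] - 1)
    if (starts[i] == 1 || !any(lab[win] == "NREM")) r$values[i] <- "WAKE"
  }
  inverse.rle(r)
}
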