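#' Synthesize EEG and accelerometer signals for a ground-truth hypnogram
#'
#' Each EEG channel is the sum of a 1/f-shaped background with a broadband
#' noise floor (power ~ 1/f^slope plus a white term) and one band-limited
#' Gaussian component per configured (state, site) peak. Components are
#' Gaussian noise with an order-2 Butterworth band-pass power spectrum,
#' synthesized by Fourier-domain shaping (equivalent in distribution to
#' filtering white noise) and normalized so the configured amplitude is
#' the component's RMS. Each
#' bout's oscillation mixture is synthesized over its own (fade-extended)
#' span and overlap-added with a 0.5-s raised-cosine cross-fade at every
#' state boundary to avoid switching artifacts, and the whole channel is
#' multiplied by a slowly varying log-normal gain (see [sim_config()]).
#' Accelerometer channels are white noise whose standard deviation
#' switches with state.
#'
#' @param truth A `ground_truth` from [sample_hypnogram()].
#' @param config A [sim_config()]; defaults to the effective config stored
#'   in `truth` (genotype effects already applied).
#' @param seed Integer seed for the noise draws.
#' @return A list of class `psg_recording` with elements `signals`
#'   (samples x channels matrix), `channel_info`, `sample_rate`,
#'   `duration_s`, `lights_on`, plus `id`/`genotype` when set by
#'   [simulate_cohort()].
#' @export
synthesize_signals <- function(truth, config = truth$config, seed) {
  cfg <- apply_genotype_effects(config)
  fs <- cfg$sample_rate
  nyq <- fs / 2
  if (any(cfg$components$center_hz + cfg$components$bw_hz / 2 >= nyq)) {
    stop("component frequency above Nyquist", call. = FALSE)
  }
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)

  n <- as.integer(cfg$duration_s * fs)
  bouts <- truth$bouts
  if (sum(bouts$length_s) != cfg$duration_s) {
    stop("hypnogram does not cover the full duration", call. = FALSE)
  }
  ci <- cfg$channel_info
  sig <- matrix(0, nrow = n, ncol = nrow(ci),
                dimnames = list(NULL, ci$channel))

  white_sd <- cfg$background$white %||% 0
  w_bg <- background_weight(two_sided_freqs(n, fs), cfg$background$slope,
                            cfg$background$scale, white_sd)
  half <- as.integer(round(0.25 * fs))        # half of the 0.5-s cross-fade
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = 2 * half)))
  a <- as.integer(bouts$start_s * fs) + 1L    # bout start samples
  b <- a + as.integer(bouts$length_s * fs)    # one past bout end

  for (j in which(ci$type == "eeg")) {
    x <- shaped_noise(n, w_bg)
    comp <- cfg$components[cfg$components$role == ci$role[j] &
                             cfg$components$amp > 0, ]
    # overlap-add one band-limited noise mixture per bout, ramped across
    # the 0.5-s cross-fade window centred on each state boundary
    for (i in seq_len(nrow(bouts))) {
      cs <- comp[comp$state == bouts$state[i], ]
      if (!nrow(cs)) next
      lo <- if (i == 1) a[i] else a[i] - half
      hi <- if (i == nrow(bouts)) b[i] - 1L else b[i] + half - 1L
      len <- hi - lo + 1L
      nn <- stats::nextn(len, c(2, 3, 5))
      y <- shaped_noise(nn, component_weight(two_sided_freqs(nn, fs), cs))[
        seq_len(len)]
      if (i > 1) y[seq_len(2 * half)] <- y[seq_len(2 * half)] * ramp
      if (i < nrow(bouts)) {
        tail_idx <- (len - 2 * half + 1):len
        y[tail_idx] <- y[tail_idx] * rev(ramp)
      }
      x[lo:hi] <- x[lo:hi] + y
    }
    sig[, j] <- x * slow_gain(cfg, n, fs)
  }
  sd_per_sample <- cfg$movement_sd[rep(bouts$state, bouts$length_s * fs)]
  for (j in which(ci$type == "accel")) {
    sig[, j] <- stats::rnorm(n) * sd_per_sample
  }

  structure(list(signals = sig, channel_info = ci, sample_rate = fs,
                 duration_s = cfg$duration_s, lights_on = cfg$lights_on),
            class = "psg_recording")
}

# Slowly varying log-normal amplitude gain, one AR(1) step per second,
# emulating arousal-related power fluctuations of real EEG.
slow_gain <- function(cfg, n, fs) {
  pm <- cfg$power_modulation
  if (is.null(pm) || pm$sd_log <= 0) return(1)
  n_s <- ceiling(n / fs)
  g <- numeric(n_s)
  innov <- stats::rnorm(n_s)
  g[1] <- pm$sd_log * innov[1]
  step_sd <- pm$sd_log * sqrt(1 - pm$ar^2)
  for (t in seq_len(n_s)[-1]) g[t] <- pm$ar * g[t - 1] + step_sd * innov[t]
  rep(exp(g), each = fs)[seq_len(n)]
}

# Two-sided frequency axis of an n-point FFT at sampling rate fs.
two_sided_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

# Gaussian noise with amplitude spectrum w (two-sided, unit variance when
# mean(w^2) == 1): white noise shaped in the Fourier domain.
shaped_noise <- function(n, w) {
  if (all(w == 0)) return(numeric(n))
  z <- stats::fft(stats::rnorm(n))
  Re(stats::fft(z * w, inverse = TRUE)) / n
}

# Amplitude weight of the 1/f^slope background plus a white floor, scaled
# so the shaped noise has sd sqrt(scale^2 + white^2).
background_weight <- function(f2, slope, scale, white) {
  p <- numeric(length(f2))
  if (scale > 0) {
    pk <- c(0, f2[-1]^(-slope))
    p <- p + scale^2 * pk / mean(pk)
  }
  p <- p + white^2
  sqrt(p)
}

# Combined amplitude weight of a set of band-limited components: each is an
# order-2 Butterworth band-pass magnitude response normalized to unit
# variance, scaled by its RMS amplitude; independent Gaussian components
# sum in power.
component_weight <- function(f2, comps) {
  p <- numeric(length(f2))
  for (k in seq_len(nrow(comps))) {
    lo <- max(comps$center_hz[k] - comps$bw_hz[k] / 2, 0.05)
    hi <- comps$center_hz[k] + comps$bw_hz[k] / 2
    f0 <- sqrt(lo * hi)
    bw <- hi - lo
    h2 <- 1 / (1 + ((f2^2 - f0^2) / pmax(f2 * bw, 1e-12))^4)
    p <- p + comps$amp[k]^2 * h2 / mean(h2)
  }
  sqrt(p)
}

#' Simulate a two-genotype cohort
#'
#' Generates `n_wt` wild-type and `n_mut` mutant animals. Per-animal seeds
#' are drawn deterministically from the master seed, so the same
#' (config, seed) always yields a byte-identical cohort; genotype effects
#' are applied to mutant animals only.
#'
#' @param n_wt,n_mut Number of wild-type and mutant animals (the study's
#'   cohort was 9 wild types vs 5 mutants).
#' @param config A [sim_config()] describing the wild-type animal.
#' @param seed Master seed.
#' @param effects [genotype_effects()] applied to mutants; `NULL` for a
#'   null cohort with no genotype differences.
#' @param signals If `FALSE`, only hypnograms are sampled (architecture
#'   studies do not need the raw signals).
#' @return A tibble with columns `animal`, `genotype` ("WT"/"MUT"),
#'   list-columns `truth` and (when `signals`) `recording`.
#' @export
simulate_cohort <- function(n_wt, n_mut, config, seed,
                            effects = genotype_effects(), signals = TRUE) {
  stopifnot(n_wt >= 1 || n_mut >= 1)
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)
  n <- n_wt + n_mut
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * n), ncol = 2)
  genotype <- rep(c("WT", "MUT"), c(n_wt, n_mut))
  animal <- sprintf("%s%02d", genotype, c(seq_len(n_wt), seq_len(n_mut)))

  rows <- purrr::map(seq_len(n), function(i) {
    cfg <- config
    cfg$genotype_effects <- if (genotype[i] == "MUT") effects else NULL
    cfg <- apply_genotype_effects(cfg)
    gt <- sample_hypnogram(cfg, seed = seeds[i, 1])
    rec <- NULL
    if (signals) {
      rec <- synthesize_signals(gt, seed = seeds[i, 2])
      rec$id <- animal[i]
      rec$genotype <- genotype[i]
    }
    list(truth = gt, recording = rec)
  })
  out <- tibble::tibble(
    animal = animal, genotype = genotype,
    truth = purrr::map(rows, "truth")
  )
  if (signals) out$recording <- purrr::map(rows, "recording")
  out
}
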