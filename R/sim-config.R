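#' Simulator configuration
#'
#' Builds the configuration object for the synthetic polysomnography
#' generator. The defaults emulate a 12-h lights-on (ZT0--12) recording of a
#' wild-type mouse: a three-state (wake/NREM/REM) semi-Markov vigilance
#' process with log-normal bout durations, state- and site-specific
#' oscillatory components riding on 1/f background activity, and a 3-axis
#' accelerometer whose variance switches with state (high in wake, near-zero
#' in sleep, lowest in REM atonia).
#'
#' Dwell-time means (wake 30 s, NREM 26 s, REM 19 s, CV 0.7) and the
#' transition structure (wake always enters sleep through NREM; REM is
#' entered only from NREM and usually exits to wake) follow standard rodent
#' sleep physiology. Component amplitudes are chosen so the three states are
#' spectrally well separated: NREM carries strong delta and spindle
#' oscillations, REM is theta-dominant (strongest parietally, consistent
#' with volume-conducted hippocampal theta), and wake mixes moderate theta
#' and broadband gamma. Every state also carries a small beta component and
#' REM a small parietal ripple bump so that multiplicative genotype effects
#' on those bands act on a nonzero baseline.
#'
#' @param duration_s Recording length in seconds (default 43200 = 12 h).
#' @param sample_rate Sampling rate in Hz (default 1000). Must be at least
#'   twice the highest component edge (centre + bandwidth).
#' @param dwell Tibble with columns `state`, `mean_s`, `cv`: per-state
#'   log-normal bout-duration mean (seconds) and coefficient of variation.
#' @param transition 3x3 row-stochastic matrix of next-state probabilities
#'   with zero diagonal; dimnames must be the states WAKE/NREM/REM.
#' @param components Tibble with columns `state`, `role`, `center_hz`,
#'   `bw_hz`, `amp`: band-limited oscillatory components per state and
#'   electrode site.
#' @param background List with `slope` (power-law exponent of the 1/f
#'   background, power ~ 1/f^slope), `scale` (its amplitude) and `white`
#'   (standard deviation of a broadband noise floor emulating
#'   electrode/amplifier noise, so no band ever sits at zero power).
#' @param power_modulation List with `sd_log` and `ar`: every EEG channel
#'   is multiplied by a slowly varying log-normal gain (AR(1) on the log
#'   scale, one step per second) emulating the arousal-related power
#'   fluctuations of real EEG; this gives band powers the heavy-tailed
#'   epoch-to-epoch variability that the interquartile-range outlier rule
#'   presumes. Set `sd_log = 0` to disable.
#' @param movement_sd Named numeric vector: per-state accelerometer standard
#'   deviation per axis (arbitrary units).
#' @param genotype_effects Effects applied to mutant animals; see
#'   [genotype_effects()]. `NULL` means wild type.
#' @param lights_on Length-2 numeric, lights-on window in seconds from
#'   recording start.
#' @return A list of class `sim_config`.
#' @seealso [sample_hypnogram()], [synthesize_signals()], [simulate_cohort()]
#' @export
sim_config <- function(duration_s = 43200,
                       sample_rate = 1000,
                       dwell = default_dwell(),
                       transition = default_transition(),
                       components = default_components(),
                       background = list(slope = 2, scale = 0.3, white = 0.3),
                       power_modulation = list(sd_log = 0.35, ar = 0.9),
                       movement_sd = c(WAKE = 1, NREM = 0.08, REM = 0.04),
                       genotype_effects = NULL,
                       lights_on = c(0, duration_s)) {
  cfg <- list(
    duration_s = duration_s, sample_rate = sample_rate,
    dwell = tibble::as_tibble(dwell), transition = transition,
    components = tibble::as_tibble(components), background = background,
    power_modulation = power_modulation,
    movement_sd = movement_sd, genotype_effects = genotype_effects,
    lights_on = lights_on,
    channel_info = default_channel_info()
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

default_channel_info <- function() {
  tibble::tibble(
    channel = c("EEG frontal-L", "EEG frontal-R", "EEG parietal-L",
                "EEG parietal-R", "ACC X", "ACC Y", "ACC Z"),
    type = c(rep("eeg", 4), rep("accel", 3)),
    role = c("frontal", "frontal", "parietal", "parietal",
             "accel", "accel", "accel"),
    side = c("L", "R", "L", "R", NA, NA, NA)
  )
}

#' @rdname sim_config
#' @export
default_dwell <- function() {
  tibble::tibble(
    state  = c("WAKE", "NREM", "REM"),
    mean_s = c(30, 26, 19),
    cv     = c(0.7, 0.7, 0.7)
  )
}

#' @rdname sim_config
#' @export
default_transition <- function() {
  m <- matrix(c(
    0.00, 1.00, 0.00,   # WAKE ->
    0.50, 0.00, 0.50,   # NREM ->
    0.85, 0.15, 0.00    # REM  ->
  ), nrow = 3, byrow = TRUE, dimnames = list(state_levels(), state_levels()))
  m
}

#' @rdname sim_config
#' @export
default_components <- function() {
  tribble_c <- function(state, role, center_hz, bw_hz, amp) {
    tibble::tibble(state = state, role = role, center_hz = center_hz,
                   bw_hz = bw_hz, amp = amp)
  }
  dplyr::bind_rows(
    # WAKE: strong theta (active exploration), broadband gamma, weak delta,
    # a beta baseline shared by every state
    tribble_c("WAKE", "frontal",  c(7, 60, 2, 25), c(2, 30, 1.5, 4),
              c(1.6, 0.45, 0.25, 0.30)),
    tribble_c("WAKE", "parietal", c(7.5, 60, 2, 25), c(2, 30, 1.5, 4),
              c(2.0, 0.45, 0.50, 0.30)),
    # NREM: strong delta, spindles, beta baseline, weak gamma
    tribble_c("NREM", "frontal",  c(2, 14, 25, 60), c(1.5, 3, 4, 30),
              c(2.5, 1.0, 0.30, 0.25)),
    tribble_c("NREM", "parietal", c(2, 14, 25, 60), c(1.5, 3, 4, 30),
              c(1.6, 1.1, 0.30, 0.25)),
    # REM: dominant theta (parietal > frontal), modest delta, beta
    # baseline, small parietal ripple bump
    tribble_c("REM", "frontal",  c(7.5, 2, 25, 60), c(1.5, 1.5, 4, 30),
              c(1.8, 0.50, 0.30, 0.25)),
    tribble_c("REM", "parietal", c(7.5, 2, 25, 60, 150), c(1.5, 1.5, 4, 30, 25),
              c(2.2, 0.90, 0.30, 0.25, 0.20))
  )
}

#' Genotype effects for mutant animals
#'
#' Multiplicative and additive modifiers applied to the generator when an
#' animal is labelled mutant. Defaults express the mutant phenotype the
#' package is designed to recover: globally halved bout durations (more,
#' shorter bouts in every state), a 1.8-fold increased NREM-to-REM entry probability
#' (longer total REM and higher REM share of sleep), a 1 Hz slowing of the
#' REM theta peak, and band-amplitude changes -- REM beta x2 at both sites,
#' REM frontal delta x1.5, REM parietal ripple x0.7, NREM parietal beta
#' x1.5, wake parietal delta x1.5 and wake parietal gamma x0.67.
#'
#' @param bout_scale Multiplier on every state's mean bout duration.
#' @param rem_entry_boost Multiplier on the NREM-to-REM transition
#'   probability (row renormalized).
#' @param theta_shift_hz Additive shift (Hz) of REM theta component centres.
#' @param band_scale Tibble `state`, `role`, `band`, `factor`: amplitude
#'   multipliers applied to components whose centre frequency falls in
#'   `band` for that state and site.
#' @return A list of class `genotype_effects`.
#' @export
genotype_effects <- function(bout_scale = 0.5,
                             rem_entry_boost = 1.8,
                             theta_shift_hz = -1,
                             band_scale = default_band_scale()) {
  fx <- list(bout_scale = bout_scale, rem_entry_boost = rem_entry_boost,
             theta_shift_hz = theta_shift_hz,
             band_scale = tibble::as_tibble(band_scale))
  class(fx) <- "genotype_effects"
  fx
}

#' @rdname genotype_effects
#' @export
no_effects <- function() {
  genotype_effects(bout_scale = 1, rem_entry_boost = 1, theta_shift_hz = 0,
                   band_scale = default_band_scale()[0, ])
}

#' @rdname genotype_effects
#' @export
default_band_scale <- function() {
  tibble::tibble(
    state  = c("REM", "REM", "REM", "REM", "NREM", "WAKE", "WAKE"),
    role   = c("frontal", "parietal", "frontal", "parietal", "parietal",
               "parietal", "parietal"),
    band   = c("beta", "beta", "delta", "ripple", "beta", "delta", "gamma"),
    factor = c(2, 2, 1.5, 0.7, 1.5, 1.5, 0.67)
  )
}

validate_sim_config <- function(cfg) {
  tm <- cfg$transition
  if (!is.matrix(tm) || !identical(dim(tm), c(3L, 3L))) {
    stop("transition must be a 3x3 matrix", call. = FALSE)
  }
  if (any(diag(tm) != 0)) {
    stop("transition matrix must have a zero diagonal (no self-transitions)",
         call. = FALSE)
  }
  rs <- rowSums(tm)
  if (any(tm < 0) || any(abs(rs - 1) > 1e-8 & abs(rs) > 1e-8)) {
    stop("transition matrix rows must be nonnegative and sum to 1 (an all-zero row marks an absorbing state)",
         call. = FALSE)
  }
  if (any(cfg$dwell$mean_s <= 1)) {
    stop("all dwell means must exceed 1 s", call. = FALSE)
  }
  if (!setequal(cfg$dwell$state, state_levels())) {
    stop("dwell table must cover states WAKE, NREM, REM", call. = FALSE)
  }
  if (any(cfg$components$amp < 0)) {
    stop("component amplitudes must be nonnegative", call. = FALSE)
  }
  top <- if (nrow(cfg$components)) {
    max(cfg$components$center_hz + cfg$components$bw_hz)
  } else 0
  if (cfg$sample_rate < 2 * top) {
    stop(sprintf(
      "sample_rate %.0f Hz below 2 x highest component edge (%.0f Hz)",
      cfg$sample_rate, top), call. = FALSE)
  }
  invisible(cfg)
}

#' Apply genotype effects to a configuration
#'
#' Returns a new `sim_config` with the mutant modifiers folded into the
#' dwell table, transition matrix and component table; used internally by
#' [simulate_cohort()] and exported for single-animal use.
#'
#' @param config A [sim_config()].
#' @param effects A [genotype_effects()] or `NULL` (returns config as-is).
#' @return A `sim_config`.
#' @export
apply_genotype_effects <- function(config, effects = config$genotype_effects) {
  if (is.null(effects)) return(config)
  cfg <- config
  cfg$dwell$mean_s <- pmax(1 + 1e-6, cfg$dwell$mean_s * effects$bout_scale)
  tm <- cfg$transition
  tm["NREM", "REM"] <- min(1, tm["NREM", "REM"] * effects$rem_entry_boost)
  tm["NREM", ] <- tm["NREM", ] / sum(tm["NREM", ])
  cfg$transition <- tm
  comp <- cfg$components
  # theta shift: move REM theta-band component centres
  theta <- default_bands()[default_bands()$band == "theta", ]
  is_rem_theta <- comp$state == "REM" &
    comp$center_hz >= theta$lo_hz & comp$center_hz <= theta$hi_hz
  comp$center_hz[is_rem_theta] <- comp$center_hz[is_rem_theta] +
    effects$theta_shift_hz
  if (nrow(effects$band_scale)) {
    comp$band <- band_of(comp$center_hz)
    for (i in seq_len(nrow(effects$band_scale))) {
      bs <- effects$band_scale[i, ]
      hit <- comp$state == bs$state & comp$role == bs$role &
        !is.na(comp$band) & comp$band == bs$band
      comp$amp[hit] <- comp$amp[hit] * bs$factor
    }
    comp$band <- NULL
  }
  cfg$components <- comp
  cfg$genotype_effects <- NULL
  validate_sim_config(cfg)
  cfg
}
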