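sine_recording <- function(freq_hz, duration_s = 10, fs = 1000, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  ci <- tibble::tibble(channel = "EEG frontal-L", type = "eeg",
                       role = "frontal", side = "L")
  sig <- matrix(amp * sin(2 * pi * freq_hz * t), ncol = 1,
                dimnames = list(NULL, ci$channel))
  structure(list(signals = sig, channel_info = ci, sample_rate = fs,
                 duration_s = duration_s, lights_on = c(0, duration_s)),
            class = "psg_recording")
}

test_that("every epoch's PSD of a pure sinusoid peaks at its frequency", {
  rec <- sine_recording(7, duration_s = 10, fs = 1000)
  sp <- compute_epoch_spectra(rec)
  res <- sp$freqs[2] - sp$freqs[1]
  peaks <- apply(sp$power[, 1, ], 1, function(p) sp$freqs[which.max(p)])
  expect_equal(dim(sp$power)[1], 10)
  expect_true(all(abs(peaks - 7) <= res + 1e-9))
})

test_that("zero signal gives all-zero power and a trailing partial epoch is dropped", {
  rec <- sine_recording(7, duration_s = 5, fs = 1000, amp = 0)
  rec$signals <- rbind(rec$signals, matrix(0, 400, 1))  # 5.4 s of samples
  sp <- compute_epoch_spectra(rec)
  expect_equal(dim(sp$power)[1], 5)
  expect_true(all(sp$power == 0))
})

test_that("a 12-h recording at 1-s epochs yields 43200 epochs (grid arithmetic)", {
  # pure arithmetic on the epoch grid; the full-signal case is exercised in
  # the acceptance suite
  fs <- 400
  n_ep <- floor(43200 * fs / (fs * 1))
  expect_equal(n_ep, 43200)
})

test_that("low sample rates are rejected naming the unresolvable bands", {
  rec <- sine_recording(7, duration_s = 5, fs = 200)
  expect_error(compute_epoch_spectra(rec), "ripple")
})

test_that("band integration reproduces hand-computed means on a toy table", {
  freqs <- c(2, 7, 14, 25, 60, 180)
  power <- array(0, dim = c(3, 1, 6))
  power[1, 1, ] <- c(1, 2, 3, 4, 5, 6)
  power[2, 1, ] <- c(10, 0, 0, 0, 0, 0)
  power[3, 1, ] <- c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5)
  sp <- make_spectra(power, freqs)
  # a grid that stops short of a band is rejected naming the limit
  expect_error(integrate_bands(make_spectra(power[, , 1:5, drop = FALSE],
                                            freqs[1:5])),
               "frequency grid")
  bp <- integrate_bands(sp)   # one bin per default band on this grid
  get <- function(ep, band) bp$raw[bp$epoch_s == ep & bp$band == band]
  expect_equal(get(0, "delta"), 1)
  expect_equal(get(0, "theta"), 2)
  expect_equal(get(0, "gamma"), 5)
  expect_equal(get(0, "ripple"), 6)
  expect_equal(get(1, "delta"), 10)
  expect_equal(get(1, "beta"), 0)
  expect_equal(get(2, "spindle"), 2.5)
  expect_equal(nrow(bp), 3 * 6)
})

test_that("a flat PSD yields the same power in every band", {
  freqs <- seq(0, 200, by = 2)
  power <- array(3.7, dim = c(4, 2, length(freqs)))
  sp <- make_spectra(power, freqs, roles = c("frontal", "parietal"))
  bp <- integrate_bands(sp)
  expect_true(all(bp$raw == 3.7))
})

test_that("band integration is linear in the spectra", {
  freqs <- seq(0, 200, by = 2)
  set.seed(1)
  p1 <- array(rexp(5 * 1 * length(freqs)), dim = c(5, 1, length(freqs)))
  p2 <- array(rexp(5 * 1 * length(freqs)), dim = c(5, 1, length(freqs)))
  a <- 2.5; b <- 0.7
  sp_lin <- make_spectra(a * p1 + b * p2, freqs)
  bp_lin <- integrate_bands(sp_lin)
  bp1 <- integrate_bands(make_spectra(p1, freqs))
  bp2 <- integrate_bands(make_spectra(p2, freqs))
  expect_equal(bp_lin$raw, a * bp1$raw + b * bp2$raw, tolerance = 1e-12)
})

test_that("white-noise band levels are flat across all six default bands", {
  set.seed(42)
  ci <- tibble::tibble(channel = "EEG frontal-L", type = "eeg",
                       role = "frontal", side = "L")
  sig <- matrix(rnorm(200 * 400), ncol = 1,
                dimnames = list(NULL, ci$channel))
  rec <- structure(list(signals = sig, channel_info = ci, sample_rate = 400,
                        duration_s = 200, lights_on = c(0, 200)),
                   class = "psg_recording")
  bp <- integrate_bands(compute_epoch_spectra(rec))
  levels <- tapply(bp$raw, bp$band, mean)
  expect_lt(max(levels) / min(levels), 1.2)
})

test_that("a constructed spike beyond the 15xIQR fence is the only epoch masked", {
  set.seed(7)
  x <- rnorm(1000, mean = 10, sd = 0.5)
  q1 <- oracle_quantile(x[-1], 0.25); q3 <- oracle_quantile(x[-1], 0.75)
  x[1] <- q3 + 16 * (q3 - q1)       # beyond the fence by construction
  bt <- make_band_table(x)
  out <- flag_outliers(bt, k = 15)
  expect_true(out$outlier[out$epoch_s == 0])
  expect_equal(sum(out$outlier), 1)
})

test_that("constant band power yields no outliers (zero IQR, no exceedance)", {
  bt <- make_band_table(rep(2.2, 50))
  out <- flag_outliers(bt, k = 15)
  expect_false(any(out$outlier))
})

test_that("masked fraction at k = 0.5 matches the normal-tail calculation", {
  set.seed(11)
  bt <- make_band_table(rnorm(10000))
  out <- flag_outliers(bt, k = 0.5)
  z <- qnorm(0.75) + 0.5 * (qnorm(0.75) - qnorm(0.25))
  expected <- 2 * pnorm(z, lower.tail = FALSE)
  expect_lt(abs(mean(out$outlier) - expected), 0.02)
})

test_that("outlier masking agrees with the brute-force oracle and is idempotent", {
  set.seed(3)
  for (rep in 1:10) {
    x <- rlnorm(50, sdlog = 1.5)
    bt <- make_band_table(x)
    out <- flag_outliers(bt, k = 2)
    expect_equal(out$outlier, oracle_outlier_mask(x, k = 2))
    again <- flag_outliers(out, k = 2)
    expect_identical(again$outlier, out$outlier)
  }
  expect_error(flag_outliers(make_band_table(rnorm(10)), k = 0), "positive")
  expect_error(flag_outliers(make_band_table(rnorm(3))), "4 epochs")
})

test_that("median normalization matches the worked example and its invariants", {
  bt <- flag_outliers(make_band_table(1:5), k = 15)
  out <- normalize_power(bt)
  expect_equal(out$normalized, c(1, 2, 3, 4, 5) / 3)

  # scale invariance
  out10 <- normalize_power(flag_outliers(make_band_table((1:5) * 10), k = 15))
  expect_equal(out10$normalized, out$normalized)

  # median of unmasked normalized values is exactly 1
  set.seed(5)
  for (rep in 1:5) {
    x <- rlnorm(200, sdlog = 2)
    out <- normalize_power(flag_outliers(make_band_table(x), k = 5))
    expect_equal(median(out$normalized[!out$outlier]), 1, tolerance = 1e-12)
  }
  expect_error(normalize_power(make_band_table(1:5)), "flag_outliers")
  expect_error(normalize_power(flag_outliers(make_band_table(rep(0, 10)), k = 15)),
               "median")
})

test_that("quantiles used for the fences follow the linear-interpolation convention", {
  set.seed(9)
  for (rep in 1:20) {
    x <- rexp(50)
    expect_equal(quantile(x, 0.25, type = 7, names = FALSE),
                 oracle_quantile(x, 0.25))
    expect_equal(quantile(x, 0.75, type = 7, names = FALSE),
                 oracle_quantile(x, 0.75))
  }
})

test_that("state band summary averages hand-computed per-state means and sites", {
  # 6 epochs, 2 channels of one role; alternate WAKE/NREM
  h <- new_hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "WAKE", "NREM"))
  tb <- tibble::tibble(
    epoch_s = rep(0:5, 2),
    channel = rep(c("EEG frontal-L", "EEG frontal-R"), each = 6),
    role = "frontal",
    band = factor("delta", levels = band_levels()),
    raw = c(1, 2, 3, 4, 5, 6, 10, 20, 30, 40, 50, 60),
    outlier = FALSE
  )
  tb$normalized <- tb$raw
  class(tb) <- c("band_power", class(tb))
  ss <- state_band_summary(tb, h)
  wake <- ss$mean_norm_power[ss$state == "WAKE" & ss$band == "delta"]
  nrem <- ss$mean_norm_power[ss$state == "NREM" & ss$band == "delta"]
  # per-channel means first, then across channels of the role
  expect_equal(wake, mean(c(mean(c(1, 2, 5)), mean(c(10, 20, 50)))))
  expect_equal(nrem, mean(c(mean(c(3, 4, 6)), mean(c(30, 40, 60)))))
  # absent state is NA, not zero
  expect_true(is.na(ss$mean_norm_power[ss$state == "REM" & ss$band == "delta"]))
  expect_error(state_band_summary(tb, new_hypnogram(rep("WAKE", 4))),
               "grids differ")
})

test_that("all-wake summary with unit power gives wake mean 1 and missing sleep states", {
  h <- new_hypnogram(rep("WAKE", 8))
  tb <- make_band_table(rep(1, 8))
  tb$outlier <- FALSE
  tb$normalized <- tb$raw
  ss <- state_band_summary(tb, h)
  expect_equal(ss$mean_norm_power[ss$state == "WAKE" & ss$band == "beta"], 1)
  expect_true(is.na(ss$mean_norm_power[ss$state == "REM" & ss$band == "beta"]))
  expect_true(is.na(ss$mean_norm_power[ss$state == "NREM" & ss$band == "beta"]))
})

test_that("theta peak recovers a REM theta component to sub-bin accuracy", {
  # REM epochs carry a 7 Hz component; wake epochs do not. Flat-ish
  # background so the per-frequency median normalization cannot tilt the
  # peak.
  tm <- matrix(0, 3, 3, dimnames = list(c("WAKE", "NREM", "REM"),
                                        c("WAKE", "NREM", "REM")))
  tm["WAKE", "REM"] <- 1; tm["REM", "WAKE"] <- 1
  comps <- tibble::tibble(state = "REM", role = c("frontal", "parietal"),
                          center_hz = 7, bw_hz = 1.5, amp = 1.5)
  cfg <- sim_config(duration_s = 400, sample_rate = 400, transition = tm,
                    dwell = tibble::tibble(state = c("WAKE", "NREM", "REM"),
                                           mean_s = c(60, 30, 20),
                                           cv = c(0.3, 0.3, 0.3)),
                    components = comps,
                    background = list(slope = 0, scale = 0, white = 0.3),
                    power_modulation = list(sd_log = 0, ar = 0))
  gt <- sample_hypnogram(cfg, seed = 2)
  rec <- synthesize_signals(gt, seed = 3)
  sp <- compute_epoch_spectra(rec, segment_s = 1)
  pk <- theta_peak_frequency(sp, gt$hypnogram)
  expect_equal(nrow(pk), 2)
  expect_true(all(abs(pk$peak_hz - 7) <= 0.25))
})

test_that("theta peak ties break to the lower frequency and missing state gives NA", {
  freqs <- 0:20
  power <- array(1, dim = c(9, 1, length(freqs)))
  power[1:4, 1, freqs == 6] <- 5
  power[1:4, 1, freqs == 9] <- 5   # equal-power second peak in REM epochs
  sp <- make_spectra(power, freqs)
  h <- new_hypnogram(c(rep("REM", 4), rep("WAKE", 5)))
  pk <- theta_peak_frequency(sp, h)
  expect_equal(pk$peak_hz, 6)

  h2 <- new_hypnogram(rep("WAKE", 9))
  pk2 <- theta_peak_frequency(sp, h2)
  expect_true(all(is.na(pk2$peak_hz)))
})
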