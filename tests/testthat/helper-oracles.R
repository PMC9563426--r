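# Independent brute-force oracles used by the equivalence tests. These are
# deliberately naive implementations that never share code with the package.

# Run-length architecture oracle: scan the label vector and accumulate runs.
oracle_architecture <- function(labels) {
  runs <- list()
  cur <- labels[1]; len <- 0
  for (l in labels) {
    if (l == cur) {
      len <- len + 1
    } else {
      runs[[length(runs) + 1]] <- list(state = cur, len = len)
      cur <- l; len <- 1
    }
  }
  runs[[length(runs) + 1]] <- list(state = cur, len = len)
  out <- list()
  for (s in c("WAKE", "NREM", "REM")) {
    lens <- unlist(lapply(runs, function(r) if (r$state == s) r$len))
    out[[s]] <- list(
      total_s = sum(lens), n_bouts = length(lens),
      mean_bout_s = if (length(lens)) mean(lens) else NA_real_
    )
  }
  out
}

# Linear-interpolation quantile oracle (the type-7 convention, by hand).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force outlier mask for a single (channel, band) series.
oracle_outlier_mask <- function(x, k) {
  q1 <- oracle_quantile(x, 0.25); q3 <- oracle_quantile(x, 0.75)
  iqr <- q3 - q1
  x > q3 + k * iqr | x < q1 - k * iqr
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mann_whitney_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(m))
  us <- combn(m + n, m, u_stat)
  center <- m * n / 2
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Per-state F1 of a predicted hypnogram against truth.
state_f1 <- function(truth, pred, state) {
  tp <- sum(truth == state & pred == state)
  denom <- sum(truth == state) + sum(pred == state)
  if (denom == 0) return(NA_real_)
  2 * tp / denom
}

# Small fast config used across tests (Nyquist-safe for the ripple band).
tiny_config <- function(duration_s = 300, ...) {
  sim_config(duration_s = duration_s, sample_rate = 400, ...)
}

# Hand-built epoch_spectra object for unit tests of the band integrator.
make_spectra <- function(power, freqs, roles = NULL) {
  n_ch <- dim(power)[2]
  if (is.null(roles)) roles <- rep("frontal", n_ch)
  structure(list(
    times = seq_len(dim(power)[1]) - 1, freqs = freqs, power = power,
    channel_info = tibble::tibble(
      channel = paste0("EEG ", roles, "-", seq_len(n_ch)),
      type = "eeg", role = roles, side = NA_character_),
    sample_rate = 2 * max(freqs), epoch_s = 1), class = "epoch_spectra")
}

# Band-power tibble from a plain matrix of per-epoch values (one channel).
make_band_table <- function(values, band = "beta", channel = "EEG frontal-L") {
  tb <- tibble::tibble(
    epoch_s = seq_along(values) - 1, channel = channel, role = "frontal",
    band = factor(band, levels = band_levels()), raw = as.numeric(values))
  class(tb) <- c("band_power", class(tb))
  tb
}
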