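#' Staging-recovery study
#'
#' Simulates independent wild-type recordings, scores them automatically
#' and pools the epochs of all seeds against the ground truth, reporting
#' overall accuracy and per-state F1.
#'
#' @param n_seeds Number of independent recordings.
#' @param duration_s Recording length per seed (seconds).
#' @param sample_rate Hz (400 keeps the ripple band Nyquist-safe at a
#'   fraction of the acquisition-rate cost).
#' @param seed Master seed.
#' @return A list with `accuracy`, `f1` (named per state), `n_epochs`.
#' @export
evaluate_staging <- function(n_seeds = 10, duration_s = 3600,
                             sample_rate = 400, seed = 1) {
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * n_seeds), ncol = 2)
  cfg <- sim_config(duration_s = duration_s, sample_rate = sample_rate)
  truth <- pred <- character(0)
  for (i in seq_len(n_seeds)) {
    gt <- sample_hypnogram(cfg, seed = seeds[i, 1])
    rec <- synthesize_signals(gt, seed = seeds[i, 2])
    sp <- compute_epoch_spectra(rec)
    h <- suppressWarnings(score_states(extract_features(sp, rec)))
    truth <- c(truth, as.character(gt$hypnogram$state))
    pred <- c(pred, as.character(h$state))
  }
  f1 <- vapply(state_levels(), function(s) {
    tp <- sum(truth == s & pred == s)
    2 * tp / (sum(truth == s) + sum(pred == s))
  }, 0)
  list(accuracy = mean(truth == pred), f1 = f1, n_epochs = length(truth))
}

#' Architecture-effect recovery study
#'
#' Simulates two-genotype cohorts (hypnograms only; the architecture
#' metrics do not need signals) with the fragmentation phenotype --
#' mutant bout durations scaled by 0.5 and an increased NREM-to-REM
#' entry rate -- and asks, per master seed, whether the comparison suite
#' flags more bouts and shorter bouts in mutants (significant after
#' Bonferroni, correct direction) in all three states.
#'
#' @param n_seeds Master seeds (cohorts).
#' @param n_wt,n_mut Cohort sizes.
#' @param duration_s Hypnogram length (default the full 12-h lights-on
#'   period).
#' @param seed Master seed.
#' @return List with `recovery_rate` (fraction of seeds with the full
#'   pattern), `per_seed` logical vector.
#' @export
evaluate_architecture_recovery <- function(n_seeds = 20, n_wt = 9, n_mut = 5,
                                           duration_s = 43200, seed = 1) {
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- sample.int(.Machine$integer.max - 1, n_seeds)
  cfg <- sim_config(duration_s = duration_s, sample_rate = 400)
  fx <- genotype_effects(bout_scale = 0.5, rem_entry_boost = 1.8,
                         theta_shift_hz = 0,
                         band_scale = default_band_scale()[0, ])
  ok <- vapply(seeds, function(s) {
    coh <- simulate_cohort(n_wt, n_mut, cfg, seed = s, effects = fx,
                           signals = FALSE)
    arch <- purrr::pmap_dfr(coh, function(animal, genotype, truth, ...) {
      compute_architecture(truth$hypnogram, animal = animal,
                           genotype = genotype)
    })
    td <- tidy(run_comparison_suite(cohort_table(arch)))
    hit <- function(metric, dir) {
      r <- td[td$family == metric, ]
      nrow(r) == 3 && all(r$significant) && all(r$direction == dir)
    }
    hit("n_bouts", 1) && hit("mean_bout_s", -1)
  }, TRUE)
  list(recovery_rate = mean(ok), per_seed = ok)
}

#' Spectral-effect recovery study
#'
#' Simulates full cohorts (signals, automatic staging, band-power
#' pipeline, comparison suite) with the spectral phenotype configured:
#' REM beta x2 at both sites, NREM parietal beta x1.5, wake parietal
#' delta x1.5, wake parietal gamma x0.67, REM theta peak shifted -1 Hz.
#' Per seed it records whether each directional contrast is recovered at
#' Bonferroni-adjusted p < 0.05, and the recovered mutant-minus-wild-type
#' theta-peak shift.
#'
#' @param n_seeds Master seeds (cohorts).
#' @param n_wt,n_mut Cohort sizes.
#' @param duration_s Per-animal recording length. The default 1500 s
#'   keeps a cohort's full pipeline within seconds while leaving every
#'   animal hundreds of REM epochs.
#' @param seed Master seed.
#' @return List with `rates` (named recovery fractions), `theta_shift_hz`
#'   (mean recovered shift), `per_seed` tibble.
#' @export
evaluate_spectral_recovery <- function(n_seeds = 20, n_wt = 9, n_mut = 5,
                                       duration_s = 1500, seed = 1) {
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- sample.int(.Machine$integer.max - 1, n_seeds)
  cfg <- sim_config(duration_s = duration_s, sample_rate = 400)
  fx <- genotype_effects(
    bout_scale = 1, rem_entry_boost = 1, theta_shift_hz = -1,
    band_scale = tibble::tibble(
      state  = c("REM", "REM", "NREM", "WAKE", "WAKE"),
      role   = c("frontal", "parietal", "parietal", "parietal", "parietal"),
      band   = c("beta", "beta", "beta", "delta", "gamma"),
      factor = c(2, 2, 1.5, 1.5, 0.67)))
  per_seed <- purrr::map_dfr(seeds, function(s) {
    coh <- simulate_cohort(n_wt, n_mut, cfg, seed = s, effects = fx)
    an <- suppressWarnings(analyze_cohort(coh))
    td <- tidy(run_comparison_suite(an$architecture, an$band_summary,
                                    an$theta_peaks))
    hit <- function(st, ro, bd, dir) {
      r <- td[td$metric == "mean_norm_power" & td$state == st &
                td$role == ro & td$band == bd, ]
      nrow(r) == 1 && r$significant && r$direction == dir
    }
    tp <- an$theta_peaks
    mm <- tapply(tp$peak_hz, tp$genotype, mean, na.rm = TRUE)
    tibble::tibble(
      rem_beta_frontal = hit("REM", "frontal", "beta", 1),
      rem_beta_parietal = hit("REM", "parietal", "beta", 1),
      nrem_beta_parietal = hit("NREM", "parietal", "beta", 1),
      wake_delta_parietal = hit("WAKE", "parietal", "delta", 1),
      wake_gamma_parietal = hit("WAKE", "parietal", "gamma", -1),
      theta_shift = unname(mm["MUT"] - mm["WT"])
    )
  })
  list(rates = colMeans(per_seed[, 1:5]),
       theta_shift_hz = mean(per_seed$theta_shift, na.rm = TRUE),
       per_seed = per_seed)
}

#' Null-calibration study
#'
#' Two checks that the statistical layer does not manufacture effects:
#' (1) cohorts with no genotype effects (hypnogram architecture metrics,
#' the full comparison suite per seed) give a per-family family-wise
#' false-positive rate compatible with the 0.05 level; (2) the gated
#' two-group test holds its type-I error at the study's group sizes under
#' both a normal and a heavy-tailed log-normal null.
#'
#' @param n_seeds Null cohorts for the family-wise check.
#' @param n_reps Replicates for the gated-test type-I check.
#' @param n_wt,n_mut Group sizes.
#' @param duration_s Hypnogram length per animal.
#' @param seed Master seed.
#' @return List with `family_fpr` (named per family), `mc_bound`
#'   (0.05 + 2 Monte-Carlo SE), `type1_normal`, `type1_lognormal`.
#' @export
evaluate_null_calibration <- function(n_seeds = 100, n_reps = 2000,
                                      n_wt = 9, n_mut = 5,
                                      duration_s = 43200, seed = 1) {
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- sample.int(.Machine$integer.max - 1, n_seeds)
  cfg <- sim_config(duration_s = duration_s, sample_rate = 400)
  fam_hits <- purrr::map_dfr(seeds, function(s) {
    coh <- simulate_cohort(n_wt, n_mut, cfg, seed = s, effects = NULL,
                           signals = FALSE)
    arch <- purrr::pmap_dfr(coh, function(animal, genotype, truth, ...) {
      compute_architecture(truth$hypnogram, animal = animal,
                           genotype = genotype)
    })
    out <- run_comparison_suite(cohort_table(arch))
    tibble::as_tibble(as.list(tapply(out$significant, out$family, any)))
  })
  family_fpr <- colMeans(fam_hits)
  mc_bound <- 0.05 + 2 * sqrt(0.05 * 0.95 / n_seeds)

  type1 <- function(rdist) {
    mean(replicate(n_reps, {
      gated_two_group_test(rdist(n_wt), rdist(n_mut))$p < 0.05
    }))
  }
  list(family_fpr = family_fpr, mc_bound = mc_bound,
       type1_normal = type1(stats::rnorm),
       type1_lognormal = type1(stats::rlnorm))
}
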