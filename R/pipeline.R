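#' Analyze one recording end-to-end
#'
#' Convenience wrapper chaining the single-animal stages: Welch epoch
#' spectra, band powers with outlier flagging and median normalization,
#' automatic staging (skipped when a hypnogram is supplied), architecture
#' metrics, per-state band summaries and the REM theta peak (computed on a
#' second, 1 Hz resolution spectral pass).
#'
#' @param recording A `psg_recording`.
#' @param hypnogram Optional `hypnogram` (e.g. ground truth or manually
#'   edited); when `NULL` the recording is scored automatically.
#' @param min_bout_s Passed to [score_states()].
#' @param k Outlier fence multiplier, see [flag_outliers()].
#' @return List with `hypnogram`, `band_power`, `band_summary`,
#'   `theta_peak`, `architecture`.
#' @export
analyze_recording <- function(recording, hypnogram = NULL, min_bout_s = 3,
                              k = 15) {
  spectra <- compute_epoch_spectra(recording)
  if (is.null(hypnogram)) {
    features <- extract_features(spectra, recording)
    hypnogram <- score_states(features, min_bout_s = min_bout_s)
  }
  n_ep <- dim(spectra$power)[1]
  if (nrow(hypnogram) != n_ep) {
    stop(sprintf("hypnogram (%d epochs) does not match recording (%d epochs)",
                 nrow(hypnogram), n_ep), call. = FALSE)
  }
  bp <- integrate_bands(spectra) |>
    flag_outliers(k = k) |>
    normalize_power()
  # theta peak: a second 1 Hz resolution pass over the REM epochs only
  rem_ep <- which(hypnogram$state == "REM")
  roles <- unique(recording$channel_info$role[recording$channel_info$type == "eeg"])
  theta_peak <- if (length(rem_ep)) {
    fs <- recording$sample_rate
    idx <- rep((rem_ep - 1) * fs, each = fs) + seq_len(fs)
    sub <- recording
    sub$signals <- recording$signals[idx, , drop = FALSE]
    sub$duration_s <- length(rem_ep)
    theta_peak_frequency(compute_epoch_spectra(sub, segment_s = 1),
                         new_hypnogram(rep("REM", length(rem_ep))))
  } else {
    tibble::tibble(role = roles, peak_hz = NA_real_)
  }
  list(
    hypnogram = hypnogram,
    band_power = bp,
    band_summary = state_band_summary(bp, hypnogram),
    theta_peak = theta_peak,
    architecture = compute_architecture(hypnogram,
                                        animal = recording$id %||% NA_character_,
                                        genotype = recording$genotype %||% NA_character_)
  )
}

#' Analyze a simulated cohort
#'
#' Runs [analyze_recording()] over every animal of a [simulate_cohort()]
#' tibble and stacks the per-animal results into the cohort-level tables
#' the statistics layer consumes.
#'
#' @param cohort Tibble from [simulate_cohort()] (with signals).
#' @param use_truth Use the ground-truth hypnograms instead of automatic
#'   staging.
#' @param min_bout_s,k Passed through to [analyze_recording()].
#' @return List with `architecture` (long table from [cohort_table()]),
#'   `band_summary`, `theta_peaks`, and `per_animal` (list of
#'   [analyze_recording()] results).
#' @export
analyze_cohort <- function(cohort, use_truth = FALSE, min_bout_s = 3, k = 15) {
  res <- purrr::pmap(cohort, function(animal, genotype, truth, recording, ...) {
    analyze_recording(recording,
                      hypnogram = if (use_truth) truth$hypnogram else NULL,
                      min_bout_s = min_bout_s, k = k)
  })
  names(res) <- cohort$animal
  arch <- purrr::map2_dfr(res, seq_len(nrow(cohort)), function(r, i) {
    compute_architecture(r$hypnogram, animal = cohort$animal[i],
                         genotype = cohort$genotype[i])
  })
  bands <- purrr::map2_dfr(res, seq_len(nrow(cohort)), function(r, i) {
    dplyr::mutate(r$band_summary, animal = cohort$animal[i],
                  genotype = cohort$genotype[i])
  })
  thetas <- purrr::map2_dfr(res, seq_len(nrow(cohort)), function(r, i) {
    dplyr::mutate(r$theta_peak, animal = cohort$animal[i],
                  genotype = cohort$genotype[i])
  })
  list(architecture = cohort_table(arch), band_summary = bands,
       theta_peaks = thetas, per_animal = res)
}

#' Run the full reproducible pipeline
#'
#' Ties simulate - score - spectra - metrics - compare into one run that
#' writes every stage output plus a JSON manifest (config snapshot, seeds,
#' output hashes). With a fixed master seed reruns are byte-identical.
#' Instead of simulating, existing EDF files (with optional pre-scored
#' hypnograms) can be analyzed by passing `edf_paths`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the whole run.
#' @param config A [sim_config()] for the simulated animals.
#' @param n_wt,n_mut Cohort sizes (defaults follow the study: 9 wild types,
#'   5 mutants).
#' @param effects [genotype_effects()] for the mutants (`NULL` = none).
#' @param edf_paths Optional character vector of EDF files to analyze
#'   instead of simulating; genotypes are read from the sidecars.
#' @param hypnogram_paths Optional pre-scored hypnogram CSVs matching
#'   `edf_paths` (staging is then skipped).
#' @param use_truth Use ground-truth hypnograms from the simulator instead
#'   of automatic staging.
#' @param write_edfs Also write each simulated animal to EDF.
#' @param min_bout_s,k,alpha Stage parameters.
#' @return The run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, seed, config = sim_config(),
                         n_wt = 9, n_mut = 5,
                         effects = genotype_effects(),
                         edf_paths = NULL, hypnogram_paths = NULL,
                         use_truth = FALSE, write_edfs = FALSE,
                         min_bout_s = 3, k = 15, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(seed = seed, version = as.character(utils::packageVersion("somnospec")),
                   stages = list())
  tryCatch({
    if (is.null(edf_paths)) {
      cohort <- simulate_cohort(n_wt, n_mut, config, seed, effects = effects)
      manifest$config <- list(
        duration_s = config$duration_s, sample_rate = config$sample_rate,
        n_wt = n_wt, n_mut = n_mut,
        effects = if (is.null(effects)) NULL else unclass(effects[
          c("bout_scale", "rem_entry_boost", "theta_shift_hz")])
      )
      if (write_edfs) {
        for (i in seq_len(nrow(cohort))) {
          write_edf(cohort$recording[[i]],
                    file.path(out_dir, paste0(cohort$animal[i], ".edf")))
        }
      }
      truths <- purrr::map(cohort$truth, "hypnogram")
      recs <- cohort$recording
      animals <- cohort$animal
      genotypes <- cohort$genotype
    } else {
      stage <- "read"
      recs <- purrr::map(edf_paths, read_recording)
      animals <- purrr::map_chr(seq_along(recs),
                                ~ recs[[.x]]$id %||% basename(edf_paths[.x]))
      genotypes <- purrr::map_chr(recs, ~ .x$genotype %||% NA_character_)
      truths <- if (is.null(hypnogram_paths)) NULL else
        purrr::map(hypnogram_paths, load_hypnogram, provenance = "edited")
    }

    stage <- "score"
    results <- purrr::map(seq_along(recs), function(i) {
      hyp <- if (use_truth && !is.null(truths)) truths[[i]] else
        if (!is.null(edf_paths) && !is.null(truths)) truths[[i]] else NULL
      analyze_recording(recs[[i]], hypnogram = hyp,
                        min_bout_s = min_bout_s, k = k)
    })
    hyp_paths <- purrr::map_chr(seq_along(results), function(i) {
      p <- file.path(out_dir, paste0(animals[i], "_hypnogram.csv"))
      save_hypnogram(results[[i]]$hypnogram, p)
      p
    })

    stage <- "spectra"
    band_path <- file.path(out_dir, "band_power.csv")
    bp_all <- purrr::map2_dfr(results, animals, function(r, a) {
      dplyr::mutate(r$band_power, animal = a)
    })
    readr::write_csv(
      dplyr::select(bp_all, "animal", "epoch_s", "channel", "band",
                    "raw", "normalized", "outlier"), band_path)
    summary_path <- file.path(out_dir, "band_summary.csv")
    band_summary <- purrr::map_dfr(seq_along(results), function(i) {
      dplyr::mutate(results[[i]]$band_summary, animal = animals[i],
                    genotype = genotypes[i])
    })
    readr::write_csv(band_summary, summary_path)
    theta_peaks <- purrr::map_dfr(seq_along(results), function(i) {
      dplyr::mutate(results[[i]]$theta_peak, animal = animals[i],
                    genotype = genotypes[i])
    })

    stage <- "metrics"
    arch <- purrr::map_dfr(seq_along(results), function(i) {
      compute_architecture(results[[i]]$hypnogram, animal = animals[i],
                           genotype = genotypes[i])
    })
    arch_long <- cohort_table(arch)
    metrics_path <- file.path(out_dir, "architecture.csv")
    readr::write_csv(arch_long, metrics_path)

    stage <- "compare"
    comparisons <- run_comparison_suite(arch_long, band_summary, theta_peaks,
                                        alpha = alpha)
    compare_path <- file.path(out_dir, "comparisons.csv")
    readr::write_csv(tidy(comparisons), compare_path)

    outputs <- c(hyp_paths, band_path, summary_path, metrics_path,
                 compare_path)
    manifest$stages <- list(
      score = hyp_paths, spectra = c(band_path, summary_path),
      metrics = metrics_path, compare = compare_path)
    manifest$hashes <- as.list(tools::md5sum(outputs))
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
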