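#' Sleep-architecture metrics of a hypnogram
#'
#' A bout is a maximal run of identical labels (runs touching the recording
#' edges count). Per state the function reports total time, the number of
#' bouts, their mean duration, and -- for REM and NREM -- the percentage of
#' total sleep time (TST = REM + NREM seconds, the denominator used for
#' sleep-state percentages). States absent from the hypnogram get
#' `total_s = 0`, `n_bouts = 0` and missing `mean_bout_s`; with TST = 0
#' the percentages are missing, never zero. No minimum bout length is
#' imposed here: smoothing belongs to the scorer, so these metrics measure
#' exactly the hypnogram they are given (1-s singleton runs count as
#' bouts).
#'
#' @param h A `hypnogram`.
#' @param animal,genotype Optional identifiers carried into the result.
#' @return Tibble `animal`, `genotype`, `state`, `total_s`, `pct_tst`,
#'   `n_bouts`, `mean_bout_s` with one row per state.
#' @examples
#' h <- new_hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM", "REM", "WAKE"))
#' compute_architecture(h)
#' @export
compute_architecture <- function(h, animal = NA_character_,
                                 genotype = NA_character_) {
  if (!nrow(h)) stop("empty hypnogram", call. = FALSE)
  r <- rle(as.character(h$state))
  runs <- tibble::tibble(state = r$values, length_s = r$lengths)
  out <- runs |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(total_s = sum(.data$length_s),
                     n_bouts = dplyr::n(),
                     mean_bout_s = mean(.data$length_s), .groups = "drop")
  out <- tibble::tibble(state = state_levels()) |>
    dplyr::left_join(out, by = "state") |>
    dplyr::mutate(
      total_s = dplyr::coalesce(.data$total_s, 0L),
      n_bouts = dplyr::coalesce(.data$n_bouts, 0L)
    )
  tst <- sum(out$total_s[out$state %in% c("NREM", "REM")])
  out$pct_tst <- ifelse(out$state == "WAKE", NA_real_,
                        if (tst > 0) 100 * out$total_s / tst else NA_real_)
  tibble::tibble(animal = animal, genotype = genotype) |>
    dplyr::cross_join(out) |>
    dplyr::select("animal", "genotype", "state", "total_s", "pct_tst",
                  "n_bouts", "mean_bout_s")
}

#' Long-format cohort architecture table
#'
#' Stacks per-animal architecture rows into the tidy long format consumed
#' by the statistics layer: one row per (animal, state, metric), missing
#' values dropped.
#'
#' @param arch_list List of tibbles from [compute_architecture()], or a
#'   single row-bound tibble.
#' @return Tibble `animal`, `genotype`, `state`, `metric`, `value`.
#' @export
cohort_table <- function(arch_list) {
  arch <- if (is.data.frame(arch_list)) arch_list else dplyr::bind_rows(arch_list)
  if (!nrow(arch)) stop("need at least one animal", call. = FALSE)
  if (any(table(arch$animal, arch$state) > 1)) {
    stop("duplicate animal ids in architecture table", call. = FALSE)
  }
  arch |>
    tidyr::pivot_longer(cols = c("total_s", "pct_tst", "n_bouts", "mean_bout_s"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$animal, .data$state, .data$metric)
}
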