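#' Read and write hypnogram CSV files
#'
#' The hypnogram dialect is a two-column CSV with header
#' `epoch_start_s,state`, one row per contiguous 1-s epoch, states
#' `WAKE`/`NREM`/`REM`. Reading validates the state tokens and epoch
#' contiguity and reports the offending line on failure; writing then
#' reading a hypnogram is the identity.
#'
#' @param path File path.
#' @param provenance Provenance recorded on the loaded hypnogram.
#' @return `load_hypnogram()` returns a `hypnogram`;
#'   `save_hypnogram()` invisibly returns `path`.
#' @export
load_hypnogram <- function(path, provenance = "automatic") {
  df <- readr::read_csv(path, col_types = readr::cols(
    epoch_start_s = readr::col_double(), state = readr::col_character()))
  bad <- which(!df$state %in% state_levels())
  if (length(bad)) {
    stop(sprintf("unknown state token '%s' at line %d of %s",
                 df$state[bad[1]], bad[1] + 1L, path), call. = FALSE)
  }
  gaps <- which(diff(df$epoch_start_s) != 1)
  if (length(gaps)) {
    stop(sprintf("non-contiguous epochs at line %d of %s (%.0f s -> %.0f s)",
                 gaps[1] + 2L, path, df$epoch_start_s[gaps[1]],
                 df$epoch_start_s[gaps[1] + 1]), call. = FALSE)
  }
  new_hypnogram(df$state, start_s = df$epoch_start_s[1],
                provenance = provenance)
}

#' @rdname load_hypnogram
#' @param h A `hypnogram`.
#' @export
save_hypnogram <- function(h, path) {
  readr::write_csv(
    tibble::tibble(epoch_start_s = h$epoch_start_s,
                   state = as.character(h$state)),
    path)
  invisible(path)
}
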