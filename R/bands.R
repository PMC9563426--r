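#' Spectral band definitions
#'
#' The canonical rodent EEG frequency bands used throughout the package:
#' delta 0.5--4, theta 5--10, spindle 11--19, beta 20--30, gamma 40--100 and
#' ripple 130--180 Hz. Bounds are inclusive and deliberately non-contiguous
#' (the gaps 4--5, 10--11, 19--20, 30--40 and 100--130 Hz are unassigned);
#' a frequency bin belongs to a band when its centre lies inside the bounds.
#'
#' @param bands Optional tibble with columns `band`, `lo_hz`, `hi_hz` to
#'   validate and use in place of the defaults.
#' @return A tibble with columns `band` (character), `lo_hz`, `hi_hz`.
#' @examples
#' default_bands()
#' @export
default_bands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble::tibble(
      band  = c("delta", "theta", "spindle", "beta", "gamma", "ripple"),
      lo_hz = c(0.5, 5, 11, 20, 40, 130),
      hi_hz = c(4, 10, 19, 30, 100, 180)
    )
  }
  stopifnot(all(c("band", "lo_hz", "hi_hz") %in% names(bands)))
  if (any(bands$lo_hz <= 0) || any(bands$lo_hz >= bands$hi_hz)) {
    stop("band bounds must satisfy 0 < lo_hz < hi_hz", call. = FALSE)
  }
  if (anyDuplicated(bands$band)) stop("duplicate band names", call. = FALSE)
  tibble::as_tibble(bands)
}

#' @rdname default_bands
#' @export
band_levels <- function() c("delta", "theta", "spindle", "beta", "gamma", "ripple")

state_levels <- function() c("WAKE", "NREM", "REM")

role_levels <- function() c("frontal", "parietal")

#' Map a frequency to its band
#'
#' @param freq_hz Numeric vector of frequencies.
#' @param bands Band table as returned by [default_bands()].
#' @return Character vector of band names, `NA` for frequencies in a gap.
#' @export
band_of <- function(freq_hz, bands = default_bands()) {
  out <- rep(NA_character_, length(freq_hz))
  for (i in seq_len(nrow(bands))) {
    hit <- freq_hz >= bands$lo_hz[i] & freq_hz <= bands$hi_hz[i]
    out[hit] <- bands$band[i]
  }
  out
}
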