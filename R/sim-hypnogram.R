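#' Sample a ground-truth hypnogram from the semi-Markov vigilance model
#'
#' Draws an alternating sequence of wake/NREM/REM bouts: the next state
#' comes from the configured transition matrix (zero diagonal) and the bout
#' duration from the state's log-normal dwell law, truncated to at least 1 s
#' and rounded to whole seconds. The sequence starts in wake (animals are
#' handled into the recording box at lights-on) and the final bout is
#' clipped so that bouts exactly tile `[0, duration_s)`.
#'
#' @param config A [sim_config()]. Genotype effects attached to the config
#'   are applied first.
#' @param seed Integer seed; the draw is a pure function of (config, seed).
#' @return A list of class `ground_truth` with elements `hypnogram`
#'   (tibble `epoch_start_s`, `state`, 1-s epochs), `bouts` (tibble
#'   `state`, `start_s`, `length_s`) and `config` (the effective,
#'   effects-applied configuration).
#' @examples
#' gt <- sample_hypnogram(sim_config(duration_s = 600, sample_rate = 500), seed = 1)
#' table(gt$hypnogram$state)
#' @export
sample_hypnogram <- function(config, seed) {
  cfg <- apply_genotype_effects(config)
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)

  dwell <- cfg$dwell
  meanlog <- sdlog <- stats::setNames(numeric(3), dwell$state)
  sdlog[dwell$state] <- sqrt(log(1 + dwell$cv^2))
  meanlog[dwell$state] <- log(dwell$mean_s) - sdlog[dwell$state]^2 / 2

  states <- state_levels()
  total <- 0
  st <- "WAKE"
  seq_state <- character(0)
  seq_len_s <- integer(0)
  while (total < cfg$duration_s) {
    len <- max(1L, as.integer(round(stats::rlnorm(1, meanlog[st], sdlog[st]))))
    seq_state <- c(seq_state, st)
    seq_len_s <- c(seq_len_s, len)
    total <- total + len
    p <- cfg$transition[st, ]
    if (sum(p) <= 0) {  # absorbing state: stay forever
      seq_len_s[length(seq_len_s)] <- seq_len_s[length(seq_len_s)] +
        (cfg$duration_s - total)
      total <- cfg$duration_s
      break
    }
    st <- sample(states, 1, prob = p)
  }
  # clip final bout to the recording end
  overshoot <- total - cfg$duration_s
  seq_len_s[length(seq_len_s)] <- seq_len_s[length(seq_len_s)] - overshoot
  keep <- seq_len_s > 0
  seq_state <- seq_state[keep]
  seq_len_s <- seq_len_s[keep]
  # clipping may leave equal adjacent states; merge to keep bouts maximal
  r <- rle(seq_state)
  if (any(r$lengths > 1)) {
    grp <- rep(seq_along(r$lengths), r$lengths)
    seq_len_s <- as.integer(tapply(seq_len_s, grp, sum))
    seq_state <- r$values
  }

  bouts <- tibble::tibble(
    state = seq_state,
    start_s = cumsum(c(0L, seq_len_s[-length(seq_len_s)])),
    length_s = seq_len_s
  )
  hyp <- new_hypnogram(rep(bouts$state, bouts$length_s),
                       provenance = "ground-truth")
  structure(list(hypnogram = hyp, bouts = bouts, config = cfg),
            class = "ground_truth")
}

#' Construct a hypnogram tibble
#'
#' @param states Character vector of per-second labels (WAKE/NREM/REM).
#' @param start_s Start time of the first epoch, seconds.
#' @param provenance One of "automatic", "ground-truth", "edited".
#' @return Tibble of class `hypnogram` with columns `epoch_start_s`, `state`.
#' @export
new_hypnogram <- function(states, start_s = 0,
                          provenance = c("automatic", "ground-truth", "edited")) {
  provenance <- match.arg(provenance)
  bad <- setdiff(unique(states), state_levels())
  if (length(bad)) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  h <- tibble::tibble(
    epoch_start_s = start_s + seq_along(states) - 1,
    state = factor(states, levels = state_levels())
  )
  class(h) <- c("hypnogram", class(h))
  attr(h, "provenance") <- provenance
  h
}
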