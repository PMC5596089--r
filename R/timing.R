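#' Speller session timing parameters
#'
#' Bundles the stimulus-presentation timing of a P300 speller session: a
#' *round* is one flash of every key, a *trial* is the selection of one
#' symbol over several rounds. Defaults reproduce the 4-key speller paradigm
#' this package simulates: 250 Hz sampling, 1.2 s rounds, 200 ms ISI, 100 ms
#' stimulus, 600 ms analysis epochs, and an adaptive online round count
#' bounded by `m_min = 3` and `m_max = 8`.
#'
#' @param fs sampling rate in Hz.
#' @param n_keys number of speller symbols (keys).
#' @param t_round seconds per round (all keys flash once per round).
#' @param isi inter-stimulus interval: seconds between successive flash
#'   onsets within a round.
#' @param stimulus seconds a key stays lit.
#' @param t_epoch seconds of post-onset signal analyzed per flash.
#' @param rounds_per_trial_training rounds per trial used for offline
#'   training sessions.
#' @param m_min,m_max minimum and maximum number of rounds the online
#'   decoder may consume before deciding.
#'
#' @return an object of class `session_timing`.
#' @export
#' @examples
#' tm <- session_timing()
#' tm$isi * tm$n_keys <= tm$t_round
session_timing <- function(fs = 250, n_keys = 4, t_round = 1.2, isi = 0.2,
                           stimulus = 0.1, t_epoch = 0.6,
                           rounds_per_trial_training = 10,
                           m_min = 3, m_max = 8) {
  assert_scalar_num(fs, "fs", lower = 1e-9)
  assert_scalar_num(n_keys, "n_keys", lower = 2)
  assert_scalar_num(t_round, "t_round", lower = 1e-9)
  assert_scalar_num(isi, "isi", lower = 1e-9)
  assert_scalar_num(stimulus, "stimulus", lower = 0)
  assert_scalar_num(t_epoch, "t_epoch", lower = 1e-9)
  assert_scalar_num(m_min, "m_min", lower = 1)
  assert_scalar_num(m_max, "m_max", lower = 1)
  if (isi * n_keys > t_round + 1e-12) {
    stop_config("isi * n_keys must not exceed t_round")
  }
  if (!(stimulus <= isi && isi <= t_epoch && t_epoch <= t_round)) {
    stop_config("timing must satisfy stimulus <= isi <= t_epoch <= t_round")
  }
  if (m_min > m_max) stop_config("m_min must not exceed m_max")
  structure(
    list(fs = fs, n_keys = as.integer(n_keys), t_round = t_round, isi = isi,
         stimulus = stimulus, t_epoch = t_epoch,
         rounds_per_trial_training = as.integer(rounds_per_trial_training),
         m_min = as.integer(m_min), m_max = as.integer(m_max)),
    class = "session_timing")
}

#' @export
print.session_timing <- function(x, ...) {
  cat(sprintf(
    "<session_timing> %d keys @ %g Hz | round %g s, ISI %g s, stimulus %g s, epoch %g s | M in [%d, %d]\n",
    x$n_keys, x$fs, x$t_round, x$isi, x$stimulus, x$t_epoch, x$m_min, x$m_max))
  invisible(x)
}

# samples per analysis epoch (150 at 250 Hz / 600 ms)
epoch_samples <- function(timing) as.integer(round(timing$t_epoch * timing$fs))

# samples one trial occupies, including the silent inter-trial gap
trial_samples <- function(timing, rounds, gap_s) {
  as.integer(round((rounds * timing$t_round + gap_s) * timing$fs))
}

#' Build a randomized flash schedule
#'
#' Each round presents every key exactly once, in independent random order,
#' with onsets spaced by the inter-stimulus interval; round `r` starts at
#' `r * t_round` within its trial. Trials are laid out back to back with a
#' silent gap so that analysis epochs never straddle trials.
#'
#' @param timing a [session_timing()].
#' @param n_trials number of trials to schedule.
#' @param rounds rounds per trial.
#' @param seed integer seed for the key permutations, or `NULL` to use the
#'   current RNG stream.
#' @param gap_s silent gap appended after each trial, seconds.
#' @return a `data.frame` with columns `onset_sample` (1-based), `key_id`,
#'   `round`, `trial`, sorted by onset.
#' @export
make_flash_schedule <- function(timing, n_trials, rounds, seed = NULL,
                                gap_s = 1) {
  if (!inherits(timing, "session_timing")) stop_config("timing must be a session_timing")
  assert_scalar_num(n_trials, "n_trials", lower = 1)
  assert_scalar_num(rounds, "rounds", lower = 1)
  n_trials <- as.integer(n_trials); rounds <- as.integer(rounds)
  K <- timing$n_keys
  tr_len <- trial_samples(timing, rounds, gap_s)
  with_seed(seed, {
    keys <- unlist(lapply(seq_len(n_trials * rounds), function(i) sample.int(K)))
  })
  trial <- rep(seq_len(n_trials), each = rounds * K)
  round_idx <- rep(rep(seq_len(rounds), each = K), times = n_trials)
  slot <- rep(seq_len(K) - 1L, times = n_trials * rounds)
  onset <- (trial - 1L) * tr_len +
    as.integer(round(((round_idx - 1L) * timing$t_round + slot * timing$isi) * timing$fs)) + 1L
  data.frame(onset_sample = onset, key_id = keys, round = round_idx,
             trial = trial)
}
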