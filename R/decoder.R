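## Self-adaptive online decoding: accumulate rounds, score per-key round
## averages with the BLDA predictive mean, normalize the scores to [0, 1],
## and stop as soon as the best normalized score clears the threshold
## theta0 (never before m_min rounds, always by m_max rounds).

#' Normalize per-key scores to [0, 1]
#'
#' Shifted-sum normalization: `S_i = (mu_i - min mu) / sum_j (mu_j - min mu)`.
#' Shift-invariant, sums to 1, and leaves the maximum informative (a plain
#' min-max rescale would pin `max S` at 1 and make the stopping threshold
#' inert). All-equal scores give the uniform vector `1/K`.
#'
#' @param mu numeric vector of K >= 2 predictive means.
#' @return normalized score vector `S`.
#' @export
normalize_scores <- function(mu) {
  if (length(mu) < 2 || !all(is.finite(mu))) {
    stop_config("scores must be >= 2 finite values")
  }
  d <- mu - min(mu)
  s <- sum(d)
  if (s == 0) rep(1 / length(mu), length(mu)) else d / s
}

#' Fresh per-trial decoder state
#'
#' @param n_keys number of speller keys.
#' @param p feature-vector length.
#' @return a `decode_state`: round counter `M`, per-key running feature
#'   sums, raw and normalized scores, and the `decision` (NA until made).
#' @export
decode_state <- function(n_keys, p) {
  structure(list(M = 0L, sum_features = matrix(0, p, n_keys),
                 scores_raw = rep(NA_real_, n_keys),
                 scores_norm = rep(NA_real_, n_keys),
                 decision = NA_integer_, tie = FALSE),
            class = "decode_state")
}

#' Consume one round of flashes
#'
#' Adds the round's per-key feature vectors to the running sums, scores the
#' per-key means over rounds `1..M` with [predict_mean()], normalizes, and
#' decides `argmax S` once `M >= m_min` and `max S >= theta0`, or forcibly
#' at `M = m_max`. Ties at the argmax break toward the lowest key id and are
#' flagged in the returned state.
#'
#' @param state a `decode_state`.
#' @param round_features p x K matrix, one feature column per key.
#' @param model a `blda_model`.
#' @param theta0 stopping threshold on the best normalized score.
#' @param timing a [session_timing()].
#' @return the updated `decode_state`.
#' @export
decode_step <- function(state, round_features, model, theta0, timing) {
  K <- ncol(state$sum_features)
  if (!is.matrix(round_features) || ncol(round_features) != K) {
    stop_config("round_features must have one column per key")
  }
  if (nrow(round_features) != nrow(state$sum_features)) {
    stop_config("feature length does not match decoder state")
  }
  state$M <- state$M + 1L
  state$sum_features <- state$sum_features + round_features
  means <- state$sum_features / state$M
  state$scores_raw <- vapply(seq_len(K), function(k) {
    predict_mean(model, means[, k])
  }, numeric(1))
  state$scores_norm <- normalize_scores(state$scores_raw)
  best <- max(state$scores_norm)
  if ((state$M >= timing$m_min && best >= theta0) || state$M >= timing$m_max) {
    winners <- which(state$scores_norm == best)
    state$decision <- winners[1]           # lowest key id on ties
    state$tie <- length(winners) > 1
  }
  state
}

#' Replay a recording through the adaptive decoder
#'
#' Preprocesses the recording (bandpass, epoch, decimate, featurize),
#' then runs [decode_step()] per round of each trial until the decoder
#' stops. Selection time per trial is `M * t_round` — the stimulus time the
#' decision consumed, excluding inter-trial pauses.
#'
#' @param recording a labeled [eeg_recording()].
#' @param model a `blda_model`.
#' @param theta0 stopping threshold.
#' @param timing a [session_timing()].
#' @param max_rounds cap on rounds consumed (defaults to `timing$m_max`;
#'   the recording must contain at least this many rounds per trial).
#' @param prefiltered set `TRUE` if `recording` is already band-passed.
#' @param step decimation step.
#' @return list with `trials` (data.frame: target, decision, M,
#'   selection_s, correct), `accuracy`, `mean_M`, `mean_selection_s`.
#' @export
simulate_online <- function(recording, model, theta0, timing,
                            max_rounds = timing$m_max, prefiltered = FALSE,
                            step = 6) {
  if (!length(recording$targets)) stop_config("recording has no per-trial targets")
  if (!prefiltered) recording <- bandpass(recording, 0.1, 20)
  sf <- session_features(recording, timing, step = step)
  ev <- sf$events
  p <- nrow(sf$features)
  K <- timing$n_keys
  trials <- sort(unique(ev$trial))
  res <- lapply(trials, function(tr) {
    st <- decode_state(K, p)
    sel <- ev$trial == tr
    for (r in seq_len(min(max_rounds, max(ev$round[sel])))) {
      in_round <- which(sel & ev$round == r)
      rf <- matrix(0, p, K)
      rf[, ev$key_id[in_round]] <- sf$features[, in_round]
      st <- decode_step(st, rf, model, theta0, timing)
      if (!is.na(st$decision)) break
    }
    if (is.na(st$decision)) {             # recording shorter than m_max
      st$decision <- which.max(st$scores_norm)
    }
    c(decision = st$decision, M = st$M)
  })
  dec <- vapply(res, `[[`, numeric(1), "decision")
  M <- vapply(res, `[[`, numeric(1), "M")
  tgt <- recording$targets[trials]
  out <- data.frame(trial = trials, target = tgt, decision = dec, M = M,
                    selection_s = M * timing$t_round,
                    correct = dec == tgt)
  list(trials = out, accuracy = mean(out$correct), mean_M = mean(M),
       mean_selection_s = mean(out$selection_s))
}

#' Wolpaw information transfer rate
#'
#' Bits per selection
#' `B = log2 K + p log2 p + (1 - p) log2((1 - p)/(K - 1))` (limits taken at
#' p = 0 and p = 1), scaled to bits/min by the selection time:
#' `ITR = 60 * B / t_selection`.
#'
#' @param K number of selectable symbols.
#' @param p selection accuracy in [0, 1].
#' @param t_selection seconds per selection.
#' @return information transfer rate in bits/min.
#' @export
#' @examples
#' itr_bits_per_min(4, 1, 3.6)  # 33.33: perfect 4-way choice every 3.6 s
itr_bits_per_min <- function(K, p, t_selection) {
  assert_scalar_num(K, "K", lower = 2)
  assert_scalar_num(p, "p", lower = 0, upper = 1)
  if (!is.numeric(t_selection) || t_selection <= 0) {
    stop_config("t_selection must be positive")
  }
  b <- log2(K)
  if (p > 0) b <- b + p * log2(p)
  if (p < 1) b <- b + (1 - p) * log2((1 - p) / (K - 1))
  60 * b / t_selection
}

#' Choose the stopping threshold from offline data
#'
#' Simulates the adaptive decoder across a grid of thresholds and picks the
#' smallest theta0 whose accuracy first reaches the maximum over the grid
#' (ITR decreases with theta0, so the earliest peak is the efficient one).
#'
#' @param recording labeled offline [eeg_recording()].
#' @param model a `blda_model`.
#' @param timing a [session_timing()].
#' @param grid ascending candidate thresholds (default 0 to 0.95 by 0.05).
#' @param ... passed to [simulate_online()].
#' @return a `threshold_curve`: `grid`, `accuracy`, `itr`, `mean_M`,
#'   `chosen`.
#' @export
select_threshold <- function(recording, model, timing,
                             grid = seq(0, 0.95, by = 0.05), ...) {
  if (!length(grid)) stop_config("grid must be nonempty")
  if (is.unsorted(grid)) stop_config("grid must be sorted ascending")
  if (!inherits(recording, "eeg_recording")) stop_config("recording must be an eeg_recording")
  filtered <- bandpass(recording, 0.1, 20)
  sims <- lapply(grid, function(th) {
    simulate_online(filtered, model, th, timing, prefiltered = TRUE, ...)
  })
  acc <- vapply(sims, `[[`, numeric(1), "accuracy")
  mean_M <- vapply(sims, `[[`, numeric(1), "mean_M")
  itr <- vapply(seq_along(grid), function(i) {
    itr_bits_per_min(timing$n_keys, acc[i], sims[[i]]$mean_selection_s)
  }, numeric(1))
  chosen <- grid[which(acc == max(acc))[1]]
  structure(list(grid = grid, accuracy = acc, itr = itr, mean_M = mean_M,
                 chosen = chosen),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold_curve> %d thresholds | chosen theta0 = %.2f (acc %.3f, ITR %.2f bits/min)\n",
              length(x$grid), x$chosen, x$accuracy[x$grid == x$chosen][1],
              x$itr[x$grid == x$chosen][1]))
  invisible(x)
}
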