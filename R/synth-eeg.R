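#' Default 30-channel scalp montage
#'
#' Standard 10-20 labels for the 30 analysis channels (reference, ground and
#' the two EOG channels are excluded). Event-related P300 activity is
#' strongest over parietal and occipital sites, so those labels carry full
#' weight in [default_topography()].
#'
#' @return character vector of 30 channel labels.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2")
}

#' Default P300 scalp topography
#'
#' Weight 1.0 on parietal/occipital channels, 0.3 elsewhere, reflecting where
#' the P300 deflection is generated.
#'
#' @param channels channel label vector.
#' @return numeric weights, one per channel.
#' @export
default_topography <- function(channels = default_channels()) {
  strong <- c("P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
  ifelse(channels %in% strong, 1.0, 0.3)
}

#' Specification of a synthetic speller session
#'
#' Describes the stochastic world a synthetic recording is drawn from: how
#' many trials and rounds, the size and latency of the P300 deflection added
#' to target-flash epochs, and the background-noise model.
#'
#' Defaults describe a realistic naive-subject session: a 5 uV P300 peaking
#' 300 ms post-stimulus with 20 ms latency jitter, on 10 uV background noise
#' with an AR(1) (rho = 0.95) temporally correlated component approximating
#' the 1/f character of spontaneous EEG.
#'
#' @param n_trials trials per session (offline training default 40).
#' @param rounds_per_trial rounds per trial (training default 10).
#' @param p300_amplitude peak deflection amplitude, microvolts.
#' @param p300_latency peak time after flash onset, seconds.
#' @param latency_jitter_sd per-event Gaussian jitter of the latency, s.
#' @param noise_sd background noise standard deviation, microvolts.
#' @param noise_model one of `"ar1"` (AR(1)+white mix), `"white"`, `"pink"`.
#' @param channel_topography per-channel template weights.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return an object of class `synth_session_spec`.
#' @export
synth_session_spec <- function(n_trials = 40, rounds_per_trial = 10,
                               p300_amplitude = 5, p300_latency = 0.3,
                               latency_jitter_sd = 0.02, noise_sd = 10,
                               noise_model = c("ar1", "white", "pink"),
                               channel_topography = default_topography(),
                               seed = NULL) {
  noise_model <- match.arg(noise_model)
  assert_scalar_num(n_trials, "n_trials", lower = 1)
  assert_scalar_num(rounds_per_trial, "rounds_per_trial", lower = 1)
  assert_scalar_num(p300_amplitude, "p300_amplitude", lower = 0)
  assert_scalar_num(p300_latency, "p300_latency", lower = 0)
  assert_scalar_num(latency_jitter_sd, "latency_jitter_sd", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (!all(is.finite(channel_topography))) stop_config("topography must be finite")
  structure(
    list(n_trials = as.integer(n_trials),
         rounds_per_trial = as.integer(rounds_per_trial),
         p300_amplitude = p300_amplitude, p300_latency = p300_latency,
         latency_jitter_sd = latency_jitter_sd, noise_sd = noise_sd,
         noise_model = noise_model, channel_topography = channel_topography,
         seed = seed),
    class = "synth_session_spec")
}

#' Construct an EEG recording container
#'
#' Validates the core invariants: every (trial, round) presents each key
#' exactly once, onsets are strictly increasing, and every analysis epoch
#' fits inside the data matrix.
#'
#' @param data channels x samples numeric matrix (microvolts), rownames are
#'   channel labels.
#' @param fs sampling rate, Hz.
#' @param events data.frame with columns `onset_sample`, `key_id`, `round`,
#'   `trial` (and optionally `is_target`).
#' @param targets integer vector, the intended key per trial (may be empty
#'   for unlabeled recordings).
#' @param t_epoch analysis-epoch length in seconds, used for the fit check.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, events, targets = integer(),
                          t_epoch = 0.6) {
  if (!is.matrix(data) || !is.numeric(data)) stop_config("data must be a numeric matrix")
  if (is.null(rownames(data))) rownames(data) <- paste0("ch", seq_len(nrow(data)))
  events <- as.data.frame(events)
  need <- c("onset_sample", "key_id", "round", "trial")
  if (!all(need %in% names(events))) {
    stop_config("events must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(events)) {
    events <- events[order(events$onset_sample), , drop = FALSE]
    if (any(diff(events$onset_sample) <= 0)) {
      stop_config("event onsets must be strictly increasing")
    }
    ep <- as.integer(round(t_epoch * fs))
    if (any(events$onset_sample < 1L) ||
        any(events$onset_sample + ep - 1L > ncol(data))) {
      stop_config("an analysis epoch overruns the data matrix")
    }
    counts <- table(events$trial, events$round, events$key_id)
    if (any(counts != 1L)) {
      stop_config("each (trial, round) must present every key exactly once")
    }
    if (length(targets) && length(targets) != length(unique(events$trial))) {
      stop_config("targets must have one entry per trial")
    }
    if (length(targets) && !"is_target" %in% names(events)) {
      events$is_target <- events$key_id == targets[events$trial]
    }
  }
  structure(list(data = data, fs = fs, channel_names = rownames(data),
                 events = events, targets = as.integer(targets),
                 t_epoch = t_epoch),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz | %d events, %d trials\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events),
              length(unique(x$events$trial))))
  invisible(x)
}

#' P300 response template
#'
#' Positive half-cosine bump of the given width centered at the latency:
#' `A/2 * (1 + cos(pi*(t - latency)/(width/2)))` on its support, zero
#' elsewhere. Canonical monophasic P300 morphology with all shape parameters
#' explicit.
#'
#' @param timing a [session_timing()].
#' @param amplitude peak amplitude (microvolts).
#' @param latency peak time after flash onset (seconds).
#' @param width full support width (seconds).
#' @return numeric vector of `epoch_samples(timing)` values.
#' @export
p300_template <- function(timing, amplitude = 5, latency = 0.3, width = 0.2) {
  t <- (seq_len(epoch_samples(timing)) - 1L) / timing$fs
  on <- abs(t - latency) <= width / 2
  out <- numeric(length(t))
  out[on] <- amplitude / 2 * (1 + cos(pi * (t[on] - latency) / (width / 2)))
  out
}

# background noise, one channels x samples matrix
gen_noise <- function(n_ch, n_samp, sd, model) {
  if (sd == 0 || n_samp == 0) return(matrix(0, n_ch, n_samp))
  if (model == "white") {
    return(matrix(stats::rnorm(n_ch * n_samp, sd = sd), n_ch, n_samp))
  }
  if (model == "ar1") {
    # AR(1) rho 0.95 plus an equal-power white component, scaled to sd
    rho <- 0.95
    ar <- t(vapply(seq_len(n_ch), function(i) {
      as.numeric(stats::filter(stats::rnorm(n_samp), rho, method = "recursive"))
    }, numeric(n_samp)))
    ar <- ar * sqrt(1 - rho^2)           # unit marginal variance
    wh <- matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp)
    return((ar + wh) / sqrt(2) * sd)
  }
  # pink: shape white noise by 1/sqrt(f) in the frequency domain
  out <- matrix(0, n_ch, n_samp)
  f <- c(1, seq_len(n_samp - 1))         # avoid the DC singularity
  scale <- 1 / sqrt(pmin(f, n_samp - f + 1))
  for (i in seq_len(n_ch)) {
    spec <- stats::fft(stats::rnorm(n_samp)) * scale
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_samp
    out[i, ] <- x / stats::sd(x) * sd
  }
  out
}

#' Synthesize a speller EEG recording
#'
#' Generates background noise for a full session, then adds the
#' topography-weighted P300 template to each flash of the trial's target key
#' (only): a synthetic oddball paradigm. Per-trial target keys are drawn
#' uniformly at random. Deterministic given `spec$seed`.
#'
#' @param spec a [synth_session_spec()].
#' @param timing a [session_timing()].
#' @param gap_s silent gap between trials, seconds.
#' @param targets optional integer vector of intended keys, one per trial;
#'   drawn uniformly at random when `NULL`.
#' @return an [eeg_recording()].
#' @export
#' @examples
#' rec <- synthesize_recording(synth_session_spec(n_trials = 2, seed = 1),
#'                             session_timing())
#' nrow(rec$events)  # 2 trials x 10 rounds x 4 keys = 80
synthesize_recording <- function(spec, timing, gap_s = 1, targets = NULL) {
  if (!inherits(spec, "synth_session_spec")) stop_config("spec must be a synth_session_spec")
  if (!is.null(targets) && length(targets) != spec$n_trials) {
    stop_config("targets must have one entry per trial")
  }
  topo <- spec$channel_topography
  channels <- if (length(topo) == 30) default_channels() else paste0("ch", seq_along(topo))
  n_ch <- length(topo)
  n_samp <- spec$n_trials * trial_samples(timing, spec$rounds_per_trial, gap_s)
  ep <- epoch_samples(timing)

  with_seed(spec$seed, {
    events <- make_flash_schedule(timing, spec$n_trials, spec$rounds_per_trial,
                                  seed = NULL, gap_s = gap_s)
    if (is.null(targets)) {
      targets <- sample.int(timing$n_keys, spec$n_trials, replace = TRUE)
    }
    data <- gen_noise(n_ch, n_samp, spec$noise_sd, spec$noise_model)
    is_tgt <- events$key_id == targets[events$trial]
    tgt_onsets <- events$onset_sample[is_tgt]
    jit <- if (spec$latency_jitter_sd > 0) {
      stats::rnorm(length(tgt_onsets), sd = spec$latency_jitter_sd)
    } else rep(0, length(tgt_onsets))
    for (i in seq_along(tgt_onsets)) {
      tpl <- p300_template(timing, spec$p300_amplitude,
                           spec$p300_latency + jit[i])
      idx <- tgt_onsets[i] + seq_len(ep) - 1L
      data[, idx] <- data[, idx] + outer(topo, tpl)
    }
  })
  rownames(data) <- channels
  eeg_recording(data, timing$fs, events, targets, t_epoch = timing$t_epoch)
}
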