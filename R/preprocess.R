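## Preprocessing chain: narrowband 0.1-20 Hz filtering, epoch extraction,
## decimation, feature assembly, round averaging.
##
## No DSP package is assumed: the Butterworth bandpass is designed from the
## analog prototype (poles on the unit circle), transformed lowpass->bandpass,
## discretized by the bilinear transform, and applied as a cascade of
## second-order sections. SOS form matters here: with a 0.1 Hz lower edge at
## fs = 250 Hz a single 8th-order polynomial is numerically fragile.

#' Design a Butterworth bandpass as second-order sections
#'
#' Order follows the scipy/Matlab convention: `order` is the analog lowpass
#' prototype order, so the bandpass has `2 * order` poles.
#'
#' @param low,high band edges, Hz.
#' @param fs sampling rate, Hz.
#' @param order prototype order (default 4, i.e. an 8-pole bandpass).
#' @return matrix with `order` rows and columns `b0,b1,b2,a1,a2`.
#' @keywords internal
butter_bandpass_sos <- function(low, high, fs, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_config("band edges must satisfy 0 < low < high < fs/2")
  }
  fs2 <- 2 * fs
  wl <- fs2 * tan(pi * low / fs)     # pre-warped analog edges
  wh <- fs2 * tan(pi * high / fs)
  bw <- wh - wl
  w0 <- sqrt(wl * wh)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # Re < 0
  # lowpass -> bandpass: each prototype pole spawns the roots of
  # s^2 - bw*p*s + w0^2 = 0
  bp <- unlist(lapply(proto, function(p) {
    disc <- sqrt((bw * p)^2 - 4 * w0^2)
    c((bw * p + disc) / 2, (bw * p - disc) / 2)
  }))
  zp <- (1 + bp / fs2) / (1 - bp / fs2)  # bilinear
  # pair conjugate poles into biquads; each biquad takes one zero at +1
  # (from s = 0) and one at -1 (from s = infinity)
  upper <- zp[Im(zp) > 1e-12]
  reals <- sort(Re(zp[abs(Im(zp)) <= 1e-12]))
  pairs <- lapply(upper, function(p) c(p, Conj(p)))
  if (length(reals)) {
    pairs <- c(pairs, lapply(seq(1, length(reals), by = 2),
                             function(i) complex(real = reals[i + 0:1])))
  }
  stopifnot(length(pairs) == order)
  sos <- t(vapply(pairs, function(pp) {
    a <- Re(c(1, -(pp[1] + pp[2]), pp[1] * pp[2]))
    c(1, 0, -1, a[2], a[3])
  }, numeric(5)))
  colnames(sos) <- c("b0", "b1", "b2", "a1", "a2")
  # unit gain at the (warped) digital center frequency, split across sections
  wc <- 2 * atan(w0 / fs2)
  g <- 1 / abs(freqz_sos(sos, wc * fs / (2 * pi), fs))
  sos[, 1:3] <- sos[, 1:3] * g^(1 / order)
  sos
}

#' Frequency response of an SOS cascade
#'
#' @param sos section matrix from [butter_bandpass_sos()].
#' @param f frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @return complex response at each frequency.
#' @keywords internal
freqz_sos <- function(sos, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] * z1 + sos[s, 3] * z1^2) /
      (1 + sos[s, 4] * z1 + sos[s, 5] * z1^2)
  }
  h
}

# causal biquad cascade on one signal vector
sosfilt1 <- function(sos, x) {
  n <- length(x)
  for (s in seq_len(nrow(sos))) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    y <- b0 * x
    if (n > 1) y[-1] <- y[-1] + b1 * x[-n]
    if (n > 2) y[-(1:2)] <- y[-(1:2)] + b2 * x[seq_len(n - 2)]
    x <- as.numeric(stats::filter(y, -sos[s, 4:5], method = "recursive"))
  }
  x
}

#' Bandpass-filter a recording
#'
#' Forward-only (causal) Butterworth filtering of every channel, matching
#' what an online decoding loop can actually compute. DC is rejected by the
#' bandpass itself.
#'
#' @param recording an [eeg_recording()].
#' @param low,high band edges in Hz (defaults 0.1 and 20).
#' @param order prototype order, see [butter_bandpass_sos()].
#' @return a filtered [eeg_recording()] with identical events.
#' @export
bandpass <- function(recording, low = 0.1, high = 20, order = 4) {
  if (!inherits(recording, "eeg_recording")) stop_config("recording must be an eeg_recording")
  sos <- butter_bandpass_sos(low, high, recording$fs, order)
  out <- recording
  out$data <- t(apply(recording$data, 1, function(ch) sosfilt1(sos, ch)))
  rownames(out$data) <- recording$channel_names
  out
}

#' Extract per-flash analysis epochs
#'
#' One epoch per flash event, `t_epoch` seconds from onset (150 samples at
#' 250 Hz / 600 ms). Epochs overlap when the ISI is shorter than the epoch.
#'
#' @param recording an [eeg_recording()].
#' @param timing a [session_timing()].
#' @return list of `eeg_epoch` objects (fields `data`, `key_id`, `trial`,
#'   `round`, `is_target`).
#' @export
extract_epochs <- function(recording, timing) {
  ep <- epoch_samples(timing)
  ev <- recording$events
  if (!nrow(ev)) return(list())
  over <- which(ev$onset_sample + ep - 1L > ncol(recording$data))
  if (length(over)) {
    stop_config("epoch window overruns data for event at row ", over[1],
                " (onset ", ev$onset_sample[over[1]], ")")
  }
  lapply(seq_len(nrow(ev)), function(i) {
    structure(list(
      data = recording$data[, ev$onset_sample[i] + seq_len(ep) - 1L, drop = FALSE],
      key_id = ev$key_id[i], trial = ev$trial[i], round = ev$round[i],
      is_target = if ("is_target" %in% names(ev)) ev$is_target[i] else NA),
      class = "eeg_epoch")
  })
}

#' Decimate an epoch
#'
#' Plain subsampling, keeping indices `0, step, 2*step, ...` (0-based). The
#' preceding 0.1-20 Hz bandpass already suppresses content above the
#' decimated Nyquist, so no extra anti-alias filter is applied. Default step
#' 6 turns 150 samples into 25.
#'
#' @param epoch an `eeg_epoch`.
#' @param step subsampling step (>= 1).
#' @return the decimated `eeg_epoch`.
#' @export
decimate <- function(epoch, step = 6) {
  assert_scalar_num(step, "step", lower = 1)
  keep <- seq(1L, ncol(epoch$data), by = as.integer(step))
  epoch$data <- epoch$data[, keep, drop = FALSE]
  epoch
}

#' Assemble the feature vector of an epoch
#'
#' Channel-major concatenation: all retained samples of channel 1, then
#' channel 2, etc. With 30 channels and 25 retained samples the feature
#' length is P = 750.
#'
#' @param epoch a (decimated) `eeg_epoch`.
#' @return numeric feature vector with attributes `key_id`, `trial`, `round`.
#' @export
featurize <- function(epoch) {
  x <- as.vector(t(epoch$data))
  attr(x, "key_id") <- epoch$key_id
  attr(x, "trial") <- epoch$trial
  attr(x, "round") <- epoch$round
  x
}

#' Average feature vectors across rounds
#'
#' Element-wise mean of one key's feature vectors over rounds `1..M`; the
#' noise variance of the average falls as 1/M while the event-locked P300
#' component is preserved.
#'
#' @param features list of equal-length numeric vectors.
#' @return numeric vector, the element-wise mean.
#' @export
average_rounds <- function(features) {
  if (!length(features)) stop_config("cannot average an empty feature list")
  len <- lengths(features)
  if (any(len != len[1])) stop_config("feature vectors must have equal length")
  Reduce(`+`, features) / length(features)
}

#' Compute the feature matrix of a whole session
#'
#' Efficient path equivalent to `featurize(decimate(epoch))` over all events
#' of a band-passed recording, avoiding per-epoch copies.
#'
#' @param recording an [eeg_recording()] (already filtered, or set
#'   `filter = TRUE` to apply the default 0.1-20 Hz bandpass here).
#' @param timing a [session_timing()].
#' @param step decimation step.
#' @param filter if `TRUE`, apply [bandpass()] first.
#' @return list with `features` (P x n_events matrix) and `events`
#'   (the provenance data.frame).
#' @export
session_features <- function(recording, timing, step = 6, filter = FALSE) {
  if (filter) recording <- bandpass(recording, 0.1, 20)
  ep <- epoch_samples(timing)
  keep <- seq(1L, ep, by = as.integer(step)) - 1L
  ev <- recording$events
  if (!nrow(ev)) {
    return(list(features = matrix(0, nrow(recording$data) * length(keep), 0),
                events = ev))
  }
  idx <- outer(ev$onset_sample, keep, `+`)          # n_ev x n_keep
  n_ch <- nrow(recording$data); n_keep <- length(keep); n_ev <- nrow(ev)
  sub <- recording$data[, as.vector(t(idx)), drop = FALSE]
  a <- array(sub, dim = c(n_ch, n_keep, n_ev))
  feats <- matrix(aperm(a, c(2, 1, 3)), n_ch * n_keep, n_ev)
  list(features = feats, events = ev)
}

#' Build a BLDA training set from a labeled recording
#'
#' Filters, epochs, decimates and featurizes the whole recording, augments a
#' constant-1 bias coordinate as the final row, and labels target epochs +1
#' and non-target epochs -1. `Q = N * M * K` columns for a full session.
#'
#' @param recording a labeled [eeg_recording()] (targets present).
#' @param timing a [session_timing()].
#' @param low,high bandpass edges, Hz.
#' @param step decimation step.
#' @return list with `X` ((P+1) x Q matrix, bias last row) and `t`
#'   (+1/-1 labels).
#' @export
build_training_set <- function(recording, timing, low = 0.1, high = 20,
                               step = 6) {
  if (!length(recording$targets)) stop_config("recording has no per-trial targets")
  filtered <- bandpass(recording, low, high)
  sf <- session_features(filtered, timing, step = step)
  tgt <- sf$events$key_id == recording$targets[sf$events$trial]
  X <- rbind(sf$features, 1)
  list(X = X, t = ifelse(tgt, 1, -1), events = sf$events)
}
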