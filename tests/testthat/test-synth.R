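test_that("zero-noise target epochs carry exactly the template", {
  tm <- session_timing()
  spec <- synth_session_spec(n_trials = 1, rounds_per_trial = 1,
                             p300_amplitude = 5, latency_jitter_sd = 0,
                             noise_sd = 0,
                             channel_topography = rep(1, 30), seed = 3)
  rec <- synthesize_recording(spec, tm)
  epochs <- extract_epochs(rec, tm)
  tpl <- p300_template(tm, amplitude = 5)
  tgt <- Filter(function(e) isTRUE(e$is_target), epochs)[[1]]
  expect_equal(tgt$data, outer(rep(1, 30), tpl), ignore_attr = TRUE)
  # a non-target epoch whose window avoids the target's template support
  tgt_onset <- rec$events$onset_sample[rec$events$is_target]
  clear <- which(!rec$events$is_target &
                   (rec$events$onset_sample >= tgt_onset + 0.4 * tm$fs |
                      rec$events$onset_sample + 0.6 * tm$fs <= tgt_onset + 0.2 * tm$fs))
  expect_gt(length(clear), 0)
  expect_equal(max(abs(epochs[[clear[1]]]$data)), 0)
})

test_that("zero amplitude gives indistinguishable target/non-target epochs", {
  tm <- session_timing()
  spec <- synth_session_spec(n_trials = 13, rounds_per_trial = 4,
                             p300_amplitude = 0, noise_sd = 10, seed = 17)
  rec <- synthesize_recording(spec, tm)
  sf <- session_features(rec, tm)
  is_tgt <- rec$events$key_id == rec$targets[rec$events$trial]
  m <- colMeans(sf$features)
  expect_gte(length(m), 200)
  expect_gt(stats::t.test(m[is_tgt], m[!is_tgt])$p.value, 0.01)
})

test_that("a full offline session has N*M*K = 1600 flash events", {
  tm <- session_timing()
  rec <- synthesize_recording(synth_session_spec(seed = 1), tm)
  expect_equal(nrow(rec$events), 40 * 10 * 4)
  expect_equal(length(rec$targets), 40)
})

test_that("identical spec and seed give bit-identical recordings", {
  tm <- session_timing()
  spec <- synth_session_spec(n_trials = 2, rounds_per_trial = 3, seed = 99)
  a <- synthesize_recording(spec, tm)
  b <- synthesize_recording(spec, tm)
  expect_identical(a$data, b$data)
  expect_identical(a$events, b$events)
  expect_identical(a$targets, b$targets)
})

test_that("target/non-target separability is monotone in P300 amplitude", {
  tm <- session_timing()
  # discriminant: mean amplitude over parietal/occipital channels in the
  # 200-400 ms window (feature rows: channel-major, 25 samples/channel)
  keep_t <- 10:17                          # decimated samples in [0.2, 0.4] s
  rows <- as.vector(outer(keep_t, (23:30 - 1) * 25, `+`))
  auc <- vapply(c(0, 3, 6, 12), function(amp) {
    spec <- synth_session_spec(n_trials = 32, rounds_per_trial = 4,
                               p300_amplitude = amp, noise_sd = 10,
                               seed = 300)
    rec <- synthesize_recording(spec, tm)
    sf <- session_features(rec, tm)
    is_tgt <- rec$events$key_id == rec$targets[rec$events$trial]
    score <- colMeans(sf$features[rows, ])
    r <- rank(score)
    n1 <- sum(is_tgt); n0 <- sum(!is_tgt)
    (sum(r[is_tgt]) - n1 * (n1 + 1) / 2) / (n1 * n0)   # rank-sum AUC
  }, numeric(1))
  expect_true(all(diff(auc) >= -0.01))
  expect_lt(abs(auc[1] - 0.5), 0.06)       # chance at zero amplitude
  expect_gt(auc[4], 0.85)
})

test_that("recordings round-trip through plain-text files bit-exactly", {
  tm <- session_timing()
  rec <- synthesize_recording(
    synth_session_spec(n_trials = 1, rounds_per_trial = 2, seed = 7), tm)
  stem <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_identical(rec$data, back$data)
  expect_equal(rec$events$onset_sample, back$events$onset_sample)
  expect_equal(rec$events$key_id, back$events$key_id)
  expect_identical(rec$targets, back$targets)
})

test_that("malformed event sidecars raise parse errors naming the fault", {
  tm <- session_timing()
  rec <- synthesize_recording(
    synth_session_spec(n_trials = 1, rounds_per_trial = 1, seed = 7), tm)
  stem <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, stem)
  ev_path <- paste0(stem, ".events.tsv")
  lines <- readLines(ev_path)
  # truncate the last line mid-field
  writeLines(c(lines[1:4], substr(lines[5], 1, 4)), ev_path)
  expect_error(read_recording(stem), class = "assistbci_parse_error")
  # drop a required column entirely
  writeLines(gsub("key_id", "key", lines), ev_path)
  expect_error(read_recording(stem), "key_id",
               class = "assistbci_parse_error")
})

test_that("a recording with zero events round-trips as a valid object", {
  empty <- eeg_recording(matrix(0, 3, 100, dimnames = list(paste0("c", 1:3), NULL)),
                         fs = 250,
                         events = data.frame(onset_sample = integer(),
                                             key_id = integer(),
                                             round = integer(),
                                             trial = integer()))
  stem <- file.path(withr::local_tempdir(), "empty")
  write_recording(empty, stem)
  back <- read_recording(stem)
  expect_equal(nrow(back$events), 0)
  expect_identical(empty$data, back$data)
})
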