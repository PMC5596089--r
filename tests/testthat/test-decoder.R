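# a hand-made linear model whose score is w'x + b, for decoder unit tests
toy_model <- function(w, b = 0) {
  structure(list(m = c(w, b), C = diag(length(w) + 1), alpha = 1, beta = 1,
                 epsilon = 1e-10, n_iter = 0, converged = TRUE,
                 p_prime = length(w) + 1L),
            class = "blda_model")
}

test_that("score normalization is shift-invariant and sums to one", {
  expect_equal(normalize_scores(c(3, 1, 1, 1)), c(1, 0, 0, 0))
  expect_equal(normalize_scores(rep(2.7, 4)), rep(0.25, 4))
  mu <- c(0.3, -1.2, 4.5, 0.3)
  expect_equal(normalize_scores(mu + 17), normalize_scores(mu))
  expect_equal(sum(normalize_scores(mu)), 1)
  expect_error(normalize_scores(c(1, NA)), class = "assistbci_config_error")
})

test_that("decode_step stops by threshold, cap, and ties deterministically", {
  tm <- session_timing()
  model <- toy_model(c(1, 0, 0))
  sep <- matrix(0, 3, 4); sep[1, 2] <- 5     # key 2 clearly wins
  st <- decode_state(4, 3)
  for (r in 1:3) st <- decode_step(st, sep, model, theta0 = 0, timing = tm)
  expect_equal(st$M, 3L)                     # theta0 = 0: stop at m_min
  expect_equal(st$decision, 2L)

  tied <- matrix(0, 3, 4)                    # all keys identical
  st <- decode_state(4, 3)
  for (r in 1:8) {
    st <- decode_step(st, tied, model, theta0 = 0.99, timing = tm)
    if (!is.na(st$decision)) break
  }
  expect_equal(st$M, 8L)                     # forced at m_max
  expect_equal(st$decision, 1L)              # tie -> lowest key id
  expect_true(st$tie)
})

test_that("permuting key labels permutes the decision identically", {
  tm <- session_timing()
  model <- toy_model(c(1, -1))
  set.seed(8)
  rf <- matrix(stats::rnorm(2 * 4), 2, 4)
  st <- decode_state(4, 2)
  st <- decode_step(st, rf, model, 0, tm); st <- decode_step(st, rf, model, 0, tm)
  st <- decode_step(st, rf, model, 0, tm)
  perm <- c(3, 1, 4, 2)                  # new key j holds old key perm[j]
  stp <- decode_state(4, 2)
  rfp <- rf[, perm]
  for (r in 1:3) stp <- decode_step(stp, rfp, model, 0, tm)
  expect_equal(perm[stp$decision], st$decision)
})

test_that("accumulated means equal recomputation from scratch", {
  tm <- session_timing()
  model <- toy_model(stats::rnorm(5), b = 0.3)
  set.seed(21)
  rounds <- lapply(1:6, function(r) matrix(stats::rnorm(5 * 4), 5, 4))
  st <- decode_state(4, 5)
  for (r in 1:6) {
    st <- decode_step(st, rounds[[r]], model, theta0 = 2, timing = tm)
    # brute-force oracle: recompute per-key means over rounds 1..r
    mu_oracle <- vapply(1:4, function(k) {
      mk <- Reduce(`+`, lapply(rounds[1:r], function(m) m[, k])) / r
      sum(model$m * c(mk, 1))
    }, numeric(1))
    expect_equal(st$scores_raw, mu_oracle)
    if (!is.na(st$decision)) break
  }
})

test_that("online simulation respects stopping bounds and theta0 = 0", {
  fx <- highsnr_model()
  sim <- simulate_online(fx$rec, fx$model, theta0 = 0, timing = fx$tm)
  expect_true(all(sim$trials$M == 3))
  expect_equal(sim$mean_M, 3)
  expect_equal(sim$mean_selection_s, 3.6)
  sim2 <- simulate_online(fx$rec, fx$model, theta0 = 0.6, timing = fx$tm)
  expect_true(all(sim2$trials$M >= fx$tm$m_min & sim2$trials$M <= fx$tm$m_max))
})

test_that("the Wolpaw rate reproduces its worked examples", {
  expect_equal(itr_bits_per_min(4, 1.0, 3.6), 33 + 1 / 3, tolerance = 1e-9)
  expect_equal(itr_bits_per_min(4, 0.25, 5), 0, tolerance = 1e-12)
  expect_equal(itr_bits_per_min(4, 1.0, 7.2), 16 + 2 / 3, tolerance = 1e-9)
  expect_equal(itr_bits_per_min(4, 0, 1), 60 * (2 - log2(3)))  # p = 0 limit
  expect_error(itr_bits_per_min(4, 0.5, 0), class = "assistbci_config_error")
})

test_that("threshold selection picks the first accuracy peak", {
  fx <- highsnr_model()
  tc <- select_threshold(fx$rec, fx$model, fx$tm,
                         grid = seq(0, 0.8, by = 0.2))
  expect_equal(tc$chosen, tc$grid[which(tc$accuracy == max(tc$accuracy))[1]])
  # high-SNR session: accuracy is flat at 1, so the minimum grid point wins
  expect_equal(tc$chosen, 0)
  # and ITR never increases with theta0
  expect_true(all(diff(tc$itr) <= 1e-9))
  expect_error(select_threshold(fx$rec, fx$model, fx$tm, grid = numeric()),
               class = "assistbci_config_error")
})
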