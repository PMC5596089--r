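# Independent oracles: dense solves and closed-form ridge, written plainly
# against base R so they share no code with the fitting path.

dense_posterior_oracle <- function(X, t, alpha, beta, eps) {
  Pp <- nrow(X)
  A <- beta * X %*% t(X) + diag(c(rep(alpha, Pp - 1), eps))
  list(m = solve(A, beta * X %*% t), A = A)
}

random_system <- function(p_prime, q, seed) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm((p_prime - 1) * q), p_prime - 1, q), 1)
  t <- sample(c(-1, 1), q, replace = TRUE, prob = c(0.75, 0.25))
  if (length(unique(t)) == 1) t[1] <- -t[1]
  list(X = X, t = t)
}

test_that("posterior mean at fixed precisions matches a dense solve", {
  for (seed in 1:5) {
    sys <- random_system(31, 120, seed)
    alpha <- stats::runif(1, 0.1, 10); beta <- stats::runif(1, 0.1, 10)
    fit <- fit_blda(sys$X, sys$t, epsilon = 1e-10, alpha = alpha,
                    beta = beta, max_iter = 0)
    oracle <- dense_posterior_oracle(sys$X, sys$t, alpha, beta, 1e-10)
    expect_lt(max(abs(fit$m - oracle$m)), 1e-8)
    expect_lt(max(abs(fit$C %*% oracle$A - diag(31))), 1e-8)
  }
})

test_that("a uniform prior reduces to closed-form ridge regression", {
  sys <- random_system(21, 100, 7)
  alpha <- 2.5; beta <- 4
  fit <- fit_blda(sys$X, sys$t, epsilon = alpha, alpha = alpha, beta = beta,
                  max_iter = 0)
  ridge <- solve(sys$X %*% t(sys$X) + (alpha / beta) * diag(21),
                 sys$X %*% sys$t)
  expect_equal(as.numeric(fit$m), as.numeric(ridge), tolerance = 1e-10)
})

test_that("evidence iterations recover known weights and noise precision", {
  set.seed(123)
  q <- 2000; p <- 10
  w <- stats::rnorm(p, sd = 1)
  beta_true <- 4                       # noise sd 0.5
  X <- rbind(matrix(stats::rnorm(p * q), p, q), 1)
  t <- as.numeric(crossprod(X[1:p, , drop = FALSE], w)) +
    stats::rnorm(q, sd = 1 / sqrt(beta_true))
  fit <- fit_blda(X, t)
  expect_true(fit$converged)
  rel <- sqrt(sum((fit$m[1:p] - w)^2) / sum(w^2))
  expect_lt(rel, 0.05)
  expect_gt(fit$beta, beta_true / 2)
  expect_lt(fit$beta, beta_true * 2)
})

test_that("predictive mean is the linear score m'x", {
  sys <- random_system(11, 60, 3)
  fit <- fit_blda(sys$X, sys$t, max_iter = 0)
  expect_equal(predict_mean(fit, rep(0, 10)), fit$m[11])   # bias weight
  e3 <- fit; e3$m <- replace(rep(0, 11), 3, 1)
  x <- stats::rnorm(10)
  expect_equal(predict_mean(e3, x), x[3])
  expect_equal(predict_mean(fit, c(2 * x, 2)),
               2 * predict_mean(fit, c(x, 1)))
  expect_error(predict_mean(fit, rep(0, 5)), class = "assistbci_config_error")
})

test_that("predictive variance respects the 1/beta noise floor", {
  sys <- random_system(11, 60, 4)
  fit <- fit_blda(sys$X, sys$t, max_iter = 0, alpha = 1, beta = 2)
  expect_equal(predict_variance(fit, rep(0, 11)), 1 / fit$beta)
  set.seed(1)
  for (i in 1:1000) {
    expect_gte(predict_variance(fit, stats::rnorm(10)), 1 / fit$beta)
  }
  x <- stats::rnorm(11)
  quad <- function(v) predict_variance(fit, v) - 1 / fit$beta
  expect_equal(quad(2 * x), 4 * quad(x))
})

test_that("degenerate inputs are rejected with guidance", {
  X <- rbind(matrix(stats::rnorm(20), 2, 10), 1)
  expect_error(fit_blda(X, rep(1, 10)), class = "assistbci_config_error")
  expect_error(fit_blda(X, c(1, -1)), class = "assistbci_config_error")
})

test_that("models survive serialization with provenance", {
  sys <- random_system(11, 60, 5)
  fit <- fit_blda(sys$X, sys$t)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_blda(fit, path, channels = paste0("ch", 1:2), step = 6)
  back <- read_blda(path)
  expect_equal(back$m, fit$m)
  expect_equal(back$alpha, fit$alpha)
  expect_equal(back$step, 6)
  x <- stats::rnorm(10)
  expect_equal(predict_mean(back, x), predict_mean(fit, x))
})
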