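## Bayesian linear discriminant analysis.
##
## Regression of +/-1 epoch labels onto feature vectors under a Gaussian
## likelihood (noise precision beta) and a zero-mean Gaussian prior with
## precision alpha on the P feature weights and a near-flat precision
## epsilon on the constant-1 bias weight appended as the LAST coordinate.
## The posterior over weights is Gaussian with
##    m = beta * (beta * X X' + I'(alpha))^-1 X t
##    C =        (beta * X X' + I'(alpha))^-1
## where I'(alpha) = diag(alpha, ..., alpha, epsilon). alpha and beta are
## estimated by evidence (marginal-likelihood) maximization in MacKay's
## fixed-point form:
##    gamma = sum_i  beta*lambda_i / (beta*lambda_i + alpha)
##    alpha <- gamma / (m' m  over feature slots)
##    beta  <- (Q - gamma) / ||X' m - t||^2
## with lambda_i the eigenvalues of the feature-block X X' (bias excluded).

iprime <- function(p_prime, alpha, epsilon) {
  d <- rep(alpha, p_prime)
  d[p_prime] <- epsilon
  d
}

#' Fit a Bayesian linear discriminant model
#'
#' @param X feature matrix, (P+1) x Q, columns are bias-augmented feature
#'   vectors (bias = 1 in the last row, as produced by
#'   [build_training_set()]).
#' @param t length-Q label vector in \{-1, +1\}.
#' @param epsilon bias-weight prior precision; small = near-flat.
#' @param alpha,beta initial (or, with `max_iter = 0`, fixed) precisions.
#' @param tol relative-change stopping tolerance on (alpha, beta).
#' @param max_iter evidence iterations; `0` keeps `alpha`, `beta` fixed and
#'   performs a single posterior solve.
#' @return object of class `blda_model` with fields `m`, `C` (computed
#'   lazily by [predict_variance()] if `keep_C = FALSE`), `alpha`, `beta`,
#'   `epsilon`, `n_iter`, `converged`.
#' @param keep_C store the (P+1)x(P+1) posterior covariance (needed by
#'   [predict_variance()]).
#' @export
fit_blda <- function(X, t, epsilon = 1e-10, alpha = 1, beta = 1,
                     tol = 1e-6, max_iter = 500, keep_C = TRUE) {
  if (!is.matrix(X)) stop_config("X must be a matrix")
  Q <- ncol(X); Pp <- nrow(X)
  if (length(t) != Q) stop_config("length(t) must equal ncol(X)")
  if (Q < 2) stop_config("need at least two training samples")
  if (length(unique(sign(t))) < 2) stop_config("both classes must be present in t")
  XXt <- tcrossprod(X)
  Xt <- as.vector(X %*% t)
  tt <- sum(t * t)

  solve_posterior <- function(alpha, beta) {
    A <- beta * XXt
    diag(A) <- diag(A) + iprime(Pp, alpha, epsilon)
    ch <- tryCatch(chol(A), error = function(e) {
      stop_config("singular posterior system; increase epsilon or the alpha floor")
    })
    list(m = backsolve(ch, forwardsolve(t(ch), beta * Xt)), chol = ch)
  }

  n_iter <- 0L; converged <- max_iter == 0L
  if (max_iter > 0) {
    # eigenvalues of the feature-block X X' (bias slot excluded from gamma)
    lam <- eigen(XXt[-Pp, -Pp, drop = FALSE], symmetric = TRUE,
                 only.values = TRUE)$values
    lam <- pmax(lam, 0)
    for (it in seq_len(max_iter)) {
      sol <- solve_posterior(alpha, beta)
      m <- sol$m
      gamma <- sum(beta * lam / (beta * lam + alpha))
      mm <- sum(m[-Pp]^2)
      resid <- sum((crossprod(X, m) - t)^2)
      alpha_new <- gamma / max(mm, .Machine$double.eps)
      beta_new <- max(Q - gamma, .Machine$double.eps) / max(resid, .Machine$double.eps)
      rel <- max(abs(alpha_new - alpha) / max(alpha, 1e-300),
                 abs(beta_new - beta) / max(beta, 1e-300))
      alpha <- alpha_new; beta <- beta_new; n_iter <- it
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  sol <- solve_posterior(alpha, beta)
  C <- if (keep_C) chol2inv(sol$chol) else NULL
  structure(list(m = sol$m, C = C, alpha = alpha, beta = beta,
                 epsilon = epsilon, n_iter = n_iter, converged = converged,
                 p_prime = Pp),
            class = "blda_model")
}

#' @export
print.blda_model <- function(x, ...) {
  cat(sprintf("<blda_model> P'=%d | alpha=%.4g beta=%.4g eps=%.3g | %d iter, %s\n",
              x$p_prime, x$alpha, x$beta, x$epsilon, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# append the constant bias coordinate when the caller passed raw features
augment_bias <- function(model, x_hat) {
  if (length(x_hat) == model$p_prime - 1L) x_hat <- c(x_hat, 1)
  if (length(x_hat) != model$p_prime) {
    stop_config("feature length ", length(x_hat), " does not match model P' = ",
                model$p_prime)
  }
  x_hat
}

#' Predictive mean score
#'
#' The decision statistic of the speller: `mu = m' x_hat`. A vector one
#' element shorter than the model is bias-augmented with a trailing 1.
#'
#' @param model a `blda_model`.
#' @param x_hat feature vector (with or without the bias coordinate).
#' @return scalar predictive mean.
#' @export
predict_mean <- function(model, x_hat) {
  sum(model$m * augment_bias(model, x_hat))
}

#' Predictive variance
#'
#' `sigma^2 = 1/beta + x_hat' C x_hat`; never below the noise floor `1/beta`
#' since C is positive semi-definite.
#'
#' @inheritParams predict_mean
#' @return scalar predictive variance.
#' @export
predict_variance <- function(model, x_hat) {
  if (is.null(model$C)) stop_config("model was fitted with keep_C = FALSE")
  x_hat <- augment_bias(model, x_hat)
  1 / model$beta + as.numeric(crossprod(x_hat, model$C %*% x_hat))
}

#' Serialize / restore a fitted model
#'
#' Plain-JSON archive holding the posterior, precisions, and the
#' preprocessing provenance needed to apply the model (channel order,
#' decimation step), self-describing via a `format` header.
#'
#' @param model a `blda_model`.
#' @param path file path.
#' @param channels,step optional provenance stored alongside the weights.
#' @return `path` (write) or a `blda_model` (read).
#' @export
write_blda <- function(model, path, channels = NULL, step = NULL) {
  jsonlite::write_json(
    list(format = "assistbci-blda-1", m = model$m, C = model$C,
         alpha = model$alpha, beta = model$beta, epsilon = model$epsilon,
         n_iter = model$n_iter, converged = model$converged,
         channels = channels, step = step),
    path, auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_blda
#' @export
read_blda <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "assistbci-blda-1")) {
    stop_parse(path, ": not an assistbci BLDA model file")
  }
  structure(list(m = o$m, C = o$C, alpha = o$alpha, beta = o$beta,
                 epsilon = o$epsilon, n_iter = o$n_iter,
                 converged = o$converged, p_prime = length(o$m),
                 channels = o$channels, step = o$step),
            class = "blda_model")
}
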