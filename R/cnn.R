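## Convolutional recognizer for beverage-container crops.
##
## Four 3x3 same-padded convolution stages (32, 64, 128, 256 kernels), each
## followed by ReLU and 2x2 max-pooling, then four fully connected stages
## (256, 128, 64, 4) with ReLU between them, dropout (p = 0.5) between the
## third and fourth, and a 4-way softmax. No autodiff stack is available in
## this environment, so convolutions are evaluated as im2col matrix
## products against BLAS and gradients are derived by hand; Adam is the
## optimizer. Images are H x W x C arrays with values in [0, 1].

#' Architecture specification of the recognizer
#'
#' @param input `c(channels, height, width)`; height and width must be at
#'   least 16 so that four 2x2 poolings remain valid.
#' @param conv_channels kernels per convolution stage.
#' @param fc_sizes widths of the fully connected stages (last = classes).
#' @param dropout_p dropout probability between the last two FC stages.
#' @return an object of class `cnn_spec`.
#' @export
cnn_spec <- function(input = c(3, 200, 200),
                     conv_channels = c(32, 64, 128, 256),
                     fc_sizes = c(256, 128, 64, 4), dropout_p = 0.5) {
  hw <- input[2:3]
  for (s in seq_along(conv_channels)) {
    if (any(hw < 2)) {
      stop_config("input too small: 2x2 max-pool after conv stage ", s,
                  " would see a ", hw[1], "x", hw[2], " map")
    }
    hw <- hw %/% 2
  }
  structure(list(input = input, conv_channels = conv_channels,
                 fc_sizes = fc_sizes, dropout_p = dropout_p),
            class = "cnn_spec")
}

# im2col gather indices for a same-padded 3x3 convolution over an
# H x W x C input; index 0 marks padding (reads as 0)
im2col_idx <- function(h, w, c) {
  hp <- h + 2L; wp <- w + 2L
  oi <- rep(seq_len(h), times = w)          # output pixel rows
  oj <- rep(seq_len(w), each = h)
  cols <- matrix(0L, h * w, 9L * c)
  col <- 0L
  for (ch in seq_len(c)) {
    base <- (ch - 1L) * hp * wp
    for (kj in 0:2) for (ki in 0:2) {
      col <- col + 1L
      cols[, col] <- base + (oj + kj - 1L) * hp + (oi + ki)
    }
  }
  cols
}

conv_layer <- function(h, w, c_in, c_out) {
  # He-initialized weights, ordered (ki, kj, c_in) x c_out to match the
  # column layout of im2col_idx
  fan_in <- 9 * c_in
  list(type = "conv", h = h, w = w, c_in = c_in, c_out = c_out,
       W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                  fan_in, c_out),
       b = numeric(c_out),
       idx = im2col_idx(h, w, c_in))
}

fc_layer <- function(n_in, n_out) {
  list(type = "fc", n_in = n_in, n_out = n_out,
       W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

#' Build a recognizer from its specification
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `cnn_model`; `cnn_architecture()` lists the
#'   stage sequence and per-layer parameter counts.
#' @export
build_cnn <- function(spec, seed = NULL) {
  if (!inherits(spec, "cnn_spec")) stop_config("spec must be a cnn_spec")
  with_seed(seed, {
    layers <- list()
    c_in <- spec$input[1]; h <- spec$input[2]; w <- spec$input[3]
    for (c_out in spec$conv_channels) {
      layers[[length(layers) + 1L]] <- conv_layer(h, w, c_in, c_out)
      layers[[length(layers) + 1L]] <- list(type = "pool", h = h, w = w,
                                            c = c_out)
      h <- h %/% 2L; w <- w %/% 2L; c_in <- c_out
    }
    n_in <- h * w * c_in
    n_fc <- length(spec$fc_sizes)
    for (i in seq_len(n_fc)) {
      if (i == n_fc) {
        layers[[length(layers) + 1L]] <- list(type = "dropout",
                                              p = spec$dropout_p)
      }
      layers[[length(layers) + 1L]] <- fc_layer(n_in, spec$fc_sizes[i])
      n_in <- spec$fc_sizes[i]
    }
    structure(list(spec = spec, layers = layers), class = "cnn_model")
  })
}

#' Stage-by-stage architecture audit
#'
#' @param model a `cnn_model`.
#' @return data.frame with one row per stage: type, output shape, parameter
#'   count.
#' @export
cnn_architecture <- function(model) {
  rows <- lapply(model$layers, function(l) {
    switch(l$type,
      conv = data.frame(type = "conv", shape = sprintf("%dx%dx%d", l$h, l$w, l$c_out),
                        params = length(l$W) + length(l$b)),
      pool = data.frame(type = "maxpool", shape = sprintf("%dx%dx%d", l$h %/% 2, l$w %/% 2, l$c),
                        params = 0L),
      fc = data.frame(type = "fc", shape = sprintf("%d", l$n_out),
                      params = length(l$W) + length(l$b)),
      dropout = data.frame(type = "dropout", shape = sprintf("p=%g", l$p),
                           params = 0L))
  })
  do.call(rbind, rows)
}

#' @export
print.cnn_model <- function(x, ...) {
  a <- cnn_architecture(x)
  cat(sprintf("<cnn_model> input %s | %s | %d parameters\n",
              paste(x$spec$input, collapse = "x"),
              paste(a$type, collapse = "-"), sum(a$params)))
  invisible(x)
}

conv_forward <- function(layer, x) {
  hp <- layer$h + 2L; wp <- layer$w + 2L
  pad <- array(0, c(hp, wp, layer$c_in))
  pad[2:(hp - 1L), 2:(wp - 1L), ] <- x
  cols <- matrix(pad[layer$idx], nrow(layer$idx), ncol(layer$idx))
  z <- sweep(cols %*% layer$W, 2, layer$b, `+`)
  a <- pmax(z, 0)
  list(out = array(a, c(layer$h, layer$w, layer$c_out)),
       cols = cols, active = z > 0)
}

conv_backward <- function(layer, cache, d_out, need_dx) {
  dz <- matrix(d_out, layer$h * layer$w, layer$c_out) * cache$active
  dW <- crossprod(cache$cols, dz)
  db <- colSums(dz)
  dx <- NULL
  if (need_dx) {
    d_cols <- tcrossprod(dz, layer$W)
    hp <- layer$h + 2L; wp <- layer$w + 2L
    d_pad <- numeric(hp * wp * layer$c_in)
    for (k in seq_len(ncol(layer$idx))) {
      ik <- layer$idx[, k]
      d_pad[ik] <- d_pad[ik] + d_cols[, k]
    }
    d_pad <- array(d_pad, c(hp, wp, layer$c_in))
    dx <- d_pad[2:(hp - 1L), 2:(wp - 1L), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

pool_forward <- function(layer, x) {
  ho <- layer$h %/% 2L; wo <- layer$w %/% 2L
  ri <- seq_len(2L * ho); ci <- seq_len(2L * wo)
  x <- x[ri, ci, , drop = FALSE]
  q <- list(x[c(TRUE, FALSE), c(TRUE, FALSE), , drop = FALSE],
            x[c(FALSE, TRUE), c(TRUE, FALSE), , drop = FALSE],
            x[c(TRUE, FALSE), c(FALSE, TRUE), , drop = FALSE],
            x[c(FALSE, TRUE), c(FALSE, TRUE), , drop = FALSE])
  out <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  # argmax quadrant for backprop; ties break toward the first quadrant
  which_q <- array(1L, dim(out))
  best <- q[[1]]
  for (i in 2:4) {
    better <- q[[i]] > best
    which_q[better] <- i
    best[better] <- q[[i]][better]
  }
  list(out = out, which_q = which_q, ho = ho, wo = wo)
}

pool_backward <- function(layer, cache, d_out) {
  ho <- cache$ho; wo <- cache$wo
  dx <- array(0, c(layer$h, layer$w, layer$c))
  off <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (i in 1:4) {
    sel <- cache$which_q == i
    sub <- array(0, c(ho, wo, layer$c))
    sub[sel] <- d_out[sel]
    dx[seq(off[[i]][1], by = 2L, length.out = ho),
       seq(off[[i]][2], by = 2L, length.out = wo), ] <- sub
  }
  dx
}

# full forward pass for one image; training mode samples dropout
cnn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  n_layers <- length(model$layers)
  last_fc <- max(which(vapply(model$layers, `[[`, character(1), "type") == "fc"))
  for (i in seq_len(n_layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      cf <- conv_forward(l, x)
      caches[[i]] <- cf; x <- cf$out
    } else if (l$type == "pool") {
      pf <- pool_forward(l, x)
      caches[[i]] <- pf; x <- pf$out
    } else if (l$type == "dropout") {
      x <- as.numeric(x)
      if (training && l$p > 0) {
        mask <- stats::rbinom(length(x), 1, 1 - l$p) / (1 - l$p)
        x <- x * mask
        caches[[i]] <- list(mask = mask)
      } else {
        caches[[i]] <- list(mask = rep(1, length(x)))
      }
    } else {  # fc
      v <- as.numeric(x)
      z <- as.numeric(crossprod(l$W, v)) + l$b
      a <- if (i == last_fc) z else pmax(z, 0)
      caches[[i]] <- list(v = v, active = z > 0)
      x <- a
    }
  }
  z <- as.numeric(x)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  list(probs = p, caches = caches)
}

# backward pass; returns per-layer parameter gradients
cnn_backward <- function(model, fwd, label) {
  n_layers <- length(model$layers)
  last_fc <- max(which(vapply(model$layers, `[[`, character(1), "type") == "fc"))
  grads <- vector("list", n_layers)
  d <- fwd$probs
  d[label] <- d[label] - 1          # d loss / d logits
  for (i in rev(seq_len(n_layers))) {
    l <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (l$type == "fc") {
      if (i != last_fc) d <- d * cache$active
      grads[[i]] <- list(dW = outer(cache$v, d), db = d)
      d <- as.numeric(l$W %*% d)
    } else if (l$type == "dropout") {
      d <- d * cache$mask
    } else if (l$type == "pool") {
      d <- pool_backward(l, cache, array(d, c(cache$ho, cache$wo, l$c)))
    } else {  # conv
      cb <- conv_backward(l, cache, d, need_dx = i > 1L)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      d <- cb$dx
    }
  }
  grads
}

#' Class probabilities for one crop
#'
#' Inference is deterministic: dropout is disabled and the expected
#' activations are used. Crops not matching the spec input size are resized
#' by nearest neighbor.
#'
#' @param model a trained `cnn_model`.
#' @param crop H x W x C array in [0, 1].
#' @return probability vector over the 4 classes (sums to 1).
#' @export
predict_cnn <- function(model, crop) {
  spec <- model$spec
  d <- dim(crop)
  if (length(d) != 3 || d[3] != spec$input[1]) {
    stop_config("crop must be H x W x ", spec$input[1])
  }
  if (d[1] != spec$input[2] || d[2] != spec$input[3]) {
    crop <- resize_nn(crop, spec$input[2], spec$input[3])
  }
  cnn_forward(model, crop, training = FALSE)$probs
}

# nearest-neighbor spatial resize of an H x W x C array
resize_nn <- function(img, h_out, w_out) {
  d <- dim(img)
  ri <- pmin(pmax(round((seq_len(h_out) - 0.5) * d[1] / h_out + 0.5), 1), d[1])
  ci <- pmin(pmax(round((seq_len(w_out) - 0.5) * d[2] / w_out + 0.5), 1), d[2])
  img[ri, ci, , drop = FALSE]
}

#' Train the recognizer
#'
#' Minimizes softmax cross-entropy with Adam. Deterministic given `seed`
#' (shuffling, dropout and initialization all run under the seeded stream).
#'
#' @param model a `cnn_model` (freshly built or to be fine-tuned).
#' @param dataset a `crop_dataset` (see [crop_dataset()]); training uses the
#'   `train` split.
#' @param epochs passes over the training split; `0` returns the model
#'   unchanged.
#' @param seed integer seed.
#' @param lr Adam step size.
#' @param batch minibatch size.
#' @return list with `model` and `trace` (per-epoch mean loss and training
#'   accuracy).
#' @export
train_cnn <- function(model, dataset, epochs, seed = NULL, lr = 1e-3,
                      batch = 32) {
  tr <- which(dataset$split == "train")
  if (!length(tr)) stop_config("training split is empty")
  n_class <- model$spec$fc_sizes[length(model$spec$fc_sizes)]
  present <- sort(unique(dataset$labels[tr]))
  if (length(present) < n_class) {
    stop_config("class missing from the training split: need all of 1..", n_class)
  }
  if (epochs == 0) {
    return(list(model = model, trace = data.frame(epoch = integer(),
                                                  loss = numeric(),
                                                  accuracy = numeric())))
  }
  # Adam state per parameterized layer
  state <- lapply(model$layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  trace <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                      accuracy = NA_real_)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      order_ <- sample(tr)
      losses <- numeric(0); correct <- logical(0)
      for (start in seq(1, length(order_), by = batch)) {
        ids <- order_[start:min(start + batch - 1, length(order_))]
        acc_grads <- NULL
        for (id in ids) {
          fwd <- cnn_forward(model, dataset$images[[id]], training = TRUE)
          lab <- dataset$labels[id]
          losses <- c(losses, -log(max(fwd$probs[lab], 1e-12)))
          correct <- c(correct, which.max(fwd$probs) == lab)
          g <- cnn_backward(model, fwd, lab)
          if (is.null(acc_grads)) acc_grads <- g else {
            for (i in seq_along(g)) {
              if (!is.null(g[[i]])) {
                acc_grads[[i]]$dW <- acc_grads[[i]]$dW + g[[i]]$dW
                acc_grads[[i]]$db <- acc_grads[[i]]$db + g[[i]]$db
              }
            }
          }
        }
        step <- step + 1
        for (i in seq_along(model$layers)) {
          if (is.null(acc_grads[[i]])) next
          dW <- acc_grads[[i]]$dW / length(ids)
          db <- acc_grads[[i]]$db / length(ids)
          s <- state[[i]]
          s$mW <- b1 * s$mW + (1 - b1) * dW
          s$vW <- b2 * s$vW + (1 - b2) * dW^2
          s$mb <- b1 * s$mb + (1 - b1) * db
          s$vb <- b2 * s$vb + (1 - b2) * db^2
          corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
          model$layers[[i]]$W <- model$layers[[i]]$W -
            lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
          model$layers[[i]]$b <- model$layers[[i]]$b -
            lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
          state[[i]] <- s
        }
      }
      trace$loss[ep] <- mean(losses)
      trace$accuracy[ep] <- mean(correct)
    }
  })
  list(model = model, trace = trace)
}

#' Evaluate accuracy on a dataset split
#'
#' @param model a trained `cnn_model`.
#' @param dataset a `crop_dataset`.
#' @param split `"train"`, `"val"`, or `"all"`.
#' @return fraction of crops whose argmax probability matches the label.
#' @export
cnn_accuracy <- function(model, dataset, split = "val") {
  ids <- if (split == "all") seq_along(dataset$labels) else which(dataset$split == split)
  if (!length(ids)) stop_config("split '", split, "' is empty")
  pred <- vapply(ids, function(i) {
    which.max(predict_cnn(model, dataset$images[[i]]))
  }, numeric(1))
  mean(pred == dataset$labels[ids])
}
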