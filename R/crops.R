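## Synthetic labeled image crops for the recognizer.
##
## Procedurally rendered silhouettes standing in for Kinect RGB crops:
## a pop can is a squat cylinder, a bottle a tall cylinder with a neck, a
## cup a cylinder with a handle, and background a textured patch. Pose,
## size, color and illumination jitter make the classes non-trivial while
## staying fully reproducible. These are SYNTHETIC stand-ins: no real
## camera imagery is involved, so a trained model demonstrates the training
## machinery, not real-world recognition.

crop_classes <- function() c("background", "cup", "bottle", "can")

# low-frequency noise texture in [0, 1]
texture_patch <- function(size) {
  coarse <- matrix(stats::runif(16), 4, 4)
  ri <- pmin(pmax(ceiling(seq_len(size) / size * 4), 1), 4)
  fine <- coarse[ri, ri]
  fine <- fine + matrix(stats::rnorm(size^2, sd = 0.08), size, size)
  pmin(pmax(fine, 0), 1)
}

render_crop <- function(class, size) {
  x <- matrix(rep(seq_len(size), each = size), size, size)   # col coord
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row coord
  cx <- size / 2 + stats::rnorm(1, sd = size * 0.04)
  base <- size * 0.88
  light <- stats::runif(1, 0.75, 1.15)
  col <- stats::runif(3, 0.25, 0.95)
  bgc <- stats::runif(3, 0, 0.35)
  mask <- matrix(FALSE, size, size)
  if (class == "can") {
    hw <- size * stats::runif(1, 0.16, 0.20)
    ht <- size * stats::runif(1, 0.34, 0.42)
    mask <- abs(x - cx) < hw & y > base - ht & y < base
  } else if (class == "bottle") {
    hw <- size * stats::runif(1, 0.11, 0.14)
    ht <- size * stats::runif(1, 0.62, 0.72)
    neck <- size * stats::runif(1, 0.04, 0.06)
    body <- abs(x - cx) < hw & y > base - ht * 0.62 & y < base
    nk <- abs(x - cx) < neck & y > base - ht & y <= base - ht * 0.55
    mask <- body | nk
  } else if (class == "cup") {
    hw <- size * stats::runif(1, 0.15, 0.19)
    ht <- size * stats::runif(1, 0.30, 0.38)
    body <- abs(x - cx) < hw & y > base - ht & y < base
    hc <- cx + hw + size * 0.06
    hy <- base - ht / 2
    rr <- sqrt((x - hc)^2 + (y - hy)^2)
    handle <- rr < size * 0.10 & rr > size * 0.055 & x > cx + hw * 0.8
    mask <- body | handle
  }
  img <- array(0, c(size, size, 3))
  if (class == "background") {
    for (k in 1:3) img[, , k] <- texture_patch(size) * stats::runif(1, 0.4, 1)
  } else {
    shade <- 1 - 0.35 * abs(x - cx) / (size / 2)     # cylindrical shading
    for (k in 1:3) {
      ch <- matrix(bgc[k], size, size)
      ch[mask] <- pmin(col[k] * light * shade[mask], 1)
      img[, , k] <- ch + matrix(stats::rnorm(size^2, sd = 0.02), size, size)
    }
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

#' Bundle crops into a dataset
#'
#' @param images list of H x W x 3 arrays.
#' @param labels integer labels, 1..4 (see [crop_classes()][gen_crops()]).
#' @param split character vector of `"train"` / `"val"`, or `NULL` to split
#'   here.
#' @param train_frac train fraction when splitting (default 0.7, a 7:3
#'   split); splitting is stratified so every class stays present.
#' @param seed seed for the stratified split.
#' @return an object of class `crop_dataset`.
#' @export
crop_dataset <- function(images, labels, split = NULL, train_frac = 0.7,
                         seed = NULL) {
  labels <- as.integer(labels)
  if (!length(images) || length(images) != length(labels)) {
    stop_config("images and labels must be nonempty and equal length")
  }
  if (!all(labels %in% 1:4)) stop_config("labels must be in 1..4")
  if (is.null(split)) {
    split <- rep("val", length(labels))
    with_seed(seed, {
      for (cl in unique(labels)) {
        ids <- which(labels == cl)
        n_tr <- max(1L, round(train_frac * length(ids)))
        split[sample(ids, n_tr)] <- "train"
      }
    })
  }
  structure(list(images = images, labels = labels, split = split,
                 classes = crop_classes()),
            class = "crop_dataset")
}

#' @export
print.crop_dataset <- function(x, ...) {
  cat(sprintf("<crop_dataset> %d crops (%d train / %d val), classes: %s\n",
              length(x$labels), sum(x$split == "train"),
              sum(x$split == "val"), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Generate synthetic labeled crops
#'
#' @param n_per_class crops per class.
#' @param size square crop side, pixels.
#' @param seed integer seed.
#' @param train_frac train fraction of the stratified split.
#' @return a [crop_dataset()] with classes background, cup, bottle, can
#'   (labels 1-4).
#' @export
gen_crops <- function(n_per_class = 20, size = 32, seed = NULL,
                      train_frac = 0.7) {
  classes <- crop_classes()
  with_seed(seed, {
    images <- list(); labels <- integer(0)
    for (cl in seq_along(classes)) {
      for (i in seq_len(n_per_class)) {
        images[[length(images) + 1L]] <- render_crop(classes[cl], size)
        labels <- c(labels, cl)
      }
    }
    crop_dataset(images, labels, seed = NULL)
  })
}

#' Augment a crop dataset
#'
#' Adds a horizontally mirrored copy and a spatially rescaled copy
#' (resampled back to the original size) of every crop; labels and split
#' assignments are preserved, so `n` crops become `3 n`.
#'
#' @param dataset a [crop_dataset()].
#' @param scale spatial rescale factor (1.0 gives a pixel-identical copy).
#' @return the augmented `crop_dataset`.
#' @export
augment_crops <- function(dataset, scale = 0.8) {
  if (!length(dataset$labels)) stop_config("dataset is empty")
  n <- length(dataset$labels)
  images <- dataset$images; labels <- dataset$labels; split <- dataset$split
  for (i in seq_len(n)) {
    img <- dataset$images[[i]]
    images[[length(images) + 1L]] <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    d <- dim(img)
    zoomed <- resize_nn(img, max(1L, round(d[1] * scale)),
                        max(1L, round(d[2] * scale)))
    images[[length(images) + 1L]] <- resize_nn(zoomed, d[1], d[2])
    labels <- c(labels, rep(dataset$labels[i], 2))
    split <- c(split, rep(dataset$split[i], 2))
  }
  crop_dataset(images, labels, split = split)
}
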