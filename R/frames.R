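## Rigid coordinate transforms between the camera (K), calibration-board
## (C) and robot (R) frames. A transform maps points of its `from` frame
## into its `to` frame homogeneously: p_to = R p_from + T.

#' Construct a rigid transform
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param T length-3 translation vector.
#' @param from,to frame labels (e.g. `"camera"`, `"board"`, `"robot"`).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), T = c(0, 0, 0),
                            from = "a", to = "b") {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stop_config("R must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    stop_config("R must be orthonormal (R'R = I within 1e-9)")
  }
  if (abs(det(R) - 1) > 1e-9) stop_config("R must be a proper rotation (det +1)")
  if (length(T) != 3) stop_config("T must have length 3")
  structure(list(R = R, T = as.numeric(T), from = from, to = to),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> %s -> %s, |T| = %.3f\n", x$from, x$to,
              sqrt(sum(x$T^2))))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or 3 x n matrix of points.
#' @return transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 3, 1) else as.matrix(points)
  if (nrow(p) != 3) stop_config("points must be 3 x n")
  out <- transform$R %*% p + transform$T
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' The inverse maps `to` back to `from`: `p = R'(p' - T)`, i.e. rotation
#' `R'` and translation `-R'T`.
#'
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$T),
                  from = transform$to, to = transform$from)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` applies `a` first, then `b` (matrix order),
#' chaining e.g. camera -> board -> robot.
#'
#' @param b,a [rigid_transform()]s with `a$to == b$from`.
#' @return the composed `rigid_transform` from `a$from` to `b$to`.
#' @export
compose_transforms <- function(b, a) {
  if (!identical(a$to, b$from)) {
    stop_config("frames do not chain: ", a$from, "->", a$to, " then ",
                b$from, "->", b$to)
  }
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$T) + b$T,
                  from = a$from, to = b$to)
}

#' Read a calibration file
#'
#' JSON with an `edges` array; each edge has `from`, `to`, `R` (row-major
#' 9-vector or 3x3 nested array) and `T` (3-vector).
#'
#' @param path JSON calibration file.
#' @return named list of [rigid_transform()]s keyed `"from:to"`.
#' @export
read_calibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(o$edges)) stop_parse(path, ": no 'edges' array")
  out <- list()
  for (e in o$edges) {
    Rm <- matrix(as.numeric(unlist(e$R)), 3, 3, byrow = TRUE)
    tr <- rigid_transform(Rm, as.numeric(unlist(e$T)), from = e$from, to = e$to)
    out[[paste0(e$from, ":", e$to)]] <- tr
  }
  out
}
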