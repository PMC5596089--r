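## Organized point clouds and synthetic tabletop scenes.
##
## An organized cloud keeps the depth camera's pixel grid: points is an
## H x W x 3 array of camera-frame coordinates (meters) and every geometric
## operation preserves the pixel <-> point correspondence. Conventions used
## throughout: pixel coordinates are (row, col), camera frame is x right,
## y down, z forward (along the optical axis); the synthetic camera looks
## straight down at the table, so "up" is (0, 0, -1) in camera coordinates.

#' Construct an organized point cloud
#'
#' @param points H x W x 3 numeric array of camera-frame points (meters).
#' @param valid H x W logical mask; invalid pixels are excluded from all
#'   geometry.
#' @param rgb optional H x W x 3 color array in [0, 1].
#' @return an object of class `organized_cloud`.
#' @export
organized_cloud <- function(points, valid, rgb = NULL) {
  d <- dim(points)
  if (length(d) != 3 || d[3] != 3) stop_config("points must be H x W x 3")
  if (!identical(dim(valid), d[1:2])) stop_config("valid mask must be H x W")
  structure(list(points = points, valid = valid, rgb = rgb,
                 h = d[1], w = d[2]),
            class = "organized_cloud")
}

#' @export
print.organized_cloud <- function(x, ...) {
  cat(sprintf("<organized_cloud> %d x %d, %d valid points\n",
              x$h, x$w, sum(x$valid)))
  invisible(x)
}

# 3 x (H*W) matrix view of the points, column-major pixel order
cloud_matrix <- function(cloud) {
  t(matrix(cloud$points, cloud$h * cloud$w, 3))
}

#' Describe a synthetic tabletop scene
#'
#' A horizontal table plane at `plane_depth` meters below a downward-looking
#' pinhole camera, bearing cylinder (cup/can/bottle) and box solids standing
#' on it. Geometry is in meters; object `center` is the (x, y) footprint
#' center on the plane.
#'
#' @param h,w image grid size in pixels.
#' @param f focal length in pixels.
#' @param plane_depth camera-to-table distance along the optical axis, m.
#' @param plane_extent half-widths `c(ex, ey)` of the table, m.
#' @param objects list of object descriptions: for a cylinder
#'   `list(shape = "cylinder", center = c(x, y), radius, height)`, for a box
#'   `list(shape = "box", center = c(x, y), half = c(hx, hy), height)`.
#' @param noise_sd depth noise standard deviation along each ray, m.
#' @param seed integer seed for the noise.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(h = 160, w = 200, f = 180, plane_depth = 0.8,
                       plane_extent = c(0.42, 0.34), objects = list(),
                       noise_sd = 0, seed = NULL) {
  structure(list(h = as.integer(h), w = as.integer(w), f = f,
                 cx = (w + 1) / 2, cy = (h + 1) / 2,
                 plane_depth = plane_depth, plane_extent = plane_extent,
                 objects = objects, noise_sd = noise_sd, seed = seed),
            class = "scene_spec")
}

#' A default three-container scene
#'
#' Cup (short wide cylinder), bottle (tall narrow cylinder) and pop can
#' (mid cylinder) standing on the table, sized to real beverage containers.
#'
#' @param ... overrides forwarded to [scene_spec()].
#' @export
default_scene <- function(...) {
  scene_spec(objects = list(
    list(shape = "cylinder", center = c(-0.25, 0.05), radius = 0.045,
         height = 0.10, label = "cup"),
    list(shape = "cylinder", center = c(0.02, -0.08), radius = 0.035,
         height = 0.24, label = "bottle"),
    list(shape = "cylinder", center = c(0.26, 0.10), radius = 0.033,
         height = 0.12, label = "can")), ...)
}

# Chebyshev dilation of a logical mask by `r` pixels
dilate_mask <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  for (k in seq_len(r)) {
    out <- m
    out[-1, ] <- out[-1, ] | m[-h, ]
    out[-h, ] <- out[-h, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -w]
    out[, -w] <- out[, -w] | m[, -1]
    out[-1, -1] <- out[-1, -1] | m[-h, -w]
    out[-h, -w] <- out[-h, -w] | m[-1, -1]
    out[-1, -w] <- out[-1, -w] | m[-h, -1]
    out[-h, -1] <- out[-h, -1] | m[-1, -w]
    m <- out
  }
  m
}

# ray/solid intersection over the full pixel grid: returns the hit
# parameter t (depth along z) per pixel, Inf where the ray misses
ray_hit_cylinder <- function(dx, dy, obj, z_base) {
  r2 <- obj$radius^2
  z_top <- z_base - obj$height
  # top disk
  x <- z_top * dx - obj$center[1]
  y <- z_top * dy - obj$center[2]
  t_top <- ifelse(x * x + y * y <= r2, z_top, Inf)
  # side wall: |t*(dx,dy) - c|^2 = r^2
  a <- dx * dx + dy * dy
  b <- -2 * (dx * obj$center[1] + dy * obj$center[2])
  cc <- sum(obj$center^2) - r2
  disc <- b * b - 4 * a * cc
  t_side <- array(Inf, dim(dx))
  ok <- disc >= 0 & a > 0
  t1 <- (-b[ok] - sqrt(disc[ok])) / (2 * a[ok])   # nearer wall
  t1[t1 < z_top | t1 > z_base] <- Inf
  t_side[ok] <- t1
  pmin(t_top, t_side)
}

ray_hit_box <- function(dx, dy, obj, z_base) {
  z_top <- z_base - obj$height
  slab <- function(d, lo, hi) {
    # t-interval where t*d is inside [lo, hi]
    t1 <- ifelse(d != 0, lo / d, ifelse(lo <= 0 & hi >= 0, -Inf, Inf))
    t2 <- ifelse(d != 0, hi / d, ifelse(lo <= 0 & hi >= 0, Inf, -Inf))
    list(lo = pmin(t1, t2), hi = pmax(t1, t2))
  }
  sx <- slab(dx, obj$center[1] - obj$half[1], obj$center[1] + obj$half[1])
  sy <- slab(dy, obj$center[2] - obj$half[2], obj$center[2] + obj$half[2])
  enter <- pmax(sx$lo, sy$lo, z_top)
  exit <- pmin(sx$hi, sy$hi, z_base)
  ifelse(enter <= exit, enter, Inf)
}

#' Render an organized cloud from a scene description
#'
#' Per-pixel ray casting from the pinhole model: each pixel's ray is
#' intersected with the table plane and every solid; the nearest hit wins.
#' Pixels whose rays miss everything are invalid.
#'
#' Two label matrices are returned. `raw_labels` is the pure geometric
#' truth per pixel: 0 = plane, i = i-th object, NA = ray miss. `labels`
#' additionally marks a `void_band`-pixel band around every class boundary
#' (including miss boundaries) as NA ("void"): the standard
#' segmentation-benchmark convention for pixels whose class is ill-defined
#' at the sensor's resolution — exactly where a real depth camera's
#' occlusion boundaries are unreliable and where the 4-neighbor normal
#' stencil straddles two surfaces. Per-pixel evaluation uses `labels`;
#' geometric oracles (e.g. ray-cast pixel counts) use `raw_labels`.
#'
#' @param spec a [scene_spec()].
#' @param void_band width in pixels of the boundary band voided in
#'   `labels` (0 disables).
#' @return list with `cloud` (an [organized_cloud()]), `labels` and
#'   `raw_labels` (H x W integer matrices).
#' @export
synth_scene <- function(spec, void_band = 2) {
  if (!inherits(spec, "scene_spec")) stop_config("spec must be a scene_spec")
  if (spec$f <= 0) stop_config("degenerate camera: focal length must be positive")
  h <- spec$h; w <- spec$w
  dx <- matrix((col(matrix(0, h, w)) - spec$cx) / spec$f, h, w)
  dy <- matrix((row(matrix(0, h, w)) - spec$cy) / spec$f, h, w)
  zb <- spec$plane_depth

  px <- zb * dx; py <- zb * dy
  t_best <- ifelse(abs(px) <= spec$plane_extent[1] &
                     abs(py) <= spec$plane_extent[2], zb, Inf)
  labels <- ifelse(is.finite(t_best), 0L, NA_integer_)
  for (i in seq_along(spec$objects)) {
    obj <- spec$objects[[i]]
    t_obj <- switch(obj$shape,
                    cylinder = ray_hit_cylinder(dx, dy, obj, zb),
                    box = ray_hit_box(dx, dy, obj, zb),
                    stop_config("unknown shape: ", obj$shape))
    closer <- t_obj < t_best
    t_best[closer] <- t_obj[closer]
    labels[closer] <- i
  }
  if (spec$noise_sd > 0) {
    t_best <- with_seed(spec$seed, {
      n <- matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
      ifelse(is.finite(t_best), t_best + n, t_best)
    })
  }
  valid <- is.finite(t_best)
  tb <- ifelse(valid, t_best, 0)
  points <- array(c(tb * dx, tb * dy, tb), dim = c(h, w, 3))
  raw_labels <- labels
  if (void_band > 0) {
    # class-boundary edges on the raw labels, ray misses as their own class
    lab <- ifelse(is.na(raw_labels), -1L, raw_labels)
    edge <- matrix(FALSE, h, w)
    d <- lab[-1, ] != lab[-h, ]
    edge[-1, ] <- edge[-1, ] | d
    edge[-h, ] <- edge[-h, ] | d
    d <- lab[, -1] != lab[, -w]
    edge[, -1] <- edge[, -1] | d
    edge[, -w] <- edge[, -w] | d
    void <- dilate_mask(edge | !valid, void_band)
    labels[void] <- NA_integer_
  }
  list(cloud = organized_cloud(points, valid), labels = labels,
       raw_labels = raw_labels)
}

#' Per-pixel surface normals of an organized cloud
#'
#' Cross product of the two pixel-grid difference vectors through each
#' point's 4-neighborhood: `v1 = P(i, j-1) - P(i, j+1)`,
#' `v2 = P(i+1, j) - P(i-1, j)`, `n = v1 x v2`, normalized to unit length.
#' Border pixels and pixels with an invalid neighbor get no normal (NA).
#'
#' @param cloud an [organized_cloud()].
#' @return H x W x 3 array of unit normals (NA where undefined).
#' @export
cloud_normals <- function(cloud) {
  h <- cloud$h; w <- cloud$w
  P <- cloud$points
  shift <- function(a, di, dj) {
    out <- array(NA_real_, dim(a))
    ri <- max(1, 1 + di):min(h, h + di)
    rj <- max(1, 1 + dj):min(w, w + dj)
    out[ri, rj, ] <- a[ri - di, rj - dj, , drop = FALSE]
    out
  }
  okshift <- function(m, di, dj) {
    out <- matrix(FALSE, h, w)
    ri <- max(1, 1 + di):min(h, h + di)
    rj <- max(1, 1 + dj):min(w, w + dj)
    out[ri, rj] <- m[ri - di, rj - dj]
    out
  }
  v1 <- shift(P, 0, 1) - shift(P, 0, -1)   # P(i, j-1) - P(i, j+1)
  v2 <- shift(P, -1, 0) - shift(P, 1, 0)   # P(i+1, j) - P(i-1, j)
  n1 <- v1[, , 2] * v2[, , 3] - v1[, , 3] * v2[, , 2]
  n2 <- v1[, , 3] * v2[, , 1] - v1[, , 1] * v2[, , 3]
  n3 <- v1[, , 1] * v2[, , 2] - v1[, , 2] * v2[, , 1]
  len <- sqrt(n1^2 + n2^2 + n3^2)
  ok <- cloud$valid &
    okshift(cloud$valid, 0, 1) & okshift(cloud$valid, 0, -1) &
    okshift(cloud$valid, -1, 0) & okshift(cloud$valid, 1, 0) &
    is.finite(len) & len > 0
  n1 <- ifelse(ok, n1 / len, NA_real_)
  n2 <- ifelse(ok, n2 / len, NA_real_)
  n3 <- ifelse(ok, n3 / len, NA_real_)
  array(c(n1, n2, n3), dim = c(h, w, 3))
}
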