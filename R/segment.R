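## Region-growing segmentation on organized clouds.
##
## All pixel sets are vectors of linear (column-major) indices into the
## H x W grid. Growth uses 4-connectivity by default — the same neighborhood
## the normal estimation uses — and admits a neighbor when it satisfies the
## stage's predicate and lies within `d_threshold` meters (3D Euclidean) of
## the point it grows from.

# neighbor linear indices for a frontier, per connectivity
neighbor_offsets <- function(h, connectivity) {
  if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
}

# frontier-parallel growth: expand `seeds` through `allowed` pixels,
# admitting an edge when the 3D distance is <= thr (thr = Inf gives plain
# connected growth). Returns the grown set as linear indices.
grow_set <- function(seeds, allowed, P, h, w, thr, connectivity = 4) {
  n <- h * w
  in_set <- logical(n)
  in_set[seeds] <- TRUE
  frontier <- seeds
  offs <- neighbor_offsets(h, connectivity)
  while (length(frontier)) {
    added <- integer(0)
    fr <- ((frontier - 1L) %% h) + 1L
    fc <- ((frontier - 1L) %/% h) + 1L
    for (o in offs) {
      nr <- fr + o[1]; nc <- fc + o[2]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      if (!any(ok)) next
      nb <- (nc[ok] - 1L) * h + nr[ok]
      src <- frontier[ok]
      keep <- allowed[nb] & !in_set[nb]
      if (!any(keep)) next
      nb <- nb[keep]; src <- src[keep]
      if (is.finite(thr)) {
        d2 <- (P[1, nb] - P[1, src])^2 + (P[2, nb] - P[2, src])^2 +
          (P[3, nb] - P[3, src])^2
        pass <- d2 <= thr^2
        nb <- nb[pass]
      }
      if (length(nb)) {
        nb <- unique(nb)
        in_set[nb] <- TRUE
        added <- c(added, nb)
      }
    }
    frontier <- added
  }
  which(in_set)
}

# partition `allowed` pixels into maximal grown regions
grow_components <- function(allowed, P, h, w, thr, connectivity = 4) {
  remaining <- allowed
  regions <- list()
  repeat {
    seed <- which(remaining)[1]
    if (is.na(seed)) break
    reg <- grow_set(seed, remaining, P, h, w, thr, connectivity)
    remaining[reg] <- FALSE
    regions[[length(regions) + 1L]] <- reg
  }
  regions
}

#' Extract horizontal planes by region growing
#'
#' Pixels whose normals are within `angle_tol` of the vertical axis seed a
#' queue-based region growth; a neighbor joins a region when its own normal
#' is near-vertical and it lies within `d_threshold` of the point it grows
#' from. Regions with at least `n_c` pixels are accepted; their union is the
#' horizontal background plane.
#'
#' @param cloud an [organized_cloud()].
#' @param normals array from [cloud_normals()] (computed here if `NULL`).
#' @param up unit vertical axis in camera coordinates (default
#'   `c(0, 0, -1)`: camera looking straight down).
#' @param angle_tol admission tolerance on the normal angle, degrees.
#' @param d_threshold neighbor distance threshold, meters.
#' @param n_c minimum accepted plane size, pixels.
#' @param connectivity 4 (default) or 8.
#' @return a `plane_set`: list of accepted pixel-index sets (`planes`), their
#'   union (`h_plane`), and an H x W membership mask (`mask`).
#' @export
extract_planes <- function(cloud, normals = NULL, up = c(0, 0, -1),
                           angle_tol = 10, d_threshold = 0.02, n_c = 500,
                           connectivity = 4) {
  if (is.null(normals)) normals <- cloud_normals(cloud)
  h <- cloud$h; w <- cloud$w
  up <- up / sqrt(sum(up^2))
  dot <- normals[, , 1] * up[1] + normals[, , 2] * up[2] +
    normals[, , 3] * up[3]
  vertical <- !is.na(dot) & abs(dot) >= cos(angle_tol * pi / 180) & cloud$valid
  P <- cloud_matrix(cloud)
  regions <- grow_components(vertical, P, h, w, d_threshold, connectivity)
  planes <- regions[lengths(regions) >= n_c]
  mask <- matrix(FALSE, h, w)
  for (p in planes) mask[p] <- TRUE
  structure(list(planes = planes, h_plane = which(mask), mask = mask),
            class = "plane_set")
}

#' @export
print.plane_set <- function(x, ...) {
  cat(sprintf("<plane_set> %d plane(s), %d pixels total\n",
              length(x$planes), length(x$h_plane)))
  invisible(x)
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Crossing-number test with an explicit on-segment check so that points
#' lying exactly on a polygon edge or vertex are inside — pass-2 growth
#' seeds live on the hull boundary.
#'
#' @param px,py point coordinates.
#' @param poly k x 2 matrix of polygon vertices (columns x, y), implicitly
#'   closed.
#' @return logical vector.
#' @keywords internal
point_in_poly <- function(px, py, poly) {
  k <- nrow(poly)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- k
  for (i in seq_len(k)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    d <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    onedge <- onedge | (abs(d) < 1e-9 & within)
    j <- i
  }
  inside | onedge
}

#' Candidate object convex hulls
#'
#' Connected components of valid non-plane pixels that are enclosed by the
#' plane's pixel footprint are the object candidates; each component's 2D
#' convex hull in pixel coordinates is returned together with the
#' component. Enclosure is tested on bounding boxes: a candidate must lie
#' strictly inside the plane's bounding box, which keeps on-table objects
#' and rejects the open ring of no-normal pixels that borders the table
#' from outside.
#'
#' @param plane_set result of [extract_planes()].
#' @param cloud the same [organized_cloud()].
#' @param min_size drop components smaller than this many pixels.
#' @param connectivity 4 (default) or 8.
#' @return list of candidates, each `list(poly = k x 2 (col, row) hull
#'   vertices, component = pixel indices)`.
#' @export
object_hulls <- function(plane_set, cloud, min_size = 5, connectivity = 4) {
  if (!length(plane_set$h_plane)) stop_config("plane set is empty")
  h <- cloud$h; w <- cloud$w
  cand <- cloud$valid & !plane_set$mask
  P <- cloud_matrix(cloud)
  comps <- grow_components(cand, P, h, w, Inf, connectivity)
  comps <- comps[lengths(comps) >= min_size]
  pr <- ((plane_set$h_plane - 1L) %% h) + 1L
  pc <- ((plane_set$h_plane - 1L) %/% h) + 1L
  pbox <- c(min(pr), max(pr), min(pc), max(pc))
  out <- list()
  for (idx in comps) {
    r <- ((idx - 1L) %% h) + 1L
    c_ <- ((idx - 1L) %/% h) + 1L
    enclosed <- min(r) > pbox[1] && max(r) < pbox[2] &&
      min(c_) > pbox[3] && max(c_) < pbox[4]
    if (!enclosed) next
    hull <- grDevices::chull(c_, r)
    out[[length(out) + 1L]] <- list(poly = cbind(col = c_[hull], row = r[hull]),
                                    component = idx)
  }
  out
}

#' Two-times region growing object segmentation
#'
#' Pass 1: every valid pixel inside (or on) a candidate hull that is not a
#' plane pixel is an interior point of that object; candidate sets smaller
#' than `n_c_prime` are rejected. Pass 2: interior points on the hull
#' boundary seed a second growth that may cross outside the hull — a
#' neighbor joins when it is valid, not a plane pixel, and within
#' `d_threshold` of the point it grows from — iterated to closure, so object
#' parts protruding past the hull are recovered.
#'
#' @param cloud an [organized_cloud()].
#' @param plane_set result of [extract_planes()].
#' @param hulls result of [object_hulls()] (or hand-built candidates).
#' @param d_threshold neighbor distance threshold, meters.
#' @param n_c_prime minimum accepted object size, pixels.
#' @param connectivity 4 (default) or 8.
#' @return an `object_set`: `objects` (list of pixel-index sets) and their
#'   union `all` (disjoint from the plane).
#' @export
segment_objects <- function(cloud, plane_set, hulls, d_threshold = 0.02,
                            n_c_prime = 50, connectivity = 4) {
  h <- cloud$h; w <- cloud$w
  P <- cloud_matrix(cloud)
  allowed <- cloud$valid & !plane_set$mask
  taken <- logical(h * w)
  objects <- list()
  for (cand in hulls) {
    poly <- cand$poly
    idx_all <- which(allowed & !taken)
    if (!length(idx_all)) break
    r <- ((idx_all - 1L) %% h) + 1L
    c_ <- ((idx_all - 1L) %/% h) + 1L
    ins <- point_in_poly(c_, r, poly)
    m_object <- idx_all[ins]                      # pass-1 interior points
    if (length(m_object) < n_c_prime) next
    # pass 2: seeds are interior points on the hull boundary (a 4-neighbor
    # falls outside the hull, or the pixel sits on the polygon itself)
    rr <- ((m_object - 1L) %% h) + 1L
    cc <- ((m_object - 1L) %/% h) + 1L
    on_boundary <- logical(length(m_object))
    for (o in neighbor_offsets(h, connectivity)) {
      nr <- rr + o[1]; nc <- cc + o[2]
      inb <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      out_hull <- !inb
      out_hull[inb] <- !point_in_poly(nc[inb], nr[inb], poly)
      on_boundary <- on_boundary | out_hull
    }
    seeds <- m_object[on_boundary]
    grown <- if (length(seeds)) {
      grow_set(seeds, allowed & !taken, P, h, w, d_threshold, connectivity)
    } else integer(0)
    final <- sort(union(m_object, grown))
    taken[final] <- TRUE
    objects[[length(objects) + 1L]] <- final
  }
  mask <- logical(h * w)
  for (o in objects) mask[o] <- TRUE
  structure(list(objects = objects, all = which(mask)),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> %d object(s): %s pixels\n", length(x$objects),
              paste(lengths(x$objects), collapse = ", ")))
  invisible(x)
}

#' Per-pixel precision and recall against generator labels
#'
#' Scores plane and object claims against a scene's ground truth, over the
#' labeled (non-void) pixels only.
#'
#' @param labels H x W truth matrix from [synth_scene()] (`labels`, i.e.
#'   with the void band as NA).
#' @param plane_set result of [extract_planes()].
#' @param object_set result of [segment_objects()].
#' @return named vector: plane/object precision and recall.
#' @export
segmentation_scores <- function(labels, plane_set, object_set) {
  scored <- !is.na(labels)
  truth_plane <- scored & labels == 0L
  truth_obj <- scored & labels > 0L
  claim_plane <- matrix(FALSE, nrow(labels), ncol(labels))
  claim_plane[plane_set$h_plane] <- TRUE
  claim_obj <- matrix(FALSE, nrow(labels), ncol(labels))
  claim_obj[object_set$all] <- TRUE
  pr <- function(claim, truth) {
    c(precision = sum(claim & truth & scored) / max(sum(claim & scored), 1),
      recall = sum(claim & truth & scored) / max(sum(truth), 1))
  }
  c(plane = pr(claim_plane, truth_plane), object = pr(claim_obj, truth_obj))
}

#' Locate an object's 3D centroid
#'
#' Coordinate-wise mean of the member points, in the camera frame.
#'
#' @param pixel_set vector of linear pixel indices.
#' @param cloud an [organized_cloud()].
#' @return length-3 centroid.
#' @export
locate_object <- function(pixel_set, cloud) {
  if (!length(pixel_set)) stop_config("cannot locate an empty point set")
  P <- cloud_matrix(cloud)
  rowMeans(P[, pixel_set, drop = FALSE])
}
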