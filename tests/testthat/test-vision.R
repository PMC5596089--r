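# independent scalar ray-cast oracle for a standing cylinder, written
# against the geometry directly (no shared code with synth_scene)
oracle_cylinder_pixels <- function(spec, obj) {
  hits <- 0L
  for (i in seq_len(spec$h)) {
    for (j in seq_len(spec$w)) {
      dx <- (j - spec$cx) / spec$f
      dy <- (i - spec$cy) / spec$f
      zb <- spec$plane_depth; zt <- zb - obj$height
      hit <- FALSE
      # top disk
      if ((zt * dx - obj$center[1])^2 + (zt * dy - obj$center[2])^2 <=
          obj$radius^2) hit <- TRUE
      # side wall: scan the quadratic root
      a <- dx^2 + dy^2
      if (!hit && a > 0) {
        b <- -2 * (dx * obj$center[1] + dy * obj$center[2])
        cc <- sum(obj$center^2) - obj$radius^2
        disc <- b^2 - 4 * a * cc
        if (disc >= 0) {
          t1 <- (-b - sqrt(disc)) / (2 * a)
          if (t1 >= zt && t1 <= zb) hit <- TRUE
        }
      }
      if (hit) hits <- hits + 1L
    }
  }
  hits
}

test_that("scene synthesis matches the brute-force ray-cast oracle", {
  spec <- scene_spec(h = 40, w = 40, f = 60, plane_depth = 1,
                     plane_extent = c(0.5, 0.5))
  flat <- synth_scene(spec)
  expect_true(all(flat$raw_labels[flat$cloud$valid] == 0))
  obj <- list(shape = "cylinder", center = c(0.05, -0.03), radius = 0.08,
              height = 0.2)
  spec2 <- scene_spec(h = 40, w = 40, f = 60, plane_depth = 1,
                      plane_extent = c(0.5, 0.5), objects = list(obj))
  sc <- synth_scene(spec2)
  expect_equal(sum(sc$raw_labels == 1, na.rm = TRUE),
               oracle_cylinder_pixels(spec2, obj))
  noisy <- scene_spec(h = 20, w = 20, noise_sd = 0.005, seed = 5)
  expect_identical(synth_scene(noisy)$cloud$points,
                   synth_scene(noisy)$cloud$points)
})

test_that("normals are vertical on a flat field and rotate with the plane", {
  sc <- synth_scene(scene_spec(h = 30, w = 30, f = 40, plane_depth = 1,
                               plane_extent = c(2, 2)))
  nm <- cloud_normals(sc$cloud)
  interior <- !is.na(nm[, , 3])
  dev <- acos(pmin(abs(nm[, , 3][interior]), 1))
  expect_lt(max(dev), 1e-6)
  # constructed 30-degree tilted plane
  h <- 20; w <- 20; step <- 0.01
  x <- outer(rep(1, h), seq_len(w)) * step
  y <- outer(seq_len(h), rep(1, w)) * step
  z <- 1 + x * tan(pi / 6)
  tilted <- organized_cloud(array(c(x, y, z), c(h, w, 3)), matrix(TRUE, h, w))
  nt <- cloud_normals(tilted)
  ang <- acos(abs(nt[10, 10, 3]))
  expect_equal(ang, pi / 6, tolerance = 1e-9)
  # cross-product property on a random grid
  set.seed(4)
  rnd <- organized_cloud(array(stats::rnorm(h * w * 3), c(h, w, 3)),
                         matrix(TRUE, h, w))
  nr <- cloud_normals(rnd)
  i <- 7; j <- 9
  v1 <- rnd$points[i, j - 1, ] - rnd$points[i, j + 1, ]
  v2 <- rnd$points[i + 1, j, ] - rnd$points[i - 1, j, ]
  expect_lt(abs(sum(nr[i, j, ] * v1)), 1e-9)
  expect_lt(abs(sum(nr[i, j, ] * v2)), 1e-9)
})

test_that("plane extraction recovers the table and rejects objects", {
  sc <- default_scene_fixture()
  ps <- extract_planes(sc$cloud)
  expect_length(ps$planes, 1)
  truth_plane <- !is.na(sc$labels) & sc$labels == 0
  expect_gte(sum(ps$mask & truth_plane) / sum(truth_plane), 0.99)
  truth_obj <- !is.na(sc$labels) & sc$labels > 0
  expect_equal(sum(ps$mask & truth_obj), 0)
  # n_c larger than the scene: nothing qualifies
  empty <- extract_planes(sc$cloud, n_c = 1e6)
  expect_length(empty$planes, 0)
})

test_that("two separated shelves yield two planes", {
  h <- 30; w <- 40; step <- 0.01
  x <- outer(rep(1, h), seq_len(w)) * step
  y <- outer(seq_len(h), rep(1, w)) * step
  z <- matrix(1, h, w); z[, 21:40] <- 0.8
  valid <- matrix(TRUE, h, w); valid[, 19:22] <- FALSE   # gap between shelves
  cloud <- organized_cloud(array(c(x, y, z), c(h, w, 3)), valid)
  ps <- extract_planes(cloud, n_c = 100)
  expect_length(ps$planes, 2)
})

test_that("hulls enclose their components and convexify", {
  tc <- toy_cloud(NULL, h = 20, w = 20)
  # disk component
  disk <- which((row(matrix(0, 20, 20)) - 10)^2 +
                  (col(matrix(0, 20, 20)) - 10)^2 <= 16)
  tc <- toy_cloud(disk, h = 20, w = 20)
  hulls <- object_hulls(tc$plane, tc$cloud, min_size = 3)
  expect_length(hulls, 1)
  r <- ((hulls[[1]]$component - 1) %% 20) + 1
  c_ <- ((hulls[[1]]$component - 1) %/% 20) + 1
  expect_true(all(assistbci:::point_in_poly(c_, r, hulls[[1]]$poly)))
  # hull of a hull is the same hull
  poly <- hulls[[1]]$poly
  again <- grDevices::chull(poly[, 1], poly[, 2])
  expect_setequal(seq_len(nrow(poly)), again)
  # L-shape: hull area exceeds the component's pixel count
  Lpix <- which((row(matrix(0, 20, 20)) %in% 5:14 & col(matrix(0, 20, 20)) %in% 5:6) |
                  (row(matrix(0, 20, 20)) %in% 13:14 & col(matrix(0, 20, 20)) %in% 5:14))
  tcl <- toy_cloud(Lpix, h = 20, w = 20)
  hl <- object_hulls(tcl$plane, tcl$cloud, min_size = 3)[[1]]
  shoelace <- function(p) {
    n <- nrow(p); s <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
    }
    abs(s) / 2
  }
  expect_gt(shoelace(hl$poly), length(Lpix))
})

test_that("two-times growing matches the flood-fill oracle on a protruding object", {
  obj <- rbind(expand.grid(r = 3:8, c = 3:8),
               expand.grid(r = 5:6, c = 9:10))     # protrudes past the hull
  idx <- as.integer((obj$c - 1) * 12 + obj$r)
  tc <- toy_cloud(idx)
  hull <- list(poly = cbind(col = c(3, 8, 8, 3), row = c(3, 3, 8, 8)),
               component = idx)
  os <- segment_objects(tc$cloud, tc$plane, list(hull), d_threshold = 0.02,
                        n_c_prime = 5)
  expect_length(os$objects, 1)
  allowed <- !tc$plane$mask
  seeds <- intersect(idx, which(matrix(assistbci:::point_in_poly(
    ((seq_len(144) - 1) %/% 12) + 1, ((seq_len(144) - 1) %% 12) + 1,
    hull$poly), 12, 12)))
  oracle <- flood_oracle(seeds, allowed, tc$cloud, 0.02)
  expect_identical(os$objects[[1]], oracle)
  expect_identical(sort(os$objects[[1]]), sort(idx))  # full object recovered

  # object entirely inside the hull: pass 2 adds nothing
  hull_big <- list(poly = cbind(col = c(2, 11, 11, 2), row = c(2, 2, 11, 11)),
                   component = idx)
  os2 <- segment_objects(tc$cloud, tc$plane, list(hull_big),
                         d_threshold = 0.02, n_c_prime = 5)
  expect_identical(os2$objects[[1]], sort(idx))

  # n'_C above the object size rejects it
  os3 <- segment_objects(tc$cloud, tc$plane, list(hull_big),
                         d_threshold = 0.02, n_c_prime = 1000)
  expect_length(os3$objects, 0)
})

test_that("plane and object sets stay disjoint within the valid pixels", {
  sc <- default_scene_fixture()
  ps <- extract_planes(sc$cloud)
  os <- segment_objects(sc$cloud, ps, object_hulls(ps, sc$cloud))
  expect_length(intersect(ps$h_plane, os$all), 0)
  expect_true(all(sc$cloud$valid[ps$h_plane]))
  expect_true(all(sc$cloud$valid[os$all]))
})

test_that("accepted planes are invariant to scan order (mirrored scene)", {
  sc <- default_scene_fixture()
  ps <- extract_planes(sc$cloud)
  flipped <- organized_cloud(sc$cloud$points[, sc$cloud$w:1, , drop = FALSE],
                             sc$cloud$valid[, sc$cloud$w:1])
  psf <- extract_planes(flipped)
  expect_identical(ps$mask, psf$mask[, sc$cloud$w:1])
})

test_that("localization is exact, symmetric, and translation-equivariant", {
  tc <- toy_cloud(c(40L))
  expect_equal(locate_object(40L, tc$cloud), tc$cloud$points[4, 4, ],
               ignore_attr = TRUE)
  expect_error(locate_object(integer(), tc$cloud),
               class = "assistbci_config_error")
  # centered symmetric cylinder: centroid on the axis within one voxel
  sc <- synth_scene(scene_spec(objects = list(
    list(shape = "cylinder", center = c(0, 0), radius = 0.05, height = 0.12))))
  ps <- extract_planes(sc$cloud)
  os <- segment_objects(sc$cloud, ps, object_hulls(ps, sc$cloud))
  cen <- locate_object(os$objects[[1]], sc$cloud)
  voxel <- 0.8 / 180                     # pixel pitch at table depth
  expect_lt(abs(cen[1]), voxel)
  expect_lt(abs(cen[2]), voxel)
  # translation equivariance
  shifted <- sc$cloud
  shifted$points <- sc$cloud$points + rep(c(0.1, -0.2, 0.3),
                                          each = prod(dim(sc$cloud$valid)))
  expect_equal(locate_object(os$objects[[1]], shifted), cen + c(0.1, -0.2, 0.3),
               ignore_attr = TRUE)
})
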