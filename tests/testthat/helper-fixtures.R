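# Shared fixtures, built lazily and cached for the session so expensive
# objects (trained models, rendered scenes) are constructed once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, expr, envir = .fixtures)
  .fixtures[[name]]
}

default_tm <- function() session_timing()

# small high-SNR training session + fitted model for decoder tests
highsnr_model <- function() {
  fixture("highsnr_model", {
    tm <- default_tm()
    rec <- synthesize_recording(
      synth_session_spec(n_trials = 12, rounds_per_trial = 8,
                         p300_amplitude = 10, noise_sd = 5, seed = 401),
      tm)
    ts <- build_training_set(rec, tm)
    list(model = fit_blda(ts$X, ts$t), rec = rec, tm = tm)
  })
}

default_scene_fixture <- function() {
  fixture("default_scene", synth_scene(default_scene()))
}

# hand-built 12 x 12 organized cloud: flat plane at z = 1 with an object
# (z = 0.9) occupying given pixels; plane membership supplied explicitly
toy_cloud <- function(object_pixels, h = 12, w = 12) {
  z <- matrix(1, h, w)
  z[object_pixels] <- 0.9
  step <- 0.005                       # 5 mm pixel pitch: below d_threshold
  x <- outer(rep(1, h), seq_len(w)) * step
  y <- outer(seq_len(h), rep(1, w)) * step
  cloud <- organized_cloud(array(c(x, y, z), c(h, w, 3)),
                           matrix(TRUE, h, w))
  plane_mask <- matrix(TRUE, h, w)
  plane_mask[object_pixels] <- FALSE
  ps <- structure(list(planes = list(which(plane_mask)),
                       h_plane = which(plane_mask), mask = plane_mask),
                  class = "plane_set")
  list(cloud = cloud, plane = ps, h = h, w = w)
}

# independent flood-fill oracle: 4-connected component of `allowed` pixels
# reachable from `seeds`, edges admitted when 3D distance <= thr
flood_oracle <- function(seeds, allowed, cloud, thr) {
  h <- cloud$h; w <- cloud$w
  P <- t(matrix(cloud$points, h * w, 3))
  in_set <- logical(h * w)
  stack <- seeds
  in_set[seeds] <- TRUE
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    r <- ((cur - 1) %% h) + 1; c_ <- ((cur - 1) %/% h) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nr <- r + d[1]; nc <- c_ + d[2]
      if (nr < 1 || nr > h || nc < 1 || nc > w) next
      nb <- (nc - 1) * h + nr
      if (in_set[nb] || !allowed[nb]) next
      if (sqrt(sum((P[, nb] - P[, cur])^2)) > thr) next
      in_set[nb] <- TRUE
      stack <- c(stack, nb)
    }
  }
  sort(which(in_set))
}
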