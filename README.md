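# assistbci

Hardware-free computational core of an intention-driven assistive drinking
robot, for researchers in non-invasive brain–computer interfacing and
assistive robotics who want the full decode→perceive→act loop on a desk,
with every sensor replaced by a tested generative model.

The package has two halves plus a connector:

* **BCI half** — a 4-key P300 speller: synthetic oddball-paradigm EEG
  (30 channels, 250 Hz, 1.2 s rounds, 200 ms ISI, 600 ms epochs), a
  0.1–20 Hz Butterworth preprocessing chain with ×6 decimation, Bayesian
  linear discriminant analysis with evidence-framework hyperparameter
  estimation, and a self-adaptive online decoder that accumulates rounds
  (3 ≤ M ≤ 8) until the best normalized score clears a threshold θ0,
  chosen on offline data from accuracy/ITR curves.
* **Perception half** — synthetic organized point clouds of a table
  bearing cup/bottle/can solids; cross-product surface normals;
  region-growing extraction of the horizontal plane; convex-hull candidate
  regions; two-times region growing that recovers object parts protruding
  past their hull; centroid localization; rigid camera→board→robot
  transforms; and a 4-class convolutional recognizer (32/64/128/256
  3×3 kernels, FC 256/128/64/4, dropout 0.5, softmax) implemented in
  vectorized base R with hand-derived gradients and Adam.
* **Decision layer** — a guarded state machine sequencing two-command
  drinking tasks end to end (`run_e2e()`).

The core statistics, in standard notation: BLDA posterior
`m = β(βXXᵀ + I'(α))⁻¹Xt`, `C = (βXXᵀ + I'(α))⁻¹` with
`I'(α) = diag(α,…,α,ε)`, α and β from MacKay's evidence fixed point;
normalized scores `Sᵢ = (μᵢ − min μ)/Σⱼ(μⱼ − min μ)`; Wolpaw information
transfer rate `ITR = 60/t · (log₂K + p log₂p + (1−p) log₂((1−p)/(K−1)))`
bits/min. Normals are `v₁ × v₂` over the pixel 4-neighborhood; region
growth admits a neighbor within `d_threshold` meters whose normal (for
planes) is within `angle_tol` of vertical.

## Worked example

```r
library(assistbci)
tm <- session_timing()

# offline training session: high-SNR synthetic subject
train <- synthesize_recording(
  synth_session_spec(n_trials = 16, rounds_per_trial = 8,
                     p300_amplitude = 10, noise_sd = 5, seed = 42), tm)
ts <- build_training_set(train, tm)     # X: 751 x 512, t in {-1, +1}
model <- fit_blda(ts$X, ts$t)
#> <blda_model> P'=751 | alpha=1.004e+05 beta=25.09 eps=1e-10 | 25 iter, converged

# online decoding of a fresh session
test <- synthesize_recording(
  synth_session_spec(n_trials = 10, rounds_per_trial = 8,
                     p300_amplitude = 10, noise_sd = 5, seed = 43), tm)
sim <- simulate_online(test, model, theta0 = 0.9, timing = tm)
head(sim$trials, 3)
#>   trial target decision M selection_s correct
#> 1     1      1        1 5         6.0    TRUE
#> 2     2      2        2 4         4.8    TRUE
#> 3     3      3        3 5         6.0    TRUE
itr_bits_per_min(4, sim$accuracy, sim$mean_selection_s)
#> [1] 19.23077
```

All 10 trials decode correctly; the adaptive rule spends 4–8 rounds per
trial (mean M = 5.2, i.e. 6.24 s per selection), giving 19.23 bits/min.
With θ0 = 0 every trial would stop at M = 3 and a perfect subject would
reach the 33.33 bits/min ceiling for K = 4 at 3.6 s.

```r
# perception: segment and locate the three containers
sc <- synth_scene(default_scene())
ps <- extract_planes(sc$cloud)
os <- segment_objects(sc$cloud, ps, object_hulls(ps, sc$cloud))
os
#> <object_set> 3 object(s): 633, 538, 455 pixels
locate_object(os$objects[[1]], sc$cloud)
#> [1] -0.245  0.049  0.722
```

The first centroid sits at (−0.245, 0.049, 0.722) m in the camera frame —
the cup the generator placed at (−0.25, 0.05) on a table 0.8 m below the
camera (the z of 0.72 is the cup's visible surface, not the tabletop).
`segmentation_scores(sc$labels, ps, os)` reports per-pixel precision and
recall of 1.0 on this noiseless scene.

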