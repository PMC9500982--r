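# Shared fixtures and independent oracles. Oracles are written from the
# definitions (direct loops), independent of the package's implementation
# paths, and are deliberately slow/naive.

# independent Keys cubic kernel (a = -0.5), re-derived from the piecewise form
oracle_keys <- function(x, a = -0.5) {
  x <- abs(x)
  if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
  else if (x < 2) a * (x^3 - 5 * x^2 + 8 * x - 4)
  else 0
}

# direct (non-separable) bicubic resampling: per target pixel, evaluate the
# 2D product kernel over the 4x4 source neighbourhood with mirror indices
oracle_bicubic <- function(m, target_side) {
  S1 <- nrow(m); S2 <- ncol(m)
  refl <- function(i, n) { i <- abs(i); if (i > n - 1) i <- 2 * (n - 1) - i; i }
  out <- matrix(0, target_side, target_side)
  for (i in seq_len(target_side)) {
    x <- (i - 1) * (S1 - 1) / (target_side - 1)
    for (j in seq_len(target_side)) {
      y <- (j - 1) * (S2 - 1) / (target_side - 1)
      acc <- 0
      for (p in (floor(x) - 1):(floor(x) + 2)) {
        for (q in (floor(y) - 1):(floor(y) + 2)) {
          w <- oracle_keys(x - p) * oracle_keys(y - q)
          if (w != 0) acc <- acc + w * m[refl(p, S1) + 1, refl(q, S2) + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# direct 3D convolution from the definition (zero padding, stride)
oracle_conv3d <- function(x, w, b, stride, pad) {
  dmx <- dim(x); dmw <- dim(w)
  N <- dmx[1]; C <- dmx[2]; D <- dmx[3]; H <- dmx[4]; W <- dmx[5]
  Co <- dmw[1]; Kd <- dmw[3]; Kh <- dmw[4]; Kw <- dmw[5]
  Do <- (D + 2 * pad[1] - Kd) %/% stride[1] + 1
  Ho <- (H + 2 * pad[2] - Kh) %/% stride[2] + 1
  Wo <- (W + 2 * pad[3] - Kw) %/% stride[3] + 1
  y <- array(0, c(N, Co, Do, Ho, Wo))
  for (n in 1:N) for (co in 1:Co) for (dd in 1:Do) for (hh in 1:Ho) for (ww in 1:Wo) {
    acc <- if (length(b)) b[co] else 0
    for (ci in 1:C) for (kd in 1:Kd) for (kh in 1:Kh) for (kw in 1:Kw) {
      di <- (dd - 1) * stride[1] - pad[1] + kd
      hi <- (hh - 1) * stride[2] - pad[2] + kh
      wi <- (ww - 1) * stride[3] - pad[3] + kw
      if (di >= 1 && di <= D && hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[n, ci, di, hi, wi] * w[co, ci, kd, kh, kw]
      }
    }
    y[n, co, dd, hh, ww] <- acc
  }
  y
}

# desk-scale fixtures: short trials, 0.25-s windows rendered at side 16, and
# a width-reduced bottleneck network that accepts 1 x 32 x 16 x 16 windows
make_trials <- function(n_trials, delta, seed, trial_seconds = 11,
                        valence_pattern = rep(c(TRUE, FALSE), length.out = n_trials)) {
  cfg <- synth_config(trial_seconds = trial_seconds, delta = delta, seed = seed)
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    generate_trial(valence_pattern[i], FALSE, cfg, trial_id = i)
  })
}

make_desk_dataset <- function(n_trials = 2, delta = 5, seed = 11) {
  ds_cfg <- list(window_seconds = 0.25, target_side = 16L, pre_stimulus_seconds = 3)
  build_dataset(make_trials(n_trials, delta, seed), montage_grid(), ds_cfg)
}

desk_cnn_bn <- function() {
  build_cnn_bn(input_shape = c(1L, 32L, 16L, 16L), stem_channels = 4L,
               bottlenecks = list(c(2L, 8L), c(4L, 16L)), dense_width = 32L)
}

# smaller still: used where the network only needs to run, not to learn well
mini_cnn_bn <- function() {
  build_cnn_bn(input_shape = c(1L, 32L, 16L, 16L), stem_channels = 2L,
               bottlenecks = list(c(1L, 4L)), dense_width = 16L)
}
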