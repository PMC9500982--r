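test_that("trimming removes exactly the pre-stimulus prefix", {
  x <- matrix(rnorm(32 * 63 * 128), 32, 63 * 128)
  tr <- raw_trial(x, 128, valence_rating = 6, arousal_rating = 3,
                  trial_id = 7, subject_id = 2)
  out <- trim_trial(tr, 3)
  expect_equal(ncol(out$samples), 60 * 128)  # last 60 s retained
  expect_equal(out$samples, x[, (3 * 128 + 1):(63 * 128)])
  expect_equal(out$trial_id, 7)
  expect_equal(out$valence_rating, 6)
  expect_identical(trim_trial(tr, 0), tr)
  expect_error(trim_trial(tr, 100), "8064")
  expect_error(trim_trial(tr, 0.001), "integer")
})

test_that("windowing is contiguous, non-overlapping, floor-ruled", {
  mk <- function(n) raw_trial(matrix(seq_len(2 * n), 2, n, byrow = TRUE), 128,
                              5, 5)
  segs <- segment_windows(mk(7680), 1)
  expect_length(segs, 60)
  expect_true(all(vapply(segs, ncol, integer(1)) == 128))
  # temporal order and contiguity
  expect_equal(segs[[2]][1, ], (129:256))
  expect_length(segment_windows(mk(128), 1), 1)
  expect_message(segs <- segment_windows(mk(200), 2), "no windows")
  expect_length(segs, 0)
  segs <- segment_windows(mk(200), 1)
  expect_length(segs, 1)  # 72 trailing samples dropped
  expect_error(segment_windows(mk(128), 0.001), "integer")
})

test_that("grid projection occupies one cell per channel and nulls the rest", {
  mg <- montage_grid()
  v <- rnorm(32)
  fm <- project_to_grid(v, mg)
  expect_equal(sum(fm$occupancy), 32)
  expect_equal(sum(!fm$occupancy), 49)
  expect_equal(sum(is.na(fm$values)), 49)
  # montage order is preserved cell by cell
  for (ci in c(1, 10, 32)) {
    rc <- mg$assignments[ci, ] + 1
    expect_equal(fm$values[rc[1], rc[2]], v[ci])
  }
  one_hot <- c(1, rep(0, 31))
  fm1 <- project_to_grid(one_hot, mg)
  expect_equal(sum(fm1$values == 1, na.rm = TRUE), 1)
  rc <- mg$assignments[1, ] + 1
  expect_equal(fm1$values[rc[1], rc[2]], 1)
  fm0 <- project_to_grid(rep(0, 32), mg)
  expect_true(all(fm0$values[fm0$occupancy] == 0))
  expect_error(project_to_grid(rnorm(31), mg), "expected 32")
})

test_that("thin-plate-spline fill interpolates and reproduces affine fields", {
  mg <- montage_grid()
  # constant field
  fc <- rbf_fill(project_to_grid(rep(3.25, 32), mg), mg)
  expect_false(anyNA(fc$values))
  expect_true(all(abs(fc$values - 3.25) < 1e-6))
  # electrode cells untouched (interpolation condition)
  v <- rnorm(32)
  fm <- project_to_grid(v, mg)
  filled <- rbf_fill(fm, mg)
  expect_equal(filled$values[fm$occupancy], fm$values[fm$occupancy])
  # planar ramp recovered at the empty cells
  a <- 0.7; b <- -1.3
  ramp_at <- function(rc) a * rc[1] + b * rc[2]
  v_ramp <- apply(mg$assignments, 1, ramp_at)
  fr <- rbf_fill(project_to_grid(v_ramp, mg), mg)
  expected <- outer(0:8, 0:8, function(r, c) a * r + b * c)
  expect_true(max(abs(fr$values - expected)) < 1e-6)
})

test_that("degenerate (collinear) node sets are rejected", {
  mg <- montage_grid()
  vals <- matrix(NA_real_, 9, 9)
  occ <- matrix(FALSE, 9, 9)
  occ[5, c(2, 5, 8)] <- TRUE  # three nodes on one row
  vals[occ] <- rnorm(3)
  frame <- structure(list(values = vals, occupancy = occ), class = "frame_map")
  expect_error(rbf_fill(frame, mg), "collinear")
})

test_that("bicubic upsampling matches a direct kernel-evaluation oracle", {
  const <- matrix(2.5, 9, 9)
  up <- upsample_bicubic(const, 64L)
  expect_equal(dim(up), c(64L, 64L))
  expect_true(max(abs(up - 2.5)) < 1e-9)

  ramp <- outer(0:8, 0:8, function(r, c) 1.5 * r - 0.25 * c)
  expect_lt(max(abs(upsample_bicubic(ramp, 33L) - oracle_bicubic(ramp, 33L))),
            1e-6)
  set.seed(1)
  m <- matrix(rnorm(81), 9, 9)
  expect_lt(max(abs(upsample_bicubic(m, 21L) - oracle_bicubic(m, 21L))), 1e-6)
  # deterministic
  expect_identical(upsample_bicubic(m, 21L), upsample_bicubic(m, 21L))
  expect_error(upsample_bicubic(m, 8L), "downsampling")
  expect_error(upsample_bicubic(matrix(c(1, NA, 1, 1), 2, 2), 8L))
})

test_that("window tensors stack per-sample maps in temporal order", {
  mg <- montage_grid()
  set.seed(4)
  seg <- matrix(rnorm(32 * 16), 32, 16)
  wt <- build_window_tensor(seg, mg, 16L)
  expect_equal(dim(wt$data), c(16L, 16L, 16L))
  expect_true(all(is.finite(wt$data)))
  # each depth slice equals the full per-sample pipeline run independently
  for (t in c(1L, 9L)) {
    ref <- upsample_bicubic(rbf_fill(project_to_grid(seg[, t], mg), mg), 16L)
    expect_equal(wt$data[t, , ], ref, tolerance = 1e-12)
  }
  # time-constant segment: identical slices
  wtc <- build_window_tensor(matrix(rnorm(32), 32, 16), mg, 16L)
  expect_equal(wtc$data[5, , ], wtc$data[1, , ])
  # swapping two time samples swaps exactly those depth slices
  seg2 <- seg; seg2[, c(3, 12)] <- seg[, c(12, 3)]
  wt2 <- build_window_tensor(seg2, mg, 16L)
  expect_equal(wt2$data[3, , ], wt$data[12, , ])
  expect_equal(wt2$data[12, , ], wt$data[3, , ])
  expect_equal(wt2$data[c(-3, -12), , ], wt$data[c(-3, -12), , ])
  # default target renders the published 128 x 64 x 64 stack
  seg_full <- matrix(rnorm(32 * 128), 32, 128)
  expect_equal(dim(build_window_tensor(seg_full, mg, 64L)$data),
               c(128L, 64L, 64L))
})

test_that("pipeline is linear in amplitude and bit-deterministic", {
  mg <- montage_grid()
  set.seed(9)
  seg <- matrix(rnorm(32 * 8), 32, 8)
  a <- build_window_tensor(seg, mg, 16L)
  b <- build_window_tensor(seg, mg, 16L)
  expect_identical(a$data, b$data)
  s <- 3.7
  scaled <- build_window_tensor(s * seg, mg, 16L)
  expect_equal(scaled$data, s * a$data, tolerance = 1e-12)
})

test_that("electrode-backed cells carry raw channel values pre-upsampling", {
  mg <- montage_grid()
  set.seed(10)
  seg <- matrix(rnorm(32 * 4), 32, 4)
  for (t in seq_len(4)) {
    filled <- rbf_fill(project_to_grid(seg[, t], mg), mg)
    idx <- cbind(mg$assignments[, 1] + 1, mg$assignments[, 2] + 1)
    expect_equal(filled$values[idx], seg[, t])
  }
})

test_that("dataset assembly labels, counts and tracks every window", {
  mg <- montage_grid()
  trials <- make_trials(2, delta = 1, seed = 21, trial_seconds = 11,
                        valence_pattern = c(TRUE, FALSE))
  ds <- build_dataset(trials, mg, list(window_seconds = 1, target_side = 16L))
  expect_length(ds, 2 * 8)  # (11 - 3) s per trial, 1-s windows
  expect_false(any(duplicated(ds$provenance[c("trial_id", "window_index")])))
  expect_setequal(unique(ds$provenance$label_valence), c(0L, 1L))
  # labels agree with the threshold rule applied to the ratings
  for (tr in trials) {
    rows <- ds$provenance$trial_id == tr$trial_id
    expect_true(all(ds$provenance$label_valence[rows] ==
                      binarize_rating(tr$valence_rating)))
  }
  expect_length(build_dataset(list(), mg), 0)
  bad <- trials
  bad[[2]]$samples <- bad[[2]]$samples[1:16, ]
  expect_error(build_dataset(bad, mg, list(target_side = 16L)), "channel counts")
})

test_that("full-length trials produce the published window count", {
  mg <- montage_grid()
  x <- matrix(0, 32, 63 * 128)
  tr <- raw_trial(x, 128, 6, 6)
  trimmed <- trim_trial(tr, 3)
  expect_length(segment_windows(trimmed, 1), 60)
})
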