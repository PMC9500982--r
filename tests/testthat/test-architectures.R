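# frozen architecture table for the default bottleneck network: every conv /
# pool stage with its expected output shape (C, D, H, W)
cnn_bn_expected <- list(
  conv3d    = c(64, 128, 64, 64),
  maxpool3d = c(64, 64, 64, 64),
  conv3d    = c(16, 64, 64, 64),
  conv3d    = c(16, 64, 64, 64),
  conv3d    = c(128, 64, 64, 64),
  maxpool3d = c(128, 32, 32, 32),
  conv3d    = c(32, 32, 32, 32),
  conv3d    = c(32, 32, 32, 32),
  conv3d    = c(256, 32, 32, 32),
  maxpool3d = c(256, 16, 16, 16),
  conv3d    = c(64, 16, 16, 16),
  conv3d    = c(64, 16, 16, 16),
  conv3d    = c(256, 16, 16, 16),
  maxpool3d = c(256, 8, 8, 8),
  conv3d    = c(64, 8, 8, 8),
  conv3d    = c(64, 8, 8, 8),
  conv3d    = c(256, 8, 8, 8),
  maxpool3d = c(256, 4, 4, 4),
  conv3d    = c(64, 4, 4, 4),
  conv3d    = c(64, 4, 4, 4),
  conv3d    = c(256, 4, 4, 4),
  maxpool3d = c(256, 2, 2, 2))

test_that("bottleneck network reproduces the published shape table", {
  spec <- build_cnn_bn()
  fs <- forward_shapes(spec)
  got <- fs[fs$kind %in% c("conv3d", "maxpool3d"), ]
  expect_equal(nrow(got), length(cnn_bn_expected))
  expect_equal(got$kind, names(cnn_bn_expected))
  for (i in seq_len(nrow(got))) {
    expect_equal(got$output_shape[[i]], as.integer(cnn_bn_expected[[i]]),
                 info = paste("stage", i))
  }
  # flattened feature length entering the dense head
  expect_equal(fs$output_shape[[which(fs$kind == "flatten")]], 2048L)
  # final output: two logits
  expect_equal(fs$output_shape[[nrow(fs)]], 2L)
})

test_that("layer censuses match the published architecture accounting", {
  cen <- layer_census(build_cnn_bn())
  expect_equal(unname(cen[c("conv3d", "batchnorm", "relu", "maxpool3d", "dense")]),
               c(16L, 16L, 17L, 6L, 2L))
  cen3 <- layer_census(build_c3d())
  expect_equal(unname(cen3[c("conv3d", "batchnorm", "maxpool3d", "dense")]),
               c(6L, 6L, 6L, 2L))
  cenl <- layer_census(build_lstm())
  expect_equal(unname(cenl[c("lstm", "dense", "dropout", "tanh")]),
               c(3L, 2L, 1L, 3L))
  empty <- model_spec("empty", c(1L, 4L, 4L, 4L), list())
  expect_true(all(layer_census(empty) == 0L))
})

test_that("bottleneck blocks reduce, keep, then expand channel width", {
  spec <- build_cnn_bn()
  convs <- Filter(function(l) l$kind == "conv3d", spec$layers)
  # blocks of three convs after the stem
  blocks <- split(convs[-1], rep(1:5, each = 3))
  for (b in seq_along(blocks)) {
    tri <- blocks[[b]]
    expect_equal(tri[[1]]$out_channels, tri[[2]]$in_channels)
    expect_equal(tri[[2]]$out_channels, tri[[3]]$in_channels)
    expect_equal(tri[[2]]$in_channels, tri[[2]]$out_channels)  # same-width middle
    if (b <= 3) {  # quarter-width reduction in the first three blocks
      expect_equal(tri[[1]]$out_channels * 4L, tri[[1]]$in_channels)
    }
  }
  # first block reduces 64 -> 16 and expands to 128
  expect_equal(blocks[[1]][[1]]$in_channels, 64L)
  expect_equal(blocks[[1]][[1]]$out_channels, 16L)
  expect_equal(blocks[[1]][[3]]$out_channels, 128L)
})

test_that("C3D baseline uses 7x3x3 kernels, six blocks, 2048 features", {
  spec <- build_c3d()
  convs <- Filter(function(l) l$kind == "conv3d", spec$layers)
  expect_length(convs, 6)
  for (l in convs) expect_equal(l$kernel, c(7L, 3L, 3L))
  fs <- forward_shapes(spec)
  expect_equal(fs$output_shape[[which(fs$kind == "flatten")]], 2048L)
  expect_equal(vapply(convs, `[[`, integer(1), "out_channels"),
               c(64L, 128L, 256L, 256L, 256L, 256L))
})

test_that("shape propagation chains without gaps for all default models", {
  for (spec in list(build_cnn_bn(), build_c3d(), build_lstm())) {
    fs <- forward_shapes(spec)
    for (i in seq_len(nrow(fs) - 1)) {
      expect_equal(fs$input_shape[[i + 1]], fs$output_shape[[i]],
                   info = sprintf("%s layer %d", spec$name, i))
    }
  }
})

test_that("shape arithmetic handles identity convs and temporal pooling", {
  id <- model_spec("id", c(64L, 16L, 8L, 8L), list(
    spec_conv3d(64L, 64L, c(1L, 1L, 1L), padding = c(0L, 0L, 0L))))
  expect_equal(forward_shapes(id)$output_shape[[1]], c(64L, 16L, 8L, 8L))
  pool <- model_spec("pool", c(64L, 128L, 64L, 64L), list(
    spec_maxpool3d(c(2L, 1L, 1L))))
  expect_equal(forward_shapes(pool)$output_shape[[1]], c(64L, 64L, 64L, 64L))
})

test_that("indivisible pooling cascades fail with the offending stage named", {
  expect_error(build_cnn_bn(input_shape = c(1L, 127L, 64L, 64L)),
               "maxpool3d")
  expect_error(build_cnn_bn(input_shape = c(1L, 128L, 63L, 63L)),
               "not divisible")
  expect_error(build_lstm(hidden_size = 0L), "positive")
})

test_that("numeric forward passes yield finite b x 2 logits for all families", {
  set.seed(2)
  specs <- list(
    desk_cnn_bn(),
    build_c3d(input_shape = c(1L, 64L, 32L, 32L), channels = rep(1L, 6),
              dense_width = 8L),
    build_lstm(input_shape = c(16L, 4L), hidden_size = 8L, dense_width = 8L))
  batch_dims <- list(c(3L, 1L, 32L, 16L, 16L), c(3L, 1L, 64L, 32L, 32L),
                     c(3L, 16L, 4L))
  for (k in seq_along(specs)) {
    m <- instantiate_model(specs[[k]], seed = 1)
    x <- array(rnorm(prod(batch_dims[[k]])), batch_dims[[k]])
    out <- nn_forward(m, x)
    expect_equal(dim(out), c(3L, 2L))
    expect_true(all(is.finite(out)))
  }
})

test_that("seeded initialization is reproducible and seed-sensitive", {
  spec <- mini_cnn_bn()
  checksum <- function(m) {
    sum(vapply(m$params, function(p) {
      if (is.null(p)) return(0)
      sum(vapply(c("W", "b", "gamma", "beta", "W_ih", "W_hh"),
                 function(f) if (is.null(p[[f]])) 0 else sum(abs(p[[f]])),
                 numeric(1)))
    }, numeric(1)))
  }
  a <- instantiate_model(spec, seed = 5)
  b <- instantiate_model(spec, seed = 5)
  expect_identical(checksum(a), checksum(b))
  expect_false(checksum(a) == checksum(instantiate_model(spec, seed = 6)))
})

test_that("model specs survive a JSON round trip", {
  for (spec in list(build_cnn_bn(dense_width = 64L), build_lstm())) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model_spec(spec, path)
    back <- read_model_spec(path)
    expect_equal(layer_census(back), layer_census(spec))
    expect_equal(forward_shapes(back)$output, forward_shapes(spec)$output)
    expect_equal(count_parameters(back), count_parameters(spec))
  }
})
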