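# independent closed-form oracles: per-layer sums written out from the layer
# widths and the published shape table, not via the package's walkers

oracle_cnn_bn_params <- function(dense_width) {
  conv <- function(ci, co, kvol) co * ci * kvol + co
  bn <- function(c) 2 * c
  blocks <- list(c(64, 16, 128), c(128, 32, 256), c(256, 64, 256),
                 c(256, 64, 256), c(256, 64, 256))
  total <- conv(1, 64, 63) + bn(64)
  for (b in blocks) {
    total <- total + conv(b[1], b[2], 1) + bn(b[2]) +
      conv(b[2], b[2], 63) + bn(b[2]) + conv(b[2], b[3], 1) + bn(b[3])
  }
  total + (2048 * dense_width + dense_width) + (dense_width * 2 + 2)
}

oracle_c3d_params <- function() {
  conv <- function(ci, co) co * ci * 63 + co
  chans <- c(64, 128, 256, 256, 256, 256)
  ci <- 1
  total <- 0
  for (co in chans) { total <- total + conv(ci, co) + 2 * co; ci <- co }
  total + (2048 * 512 + 512) + (512 * 2 + 2)
}

# conv FLOPs = 2 x output elements x C_in x kernel volume, from the published
# spatial sizes; dense FLOPs = 2 x in x out
oracle_cnn_bn_core_flops <- function(dense_width) {
  vol <- function(d) d^3
  f <- 2 * (64 * 128 * 64 * 64) * 1 * 63                       # stem conv
  blk <- function(cin, cbn, cout, side) {
    2 * cbn * vol(side) * cin * 1 +
      2 * cbn * vol(side) * cbn * 63 +
      2 * cout * vol(side) * cbn * 1
  }
  f <- f + blk(64, 16, 128, 64) + blk(128, 32, 256, 32) +
    blk(256, 64, 256, 16) + blk(256, 64, 256, 8) + blk(256, 64, 256, 4)
  f + 2 * 2048 * dense_width + 2 * dense_width * 2
}

oracle_c3d_core_flops <- function() {
  f <- 2 * (64 * 128 * 64 * 64) * 1 * 63 +
    2 * (128 * 64 * 64 * 64) * 64 * 63 +
    2 * (256 * 32 * 32 * 32) * 128 * 63 +
    2 * (256 * 16 * 16 * 16) * 256 * 63 +
    2 * (256 * 8 * 8 * 8) * 256 * 63 +
    2 * (256 * 4 * 4 * 4) * 256 * 63
  f + 2 * 2048 * 512 + 2 * 512 * 2
}

test_that("parameter counts match independent closed-form sums", {
  expect_equal(count_parameters(build_cnn_bn(dense_width = 128L)),
               oracle_cnn_bn_params(128))
  expect_equal(count_parameters(build_cnn_bn(dense_width = 64L)),
               oracle_cnn_bn_params(64))
  expect_equal(count_parameters(build_c3d()), oracle_c3d_params())
  # frozen values from the hand audit of the same sums
  expect_equal(oracle_cnn_bn_params(128), 1240098)
  expect_equal(oracle_cnn_bn_params(64), 1108834)
  expect_equal(oracle_c3d_params(), 16024578)
  # trivial dense case
  d <- model_spec("d", 2L, list(spec_dense(2L, 2L)))
  expect_equal(count_parameters(d), 6)
})

test_that("spec-level counts equal direct enumeration of instantiated arrays", {
  specs <- list(build_cnn_bn(dense_width = 64L), build_lstm(),
                build_c3d(input_shape = c(1L, 64L, 32L, 32L),
                          channels = c(2L, 2L, 4L, 4L, 4L, 4L),
                          dense_width = 16L),
                desk_cnn_bn())
  for (spec in specs) {
    expect_equal(n_trainable(instantiate_model(spec, seed = 0)),
                 count_parameters(spec), info = spec$name)
  }
})

test_that("FLOP accounting matches the closed-form oracle and conventions", {
  # one MAC costs two FLOPs
  one <- model_spec("one", c(1L, 1L, 1L, 1L), list(
    spec_conv3d(1L, 1L, c(1L, 1L, 1L), padding = c(0L, 0L, 0L), bias = FALSE)))
  expect_equal(count_flops(one, include_elementwise = FALSE)$total, 2)
  f_bn <- count_flops(build_cnn_bn(dense_width = 64L))
  expect_equal(f_bn$conv_dense, oracle_cnn_bn_core_flops(64))
  f_c3d <- count_flops(build_c3d())
  expect_equal(f_c3d$conv_dense, oracle_c3d_core_flops())
  # add-ons are reported separately and total consistently
  expect_equal(f_bn$total, f_bn$conv_dense + f_bn$elementwise)
  expect_gt(f_bn$elementwise, 0)
  without <- count_flops(build_cnn_bn(dense_width = 64L),
                         include_elementwise = FALSE)
  expect_equal(without$total, f_bn$conv_dense)
})

test_that("bottleneck model is strictly cheaper than the plain baseline", {
  bn <- build_cnn_bn(dense_width = 64L)
  c3d <- build_c3d()
  expect_lt(count_parameters(bn), count_parameters(c3d))
  expect_lt(count_flops(bn)$total, count_flops(c3d)$total)
})

test_that("each bottleneck block costs less than one plain conv of its width", {
  # block input/output channels and spatial side, from the shape table
  blocks <- list(c(64, 128, 64), c(128, 256, 32), c(256, 256, 16),
                 c(256, 256, 8), c(256, 256, 4))
  bns <- c(16, 32, 64, 64, 64)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    side <- b[3]
    cbn <- bns[i]
    block_cost <- 2 * cbn * side^3 * b[1] + 2 * cbn * side^3 * cbn * 63 +
      2 * b[2] * side^3 * cbn
    plain_cost <- 2 * b[2] * side^3 * b[1] * 63
    expect_lt(block_cost, plain_cost)
  }
})

test_that("conv FLOPs scale linearly with temporal extent", {
  spec <- build_cnn_bn(dense_width = 64L)
  base <- count_flops(spec)$per_layer
  # doubling D doubles every conv layer's core count (dense head differs, so
  # rebuild at the doubled input)
  spec2 <- build_cnn_bn(input_shape = c(1L, 256L, 64L, 64L), dense_width = 64L)
  doubled <- count_flops(spec2)$per_layer
  conv_rows <- base$kind == "conv3d"
  expect_equal(doubled$core_flops[conv_rows], 2 * base$core_flops[conv_rows])
})

test_that("reduction percentages derive from the rounded table values", {
  # parameter pair printing as 16.05 M and 1.11 M
  pa <- model_spec("a", 16049L, list(spec_dense(16049L, 1000L)))
  pb <- model_spec("b", 1109L, list(spec_dense(1109L, 1000L)))
  expect_equal(count_parameters(pa) / 1e6, 16.05)
  expect_equal(count_parameters(pb) / 1e6, 1.11)
  r <- complexity_report(list(a = pa, b = pb))
  expect_equal(r$parameter_reduction_percent, 93.08)
  # FLOP pair printing as 449.29 G and 22.74 G
  fa <- model_spec("a", 224645000L, list(spec_dense(224645000L, 1000L, bias = FALSE)))
  fb <- model_spec("b", 1137000L, list(spec_dense(1137000L, 10000L, bias = FALSE)))
  r2 <- complexity_report(list(a = fa, b = fb), include_elementwise = FALSE)
  expect_equal(r2$models$flops_giga, c(449.29, 22.74))
  expect_equal(r2$flops_reduction_percent, 94.94)
  # identical specs: both reductions 0.00
  r3 <- complexity_report(list(x = pa, y = pa))
  expect_equal(r3$parameter_reduction_percent, 0)
  expect_equal(r3$flops_reduction_percent, 0)
  expect_error(complexity_report(list(pa)), "at least two")
})

test_that("inference timing utility validates inputs and returns positive times", {
  expect_error(measure_inference_time(mini_cnn_bn(), repeats = 0L), ">= 1")
  res <- measure_inference_time(mini_cnn_bn(), repeats = 2L)
  expect_true(is.finite(res$median_ms) && res$median_ms > 0)
})
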