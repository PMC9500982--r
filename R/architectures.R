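# Declarative model specifications. A model_spec is an ordered list of layer
# records from which shape tables, layer censuses, parameter/FLOP counts and
# the numeric engine (nn.R) all derive, so the three views cannot drift apart.

.layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' Layer record constructors
#'
#' Building blocks for [model_spec()]. Kernels, strides and paddings are
#' `(d, k, k)`-style integer triples ordered depth (time), height, width.
#'
#' @param in_channels,out_channels Channel widths entering/leaving the layer.
#' @param kernel,stride,padding Integer triples for 3D convolution/pooling.
#' @param bias Whether the layer carries an additive bias term.
#' @param channels Channel width normalized by a batch-norm layer.
#' @param in_features,out_features Widths of a fully connected layer.
#' @param rate Dropout rate in `[0, 1)`.
#' @param input_size,hidden_size Per-time-step input width and state width of
#'   a recurrent (LSTM) layer.
#' @return A `layer_spec` record.
#' @name layer-constructors
NULL

#' @rdname layer-constructors
#' @export
spec_conv3d <- function(in_channels, out_channels, kernel = c(7L, 3L, 3L),
                        stride = c(1L, 1L, 1L), padding = c(3L, 1L, 1L),
                        bias = TRUE) {
  stopifnot(in_channels >= 1, out_channels >= 1, all(kernel >= 1),
            all(stride >= 1), all(padding >= 0))
  .layer("conv3d", in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels), kernel = as.integer(kernel),
         stride = as.integer(stride), padding = as.integer(padding),
         bias = isTRUE(bias))
}

#' @rdname layer-constructors
#' @export
spec_batchnorm <- function(channels) {
  .layer("batchnorm", channels = as.integer(channels))
}

#' @rdname layer-constructors
#' @export
spec_relu <- function() .layer("relu")

#' @rdname layer-constructors
#' @export
spec_tanh <- function() .layer("tanh")

#' @rdname layer-constructors
#' @export
spec_maxpool3d <- function(kernel, stride = kernel) {
  stopifnot(all(kernel >= 1), all(stride >= 1))
  .layer("maxpool3d", kernel = as.integer(kernel), stride = as.integer(stride))
}

#' @rdname layer-constructors
#' @export
spec_flatten <- function() .layer("flatten")

#' @rdname layer-constructors
#' @export
spec_dense <- function(in_features, out_features, bias = TRUE) {
  stopifnot(in_features >= 1, out_features >= 1)
  .layer("dense", in_features = as.integer(in_features),
         out_features = as.integer(out_features), bias = isTRUE(bias))
}

#' @rdname layer-constructors
#' @export
spec_dropout <- function(rate = 0.5) {
  stopifnot(rate >= 0, rate < 1)
  .layer("dropout", rate = rate)
}

#' @rdname layer-constructors
#' @export
spec_lstm <- function(input_size, hidden_size) {
  if (hidden_size < 1) stop("hidden_size must be positive")
  .layer("lstm", input_size = as.integer(input_size),
         hidden_size = as.integer(hidden_size))
}

#' Select the last time step of a sequence output
#' @rdname layer-constructors
#' @export
spec_last_step <- function() .layer("last_step")

#' Construct a model specification
#'
#' @param name Model name.
#' @param input_shape Integer vector: `(C, D, H, W)` for volumetric models or
#'   `(T, F)` (time steps, features) for sequence models.
#' @param layers List of layer records (see [spec_conv3d()] and friends).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, input_shape, layers) {
  stopifnot(is.character(name), is.numeric(input_shape), is.list(layers))
  spec <- structure(list(name = name, input_shape = as.integer(input_shape),
                         layers = layers),
                    class = "model_spec")
  .check_chaining(spec)
  spec
}

# channel chaining: every conv/batchnorm/dense width must match what the
# previous layer emits; caught at construction, not at run time
.check_chaining <- function(spec) {
  ch <- if (length(spec$input_shape) == 4L) spec$input_shape[1L] else spec$input_shape[2L]
  feat <- NA_integer_
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    switch(ly$kind,
      conv3d = {
        if (ly$in_channels != ch) {
          stop(sprintf("layer %d (conv3d): in_channels %d != incoming channels %d",
                       i, ly$in_channels, ch))
        }
        ch <- ly$out_channels
      },
      batchnorm = {
        if (ly$channels != ch) {
          stop(sprintf("layer %d (batchnorm): channels %d != incoming channels %d",
                       i, ly$channels, ch))
        }
      },
      dense = {
        if (!is.na(feat) && ly$in_features != feat) {
          stop(sprintf("layer %d (dense): in_features %d != incoming features %d",
                       i, ly$in_features, feat))
        }
        feat <- ly$out_features
      },
      lstm = {
        if (ly$input_size != ch) {
          stop(sprintf("layer %d (lstm): input_size %d != incoming features %d",
                       i, ly$input_size, ch))
        }
        ch <- ly$hidden_size
      },
      flatten = { feat <- NA_integer_ },
      last_step = { feat <- ch },
      NULL)
  }
  invisible(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cen <- layer_census(x)
  cat(sprintf("<model_spec> %s: input %s, %d layers (%s)\n", x$name,
              paste(x$input_shape, collapse = "x"), length(x$layers),
              paste(sprintf("%s:%d", names(cen[cen > 0]), cen[cen > 0]),
                    collapse = ", ")))
  invisible(x)
}

#' Channel-bottleneck 3D CNN
#'
#' Builds the channel-bottleneck network: a stem convolution block
#' (7x3x3 conv, batch norm, ReLU, 2x1x1 max pooling), five bottleneck blocks
#' (1x1x1 channel-reducing conv, 7x3x3 conv at the reduced width, 1x1x1
#' channel-expanding conv, each followed by batch norm + ReLU, then 2x2x2 max
#' pooling), and a dense head (flatten, fully connected `dense_width`, ReLU,
#' dropout 0.5, fully connected 2). All 7x3x3 convolutions use stride 1 and
#' padding 3x1x1 so they preserve spatial extent; 1x1x1 convolutions use
#' padding 0. Default bottleneck widths `(C_bn, C_out)` are (16,128),
#' (32,256), (64,256), (64,256), (64,256).
#'
#' @param input_shape `(C, D, H, W)`, default `c(1, 128, 64, 64)`.
#' @param dense_width Hidden width of the first fully connected layer. The
#'   architecture table lists 128; the complexity-report profile uses 64 (the
#'   value consistent with the published 1.11 M parameter total).
#' @param stem_channels Output channels of the stem convolution (default 64).
#' @param bottlenecks List of `(C_bn, C_out)` pairs, one per bottleneck block.
#' @param conv_bias Include conv bias terms (batch norm makes them redundant;
#'   kept by default so parameter counts are conservative).
#' @param dropout Dropout rate of the dense head.
#' @return A `model_spec`.
#' @export
build_cnn_bn <- function(input_shape = c(1L, 128L, 64L, 64L),
                         dense_width = 128L,
                         stem_channels = 64L,
                         bottlenecks = list(c(16L, 128L), c(32L, 256L),
                                            c(64L, 256L), c(64L, 256L),
                                            c(64L, 256L)),
                         conv_bias = TRUE,
                         dropout = 0.5) {
  layers <- list(
    spec_conv3d(input_shape[1L], stem_channels, c(7L, 3L, 3L),
                padding = c(3L, 1L, 1L), bias = conv_bias),
    spec_batchnorm(stem_channels),
    spec_relu(),
    spec_maxpool3d(c(2L, 1L, 1L)))
  ch <- stem_channels
  for (b in bottlenecks) {
    c_bn <- b[[1L]]; c_out <- b[[2L]]
    layers <- c(layers, list(
      spec_conv3d(ch, c_bn, c(1L, 1L, 1L), padding = c(0L, 0L, 0L), bias = conv_bias),
      spec_batchnorm(c_bn), spec_relu(),
      spec_conv3d(c_bn, c_bn, c(7L, 3L, 3L), padding = c(3L, 1L, 1L), bias = conv_bias),
      spec_batchnorm(c_bn), spec_relu(),
      spec_conv3d(c_bn, c_out, c(1L, 1L, 1L), padding = c(0L, 0L, 0L), bias = conv_bias),
      spec_batchnorm(c_out), spec_relu(),
      spec_maxpool3d(c(2L, 2L, 2L))))
    ch <- c_out
  }
  head_in <- .flat_features(input_shape, layers)
  layers <- c(layers, list(
    spec_flatten(),
    spec_dense(head_in, dense_width), spec_relu(), spec_dropout(dropout),
    spec_dense(dense_width, 2L)))
  model_spec("cnn-bn", input_shape, layers)
}

#' Plain C3D-style 3D CNN baseline
#'
#' Six convolution blocks (7x3x3 conv with padding 3x1x1, batch norm, ReLU,
#' max pooling: 2x1x1 after the first block, 2x2x2 after the rest), then
#' flatten, fully connected `dense_width`, ReLU, dropout, fully connected 2.
#' The default channel schedule 64, 128, 256, 256, 256, 256 with dense width
#' 512 is the package's reconstruction of the baseline (its internal widths
#' are not published); every element is overridable.
#'
#' @inheritParams build_cnn_bn
#' @param channels Output channels of the six conv blocks.
#' @param dense_width Hidden width of the first fully connected layer.
#' @return A `model_spec`.
#' @export
build_c3d <- function(input_shape = c(1L, 128L, 64L, 64L),
                      channels = c(64L, 128L, 256L, 256L, 256L, 256L),
                      dense_width = 512L,
                      conv_bias = TRUE,
                      dropout = 0.5) {
  layers <- list()
  ch <- input_shape[1L]
  for (i in seq_along(channels)) {
    pool <- if (i == 1L) c(2L, 1L, 1L) else c(2L, 2L, 2L)
    layers <- c(layers, list(
      spec_conv3d(ch, channels[i], c(7L, 3L, 3L), padding = c(3L, 1L, 1L),
                  bias = conv_bias),
      spec_batchnorm(channels[i]), spec_relu(),
      spec_maxpool3d(pool)))
    ch <- channels[i]
  }
  head_in <- .flat_features(input_shape, layers)
  layers <- c(layers, list(
    spec_flatten(),
    spec_dense(head_in, dense_width), spec_relu(), spec_dropout(dropout),
    spec_dense(dense_width, 2L)))
  model_spec("c3d", input_shape, layers)
}

#' Stacked-LSTM baseline
#'
#' Three stacked recurrent layers, each followed by a tanh activation, on raw
#' 1-s windows laid out as `T` time steps x `F` features (default 128 x 32);
#' the last time-step state feeds a dense head (fully connected `dense_width`,
#' ReLU, dropout 0.5, fully connected 2).
#'
#' @param input_shape `(T, F)`: sequence length and per-step features.
#' @param hidden_size State width of each recurrent layer (default 128).
#' @param dense_width Hidden width of the first fully connected layer.
#' @param dropout Dropout rate.
#' @return A `model_spec`.
#' @export
build_lstm <- function(input_shape = c(128L, 32L), hidden_size = 128L,
                       dense_width = 128L, dropout = 0.5) {
  if (hidden_size < 1) stop("hidden_size must be positive")
  layers <- list(
    spec_lstm(input_shape[2L], hidden_size), spec_tanh(),
    spec_lstm(hidden_size, hidden_size), spec_tanh(),
    spec_lstm(hidden_size, hidden_size), spec_tanh(),
    spec_last_step(),
    spec_dense(hidden_size, dense_width), spec_relu(), spec_dropout(dropout),
    spec_dense(dense_width, 2L))
  model_spec("lstm", input_shape, layers)
}

.flat_features <- function(input_shape, layers) {
  shp <- .propagate(input_shape, layers)
  as.integer(prod(shp))
}

# shape propagation core; errors name the offending layer
.propagate <- function(shape, layers, record = FALSE) {
  recs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    inshape <- shape
    shape <- switch(ly$kind,
      conv3d = {
        if (length(shape) != 4L) stop(sprintf("layer %d (conv3d): needs a (C,D,H,W) input", i))
        sp <- floor((shape[2:4] + 2L * ly$padding - ly$kernel) / ly$stride) + 1L
        c(ly$out_channels, sp)
      },
      batchnorm = shape,
      relu = shape,
      tanh = shape,
      dropout = shape,
      maxpool3d = {
        if (length(shape) != 4L) stop(sprintf("layer %d (maxpool3d): needs a (C,D,H,W) input", i))
        if (any((shape[2:4] - ly$kernel) %% ly$stride != 0)) {
          stop(sprintf("layer %d (maxpool3d %s): input extent %s not divisible by the pooling kernel",
                       i, paste(ly$kernel, collapse = "x"),
                       paste(shape[2:4], collapse = "x")))
        }
        c(shape[1L], (shape[2:4] - ly$kernel) %/% ly$stride + 1L)
      },
      flatten = prod(shape),
      dense = {
        if (length(shape) != 1L || shape != ly$in_features) {
          stop(sprintf("layer %d (dense): expects %d features, got %s", i,
                       ly$in_features, paste(shape, collapse = "x")))
        }
        ly$out_features
      },
      lstm = {
        if (length(shape) != 2L) stop(sprintf("layer %d (lstm): needs a (T,F) input", i))
        c(shape[1L], ly$hidden_size)
      },
      last_step = {
        if (length(shape) != 2L) stop(sprintf("layer %d (last_step): needs a (T,F) input", i))
        shape[2L]
      },
      stop(sprintf("layer %d: unknown kind '%s'", i, ly$kind)))
    if (any(shape <= 0)) {
      stop(sprintf("layer %d (%s): nonpositive output dimension (%s)", i, ly$kind,
                   paste(shape, collapse = "x")))
    }
    shape <- as.integer(shape)
    if (record) recs[[i]] <- list(layer = i, kind = ly$kind,
                                  input_shape = as.integer(inshape),
                                  output_shape = shape)
  }
  if (record) recs else shape
}

#' Symbolic shape propagation through a model specification
#'
#' Propagates an input shape layer by layer without any numerics. Convolution
#' output extent per axis is `floor((n + 2 pad - kernel) / stride) + 1`;
#' max-pooling requires exact divisibility and errors otherwise, naming the
#' offending layer.
#'
#' @param spec A [model_spec()].
#' @param input_shape Input shape; defaults to `spec$input_shape`.
#' @return A data frame with one row per layer: `layer`, `kind`, `input`,
#'   `output` (printable `C x D x H x W` strings) and list columns
#'   `input_shape` / `output_shape` holding the integer vectors.
#' @export
forward_shapes <- function(spec, input_shape = spec$input_shape) {
  stopifnot(inherits(spec, "model_spec"))
  recs <- .propagate(as.integer(input_shape), spec$layers, record = TRUE)
  fmt <- function(s) paste(s, collapse = "x")
  out <- data.frame(
    layer = vapply(recs, `[[`, integer(1), "layer"),
    kind = vapply(recs, `[[`, character(1), "kind"),
    input = vapply(recs, function(r) fmt(r$input_shape), character(1)),
    output = vapply(recs, function(r) fmt(r$output_shape), character(1)),
    stringsAsFactors = FALSE)
  out$input_shape <- lapply(recs, `[[`, "input_shape")
  out$output_shape <- lapply(recs, `[[`, "output_shape")
  out
}

.layer_kinds <- c("conv3d", "batchnorm", "relu", "maxpool3d", "flatten",
                  "dense", "dropout", "lstm", "tanh", "last_step")

#' Count layers of each kind in a specification
#'
#' @param spec A [model_spec()].
#' @return Named integer vector over all known layer kinds (zero where absent).
#' @export
layer_census <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  out <- stats::setNames(integer(length(.layer_kinds)), .layer_kinds)
  tab <- table(kinds)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Serialize / deserialize a model specification as JSON
#'
#' @param spec A [model_spec()].
#' @param path File path.
#' @return `read_model_spec()` returns the reconstructed `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  payload <- list(name = spec$name, input_shape = spec$input_shape,
                  layers = lapply(spec$layers, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(payload$layers, function(ly) {
    ly$kind <- as.character(ly$kind)
    for (f in c("in_channels", "out_channels", "kernel", "stride", "padding",
                "channels", "in_features", "out_features", "input_size",
                "hidden_size")) {
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    }
    structure(ly, class = "layer_spec")
  })
  model_spec(as.character(payload$name), as.integer(payload$input_shape), layers)
}
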