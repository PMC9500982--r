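# Trainable-parameter and FLOP accounting over model specifications.
# Conventions (documented, testable): parameters count every trainable scalar
# (conv/dense weights + biases, batch-norm scale and shift, all LSTM gate
# weights with both bias sets); FLOPs count 2 per multiply-accumulate for
# convolution and dense layers, with optional elementwise add-ons (batch norm
# 2 ops/element, ReLU/tanh 1 op/element, max pooling kernel_volume - 1
# comparisons per output element). Bias additions are excluded by default.

# two-decimal half-up rounding, matching printed "millions"/"giga" tables
.round2 <- function(x) floor(x * 100 + 0.5) / 100

.layer_params <- function(ly) {
  switch(ly$kind,  # double arithmetic: counts can exceed .Machine$integer.max
    conv3d = as.numeric(ly$out_channels) * ly$in_channels * prod(ly$kernel) +
      if (isTRUE(ly$bias)) ly$out_channels else 0,
    batchnorm = 2 * as.numeric(ly$channels),
    dense = as.numeric(ly$out_features) * ly$in_features +
      if (isTRUE(ly$bias)) ly$out_features else 0,
    lstm = 4 * (as.numeric(ly$hidden_size) * (ly$input_size + ly$hidden_size) +
                  2 * ly$hidden_size),
    0)
}

#' Count trainable parameters of a model specification
#'
#' Closed-form per-layer accounting: conv3d `C_out C_in d k k (+ C_out)`;
#' batch norm `2C`; dense `out * in + out`; recurrent layer
#' `4 (h (in + h) + 2h)` (four gates, input and recurrent bias sets);
#' activation, pooling, flatten and dropout layers hold no parameters.
#'
#' @param spec A [model_spec()].
#' @return Total parameter count (numeric scalar, exact integer value).
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  sum(vapply(spec$layers, .layer_params, numeric(1)))
}

#' Count forward-pass FLOPs of a model specification
#'
#' Multiply-accumulate operations are counted as 2 FLOPs. Convolution cost is
#' `2 x output_elements x C_in d k k`, dense cost `2 x out x in`, recurrent
#' cost `2 x T x 4 h (in + h)`. Elementwise add-ons (selectable): batch norm 2
#' ops/element, ReLU/tanh 1 op/element, max pooling `kernel_volume - 1`
#' comparisons per output element. Totals are reported both with and without
#' the add-ons.
#'
#' @param spec A [model_spec()].
#' @param input_shape Input shape; defaults to `spec$input_shape`.
#' @param include_elementwise Include the elementwise add-ons in `total`.
#' @param include_bias Count bias additions (1 op per output element).
#' @return List with `total`, `conv_dense` (MAC-derived core), `elementwise`,
#'   `total_giga` (2 dp), and a `per_layer` data frame.
#' @export
count_flops <- function(spec, input_shape = spec$input_shape,
                        include_elementwise = TRUE, include_bias = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  shp <- forward_shapes(spec, input_shape)
  core <- numeric(length(spec$layers))
  elem <- numeric(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    out_shape <- shp$output_shape[[i]]
    out_els <- prod(out_shape)
    if (ly$kind == "conv3d") {
      core[i] <- 2 * out_els * ly$in_channels * prod(ly$kernel)
      if (include_bias && isTRUE(ly$bias)) core[i] <- core[i] + out_els
    } else if (ly$kind == "dense") {
      core[i] <- 2 * ly$out_features * ly$in_features
      if (include_bias && isTRUE(ly$bias)) core[i] <- core[i] + ly$out_features
    } else if (ly$kind == "lstm") {
      core[i] <- 2 * out_shape[1L] * 4 * ly$hidden_size *
        (ly$input_size + ly$hidden_size)
    } else if (ly$kind == "batchnorm") {
      elem[i] <- 2 * out_els
    } else if (ly$kind %in% c("relu", "tanh")) {
      elem[i] <- out_els
    } else if (ly$kind == "maxpool3d") {
      elem[i] <- (prod(ly$kernel) - 1) * out_els
    }
  }
  total_core <- sum(core)
  total_elem <- sum(elem)
  total <- total_core + if (include_elementwise) total_elem else 0
  list(total = total,
       conv_dense = total_core,
       elementwise = total_elem,
       total_giga = .round2(total / 1e9),
       per_layer = data.frame(layer = seq_along(spec$layers),
                              kind = shp$kind, core_flops = core,
                              elementwise_flops = elem))
}

#' Complexity report with pairwise reduction percentages
#'
#' Tabulates parameter and FLOP totals for a set of models and, for a
#' designated (baseline, proposed) pair, the percentage reductions
#' `100 (1 - small/large)` computed from the two-decimal rounded
#' millions/giga values (matching how such tables are printed).
#'
#' @param specs Named list of [model_spec()] objects (at least two).
#' @param input_shape Optional common input shape; default: each spec's own.
#' @param baseline,proposed Names (in `specs`) of the pair to compare;
#'   defaults to the first and second spec.
#' @param ... Passed to [count_flops()].
#' @return An object of class `complexity_report`: list with `models` (data
#'   frame: parameters, parameters_millions, flops, flops_giga per model),
#'   `parameter_reduction_percent`, `flops_reduction_percent`, and
#'   `per_layer` breakdowns.
#' @export
complexity_report <- function(specs, input_shape = NULL,
                              baseline = NULL, proposed = NULL, ...) {
  if (!is.list(specs) || length(specs) < 2L) {
    stop("complexity_report() needs at least two model specs")
  }
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  }
  if (is.null(baseline)) baseline <- names(specs)[1L]
  if (is.null(proposed)) proposed <- names(specs)[2L]
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    ishape <- if (is.null(input_shape)) sp$input_shape else input_shape
    p <- count_parameters(sp)
    f <- count_flops(sp, ishape, ...)
    data.frame(model = nm, parameters = p,
               parameters_millions = .round2(p / 1e6),
               flops = f$total, flops_giga = .round2(f$total / 1e9))
  })
  models <- do.call(rbind, rows)
  per_layer <- lapply(stats::setNames(names(specs), names(specs)), function(nm) {
    ishape <- if (is.null(input_shape)) specs[[nm]]$input_shape else input_shape
    count_flops(specs[[nm]], ishape, ...)$per_layer
  })
  red <- function(a, b) {  # reduction of the smaller relative to the larger
    lo <- min(a, b); hi <- max(a, b)
    .round2(100 * (1 - lo / hi))
  }
  pb <- models[models$model == baseline, ]
  pp <- models[models$model == proposed, ]
  structure(
    list(models = models,
         baseline = baseline, proposed = proposed,
         parameter_reduction_percent = red(pb$parameters_millions,
                                           pp$parameters_millions),
         flops_reduction_percent = red(pb$flops_giga, pp$flops_giga),
         per_layer = per_layer),
    class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("<complexity_report>\n")
  print(x$models[, c("model", "parameters_millions", "flops_giga")],
        row.names = FALSE)
  cat(sprintf("%s vs %s: parameter reduction %.2f%%, FLOP reduction %.2f%%\n",
              x$proposed, x$baseline,
              x$parameter_reduction_percent, x$flops_reduction_percent))
  invisible(x)
}

#' Wall-clock inference time of an instantiated model
#'
#' Median milliseconds per forward pass after one warm-up pass. The result is
#' hardware- and backend-dependent and is reported for orientation only; it
#' is not a validated quantity.
#'
#' @param model An instantiated model ([instantiate_model()]) or a
#'   [model_spec()] (instantiated with seed 0).
#' @param input_shape Input shape per sample; defaults to the spec's.
#' @param repeats Number of timed passes (>= 1).
#' @param batch_size Batch size of the timed input.
#' @return List with `median_ms`, `min_ms`, `max_ms`, `repeats`.
#' @export
measure_inference_time <- function(model, input_shape = NULL, repeats = 5L,
                                   batch_size = 1L) {
  if (repeats < 1L) stop("repeats must be >= 1")
  if (inherits(model, "model_spec")) model <- instantiate_model(model, seed = 0L)
  spec <- model$spec
  if (is.null(input_shape)) input_shape <- spec$input_shape
  x <- array(stats::rnorm(batch_size * prod(input_shape)),
             dim = c(batch_size, input_shape))
  nn_forward(model, x)  # warm-up
  times <- vapply(seq_len(repeats), function(i) {
    unname(system.time(nn_forward(model, x))["elapsed"]) * 1000
  }, numeric(1))
  list(median_ms = stats::median(times), min_ms = min(times),
       max_ms = max(times), repeats = repeats)
}
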