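# Numeric engine over model_spec: seeded parameter initialization, forward
# pass (with per-layer caches), exact backpropagation for the feed-forward
# layer kinds, and momentum SGD. Batches are R arrays with dim (N, C, D, H, W)
# for volumetric models and (N, T, F) for sequence models. The convolution and
# pooling inner loops live in src/kernels.cpp.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Instantiate numeric parameters for a model specification
#'
#' Initialization: Kaiming-style fan-in normal draws for convolution and
#' dense weights (`sd = sqrt(2 / fan_in)`), zero biases, batch-norm scale 1 /
#' shift 0, uniform `(-1/sqrt(h), 1/sqrt(h))` input weights and per-gate
#' orthogonal recurrent weights for LSTM layers. Fully reproducible: the same
#' seed yields bit-identical parameters.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the parameter draws.
#' @return An object of class `nn_model`: list with `spec`, `params` (one
#'   entry per layer; `NULL` for parameter-free layers), and `seed`.
#' @export
instantiate_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  params <- lapply(spec$layers, function(ly) {
    switch(ly$kind,
      conv3d = {
        fan_in <- ly$in_channels * prod(ly$kernel)
        W <- array(rnorm(ly$out_channels * fan_in, sd = sqrt(2 / fan_in)),
                   dim = c(ly$out_channels, ly$in_channels, ly$kernel))
        list(W = W, b = if (isTRUE(ly$bias)) numeric(ly$out_channels) else NULL)
      },
      batchnorm = list(gamma = rep(1, ly$channels), beta = numeric(ly$channels),
                       running_mean = numeric(ly$channels),
                       running_var = rep(1, ly$channels),
                       eps = 1e-5, momentum = 0.1),
      dense = list(W = matrix(rnorm(ly$in_features * ly$out_features,
                                    sd = sqrt(2 / ly$in_features)),
                              ly$in_features, ly$out_features),
                   b = if (isTRUE(ly$bias)) numeric(ly$out_features) else NULL),
      lstm = {
        h <- ly$hidden_size; f <- ly$input_size
        k <- 1 / sqrt(h)
        W_hh <- do.call(rbind, lapply(1:4, function(g) {
          qr.Q(qr(matrix(rnorm(h * h), h, h)))
        }))
        list(W_ih = matrix(runif(4 * h * f, -k, k), 4 * h, f),
             W_hh = W_hh, b_ih = numeric(4 * h), b_hh = numeric(4 * h))
      },
      NULL)
  })
  structure(list(spec = spec, params = params, seed = seed), class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %s, %s trainable parameters (seed %d)\n",
              x$spec$name, format(count_parameters(x$spec), big.mark = ","),
              x$seed))
  invisible(x)
}

#' Enumerate trainable parameters of an instantiated model
#'
#' Direct enumeration over the stored numeric arrays; serves as the runtime
#' cross-check of the closed-form [count_parameters()].
#'
#' @param model An `nn_model`.
#' @return Total number of trainable scalars.
#' @export
n_trainable <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  tot <- 0
  for (p in model$params) {
    if (is.null(p)) next
    for (f in c("W", "b", "gamma", "beta", "W_ih", "W_hh", "b_ih", "b_hh")) {
      if (!is.null(p[[f]])) tot <- tot + length(p[[f]])
    }
  }
  tot
}

.bn_forward <- function(x, p, training) {
  dm <- dim(x)
  C <- dm[2L]
  y <- x
  cache <- list(xhat = x, invstd = numeric(C), dims = dm)
  for (c in seq_len(C)) {
    v <- x[, c, , , , drop = FALSE]
    if (training) {
      mu <- mean(v)
      va <- mean((v - mu)^2)
      p$running_mean[c] <- (1 - p$momentum) * p$running_mean[c] + p$momentum * mu
      p$running_var[c] <- (1 - p$momentum) * p$running_var[c] + p$momentum * va
    } else {
      mu <- p$running_mean[c]
      va <- p$running_var[c]
    }
    invstd <- 1 / sqrt(va + p$eps)
    xhat <- (v - mu) * invstd
    y[, c, , , ] <- p$gamma[c] * xhat + p$beta[c]
    cache$xhat[, c, , , ] <- xhat
    cache$invstd[c] <- invstd
  }
  list(y = y, cache = cache, params = p)
}

.bn_backward <- function(dy, p, cache) {
  dm <- cache$dims
  C <- dm[2L]
  m <- prod(dm) / C
  dx <- dy
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  for (c in seq_len(C)) {
    g <- dy[, c, , , , drop = FALSE]
    xhat <- cache$xhat[, c, , , , drop = FALSE]
    dgamma[c] <- sum(g * xhat)
    dbeta[c] <- sum(g)
    dxhat <- g * p$gamma[c]
    dx[, c, , , ] <- (cache$invstd[c] / m) *
      (m * dxhat - sum(dxhat) - xhat * sum(dxhat * xhat))
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.lstm_forward <- function(x, p, hidden_size) {
  dm <- dim(x)
  N <- dm[1L]; TT <- dm[2L]
  h <- matrix(0, N, hidden_size)
  cc <- matrix(0, N, hidden_size)
  out <- array(0, c(N, TT, hidden_size))
  hs <- hidden_size
  b <- p$b_ih + p$b_hh
  for (t in seq_len(TT)) {
    xt <- matrix(x[, t, ], nrow = N)
    gates <- xt %*% t(p$W_ih) + h %*% t(p$W_hh) +
      matrix(b, N, 4 * hs, byrow = TRUE)
    i <- .sigmoid(gates[, 1:hs, drop = FALSE])
    f <- .sigmoid(gates[, (hs + 1):(2 * hs), drop = FALSE])
    g <- tanh(gates[, (2 * hs + 1):(3 * hs), drop = FALSE])
    o <- .sigmoid(gates[, (3 * hs + 1):(4 * hs), drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    out[, t, ] <- h
  }
  out
}

# forward pass; when cache=TRUE returns per-layer caches for backprop
.forward_pass <- function(model, x, training = FALSE, cache = FALSE) {
  layers <- model$spec$layers
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    p <- model$params[[i]]
    if (ly$kind == "conv3d") {
      xin <- x
      x <- conv3d_fwd(as.numeric(x), dim(x), as.numeric(p$W), dim(p$W),
                      if (is.null(p$b)) numeric(0) else p$b,
                      ly$stride, ly$padding)
      if (cache) caches[[i]] <- list(x = xin)
    } else if (ly$kind == "batchnorm") {
      res <- .bn_forward(x, p, training)
      x <- res$y
      model$params[[i]] <- res$params  # running-stat update
      if (cache) caches[[i]] <- res$cache
    } else if (ly$kind == "relu") {
      mask <- x > 0
      x <- x * mask
      if (cache) caches[[i]] <- list(mask = mask)
    } else if (ly$kind == "tanh") {
      x <- tanh(x)
      if (cache) caches[[i]] <- list(y = x)
    } else if (ly$kind == "maxpool3d") {
      res <- maxpool3d_fwd(as.numeric(x), dim(x), ly$kernel, ly$stride)
      if (cache) caches[[i]] <- list(argmax = res$argmax, xdim = dim(x))
      x <- res$y
    } else if (ly$kind == "flatten") {
      if (cache) caches[[i]] <- list(xdim = dim(x))
      x <- matrix(x, nrow = dim(x)[1L])
    } else if (ly$kind == "dense") {
      xin <- x
      x <- x %*% p$W
      if (!is.null(p$b)) x <- x + matrix(p$b, nrow(x), ncol(x), byrow = TRUE)
      if (cache) caches[[i]] <- list(x = xin)
    } else if (ly$kind == "dropout") {
      if (training) {
        keep <- 1 - ly$rate
        mask <- array((runif(length(x)) < keep) / keep, dim = dim(x))
        x <- x * mask
        if (cache) caches[[i]] <- list(mask = mask)
      } else if (cache) {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$kind == "lstm") {
      x <- .lstm_forward(x, p, ly$hidden_size)
    } else if (ly$kind == "last_step") {
      x <- matrix(x[, dim(x)[2L], ], nrow = dim(x)[1L])
    } else {
      stop("unknown layer kind: ", ly$kind)
    }
  }
  list(out = x, caches = caches, model = model)
}

#' Run a forward pass through an instantiated model
#'
#' @param model An `nn_model` from [instantiate_model()].
#' @param x Batch array: `(N, C, D, H, W)` for volumetric models, `(N, T, F)`
#'   for sequence models.
#' @param training Use batch statistics for batch norm and apply dropout.
#' @return The network output (for the shipped architectures, an `N x 2`
#'   logit matrix).
#' @export
nn_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "nn_model"))
  .forward_pass(model, x, training = training, cache = FALSE)$out
}

# softmax cross-entropy from logits; returns loss and dlogits (mean reduction)
.softmax_ce <- function(logits, labels) {
  N <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  picked <- p[cbind(seq_len(N), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  onehot <- matrix(0, N, ncol(logits))
  onehot[cbind(seq_len(N), labels + 1L)] <- 1
  list(loss = loss, prob = p, dlogits = (p - onehot) / N)
}

.backward_pass <- function(model, caches, dout) {
  layers <- model$spec$layers
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    p <- model$params[[i]]
    if (ly$kind == "conv3d") {
      cc <- caches[[i]]
      res <- conv3d_bwd(as.numeric(cc$x), dim(cc$x), as.numeric(p$W), dim(p$W),
                        as.numeric(dout), dim(dout), ly$stride, ly$padding,
                        !is.null(p$b))
      grads[[i]] <- list(W = res$dw, b = if (is.null(p$b)) NULL else res$db)
      dout <- res$dx
    } else if (ly$kind == "batchnorm") {
      res <- .bn_backward(dout, p, caches[[i]])
      grads[[i]] <- res$grads
      dout <- res$dx
    } else if (ly$kind == "relu") {
      dout <- dout * caches[[i]]$mask
    } else if (ly$kind == "tanh") {
      dout <- dout * (1 - caches[[i]]$y^2)
    } else if (ly$kind == "maxpool3d") {
      cc <- caches[[i]]
      dout <- maxpool3d_bwd(as.numeric(dout), cc$argmax, cc$xdim)
    } else if (ly$kind == "flatten") {
      dout <- array(dout, dim = caches[[i]]$xdim)
    } else if (ly$kind == "dense") {
      cc <- caches[[i]]
      grads[[i]] <- list(W = t(cc$x) %*% dout,
                         b = if (is.null(p$b)) NULL else colSums(dout))
      dout <- dout %*% t(p$W)
    } else if (ly$kind == "dropout") {
      if (!is.null(caches[[i]]$mask)) dout <- dout * caches[[i]]$mask
    } else if (ly$kind %in% c("lstm", "last_step")) {
      stop("backpropagation is implemented for the feed-forward layer kinds; ",
           "recurrent specs support forward passes only")
    }
  }
  grads
}

.sgd_step <- function(model, grads, velocity, lr, momentum, weight_decay = 0) {
  for (i in seq_along(model$params)) {
    p <- model$params[[i]]
    g <- grads[[i]]
    if (is.null(p) || is.null(g)) next
    for (f in names(g)) {
      if (is.null(g[[f]])) next
      gf <- g[[f]]
      if (weight_decay > 0 && f == "W") gf <- gf + weight_decay * p[[f]]
      if (momentum > 0) {
        v <- velocity[[i]][[f]]
        if (is.null(v)) v <- 0 * gf
        v <- momentum * v - lr * gf
        velocity[[i]][[f]] <- v
        p[[f]] <- p[[f]] + v
      } else {
        p[[f]] <- p[[f]] - lr * gf
      }
    }
    model$params[[i]] <- p
  }
  list(model = model, velocity = velocity)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: mini-batch 32, initial learning
#' rate 0.01 decayed by 0.9 every 10 epochs, 90 epochs, plain SGD (momentum
#' 0, no weight decay), 80/20 random window-level splits repeated 5 times.
#'
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor.
#' @param lr_step_epochs Epochs between decays.
#' @param epochs Training epochs (fixed budget, no early stopping).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on weights (0 by default).
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @param split_fraction Training fraction of random splits.
#' @param repeats Number of repeated split/train/evaluate runs.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, initial_lr = 0.01, lr_decay = 0.9,
                         lr_step_epochs = 10L, epochs = 90L, momentum = 0,
                         weight_decay = 0, seed = 0L, split_fraction = 0.8,
                         repeats = 5L) {
  stopifnot(batch_size >= 1, initial_lr > 0, lr_decay > 0, lr_step_epochs >= 1,
            epochs >= 1, momentum >= 0, weight_decay >= 0, repeats >= 1)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie in (0, 1)")
  }
  structure(list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
                 lr_decay = lr_decay, lr_step_epochs = as.integer(lr_step_epochs),
                 epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 split_fraction = split_fraction, repeats = as.integer(repeats)),
            class = "train_config")
}

#' Learning rate at a given epoch under the step-decay schedule
#'
#' @param config A [train_config()].
#' @param epoch 1-based epoch number.
#' @return `initial_lr * lr_decay^floor((epoch - 1) / lr_step_epochs)`.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$initial_lr * config$lr_decay^((epoch - 1) %/% config$lr_step_epochs)
}

# stack window tensors into an (N, 1, D, H, W) batch with 0/1 labels
.dataset_to_batch <- function(dataset, task = c("valence", "arousal")) {
  task <- match.arg(task)
  n <- length(dataset$windows)
  if (n == 0L) stop("dataset is empty")
  d <- dim(dataset$windows[[1L]]$data)
  x <- array(0, c(n, 1L, d))
  for (i in seq_len(n)) x[i, 1L, , , ] <- dataset$windows[[i]]$data
  lab <- dataset$provenance[[paste0("label_", task)]]
  if (anyNA(lab)) stop("dataset has unlabelled windows")
  list(x = x, y = as.integer(lab))
}

#' Train a model with mini-batch SGD and cross-entropy loss
#'
#' Minimizes the mean binary cross-entropy (softmax over the two output
#' logits) over shuffled mini-batches, with the step-decay learning-rate
#' schedule of [train_config()]. The run is fully seed-reproducible on one
#' device: initialization, shuffling and dropout all draw from the seeded RNG
#' stream. A non-finite loss aborts with a diagnostic. Recurrent specs are
#' not trainable with this engine (forward passes only) and raise an error.
#'
#' @param spec A feed-forward [model_spec()].
#' @param dataset A `window_dataset` from [build_dataset()], or a list with
#'   elements `x` (batch array) and `y` (0/1 labels).
#' @param task `"valence"` or `"arousal"` (ignored when `dataset` is a raw
#'   batch list).
#' @param config A [train_config()].
#' @return Object of class `trained_model`: list with the fitted `model`, the
#'   per-epoch `history` (epoch, lr, loss, train accuracy), `config`, `task`.
#' @export
train_model <- function(spec, dataset, task = "valence", config = train_config()) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(vapply(spec$layers, `[[`, character(1), "kind") == "lstm")) {
    stop("train_model() supports feed-forward convolutional specs; ",
         "recurrent specs support forward passes only")
  }
  batch <- if (inherits(dataset, "window_dataset")) {
    .dataset_to_batch(dataset, task)
  } else {
    dataset
  }
  x <- batch$x; y <- batch$y
  stopifnot(all(y %in% c(0L, 1L)))
  N <- dim(x)[1L]
  model <- instantiate_model(spec, seed = config$seed)
  velocity <- vector("list", length(spec$layers))
  for (i in seq_along(velocity)) velocity[[i]] <- list()
  history <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                        accuracy = numeric(0))
  ndim <- length(dim(x))
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample(N)
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, N)]
      xb <- if (ndim == 5L) x[idx, , , , , drop = FALSE] else x[idx, , , drop = FALSE]
      yb <- y[idx]
      fw <- .forward_pass(model, xb, training = TRUE, cache = TRUE)
      model <- fw$model
      ce <- .softmax_ce(fw$out, yb)
      if (!is.finite(ce$loss)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d (lr %.4g)",
                     epoch, lr))
      }
      grads <- .backward_pass(model, fw$caches, ce$dlogits)
      upd <- .sgd_step(model, grads, velocity, lr, config$momentum,
                       config$weight_decay)
      model <- upd$model
      velocity <- upd$velocity
      losses <- c(losses, ce$loss * length(idx))
      correct <- correct + sum(max.col(ce$prob) - 1L == yb)
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = sum(losses) / N,
                                         accuracy = correct / N))
  }
  structure(list(model = model, history = history, config = config, task = task),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<trained_model> %s (%s): %d epochs, final loss %.4f, train accuracy %.3f\n",
              x$model$spec$name, x$task, nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}

#' Predict class probabilities and labels
#'
#' @param object A `trained_model` or `nn_model`.
#' @param newdata A `window_dataset` or a batch array.
#' @param task Label task used when `newdata` is a `window_dataset` (only
#'   affects which labels are returned alongside predictions).
#' @return List with `prob` (`N x 2` softmax matrix), `label` (0/1 predicted),
#'   and `actual` (0/1, when available).
#' @export
predict_model <- function(object, newdata, task = "valence") {
  model <- if (inherits(object, "trained_model")) object$model else object
  actual <- NULL
  x <- if (inherits(newdata, "window_dataset")) {
    b <- .dataset_to_batch(newdata, task)
    actual <- b$y
    b$x
  } else {
    newdata
  }
  logits <- nn_forward(model, x, training = FALSE)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  list(prob = p, label = max.col(p) - 1L, actual = actual)
}
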