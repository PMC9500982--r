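# Label binarization, random splits, the cross-entropy loss in probability
# form, confusion counts and derived metrics, and the repeated
# split/train/evaluate harness.

#' Binarize a 1-9 rating at a threshold
#'
#' Ratings strictly above the threshold are "high" (1); the boundary value is
#' assigned to "low" (0) — a documented convention, since rating scales place
#' the neutral anchor at the threshold.
#'
#' @param rating Numeric rating(s) in `[1, 9]`.
#' @param threshold Cut point (default 5).
#' @return Integer 0 (low) / 1 (high), vectorized over `rating`.
#' @export
binarize_rating <- function(rating, threshold = 5) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 9)) {
    stop("ratings must lie in [1, 9]; got ",
         paste(utils::head(rating[!is.finite(rating) | rating < 1 | rating > 9]),
               collapse = ", "))
  }
  as.integer(rating > threshold)
}

.subset_windows <- function(dataset, idx) {
  structure(list(windows = dataset$windows[idx],
                 provenance = dataset$provenance[idx, , drop = FALSE]),
            class = "window_dataset")
}

#' Random window-level train/test split
#'
#' Uniformly random partition of the windows: `round(fraction * n)` training
#' windows, the rest test; disjoint and exhaustive, reproducible under the
#' seed. (Window-level splitting mirrors the reference protocol; note that
#' windows of one trial can land on both sides, so trial identity leaks
#' between the sets.)
#'
#' @param dataset A nonempty `window_dataset`.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` (`window_dataset`s) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 0L) {
  stopifnot(inherits(dataset, "window_dataset"))
  n <- length(dataset$windows)
  if (n == 0L) stop("dataset is empty")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  n_train <- round(fraction * n)
  train_idx <- sort(sample(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = .subset_windows(dataset, train_idx),
       test = .subset_windows(dataset, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Mean binary cross-entropy loss in probability form
#'
#' `L = -(1/N) sum(y log p + (1 - y) log(1 - p))` with natural logarithms;
#' predicted probabilities are clipped to `[eps, 1 - eps]` before the logs.
#'
#' @param y Binary labels (0/1).
#' @param y_hat Predicted probabilities of class 1, in `[0, 1]`.
#' @param eps Clipping constant (default `1e-7`).
#' @return Nonnegative scalar loss.
#' @export
cross_entropy_loss <- function(y, y_hat, eps = 1e-7) {
  if (length(y) == 0L) stop("empty sample: N must be positive")
  if (length(y) != length(y_hat)) {
    stop(sprintf("length mismatch: %d labels vs %d probabilities",
                 length(y), length(y_hat)))
  }
  stopifnot(all(y %in% c(0, 1)))
  if (any(y_hat < 0 | y_hat > 1)) stop("probabilities must lie in [0, 1]")
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Confusion counts for binary predictions
#'
#' "High" (1) is the positive class.
#'
#' @param predicted,actual Equal-length binary (0/1) vectors.
#' @return Object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  if (length(predicted) == 0L) stop("empty prediction vector")
  if (length(predicted) != length(actual)) {
    stop(sprintf("length mismatch: %d predicted vs %d actual",
                 length(predicted), length(actual)))
  }
  stopifnot(all(predicted %in% c(0, 1)), all(actual %in% c(0, 1)))
  structure(list(TP = sum(predicted == 1 & actual == 1),
                 TN = sum(predicted == 0 & actual == 0),
                 FP = sum(predicted == 1 & actual == 0),
                 FN = sum(predicted == 0 & actual == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Recall, precision, F1 and accuracy from confusion counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2PR/(P+R)`, `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A zero denominator
#' yields 0 for that metric, with the metric name recorded in the
#' `degenerate` field.
#'
#' @param counts A [confusion_counts()] (or list with TP/TN/FP/FN).
#' @return Object of class `metrics_record`: list with `recall`, `precision`,
#'   `f1`, `accuracy`, `degenerate` (character vector of flagged metrics).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total <= 0) stop("confusion counts sum to zero")
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  recall <- safe(TP, TP + FN, "recall")
  precision <- safe(TP, TP + FP, "precision")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  if (length(degenerate) > 0) {
    warning("degenerate metric denominator(s): ",
            paste(unique(degenerate), collapse = ", "), call. = FALSE)
  }
  structure(list(recall = recall, precision = precision, f1 = f1,
                 accuracy = (TP + TN) / total,
                 degenerate = unique(degenerate)),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> recall %.4f, precision %.4f, F1 %.4f, accuracy %.4f\n",
              x$recall, x$precision, x$f1, x$accuracy))
  invisible(x)
}

# population standard deviation (n in the denominator), used for the
# mean (SD) presentation over a small fixed number of repeats
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Repeated split/train/evaluate runs with mean (SD) metrics
#'
#' For each repeat `r`: a fresh random window-level split (seed
#' `config$seed + r`), training on the training windows, evaluation on the
#' held-out windows; confusion counts are collected per repeat and the four
#' metrics are aggregated as mean and population SD across repeats.
#'
#' @param spec A feed-forward [model_spec()].
#' @param dataset A `window_dataset`.
#' @param config A [train_config()] (`repeats`, `split_fraction`, `seed`).
#' @param tasks Tasks to evaluate (`"valence"`, `"arousal"`, or both).
#' @return Object of class `repeated_evaluation`: list with `per_repeat`
#'   (data frame of counts + metrics per task and repeat), `summary` (mean
#'   and SD per task and metric), and `confusions` (list of
#'   [confusion_counts()], one per task and repeat).
#' @export
run_repeated_evaluation <- function(spec, dataset, config = train_config(),
                                    tasks = c("valence", "arousal")) {
  stopifnot(config$repeats >= 1)
  per_repeat <- list()
  confusions <- list()
  for (task in tasks) {
    for (r in seq_len(config$repeats)) {
      seed_r <- config$seed + r
      sp <- split_dataset(dataset, config$split_fraction, seed = seed_r)
      cfg_r <- config
      cfg_r$seed <- seed_r
      tm <- train_model(spec, sp$train, task = task, config = cfg_r)
      pred <- predict_model(tm, sp$test, task = task)
      cc <- confusion_counts(pred$label, pred$actual)
      mt <- suppressWarnings(compute_metrics(cc))
      confusions[[paste(task, r, sep = "_")]] <- cc
      per_repeat[[length(per_repeat) + 1L]] <- data.frame(
        task = task, repeat_index = r, TP = cc$TP, TN = cc$TN, FP = cc$FP,
        FN = cc$FN, recall = mt$recall, precision = mt$precision, f1 = mt$f1,
        accuracy = mt$accuracy)
    }
  }
  per_repeat <- do.call(rbind, per_repeat)
  summary <- do.call(rbind, lapply(unique(per_repeat$task), function(task) {
    sub <- per_repeat[per_repeat$task == task, ]
    do.call(rbind, lapply(c("recall", "precision", "f1", "accuracy"),
                          function(m) {
      data.frame(task = task, metric = m, mean = mean(sub[[m]]),
                 sd = .pop_sd(sub[[m]]))
    }))
  }))
  structure(list(per_repeat = per_repeat, summary = summary,
                 confusions = confusions),
            class = "repeated_evaluation")
}

#' @export
print.repeated_evaluation <- function(x, ...) {
  cat("<repeated_evaluation>\n")
  s <- x$summary
  s$mean <- sprintf("%.4f", s$mean)
  s$sd <- sprintf("%.4f", s$sd)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write per-repeat confusion matrices as CSV files
#'
#' One 2x2 CSV per task and repeat (rows: actual low/high; columns:
#' predicted low/high).
#'
#' @param evaluation A [run_repeated_evaluation()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_confusions_csv <- function(evaluation, dir) {
  stopifnot(inherits(evaluation, "repeated_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(evaluation$confusions)) {
    cc <- evaluation$confusions[[nm]]
    m <- matrix(c(cc$TN, cc$FP, cc$FN, cc$TP), 2L, 2L, byrow = TRUE,
                dimnames = list(c("actual_low", "actual_high"),
                                c("predicted_low", "predicted_high")))
    path <- file.path(dir, paste0("confusion_", nm, ".csv"))
    utils::write.csv(m, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
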