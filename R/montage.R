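# Raw trials, the 9x9 electrode grid, and the 3D spatiotemporal representation:
# per 1-s window, each time sample is projected onto the grid, empty cells are
# filled by thin-plate-spline interpolation, the 9x9 map is upsampled to
# target_side x target_side by bicubic interpolation, and the maps are stacked
# along time into a depth x height x width tensor (default 128 x 64 x 64).

#' Construct a raw EEG trial
#'
#' A trial holds channel-major EEG samples (microvolts) together with its
#' sampling rate and the 1-9 self-assessment ratings used for labelling.
#'
#' @param samples Numeric matrix, `n_channels x n_samples`.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param valence_rating,arousal_rating Ratings in `[1, 9]`.
#' @param trial_id,subject_id Identifiers kept as provenance.
#' @param channel_names Optional character vector of channel names
#'   (length `n_channels`).
#' @return An object of class `raw_trial`.
#' @export
raw_trial <- function(samples, sampling_rate, valence_rating, arousal_rating,
                      trial_id = 1L, subject_id = 1L, channel_names = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric channels x samples matrix")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number")
  }
  for (r in c(valence = valence_rating, arousal = arousal_rating)) {
    if (!is.numeric(r) || r < 1 || r > 9) {
      stop("ratings must lie in [1, 9]; got ", r)
    }
  }
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == nrow(samples))
    rownames(samples) <- channel_names
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         valence_rating = valence_rating, arousal_rating = arousal_rating,
         trial_id = trial_id, subject_id = subject_id),
    class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> subject %s, trial %s: %d channels x %d samples @ %g Hz (%.1f s); valence %.2f, arousal %.2f\n",
              x$subject_id, x$trial_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate, ncol(x$samples) / x$sampling_rate,
              x$valence_rating, x$arousal_rating))
  invisible(x)
}

#' Load an electrode-to-grid assignment table
#'
#' Reads a montage description (grid shape plus one `(row, col)` cell per
#' channel, 0-based) from JSON. The package ships a canonical table for the 32
#' EEG channels of the DEAP montage on a 9x9 grid: rows run anterior to
#' posterior, columns left to right, midline in column 4. The table is a
#' documented convention, replaceable by any file with the same schema.
#'
#' @param path Path to a montage JSON file. Default: the shipped DEAP table.
#' @return An object of class `montage_grid` with fields `grid_shape`,
#'   `channels` (channel order), `assignments` (n x 2 integer matrix of
#'   0-based `(row, col)`), and `coordinates` (planar positions used for
#'   interpolation distances; the cell centers).
#' @export
montage_grid <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "deap_montage_9x9.json", package = "eegcube")
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- as.integer(spec$grid_shape)
  assign <- do.call(rbind, lapply(spec$assignments, as.integer))
  channels <- names(spec$assignments)
  if (any(assign < 0L) || any(assign[, 1L] >= shape[1L]) ||
      any(assign[, 2L] >= shape[2L])) {
    stop("montage assignment outside the ", shape[1L], "x", shape[2L], " grid")
  }
  key <- assign[, 1L] * shape[2L] + assign[, 2L]
  if (anyDuplicated(key)) {
    stop("montage assigns two channels to the same grid cell")
  }
  dimnames(assign) <- list(channels, c("row", "col"))
  structure(
    list(grid_shape = shape, channels = channels, assignments = assign,
         coordinates = assign * 1.0),
    class = "montage_grid")
}

#' @export
print.montage_grid <- function(x, ...) {
  cat(sprintf("<montage_grid> %d channels on a %dx%d grid\n",
              length(x$channels), x$grid_shape[1L], x$grid_shape[2L]))
  invisible(x)
}

#' Remove the pre-stimulus prefix of a trial
#'
#' Drops the first `pre_stimulus_seconds` of every channel, keeping channel
#' order and metadata. For DEAP-structured trials (63 s at 128 Hz) the default
#' 3 s prefix leaves the 60 s of stimulus-locked signal.
#'
#' @param trial A [raw_trial()].
#' @param pre_stimulus_seconds Seconds to drop from the start; must convert to
#'   a nonnegative integer number of samples not exceeding the trial length.
#' @return The trimmed `raw_trial`.
#' @export
trim_trial <- function(trial, pre_stimulus_seconds = 3) {
  stopifnot(inherits(trial, "raw_trial"))
  n_drop <- pre_stimulus_seconds * trial$sampling_rate
  if (abs(n_drop - round(n_drop)) > 1e-9 || n_drop < 0) {
    stop("pre_stimulus_seconds x sampling_rate must be a nonnegative integer; got ",
         n_drop)
  }
  n_drop <- as.integer(round(n_drop))
  n <- ncol(trial$samples)
  if (n_drop > n) {
    stop(sprintf("cannot trim %d samples from a trial of %d samples", n_drop, n))
  }
  if (n_drop == 0L) return(trial)
  trial$samples <- trial$samples[, (n_drop + 1L):n, drop = FALSE]
  trial
}

#' Cut a trial into non-overlapping fixed-length windows
#'
#' @param trial A [raw_trial()].
#' @param window_seconds Window length in seconds; `window_seconds *
#'   sampling_rate` must be a positive integer.
#' @return A list of channel x time matrices in temporal order
#'   (`floor(n_samples / window_samples)` of them); trailing samples that do
#'   not fill a window are discarded. A window longer than the trial yields an
#'   empty list.
#' @export
segment_windows <- function(trial, window_seconds = 1) {
  stopifnot(inherits(trial, "raw_trial"))
  w <- window_seconds * trial$sampling_rate
  if (abs(w - round(w)) > 1e-9 || w <= 0) {
    stop("window_seconds x sampling_rate must be a positive integer; got ", w)
  }
  w <- as.integer(round(w))
  n <- ncol(trial$samples)
  k <- n %/% w
  if (k == 0L) {
    message(sprintf("window of %d samples longer than trial of %d samples; no windows",
                    w, n))
    return(list())
  }
  lapply(seq_len(k), function(i) {
    trial$samples[, ((i - 1L) * w + 1L):(i * w), drop = FALSE]
  })
}

#' Place one time sample of channel values onto the montage grid
#'
#' @param channel_values Numeric vector, one value per montage channel, in
#'   montage channel order.
#' @param montage A [montage_grid()].
#' @return A `frame_map`: list with `values` (rows x cols matrix, `NA` at
#'   cells without an electrode) and `occupancy` (logical matrix).
#' @export
project_to_grid <- function(channel_values, montage) {
  stopifnot(inherits(montage, "montage_grid"))
  n_ch <- length(montage$channels)
  if (length(channel_values) != n_ch) {
    stop(sprintf("expected %d channel values (montage order), got %d",
                 n_ch, length(channel_values)))
  }
  shape <- montage$grid_shape
  values <- matrix(NA_real_, shape[1L], shape[2L])
  occupancy <- matrix(FALSE, shape[1L], shape[2L])
  idx <- cbind(montage$assignments[, 1L] + 1L, montage$assignments[, 2L] + 1L)
  values[idx] <- channel_values
  occupancy[idx] <- TRUE
  structure(list(values = values, occupancy = occupancy), class = "frame_map")
}

# Thin-plate-spline interpolation operator for a fixed node geometry: returns
# the dense matrix mapping node values to values at the evaluation points.
# Kernel r^2 log r with an affine polynomial term, so constants and planes are
# reproduced exactly and node values are interpolated, not smoothed.
.tps_operator <- function(nodes, targets) {
  n <- nrow(nodes)
  if (n < 3L) stop("thin-plate-spline interpolation needs >= 3 nodes")
  phi <- function(r2) {
    out <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)  # r^2 log r = (1/2) r^2 log r^2
    out
  }
  d2 <- function(a, b) {
    outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  }
  K <- phi(d2(nodes, nodes))
  P <- cbind(1, nodes)
  # affine part must be identifiable: nodes must not be collinear
  if (qr(P)$rank < 3L) stop("degenerate node set: electrode positions are collinear")
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  E <- cbind(phi(d2(targets, nodes)), 1, targets)
  op <- t(solve(t(M), t(E)))  # E %*% M^{-1}
  op[, seq_len(n), drop = FALSE]
}

#' Fill empty grid cells by thin-plate-spline interpolation
#'
#' Interpolates the electrode-backed cells of a frame onto the remaining cells
#' using a thin-plate-spline radial basis (kernel \eqn{r^2 \log r}) augmented
#' with an affine polynomial term, nodes and evaluation points at cell
#' centers. Values at electrode-backed cells are left untouched
#' (interpolation, not smoothing); constant and planar fields are reproduced
#' exactly.
#'
#' @param frame A `frame_map` from [project_to_grid()].
#' @param montage The [montage_grid()] that produced the frame (supplies the
#'   planar node coordinates).
#' @return The `frame_map` with all cells populated and `occupancy` all `TRUE`.
#' @export
rbf_fill <- function(frame, montage) {
  stopifnot(inherits(frame, "frame_map"), inherits(montage, "montage_grid"))
  occ <- frame$occupancy
  if (!any(!occ)) return(frame)
  nodes <- which(occ, arr.ind = TRUE) - 1
  holes <- which(!occ, arr.ind = TRUE) - 1
  op <- .tps_operator(nodes, holes)
  vals <- frame$values
  vals[!occ] <- as.numeric(op %*% vals[occ])
  frame$values <- vals
  frame$occupancy[] <- TRUE
  frame
}

# Keys bicubic kernel, a = -0.5.
.keys_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# T x S row-interpolation matrix for 1D bicubic resampling with
# "align corners" coordinate mapping and mirror (reflect, no edge repeat)
# boundary handling. Rows sum to 1, so constants are reproduced exactly.
.bicubic_weights <- function(src_n, target_n) {
  stopifnot(src_n >= 2L, target_n >= src_n)
  W <- matrix(0, target_n, src_n)
  reflect <- function(i) {  # 0-based index into 0..src_n-1
    n <- src_n - 1L
    i <- abs(i)
    i <- ifelse(i > n, 2L * n - i, i)
    i
  }
  for (t in seq_len(target_n)) {
    x <- (t - 1) * (src_n - 1) / (target_n - 1)
    base <- floor(x)
    for (k in -1:2) {
      s <- base + k
      w <- .keys_kernel(x - s)
      if (w != 0) {
        si <- reflect(as.integer(s)) + 1L
        W[t, si] <- W[t, si] + w
      }
    }
  }
  W
}

#' Upsample a fully populated grid by separable bicubic interpolation
#'
#' Uses the Keys cubic kernel (a = -0.5) with an "align corners" coordinate
#' mapping (source corners map to target corners) and mirror padding at the
#' borders, applied separably along rows and columns.
#'
#' @param frame A fully populated `frame_map` (see [rbf_fill()]) or a plain
#'   numeric matrix.
#' @param target_side Side length of the square output grid; must be at least
#'   the source side (this routine only upsamples).
#' @return A `target_side x target_side` numeric matrix.
#' @export
upsample_bicubic <- function(frame, target_side = 64L) {
  m <- if (inherits(frame, "frame_map")) {
    if (anyNA(frame$values)) stop("frame has unfilled cells; run rbf_fill() first")
    frame$values
  } else {
    frame
  }
  stopifnot(is.matrix(m), !anyNA(m))
  if (target_side < max(dim(m))) {
    stop(sprintf("target_side (%d) smaller than source side (%d): downsampling is out of scope",
                 target_side, max(dim(m))))
  }
  Wr <- .bicubic_weights(nrow(m), target_side)
  Wc <- .bicubic_weights(ncol(m), target_side)
  Wr %*% m %*% t(Wc)
}

#' Render one window segment as a 3D spatiotemporal tensor
#'
#' For every time sample of the segment: project the channel values onto the
#' montage grid, fill the empty cells by thin-plate-spline interpolation, and
#' upsample the grid bicubically to `target_side`; the resulting maps are
#' stacked along time. No amplitude normalization is applied.
#'
#' @param segment Channel x time numeric matrix (one window).
#' @param montage A [montage_grid()].
#' @param target_side Side of the square spatial maps (default 64).
#' @return A `window_tensor`: list with `data` (array `depth x target_side x
#'   target_side`, depth = window time length) plus label/provenance slots
#'   (filled by [build_dataset()]).
#' @export
build_window_tensor <- function(segment, montage, target_side = 64L) {
  stopifnot(is.matrix(segment), inherits(montage, "montage_grid"))
  n_ch <- length(montage$channels)
  if (nrow(segment) != n_ch) {
    stop(sprintf("segment has %d channels, montage has %d", nrow(segment), n_ch))
  }
  depth <- ncol(segment)
  shape <- montage$grid_shape

  # the node geometry is fixed across time samples: precompute both linear stages
  occ <- matrix(FALSE, shape[1L], shape[2L])
  idx <- cbind(montage$assignments[, 1L] + 1L, montage$assignments[, 2L] + 1L)
  occ[idx] <- TRUE
  nodes <- which(occ, arr.ind = TRUE) - 1
  holes <- which(!occ, arr.ind = TRUE) - 1
  tps <- .tps_operator(nodes, holes)
  Wr <- .bicubic_weights(shape[1L], target_side)
  Wc <- .bicubic_weights(shape[2L], target_side)

  # grid-cell linear index of each montage channel (values enter in montage order)
  chan_cell <- idx
  data <- array(NA_real_, c(depth, target_side, target_side))
  grid <- matrix(NA_real_, shape[1L], shape[2L])
  for (t in seq_len(depth)) {
    grid[chan_cell] <- segment[, t]
    grid[!occ] <- tps %*% grid[occ]
    data[t, , ] <- Wr %*% grid %*% t(Wc)
  }
  stopifnot(all(is.finite(data)))
  structure(
    list(data = data, label_valence = NA_integer_, label_arousal = NA_integer_,
         window_index = NA_integer_, trial_id = NA, subject_id = NA),
    class = "window_tensor")
}

#' Build a labelled window-tensor dataset from raw trials
#'
#' Applies [trim_trial()], [segment_windows()] and [build_window_tensor()] to
#' every trial, attaches binary valence/arousal labels via [binarize_rating()],
#' and records per-window provenance.
#'
#' @param trials List of [raw_trial()] objects sharing sampling rate and
#'   channel layout.
#' @param montage A [montage_grid()].
#' @param config List of options: `window_seconds` (1), `target_side` (64),
#'   `pre_stimulus_seconds` (3), `threshold` (5, for label binarization),
#'   `normalize` (`FALSE`; when `TRUE`, per-channel z-scoring over the trimmed
#'   trial before segmentation).
#' @return A `window_dataset`: list with `windows` (list of `window_tensor`)
#'   and `provenance` (data frame with subject, trial, window index, labels).
#' @export
build_dataset <- function(trials, montage, config = list()) {
  cfg <- modifyList(list(window_seconds = 1, target_side = 64L,
                         pre_stimulus_seconds = 3, threshold = 5,
                         normalize = FALSE), config)
  if (length(trials) == 0L) {
    return(structure(list(windows = list(),
                          provenance = data.frame(subject_id = character(0),
                                                  trial_id = character(0),
                                                  window_index = integer(0),
                                                  label_valence = integer(0),
                                                  label_arousal = integer(0))),
                     class = "window_dataset"))
  }
  n_ch <- vapply(trials, function(tr) nrow(tr$samples), integer(1))
  if (length(unique(n_ch)) != 1L) {
    stop("trials have inconsistent channel counts: ",
         paste(unique(n_ch), collapse = ", "))
  }
  rates <- vapply(trials, function(tr) tr$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("trials have inconsistent sampling rates")
  }
  windows <- list()
  prov <- list()
  for (tr in trials) {
    tr <- trim_trial(tr, cfg$pre_stimulus_seconds)
    if (isTRUE(cfg$normalize)) {
      mu <- rowMeans(tr$samples)
      sdv <- apply(tr$samples, 1L, sd)
      sdv[sdv == 0] <- 1
      tr$samples <- (tr$samples - mu) / sdv
    }
    lab_v <- binarize_rating(tr$valence_rating, cfg$threshold)
    lab_a <- binarize_rating(tr$arousal_rating, cfg$threshold)
    segs <- segment_windows(tr, cfg$window_seconds)
    for (i in seq_along(segs)) {
      wt <- build_window_tensor(segs[[i]], montage, cfg$target_side)
      wt$label_valence <- lab_v
      wt$label_arousal <- lab_a
      wt$window_index <- i
      wt$trial_id <- tr$trial_id
      wt$subject_id <- tr$subject_id
      windows[[length(windows) + 1L]] <- wt
      prov[[length(prov) + 1L]] <- data.frame(
        subject_id = tr$subject_id, trial_id = tr$trial_id, window_index = i,
        label_valence = lab_v, label_arousal = lab_a)
    }
  }
  structure(list(windows = windows, provenance = do.call(rbind, prov)),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  n <- length(x$windows)
  if (n > 0L) {
    d <- dim(x$windows[[1L]]$data)
    cat(sprintf("<window_dataset> %d windows of %d x %d x %d\n", n, d[1], d[2], d[3]))
  } else {
    cat("<window_dataset> empty\n")
  }
  invisible(x)
}

#' @export
length.window_dataset <- function(x) length(x$windows)
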