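# DEAP-structured synthetic EEG: 1/f Gaussian background plus band-limited
# sinusoids per channel, with class-conditional effects (frontal alpha
# asymmetry for high valence, frontal-central beta gain for high arousal) and
# 1-9 ratings consistent with the binary class. Everything is seeded and
# reproducible; the generator emulates the *structure* of the real recordings
# (channel count, rate, trial length, label layout), not their physiology.

.eeg_bands <- list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30))

.left_frontal <- c("Fp1", "AF3", "F3", "F7", "FC5")
.right_frontal <- c("Fp2", "AF4", "F4", "F8", "FC6")
.frontal_central <- c("Fz", "Cz", "FC1", "FC2", "FC5", "FC6")

#' Synthetic-dataset configuration
#'
#' Defaults mirror the DEAP per-subject structure: 40 trials of 63 s (3 s
#' pre-stimulus + 60 s stimulus) from 32 channels at 128 Hz. `delta` is the
#' dimensionless class effect size: high-valence trials multiply the
#' alpha-band amplitude on left-frontal channels by `1 + delta` and on
#' right-frontal channels by `max(0, 1 - delta/2)` (frontal alpha
#' asymmetry); high-arousal trials multiply the beta-band amplitude on
#' frontal-central channels by `1 + delta`. `delta = 0` gives
#' class-indistinguishable signals.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param n_trials_per_subject Trials per subject (balanced over the 2x2
#'   valence x arousal grid).
#' @param n_channels Channel count (32: the shipped montage order).
#' @param sampling_rate Hz.
#' @param trial_seconds Trial length in seconds (pre-stimulus included).
#' @param delta Class effect size (>= 0).
#' @param noise_exponent Spectral exponent of the 1/f^a background.
#' @param noise_sd Background amplitude (standard deviation, microvolts).
#' @param band_amplitude Named amplitudes (microvolts) of the theta, alpha
#'   and beta sinusoidal components.
#' @param seed RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 1L, n_trials_per_subject = 40L,
                         n_channels = 32L, sampling_rate = 128,
                         trial_seconds = 63, delta = 1,
                         noise_exponent = 1, noise_sd = 10,
                         band_amplitude = c(theta = 4, alpha = 10, beta = 5),
                         seed = 0L) {
  stopifnot(n_subjects >= 1, n_trials_per_subject >= 1, n_channels >= 1,
            sampling_rate > 0, trial_seconds > 0, delta >= 0,
            noise_sd >= 0, all(band_amplitude >= 0),
            all(c("theta", "alpha", "beta") %in% names(band_amplitude)))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 trial_seconds = trial_seconds, delta = delta,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 band_amplitude = band_amplitude, seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^a Gaussian noise via frequency-domain shaping, rescaled to sd `sd`
.colored_noise <- function(n, exponent, sd) {
  if (sd == 0) return(numeric(n))
  spec <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))  # cycles per record; DC handled below
  f <- pmin(f, n - f + 1)    # symmetric magnitude for negative frequencies
  scale <- f^(-exponent / 2)
  scale[1L] <- 0
  x <- Re(fft(spec * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

#' Generate one synthetic EEG trial
#'
#' Each channel is a 1/f-shaped Gaussian background plus one sinusoid per
#' band (theta, alpha, beta) with a frequency drawn uniformly in the band and
#' a uniform random phase; class effects rescale band amplitudes on the
#' channel groups described in [synth_config()]. The rating of each task is
#' drawn uniformly from (5, 9] for the high class and [1, 5] for the low
#' class, so ratings and binary labels agree under the threshold-5 rule.
#' Draws come from the current RNG state; seed externally (or use
#' [generate_dataset()]).
#'
#' @param valence_high,arousal_high Logical class labels.
#' @param config A [synth_config()].
#' @param trial_id,subject_id Provenance identifiers.
#' @return A [raw_trial()] with `n_channels x (trial_seconds * sampling_rate)`
#'   samples.
#' @export
generate_trial <- function(valence_high, arousal_high, config = synth_config(),
                           trial_id = 1L, subject_id = 1L) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- as.integer(round(config$trial_seconds * fs))
  tt <- (seq_len(n) - 1) / fs
  channels <- montage_grid()$channels
  if (config$n_channels != length(channels)) {
    channels <- paste0("ch", seq_len(config$n_channels))
  }
  delta <- config$delta
  amp <- config$band_amplitude
  samples <- matrix(0, config$n_channels, n)
  for (ci in seq_len(config$n_channels)) {
    ch <- channels[ci]
    a_alpha <- amp[["alpha"]]
    a_beta <- amp[["beta"]]
    if (isTRUE(valence_high)) {
      if (ch %in% .left_frontal) a_alpha <- a_alpha * (1 + delta)
      if (ch %in% .right_frontal) a_alpha <- a_alpha * max(0, 1 - delta / 2)
    }
    if (isTRUE(arousal_high) && ch %in% .frontal_central) {
      a_beta <- a_beta * (1 + delta)
    }
    band_amp <- c(theta = amp[["theta"]], alpha = a_alpha, beta = a_beta)
    sig <- .colored_noise(n, config$noise_exponent, config$noise_sd)
    for (b in names(.eeg_bands)) {
      f0 <- runif(1, .eeg_bands[[b]][1L], .eeg_bands[[b]][2L])
      phase <- runif(1, 0, 2 * pi)
      sig <- sig + band_amp[[b]] * sin(2 * pi * f0 * tt + phase)
    }
    samples[ci, ] <- sig
  }
  rating <- function(high) if (high) 5 + runif(1) * 4 else 1 + runif(1) * 4
  raw_trial(samples, fs,
            valence_rating = rating(isTRUE(valence_high)),
            arousal_rating = rating(isTRUE(arousal_high)),
            trial_id = trial_id, subject_id = subject_id,
            channel_names = channels)
}

#' Generate a DEAP-structured synthetic archive
#'
#' Trials are assigned to the four valence x arousal classes in a balanced
#' round-robin (10 each for the default 40 trials per subject). The archive
#' mirrors the per-subject DEAP array layout: `data` is trials x channels x
#' samples, `labels` is trials x 4 with columns valence, arousal, dominance,
#' liking (the last two are uniform filler in `[1, 9]`).
#'
#' @param config A [synth_config()] (its `seed` drives all draws).
#' @return Object of class `synth_archive`: list with `subjects` (each a
#'   list with `data` and `labels`), `channel_names`, `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  classes <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
  n_tr <- config$n_trials_per_subject
  n_samp <- as.integer(round(config$trial_seconds * config$sampling_rate))
  channel_names <- NULL
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    data <- array(0, c(n_tr, config$n_channels, n_samp))
    labels <- matrix(0, n_tr, 4L,
                     dimnames = list(NULL, c("valence", "arousal",
                                             "dominance", "liking")))
    for (i in seq_len(n_tr)) {
      cl <- classes[[(i - 1L) %% 4L + 1L]]
      tr <- generate_trial(cl[1L], cl[2L], config, trial_id = i, subject_id = s)
      data[i, , ] <- tr$samples
      labels[i, ] <- c(tr$valence_rating, tr$arousal_rating,
                       1 + runif(1) * 8, 1 + runif(1) * 8)
      if (is.null(channel_names)) channel_names <<- rownames(tr$samples)
    }
    list(data = data, labels = labels)
  })
  structure(list(subjects = subjects, channel_names = channel_names,
                 config = config),
            class = "synth_archive")
}

#' @export
print.synth_archive <- function(x, ...) {
  d <- dim(x$subjects[[1L]]$data)
  cat(sprintf("<synth_archive> %d subject(s) x %d trials, %d channels x %d samples (delta = %g)\n",
              length(x$subjects), d[1L], d[2L], d[3L], x$config$delta))
  invisible(x)
}

#' Write / read a synthetic archive
#'
#' Archives are stored as single RDS files (R-native serialization); a
#' write-read round trip reproduces the arrays and ratings exactly.
#'
#' @param archive A `synth_archive`.
#' @param path File path (conventionally `.rds`).
#' @return `read_archive()` returns the `synth_archive`.
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "synth_archive"))
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  archive <- readRDS(path)
  if (!inherits(archive, "synth_archive")) {
    stop("file does not contain a synth_archive: ", path)
  }
  archive
}

#' Flatten an archive into a list of raw trials
#'
#' @param archive A `synth_archive` (or any list of per-subject `data` /
#'   `labels` pairs in the DEAP layout).
#' @return List of [raw_trial()] objects.
#' @export
archive_to_trials <- function(archive) {
  stopifnot(inherits(archive, "synth_archive"))
  fs <- archive$config$sampling_rate
  trials <- list()
  for (s in seq_along(archive$subjects)) {
    sub <- archive$subjects[[s]]
    for (i in seq_len(dim(sub$data)[1L])) {
      trials[[length(trials) + 1L]] <- raw_trial(
        sub$data[i, , ], fs,
        valence_rating = sub$labels[i, 1L],
        arousal_rating = sub$labels[i, 2L],
        trial_id = i, subject_id = s,
        channel_names = archive$channel_names)
    }
  }
  trials
}

#' Load DEAP-style preprocessed per-subject arrays
#'
#' Reads one subject's preprocessed arrays — `data` (40 trials x 40 or 32
#' channels x 8064 samples) and `labels` (40 x 4: valence, arousal,
#' dominance, liking) — from an RDS file holding a list with those two
#' elements. Only the first 32 (EEG) channels are retained; peripheral
#' channels are discarded. The original distribution ships these arrays as
#' Python pickles; convert once with, e.g.,
#' `python -c "import pickle; d = pickle.load(open('s01.dat','rb'), encoding='latin1'); ..."`
#' writing `data`/`labels` to CSV or any format R can read, then `saveRDS()`
#' the list. Malformed files raise errors naming the expected shapes.
#'
#' @param path Path to the RDS file.
#' @param subject_id Identifier attached to the returned trials.
#' @param sampling_rate Hz of the preprocessed signals (128).
#' @return List of [raw_trial()] objects (one per trial).
#' @export
load_deap_preprocessed <- function(path, subject_id = 1L, sampling_rate = 128) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels)) {
    stop("expected a list with elements `data` (trials x channels x samples) ",
         "and `labels` (trials x 4)")
  }
  d <- dim(obj$data)
  if (length(d) != 3L) {
    stop("`data` must be a 3D array (trials x channels x samples); got ",
         paste(d, collapse = "x"))
  }
  if (!(d[2L] %in% c(32L, 40L))) {
    stop(sprintf("`data` has %d channels; expected 40 (32 EEG + 8 peripheral) or 32",
                 d[2L]))
  }
  expected_samples <- as.integer(63 * sampling_rate)
  if (d[3L] != expected_samples) {
    stop(sprintf("`data` has %d samples per trial; expected %d (63 s at %g Hz)",
                 d[3L], expected_samples, sampling_rate))
  }
  lab <- obj$labels
  if (!is.matrix(lab) || nrow(lab) != d[1L] || ncol(lab) != 4L) {
    stop(sprintf("`labels` must be a %d x 4 matrix (valence, arousal, dominance, liking)",
                 d[1L]))
  }
  if (any(lab[, 1:2] < 1 | lab[, 1:2] > 9)) {
    stop("valence/arousal ratings outside [1, 9]")
  }
  channels <- montage_grid()$channels
  lapply(seq_len(d[1L]), function(i) {
    raw_trial(obj$data[i, 1:32, ], sampling_rate,
              valence_rating = lab[i, 1L], arousal_rating = lab[i, 2L],
              trial_id = i, subject_id = subject_id, channel_names = channels)
  })
}

#' Welch band power of a single signal
#'
#' Mean periodogram over Hann-windowed segments (default 1 s, 50% overlap);
#' band power is the sum of the power estimates over frequency bins inside
#' the band (inclusive bounds).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 numeric `(low, high)` in Hz.
#' @param seg_seconds Segment length in seconds.
#' @param overlap Fractional overlap between segments.
#' @return Scalar band power (arbitrary units, consistent across calls).
#' @export
welch_band_power <- function(x, fs, band, seg_seconds = 1, overlap = 0.5) {
  nseg <- as.integer(round(seg_seconds * fs))
  stopifnot(nseg >= 4, length(x) >= nseg)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  freqs <- (seq_len(nseg %/% 2 + 1L) - 1L) * fs / nseg
  sel <- freqs >= band[1L] & freqs <= band[2L]
  acc <- numeric(sum(sel))
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    sp <- Mod(fft(seg)[seq_len(nseg %/% 2 + 1L)])^2 / (sum(w^2) * fs)
    acc <- acc + sp[sel]
  }
  sum(acc / length(starts))
}

#' Rank-based AUC of scores against binary labels
#'
#' Mann-Whitney formulation with midranks (ties averaged): the probability
#' that a random positive scores above a random negative.
#'
#' @param scores Numeric scores.
#' @param labels Binary (0/1) labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Linear-probe separability of an archive
#'
#' Computes per-trial alpha/beta Welch band powers averaged within the
#' left-frontal, right-frontal and frontal-central channel groups (6
#' features), fits a logistic regression probe on a random half of the
#' trials, and returns the rank AUC of its held-out predictions. Used to
#' verify the generator's effect-size dial: the score sits at chance for
#' `delta = 0` and grows with `delta`.
#'
#' @param archive A `synth_archive`.
#' @param task `"valence"` or `"arousal"`.
#' @param seed Seed for the probe split.
#' @param split_fraction Training fraction of the probe split.
#' @return Held-out AUC (numeric scalar) with attribute `n_trials`.
#' @export
band_power_probe <- function(archive, task = c("valence", "arousal"),
                             seed = 0L, split_fraction = 0.5) {
  task <- match.arg(task)
  stopifnot(inherits(archive, "synth_archive"))
  trials <- archive_to_trials(archive)
  if (length(trials) == 0L) stop("archive is empty")
  fs <- archive$config$sampling_rate
  groups <- list(lf = .left_frontal, rf = .right_frontal, fc = .frontal_central)
  feats <- t(vapply(trials, function(tr) {
    out <- numeric(0)
    for (g in groups) {
      idx <- which(rownames(tr$samples) %in% g)
      for (b in c("alpha", "beta")) {
        bp <- mean(vapply(idx, function(ci) {
          welch_band_power(tr$samples[ci, ], fs, .eeg_bands[[b]])
        }, numeric(1)))
        out <- c(out, log(bp))
      }
    }
    out
  }, numeric(6)))
  y <- vapply(trials, function(tr) {
    binarize_rating(if (task == "valence") tr$valence_rating else tr$arousal_rating)
  }, integer(1))
  if (length(unique(y)) < 2L) stop("archive holds a single class for task ", task)
  n <- length(y)
  set.seed(seed)
  tr_idx <- sort(sample(n, round(split_fraction * n)))
  te_idx <- setdiff(seq_len(n), tr_idx)
  df <- as.data.frame(feats)
  df$y <- y
  fit <- suppressWarnings(glm(y ~ ., data = df[tr_idx, ], family = binomial()))
  scores <- suppressWarnings(predict(fit, newdata = df[te_idx, ], type = "link"))
  auc <- rank_auc(scores, y[te_idx])
  attr(auc, "n_trials") <- n
  auc
}
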