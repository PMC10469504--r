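#' Synthetic motor-imagery EEG configuration
#'
#' Study conditions for the synthetic generator.  Each trial is broadband
#' Gaussian noise plus a band-limited oscillation (random frequency inside
#' `osc_band`, random phase per channel, amplitude 1) on every channel;
#' during the middle half of the trial the oscillation amplitude on the
#' label's channel group is attenuated by the factor `1 - erd_depth`,
#' emulating event-related desynchronisation of the mu rhythm over the
#' corresponding cortical patch.  Defaults: 4 classes x 100 trials, 16
#' channels in four disjoint 4-channel class groups, 2-s trials at 128 Hz,
#' mu band (8, 12) Hz, `erd_depth = 0.9`, `noise_sd = 0.5`.
#'
#' @param n_trials_per_class Trials per class.
#' @param n_channels Number of channels.
#' @param n_timepoints Samples per trial.
#' @param sampling_rate Hz.
#' @param n_classes Number of classes (`>= 2`).
#' @param osc_band Oscillation band `(low, high)` in Hz.
#' @param erd_depth Fractional attenuation in `[0, 1]`; 0 makes the data
#'   carry no class information.
#' @param noise_sd Broadband noise standard deviation (microvolts).
#' @param channel_groups Per-class list of channel indices; default splits
#'   the channels evenly over the classes.
#' @param n_subjects Number of synthetic subjects; trials are assigned in
#'   contiguous balanced blocks.
#' @param pink_noise If `TRUE`, shape the noise spectrum as 1/f instead of
#'   white (off by default so the band-power oracle stays simple).
#' @param seed RNG seed; the generated set is a pure function of the
#'   configuration.
#' @return An object of class `mi_synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 100L,
                         n_channels = 16L,
                         n_timepoints = 256L,
                         sampling_rate = 128,
                         n_classes = 4L,
                         osc_band = c(8, 12),
                         erd_depth = 0.9,
                         noise_sd = 0.5,
                         channel_groups = NULL,
                         n_subjects = 1L,
                         pink_noise = FALSE,
                         seed = 1L) {
  if (is.null(channel_groups)) {
    per <- n_channels %/% n_classes
    if (per < 1L) stop("need at least one channel per class", call. = FALSE)
    channel_groups <- lapply(seq_len(n_classes) - 1L,
                             function(k) k * per + seq_len(per))
  }
  scfg <- list(
    n_trials_per_class = as.integer(n_trials_per_class),
    n_channels = as.integer(n_channels),
    n_timepoints = as.integer(n_timepoints),
    sampling_rate = as.numeric(sampling_rate),
    n_classes = as.integer(n_classes),
    osc_band = as.numeric(osc_band),
    erd_depth = erd_depth,
    noise_sd = noise_sd,
    channel_groups = channel_groups,
    n_subjects = as.integer(n_subjects),
    pink_noise = isTRUE(pink_noise),
    seed = as.integer(seed)
  )
  stopifnot(scfg$n_classes >= 2L, scfg$erd_depth >= 0, scfg$erd_depth <= 1,
            length(scfg$osc_band) == 2L, scfg$osc_band[1] < scfg$osc_band[2])
  if (max(unlist(scfg$channel_groups)) > scfg$n_channels) {
    stop("channel_groups indices exceed n_channels", call. = FALSE)
  }
  class(scfg) <- "mi_synth_config"
  scfg
}

# ERD amplitude envelope: 0 outside the middle half of the trial, ramping
# linearly to 1 over 10% of T at either edge of that window
erd_envelope <- function(T) {
  t <- seq_len(T)
  lo <- 0.25 * T; hi <- 0.75 * T; ramp <- 0.10 * T
  w <- pmin(1, pmax(0, (t - lo) / ramp)) * pmin(1, pmax(0, (hi - t) / ramp))
  w
}

#' Generate a synthetic motor-imagery epoch set
#'
#' @param scfg A [synth_config()].
#' @return An [epoch_set()] with balanced, interleaved labels and subjects
#'   assigned in contiguous blocks.  Identical configurations (including
#'   `seed`) give bitwise-identical output.
#' @examples
#' es <- generate_epochs(synth_config(n_trials_per_class = 5, seed = 7))
#' dim(es$data)
#' @export
generate_epochs <- function(scfg) {
  stopifnot(inherits(scfg, "mi_synth_config"))
  set.seed(scfg$seed)
  C <- scfg$n_channels; T <- scfg$n_timepoints; fs <- scfg$sampling_rate
  n <- scfg$n_trials_per_class * scfg$n_classes
  if (T < 4L * 8L * 7L) {
    warning("n_timepoints = ", T, " is shorter than the 224 samples the ",
            "default pooling sizes need; pair with a reduced model_config",
            call. = FALSE)
  }
  labels <- rep(seq_len(scfg$n_classes) - 1L, times = scfg$n_trials_per_class)
  subj <- sprintf("S%02d", sort(rep(seq_len(scfg$n_subjects), length.out = n)))
  env <- erd_envelope(T)
  tt <- (seq_len(T) - 1) / fs
  x <- array(0, c(n, C, T))
  for (i in seq_len(n)) {
    f <- stats::runif(1, scfg$osc_band[1], scfg$osc_band[2])
    phase <- stats::runif(C, 0, 2 * pi)
    osc <- sin(outer(phase, 2 * pi * f * tt, "+"))        # C x T
    grp <- scfg$channel_groups[[labels[i] + 1L]]
    amp <- matrix(1, C, T)
    amp[grp, ] <- 1 - scfg$erd_depth * matrix(env, length(grp), T, byrow = TRUE)
    noise <- matrix(stats::rnorm(C * T, 0, scfg$noise_sd), C, T)
    if (scfg$pink_noise) noise <- t(apply(noise, 1, pink_shape))
    x[i, , ] <- osc * amp + noise
  }
  epoch_set(x, labels, subj, fs)
}

# 1/f spectral shaping of a white series (unit-power normalised)
pink_shape <- function(z) {
  n <- length(z)
  zf <- stats::fft(z)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  zf <- zf / sqrt(f)
  out <- Re(stats::fft(zf, inverse = TRUE)) / n
  out * stats::sd(z) / stats::sd(out)
}

#' Band power of each trial and channel
#'
#' Mean spectral power inside `band`, computed by FFT periodogram over the
#' middle half of each trial (where the class-specific attenuation acts).
#'
#' @param epochs An [epoch_set()].
#' @param band `(low, high)` in Hz.
#' @param segment `"middle_half"` or `"all"`.
#' @return Matrix `n_trials x n_channels` of log band power.
#' @export
bandpower_features <- function(epochs, band = c(8, 12),
                               segment = c("middle_half", "all")) {
  segment <- match.arg(segment)
  d <- dim(epochs$data); n <- d[1]; C <- d[2]; T <- d[3]
  fs <- epochs$sampling_rate
  idx <- if (segment == "middle_half") {
    seq.int(floor(T / 4) + 1L, floor(3 * T / 4))
  } else seq_len(T)
  m <- length(idx)
  freqs <- (seq_len(m) - 1) * fs / m
  keep <- which(freqs >= band[1] & freqs <= band[2])
  out <- matrix(0, n, C)
  for (i in seq_len(n)) {
    seg <- epochs$data[i, , idx, drop = FALSE]
    for (ch in seq_len(C)) {
      p <- Mod(stats::fft(seg[1, ch, ]))^2 / m
      out[i, ch] <- log(mean(p[keep]) + 1e-12)
    }
  }
  out
}

#' Nearest-centroid band-power baseline
#'
#' A deliberately simple reference classifier: per-channel log band power
#' over the middle half of the trial, class centroids on the training set,
#' Euclidean nearest-centroid prediction.  Used as an independent check
#' that generated data carry the intended class structure.
#'
#' @param train,test [epoch_set()] objects.
#' @param band Oscillation band `(low, high)` in Hz.
#' @return A list with `accuracy` and integer `predictions` (0-based).
#' @export
bandpower_baseline <- function(train, test, band = c(8, 12)) {
  ftr <- bandpower_features(train, band)
  fte <- bandpower_features(test, band)
  classes <- sort(unique(train$labels))
  cents <- t(vapply(classes, function(k) {
    colMeans(ftr[train$labels == k, , drop = FALSE])
  }, numeric(ncol(ftr))))
  d2 <- vapply(seq_along(classes), function(j) {
    rowSums(sweep(fte, 2, cents[j, ], "-")^2)
  }, numeric(nrow(fte)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  pred <- classes[max.col(-d2, ties.method = "first")]
  list(accuracy = mean(pred == test$labels), predictions = pred)
}

#' Cross-validation split plans
#'
#' Builds within-subject stratified k-fold plans or between-subject
#' leave-groups-out plans.  Within-subject folds stratify by class label
#' with seeded shuffling (so fold sizes differ by at most one trial);
#' between-subject folds partition whole subjects, so every test fold
#' contains complete subjects only.  Folds are disjoint and exhaustive.
#'
#' @param epochs An [epoch_set()].
#' @param scheme `"within_kfold"` or `"between_subject"`.
#' @param k Number of folds (for between-subject, the number of subject
#'   groups; set `k` to the number of subjects for leave-one-subject-out).
#' @param seed RNG seed for the shuffles.
#' @return A tibble of class `mi_splits`, one row per fold, with
#'   list-columns `train` and `test` of trial indices (and `test_subjects`
#'   for the between scheme).
#' @examples
#' es <- generate_epochs(synth_config(n_trials_per_class = 21,
#'                                    n_timepoints = 224, seed = 2))
#' make_splits(es, "within_kfold", k = 10)
#' @export
make_splits <- function(epochs, scheme = c("within_kfold", "between_subject"),
                        k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(as.integer(seed))
  n <- length(epochs$labels)
  fold_of <- integer(n)
  if (scheme == "within_kfold") {
    counts <- table(epochs$labels)
    if (k > min(counts)) {
      stop("k = ", k, " exceeds the smallest class count (", min(counts), ")",
           call. = FALSE)
    }
    offset <- 0L
    for (cl in sort(unique(epochs$labels))) {
      idx <- which(epochs$labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  } else {
    subjects <- unique(epochs$subject)
    if (length(subjects) < 2L) {
      stop("between-subject splits need at least 2 distinct subjects",
           call. = FALSE)
    }
    if (k > length(subjects)) {
      stop("k = ", k, " exceeds the number of subjects (",
           length(subjects), ")", call. = FALSE)
    }
    subjects <- subjects[sample.int(length(subjects))]
    grp <- rep(seq_len(k), length.out = length(subjects))
    subj_fold <- stats::setNames(grp, subjects)
    fold_of <- unname(subj_fold[epochs$subject])
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    list(fold = f, train = which(fold_of != f), test = test)
  })
  out <- tibble::tibble(
    fold = vapply(folds, `[[`, integer(1), "fold"),
    train = lapply(folds, `[[`, "train"),
    test = lapply(folds, `[[`, "test")
  )
  if (scheme == "between_subject") {
    out$test_subjects <- lapply(out$test,
                                function(i) unique(epochs$subject[i]))
  }
  class(out) <- c("mi_splits", class(out))
  out
}
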