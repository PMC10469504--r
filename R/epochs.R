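#' Labelled EEG trials
#'
#' The universal data currency of the package: a 3-D numeric array of
#' epoched EEG (`n_trials x n_channels x n_timepoints`, microvolt scale)
#' with an integer class label and a subject identifier per trial.
#'
#' @param data Numeric array `n_trials x n_channels x n_timepoints`; all
#'   values must be finite.
#' @param labels Integer vector of class labels in `0 .. n_classes - 1`.
#' @param subject Subject identifier per trial (recycled if length 1).
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @examples
#' x <- array(rnorm(5 * 3 * 64), c(5, 3, 64))
#' es <- epoch_set(x, labels = c(0, 1, 2, 3, 0), sampling_rate = 128)
#' dim(es$data)
#' @export
epoch_set <- function(data, labels, subject = "S01", sampling_rate) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-D array (trials x channels x timepoints)", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("data contains non-finite values", call. = FALSE)
  n <- dim(data)[1]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("length(labels) must equal n_trials", call. = FALSE)
  if (any(labels < 0L)) stop("labels must be non-negative integers", call. = FALSE)
  subject <- as.character(subject)
  if (length(subject) == 1L) subject <- rep(subject, n)
  if (length(subject) != n) stop("subject must have one entry per trial", call. = FALSE)
  structure(
    list(data = data, labels = labels, subject = subject,
         sampling_rate = as.numeric(sampling_rate)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$sampling_rate, " Hz; ",
      length(unique(x$subject)), " subject(s), classes {",
      paste(sort(unique(x$labels)), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Trial metadata as a tibble
#'
#' One row per trial with its index, label and subject; the signal itself
#' stays in the array.
#'
#' @param x An [epoch_set()].
#' @param ... Unused.
#' @return A tibble with columns `trial`, `label`, `subject`.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  tibble::tibble(
    trial = seq_len(dim(x$data)[1]),
    label = x$labels,
    subject = x$subject
  )
}

#' Subset an epoch set by trial index
#'
#' @param x An [epoch_set()].
#' @param i Integer (or logical) trial indices.
#' @return An [epoch_set()] with the selected trials.
#' @export
subset_epochs <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$labels[i], x$subject[i],
            x$sampling_rate)
}

check_epochs_config <- function(epochs, cfg) {
  d <- dim(epochs$data)
  if (d[2] != cfg$n_channels) {
    stop("channel axis mismatch: epochs have ", d[2],
         " channels but the configuration expects ", cfg$n_channels,
         call. = FALSE)
  }
  if (d[3] != cfg$n_timepoints) {
    stop("time axis mismatch: epochs have ", d[3],
         " samples but the configuration expects ", cfg$n_timepoints,
         call. = FALSE)
  }
  if (any(epochs$labels >= cfg$n_classes)) {
    stop("labels must lie in 0 .. n_classes - 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read an epoch set on disk
#'
#' Stores the trial array in R's portable serialisation alongside a CSV
#' table of per-trial labels and subjects (the CSV is the interchange
#' surface for other tools).
#'
#' @param x An [epoch_set()].
#' @param path Basename; `<path>.rds` and `<path>_trials.csv` are written.
#' @return `path`, invisibly (for `write_epochs`); an [epoch_set()] for
#'   `read_epochs`.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  saveRDS(x, paste0(path, ".rds"))
  utils::write.csv(as_tibble.epoch_set(x), paste0(path, "_trials.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(x, "epoch_set"))
  x
}
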