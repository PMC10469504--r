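#' Plot the training loss curve
#'
#' @param object A fitted `mi_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mi_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean training loss",
                  title = "Cross-entropy training loss") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix heatmap
#'
#' @param object An `mi_metrics` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("accuracy %.3f, kappa %.3f",
                                  object$accuracy, object$kappa)) +
    ggplot2::theme_minimal()
}

#' Plot class-mean spectra of an epoch set
#'
#' Average periodogram per class over all channels; a quick visual check
#' that generated oscillations sit in the intended band.
#'
#' @param epochs An [epoch_set()].
#' @param max_freq Upper frequency limit of the plot, Hz.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(epochs, max_freq = 40) {
  d <- dim(epochs$data); n <- d[1]; C <- d[2]; T <- d[3]
  fs <- epochs$sampling_rate
  freqs <- (seq_len(T) - 1) * fs / T
  keep <- freqs > 0 & freqs <= max_freq
  rows <- lapply(sort(unique(epochs$labels)), function(cl) {
    idx <- which(epochs$labels == cl)
    pow <- rep(0, T)
    for (i in idx) for (ch in seq_len(C)) {
      pow <- pow + Mod(stats::fft(epochs$data[i, ch, ]))^2 / T
    }
    tibble::tibble(class = factor(cl), freq = freqs[keep],
                   power = pow[keep] / (length(idx) * C))
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "mean power",
                  title = "Class-mean amplitude spectra") +
    ggplot2::theme_minimal()
}
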