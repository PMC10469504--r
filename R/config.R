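#' Model configuration
#'
#' Collects every architectural hyperparameter of the classifier and checks
#' their joint constraints.  The defaults are the published values used for
#' both benchmark datasets: `F1 = 16` temporal filters, depth multiplier
#' `B = 2` (so `F2 = 32` feature maps), pooling sizes `P1 = 8` and `P2 = 7`,
#' attention head size `Dh = 8` (hence `h = F2 / Dh = 4` heads), dropout
#' 0.3 in the convolutional and windowing stages and 0.5 on attention
#' weights.
#'
#' The temporal convolution kernel spans `Fs %/% 4` samples (a quarter
#' second); the token sequence emitted by the convolutional block has
#' `Tz = (T %/% P1) %/% P2` positions, each an `F2`-vector.  `Tz >= 4` is
#' required so that at least one continuous sliding window exists.
#'
#' @param n_channels Number of EEG electrodes `C`.
#' @param n_timepoints Samples per trial `T`.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_classes Number of motor-imagery classes (4 for both benchmark
#'   datasets).
#' @param temporal_filters `F1`, number of temporal convolution kernels.
#' @param depth_multiplier `B`, depthwise kernels per temporal filter.
#' @param pool1,pool2 Average-pooling widths `P1`, `P2`.
#' @param head_dim `Dh`, per-head feature dimension; must divide
#'   `F2 = F1 * B`.
#' @param dropout_conv,dropout_window,dropout_attn Dropout rates for the
#'   convolutional block, the windowed tokens, and the attention weights.
#' @param local_kernel Kernel length of the local temporal convolution.
#' @param bn_momentum,bn_eps Batch-normalisation running-average momentum
#'   and variance floor.
#'
#' @return An object of class `mi_config` (a named list) with the derived
#'   fields `feature_dim` (`F2`) and `n_heads` (`h`) filled in.
#' @examples
#' cfg <- model_config(n_channels = 22, n_timepoints = 1125, sampling_rate = 250)
#' derive_dimensions(cfg)
#' @export
model_config <- function(n_channels,
                         n_timepoints,
                         sampling_rate,
                         n_classes = 4L,
                         temporal_filters = 16L,
                         depth_multiplier = 2L,
                         pool1 = 8L,
                         pool2 = 7L,
                         head_dim = 8L,
                         dropout_conv = 0.3,
                         dropout_window = 0.3,
                         dropout_attn = 0.5,
                         local_kernel = 16L,
                         bn_momentum = 0.99,
                         bn_eps = 1e-3) {
  cfg <- list(
    n_channels = as.integer(n_channels),
    n_timepoints = as.integer(n_timepoints),
    sampling_rate = as.numeric(sampling_rate),
    n_classes = as.integer(n_classes),
    temporal_filters = as.integer(temporal_filters),
    depth_multiplier = as.integer(depth_multiplier),
    feature_dim = as.integer(temporal_filters) * as.integer(depth_multiplier),
    pool1 = as.integer(pool1),
    pool2 = as.integer(pool2),
    head_dim = as.integer(head_dim),
    n_heads = NA_integer_,
    dropout_conv = dropout_conv,
    dropout_window = dropout_window,
    dropout_attn = dropout_attn,
    local_kernel = as.integer(local_kernel),
    bn_momentum = bn_momentum,
    bn_eps = bn_eps
  )
  cfg$n_heads <- cfg$feature_dim %/% cfg$head_dim
  class(cfg) <- "mi_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_channels >= 1L, cfg$n_timepoints >= 1L, cfg$sampling_rate > 0,
    cfg$n_classes >= 2L, cfg$temporal_filters >= 1L,
    cfg$depth_multiplier >= 1L, cfg$pool1 >= 1L, cfg$pool2 >= 1L
  )
  if (cfg$feature_dim != cfg$temporal_filters * cfg$depth_multiplier) {
    stop("feature_dim must equal temporal_filters * depth_multiplier", call. = FALSE)
  }
  if (cfg$feature_dim %% cfg$head_dim != 0L) {
    stop("head_dim must divide feature_dim (F2 = ", cfg$feature_dim,
         ", Dh = ", cfg$head_dim, ")", call. = FALSE)
  }
  if (cfg$n_heads != cfg$feature_dim %/% cfg$head_dim) {
    stop("n_heads must equal feature_dim / head_dim", call. = FALSE)
  }
  drops <- c(cfg$dropout_conv, cfg$dropout_window, cfg$dropout_attn)
  if (any(drops < 0 | drops >= 1)) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$sampling_rate %/% 4 < 1) {
    stop("sampling_rate too low: temporal kernel Fs %/% 4 must be >= 1", call. = FALSE)
  }
  tz <- (cfg$n_timepoints %/% cfg$pool1) %/% cfg$pool2
  if (tz < 4L) {
    stop("configuration yields Tz = ", tz,
         " tokens; at least 4 are needed to build one continuous window",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.mi_config <- function(x, ...) {
  cat("<mi_config> C=", x$n_channels, " T=", x$n_timepoints,
      " Fs=", x$sampling_rate, "Hz  F1=", x$temporal_filters,
      " B=", x$depth_multiplier, " F2=", x$feature_dim,
      " P1=", x$pool1, " P2=", x$pool2,
      " Dh=", x$head_dim, " h=", x$n_heads,
      " classes=", x$n_classes, "\n", sep = "")
  invisible(x)
}

#' Derived sequence dimensions
#'
#' Computes, from a model configuration, every structural size of the
#' tokenization stage: the token count `Tz` (sequential floor division
#' `(T %/% P1) %/% P2`, matching two successive pooling layers), the number
#' of continuous windows `Tz %/% 4`, the fixed two dilated windows, the
#' total window count `L = Tz %/% 4 + 2`, the per-window token count
#' `Tz %/% 2`, and the same plus one once the window-type token is
#' prepended.
#'
#' @param cfg An [model_config()] object.
#' @return A one-row tibble with columns `tz`, `n_continuous`, `n_dilated`,
#'   `n_windows`, `window_len`, `window_len_with_token`.
#' @examples
#' derive_dimensions(model_config(22, 1125, 250))  # tz 20, 7 windows of 11
#' @export
derive_dimensions <- function(cfg) {
  stopifnot(inherits(cfg, "mi_config"))
  validate_config(cfg)
  tz <- (cfg$n_timepoints %/% cfg$pool1) %/% cfg$pool2
  n_cont <- tz %/% 4L
  tibble::tibble(
    tz = tz,
    n_continuous = n_cont,
    n_dilated = 2L,
    n_windows = n_cont + 2L,
    window_len = tz %/% 2L,
    window_len_with_token = tz %/% 2L + 1L
  )
}

#' Ablation switches
#'
#' The four architectural toggles studied in the ablation grid.  The type
#' token and the local attention both operate on sliding windows, so either
#' implies `sliding_window = TRUE`; illegal combinations are rejected.
#'
#' @param sliding_window Build continuous/dilated windows (otherwise the
#'   conv-block token sequence feeds the global stage as one sequence).
#' @param type_token Prepend the trainable window-type token to each window.
#' @param local_attention Apply within-window multi-head self-attention.
#' @param global_attention Apply multi-head self-attention over the
#'   concatenated sequence.
#' @return An object of class `mi_flags`.
#' @examples
#' variant_flags()                        # the full model
#' variant_flags(sliding_window = FALSE,
#'               type_token = FALSE,
#'               local_attention = FALSE,
#'               global_attention = FALSE)  # convolution + classifier only
#' @export
variant_flags <- function(sliding_window = TRUE,
                          type_token = TRUE,
                          local_attention = TRUE,
                          global_attention = TRUE) {
  fl <- list(
    sliding_window = isTRUE(sliding_window),
    type_token = isTRUE(type_token),
    local_attention = isTRUE(local_attention),
    global_attention = isTRUE(global_attention)
  )
  if (fl$type_token && !fl$sliding_window) {
    stop("the type token needs to be employed simultaneously with the ",
         "sliding window (type_token = TRUE requires sliding_window = TRUE)",
         call. = FALSE)
  }
  if (fl$local_attention && !fl$sliding_window) {
    stop("local attention operates on sliding windows ",
         "(local_attention = TRUE requires sliding_window = TRUE)",
         call. = FALSE)
  }
  class(fl) <- "mi_flags"
  fl
}

#' @export
print.mi_flags <- function(x, ...) {
  onoff <- function(b) if (b) "on" else "off"
  cat("<mi_flags> sliding_window:", onoff(x$sliding_window),
      " type_token:", onoff(x$type_token),
      " local_attention:", onoff(x$local_attention),
      " global_attention:", onoff(x$global_attention), "\n")
  invisible(x)
}

#' Read a model/variant/training configuration from a YAML file
#'
#' Keys under `model:` are passed to [model_config()], keys under
#' `variant:` to [variant_flags()], and keys under `train:` to
#' [train_config()]; missing sections fall back to defaults (the `model`
#' section is required).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `model`, `flags`, `train`.
#' @export
read_config_file <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model)) stop("config file must contain a 'model' section", call. = FALSE)
  list(
    model = do.call(model_config, raw$model),
    flags = do.call(variant_flags, if (is.null(raw$variant)) list() else raw$variant),
    train = do.call(train_config, if (is.null(raw$train)) list() else raw$train)
  )
}
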