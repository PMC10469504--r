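# Small configurations and data used across tests.

tiny_cfg <- function(n_classes = 3L, dropout_conv = 0, dropout_window = 0,
                     dropout_attn = 0, ...) {
  model_config(n_channels = 3, n_timepoints = 16, sampling_rate = 8,
               n_classes = n_classes, temporal_filters = 2,
               depth_multiplier = 2, pool1 = 2, pool2 = 2, head_dim = 2,
               dropout_conv = dropout_conv, dropout_window = dropout_window,
               dropout_attn = dropout_attn, ...)
}

tiny_epochs <- function(n = 4, cfg = tiny_cfg(), seed = 99) {
  set.seed(seed)
  epoch_set(array(rnorm(n * cfg$n_channels * cfg$n_timepoints),
                  c(n, cfg$n_channels, cfg$n_timepoints)),
            labels = rep_len(seq_len(cfg$n_classes) - 1L, n),
            sampling_rate = cfg$sampling_rate)
}

bci_cfg <- function() model_config(22, 1125, 250)
physionet_cfg <- function() model_config(18, 640, 160)

# the desk-scale study configuration paired with the synthetic generator
desk_cfg <- function() model_config(16, 256, 128)

# independent loop-based multi-head self-attention oracle: plain nested
# loops over tokens, heads and features, no shared code with the package
oracle_msa <- function(z, p, Dh, h) {
  n <- nrow(z); F2 <- ncol(z)
  q <- z %*% p$Wq; k <- z %*% p$Wk; v <- z %*% p$Wv
  heads <- matrix(0, n, h * Dh)
  for (i in seq_len(h)) {
    qi <- q %*% p$Whq[, , i]; ki <- k %*% p$Whk[, , i]; vi <- v %*% p$Whv[, , i]
    for (a in seq_len(n)) {
      scores <- numeric(n)
      for (b in seq_len(n)) scores[b] <- sum(qi[a, ] * ki[b, ]) / sqrt(Dh)
      w <- exp(scores - max(scores)); w <- w / sum(w)
      acc <- numeric(Dh)
      for (b in seq_len(n)) acc <- acc + w[b] * vi[b, ]
      heads[a, ((i - 1) * Dh + 1):(i * Dh)] <- acc
    }
  }
  heads %*% p$Wo
}

oracle_layernorm <- function(z, gamma, beta, eps = 1e-5) {
  out <- z
  for (a in seq_len(nrow(z))) {
    mu <- mean(z[a, ])
    s <- sqrt(mean((z[a, ] - mu)^2) + eps)
    out[a, ] <- (z[a, ] - mu) / s * gamma + beta
  }
  out
}

small_attn_params <- function(F2, Dh, h, seed = 5) {
  set.seed(seed)
  attnmi:::attn_params_init(F2, Dh, h)
}

# brute-force enumeration of the window index rules, independent of the
# package implementation: continuous windows slide a block of floor(Tz/2)
# consecutive positions with stride 2 starting at 1; dilated windows take
# the odd and even position subsequences truncated to the block length
brute_force_indices <- function(tz) {
  wl <- floor(tz / 2)
  cont <- list()
  start <- 1
  while (start + wl - 1 <= tz && length(cont) < floor(tz / 4)) {
    cont[[length(cont) + 1]] <- seq(start, start + wl - 1)
    start <- start + 2
  }
  odd <- seq(1, tz, by = 2)[seq_len(wl)]
  even <- seq(2, tz, by = 2)[seq_len(wl)]
  list(continuous = cont, dilated = list(odd, even))
}

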