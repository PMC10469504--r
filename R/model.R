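# Full model: convolutional feature extractor -> sliding-window tokenization
# -> local attention -> concatenation -> global attention -> classifier head,
# with the four ablation bypasses.  forward_cached/backward_full implement
# the exact reverse-mode gradients used by the trainer; both are checked
# against finite differences in the test suite.

init_params <- function(cfg, flags, seed = 1L) {
  set.seed(as.integer(seed))
  F1 <- cfg$temporal_filters; B <- cfg$depth_multiplier
  F2 <- cfg$feature_dim; C <- cfg$n_channels
  kt <- max(1L, as.integer(cfg$sampling_rate) %/% 4L)
  dims <- derive_dimensions(cfg)
  l_tot <- seq_total_tokens(cfg, flags)
  p <- list(
    conv = list(
      wt = glorot_uniform(kt, F1, c(kt, F1)),
      bn1 = bn_params(F1),
      wd = glorot_uniform(C, B, c(C, F1, B)),
      bn2 = bn_params(F2),
      wl = glorot_uniform(cfg$local_kernel, 1, c(cfg$local_kernel, F2)),
      bn3 = bn_params(F2)
    ),
    head = list(
      ln_gamma = rep(1, F2), ln_beta = rep(0, F2),
      w1 = glorot_uniform(F2, F2), b1 = rep(0, F2),
      w2 = glorot_uniform(F2, F2), b2 = rep(0, F2),
      wf = glorot_uniform(l_tot * F2, cfg$n_classes),
      bf = rep(0, cfg$n_classes)
    )
  )
  if (flags$type_token) {
    p$type <- list(et1 = stats::rnorm(F2, 0, 0.02),
                   et2 = stats::rnorm(F2, 0, 0.02))
  }
  if (flags$local_attention) {
    p$local <- attn_params_init(F2, cfg$head_dim, cfg$n_heads)
  }
  if (flags$global_attention) {
    p$global <- attn_params_init(F2, cfg$head_dim, cfg$n_heads)
  }
  p
}

# number of tokens in the sequence that reaches the classifier head
seq_total_tokens <- function(cfg, flags) {
  dims <- derive_dimensions(cfg)
  if (!flags$sliding_window) return(dims$tz)
  w <- if (flags$type_token) dims$window_len_with_token else dims$window_len
  dims$n_windows * w
}

#' Convolutional feature extractor
#'
#' Runs the three-stage convolutional block on an epoch set: temporal
#' convolution (`F1` kernels of `Fs %/% 4` samples, length-preserving) with
#' batch normalisation; depthwise channel convolution (`B` kernels spanning
#' all `C` electrodes, collapsing the channel axis into `F2 = F1 B` maps)
#' with batch normalisation, ELU, average pooling `P1` and dropout; local
#' temporal convolution (kernel 16, length-preserving) with batch
#' normalisation, ELU, average pooling `P2` and dropout.  The output is the
#' token sequence: `Tz` temporal positions of `F2` features per trial.
#'
#' @param epochs An [epoch_set()] whose dimensions match `cfg`.
#' @param cfg A [model_config()].
#' @param params Model parameters (from [init_params] via a fitted model);
#'   if `NULL`, freshly initialised parameters with `seed` are used.
#' @param training Logical; training mode enables batch statistics and
#'   dropout.
#' @param seed Seed for fresh parameter initialisation when `params` is
#'   `NULL`.
#' @return Numeric array `n_trials x Tz x F2`.
#' @export
conv_block_forward <- function(epochs, cfg, params = NULL, training = FALSE,
                               seed = 1L) {
  check_epochs_config(epochs, cfg)
  if (is.null(params)) {
    params <- init_params(cfg, variant_flags(FALSE, FALSE, FALSE, FALSE), seed)
  }
  fw <- conv_stage_fwd(epochs$data, cfg, params$conv, training)
  fw$tokens
}

conv_stage_fwd <- function(x, cfg, pc, training) {
  d <- dim(x); n <- d[1]; C <- d[2]; T <- d[3]
  F1 <- cfg$temporal_filters; F2 <- cfg$feature_dim
  c1 <- conv_temporal_fwd(x, pc$wt)
  b1 <- bn_fwd(c1$out, pc$bn1, training, cfg$bn_momentum, cfg$bn_eps)
  arr1 <- array(b1$out, c(n, T, C, F1))
  c2 <- conv_channel_fwd(arr1, pc$wd)
  b2 <- bn_fwd(c2$out, pc$bn2, training, cfg$bn_momentum, cfg$bn_eps)
  e2 <- elu_fwd(b2$out)
  arr2 <- array(e2$out, c(n, T, F2))
  pl1 <- avgpool_fwd(arr2, cfg$pool1)
  dr1 <- dropout_fwd(pl1$out, cfg$dropout_conv, training)
  c3 <- conv_local_fwd(dr1$out, pc$wl)
  t1 <- dim(c3$out)[2]
  b3 <- bn_fwd(matrix(c3$out, n * t1, F2), pc$bn3, training,
               cfg$bn_momentum, cfg$bn_eps)
  e3 <- elu_fwd(b3$out)
  pl2 <- avgpool_fwd(array(e3$out, c(n, t1, F2)), cfg$pool2)
  dr2 <- dropout_fwd(pl2$out, cfg$dropout_conv, training)
  state <- pc
  state$bn1 <- b1$state; state$bn2 <- b2$state; state$bn3 <- b3$state
  list(tokens = dr2$out, state = state,
       cache = list(c1 = c1$cache, b1 = b1$cache, c2 = c2$cache,
                    b2 = b2$cache, e2 = e2$cache, pl1 = pl1$cache,
                    dr1 = dr1$cache, c3 = c3$cache, b3 = b3$cache,
                    e3 = e3$cache, pl2 = pl2$cache, dr2 = dr2$cache,
                    n = n, C = C, T = T, t1 = t1, F1 = F1, F2 = F2))
}

conv_stage_bwd <- function(d_tokens, cache, pc) {
  n <- cache$n; C <- cache$C; T <- cache$T; t1 <- cache$t1
  F1 <- cache$F1; F2 <- cache$F2
  g <- list()
  d <- dropout_bwd(d_tokens, cache$dr2)
  d <- avgpool_bwd(d, cache$pl2)                       # (n, t1, F2)
  d <- elu_bwd(matrix(d, n * t1, F2), cache$e3)
  bb3 <- bn_bwd(d, cache$b3)
  g$bn3 <- list(gamma = bb3$dgamma, beta = bb3$dbeta)
  cl <- conv_local_bwd(array(bb3$dx, c(n, t1, F2)), cache$c3)
  g$wl <- cl$dw
  d <- dropout_bwd(cl$dx, cache$dr1)
  d <- avgpool_bwd(d, cache$pl1)                       # (n, T, F2)
  d <- elu_bwd(matrix(d, n * T, F2), cache$e2)
  bb2 <- bn_bwd(d, cache$b2)
  g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
  cc <- conv_channel_bwd(bb2$dx, cache$c2)
  g$wd <- cc$dw
  bb1 <- bn_bwd(matrix(cc$dx, n * T * C, F1), cache$b1)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  ct <- conv_temporal_bwd(bb1$dx, cache$c1)
  g$wt <- ct$dw
  list(grads = g)
}

# full forward pass with caches for backprop; returns updated params
# (batch-norm running statistics move in training mode)
forward_cached <- function(x, cfg, flags, params, training = FALSE,
                           keep_attn = FALSE) {
  n <- dim(x)[1]
  F2 <- cfg$feature_dim
  dims <- derive_dimensions(cfg)
  cs <- conv_stage_fwd(x, cfg, params$conv, training)
  params$conv <- cs$state
  tokens <- cs$tokens                                  # (n, Tz, F2)
  cache <- list(conv = cs$cache, dims = dims, flags = flags)

  if (flags$sliding_window) {
    ws <- build_windows(tokens, if (flags$type_token) params$type else NULL)
    dw <- dropout_fwd(ws$windows, cfg$dropout_window, training)
    cache$ws <- ws
    cache$dw <- dw$cache
    zw <- dw$out
    L <- dim(zw)[2]; W <- dim(zw)[3]
    if (flags$local_attention) {
      zr <- array(zw, c(n * L, W, F2))
      la <- attn_block_fwd(zr, params$local, cfg$head_dim, cfg$n_heads,
                           cfg$dropout_attn, training, keep_attn)
      cache$local <- la$cache
      cache$local_attn <- la$attn
      zw <- array(la$out, c(n, L, W, F2))
    }
    za <- concatenate_windows(zw)
    cache$L <- L; cache$W <- W
  } else {
    za <- tokens
  }

  if (flags$global_attention) {
    ga <- attn_block_fwd(za, params$global, cfg$head_dim, cfg$n_heads,
                         cfg$dropout_attn, training, keep_attn)
    cache$global <- ga$cache
    cache$global_attn <- ga$attn
    zp <- ga$out
  } else {
    zp <- za
  }
  l_tot <- dim(zp)[2]
  cache$l_tot <- l_tot

  zm <- matrix(zp, n * l_tot, F2)
  ln <- ln_fwd(zm, params$head$ln_gamma, params$head$ln_beta)
  h1 <- dense_fwd(ln$out, params$head$w1, params$head$b1)
  e1 <- elu_fwd(h1$out)
  h2 <- dense_fwd(e1$out, params$head$w2, params$head$b2)
  res <- zm + h2$out
  flat <- matrix(array(res, c(n, l_tot, F2)), n, l_tot * F2)
  fin <- dense_fwd(flat, params$head$wf, params$head$bf)
  probs <- softmax_rows(fin$out)
  cache$head <- list(ln = ln$cache, h1 = h1$cache, e1 = e1$cache,
                     h2 = h2$cache, fin = fin$cache, n = n, F2 = F2)
  list(logits = fin$out, probs = probs, tokens = tokens,
       features = flat, cache = cache, params = params)
}

backward_full <- function(d_logits, cache, cfg, flags, params) {
  n <- cache$head$n; F2 <- cache$head$F2
  l_tot <- cache$l_tot
  g <- list(head = list())
  fb <- dense_bwd(d_logits, cache$head$fin)
  g$head$wf <- fb$dw; g$head$bf <- fb$db
  dres <- matrix(array(fb$dx, c(n, l_tot, F2)), n * l_tot, F2)
  h2b <- dense_bwd(dres, cache$head$h2)
  g$head$w2 <- h2b$dw; g$head$b2 <- h2b$db
  de1 <- elu_bwd(h2b$dx, cache$head$e1)
  h1b <- dense_bwd(de1, cache$head$h1)
  g$head$w1 <- h1b$dw; g$head$b1 <- h1b$db
  lnb <- ln_bwd(h1b$dx, cache$head$ln)
  g$head$ln_gamma <- lnb$dgamma; g$head$ln_beta <- lnb$dbeta
  dzm <- dres + lnb$dx                    # residual: d z'_a
  dzp <- array(dzm, c(n, l_tot, F2))

  if (flags$global_attention) {
    gb <- attn_block_bwd(dzp, cache$global, params$global)
    g$global <- gb$grads
    dza <- gb$dx
  } else {
    dza <- dzp
  }

  if (flags$sliding_window) {
    L <- cache$L; W <- cache$W
    dzw <- concat_bwd(dza, L, W)
    if (flags$local_attention) {
      lb <- attn_block_bwd(array(dzw, c(n * L, W, F2)), cache$local,
                           params$local)
      g$local <- lb$grads
      dzw <- array(lb$dx, c(n, L, W, F2))
    }
    dzw <- dropout_bwd(dzw, cache$dw)
    wb <- windows_bwd(dzw, cache$ws)
    dtok <- wb$dtokens
    if (flags$type_token) g$type <- list(et1 = wb$det1, et2 = wb$det2)
  } else {
    dtok <- dza
  }

  cb <- conv_stage_bwd(dtok, cache$conv, params$conv)
  g$conv <- cb$grads
  g
}

#' Run the full model forward
#'
#' Composes the pipeline according to the ablation switches: with
#' `sliding_window` off the conv-block token sequence feeds the global
#' stage directly as one sequence; with `type_token` off windows carry no
#' type slot; with `local_attention` off windows pass unchanged to
#' concatenation; with `global_attention` off the concatenated sequence
#' goes straight to the classifier head.  With all switches off the model
#' is the convolutional block plus the classifier head.
#'
#' @param epochs An [epoch_set()].
#' @param cfg A [model_config()].
#' @param flags A [variant_flags()] object.
#' @param params Model parameters; freshly initialised with `seed` if
#'   `NULL`.
#' @param training Logical; enables dropout and batch statistics.
#' @param seed Seed for fresh initialisation.
#' @return Matrix `n_trials x n_classes` of class probabilities (each row
#'   sums to 1).
#' @examples
#' cfg <- model_config(4, 64, 32, pool1 = 4, pool2 = 4,
#'                     temporal_filters = 4, head_dim = 4)
#' es <- epoch_set(array(rnorm(3 * 4 * 64), c(3, 4, 64)),
#'                 labels = c(0, 1, 2), sampling_rate = 32)
#' p <- model_forward(es, cfg, variant_flags())
#' rowSums(p)
#' @export
model_forward <- function(epochs, cfg, flags = variant_flags(),
                          params = NULL, training = FALSE, seed = 1L) {
  check_epochs_config(epochs, cfg)
  if (is.null(params)) params <- init_params(cfg, flags, seed)
  fw <- forward_cached(epochs$data, cfg, flags, params, training)
  fw$probs
}
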