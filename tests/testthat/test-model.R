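test_that("intermediate shapes reproduce the published table for both configs", {
  for (case in list(list(cfg = bci_cfg(), tz = 20L, L = 7L, w = 11L),
                    list(cfg = physionet_cfg(), tz = 11L, L = 4L, w = 6L))) {
    cfg <- case$cfg
    set.seed(1)
    es <- epoch_set(array(rnorm(2 * cfg$n_channels * cfg$n_timepoints),
                          c(2, cfg$n_channels, cfg$n_timepoints)),
                    c(0, 1), sampling_rate = cfg$sampling_rate)
    tok <- conv_block_forward(es, cfg)
    expect_equal(dim(tok), c(2L, case$tz, 32L))

    ws <- build_windows(tok, list(et1 = rnorm(32), et2 = rnorm(32)))
    expect_equal(dim(ws$windows), c(2L, case$L, case$w, 32L))

    za <- concatenate_windows(ws)
    expect_equal(dim(za), c(2L, case$L * case$w, 32L))

    flags <- variant_flags()
    params <- attnmi:::init_params(cfg, flags, 1)
    fw <- attnmi:::forward_cached(es$data, cfg, flags, params)
    expect_equal(dim(fw$features), c(2L, case$L * case$w * 32L))
    expect_equal(dim(fw$probs), c(2L, 4L))
  }
})

test_that("all-zero input in inference mode gives identical tokens", {
  cfg <- tiny_cfg()
  es <- epoch_set(array(0, c(2, 3, 16)), c(0, 1), sampling_rate = 8)
  tok <- conv_block_forward(es, cfg, training = FALSE)
  # translation-invariant layers on constant input: every temporal position
  # carries the same feature vector
  for (f in seq_len(dim(tok)[3])) {
    expect_equal(diff(range(tok[1, , f])), 0, tolerance = 1e-12)
  }
})

test_that("epochs and configuration dimension mismatches name the axis", {
  cfg <- tiny_cfg()
  es_badc <- epoch_set(array(0, c(2, 4, 16)), c(0, 1), sampling_rate = 8)
  expect_error(conv_block_forward(es_badc, cfg), "channel")
  es_badt <- epoch_set(array(0, c(2, 3, 20)), c(0, 1), sampling_rate = 8)
  expect_error(conv_block_forward(es_badt, cfg), "time")
})

test_that("every variant emits probability rows", {
  cfg <- tiny_cfg()
  es <- tiny_epochs(3, cfg)
  v <- ablation_variants()
  for (i in seq_len(nrow(v))) {
    fl <- variant_flags(v$sliding_window[i], v$type_token[i],
                        v$local_attention[i], v$global_attention[i])
    p <- model_forward(es, cfg, fl, seed = 2)
    expect_equal(dim(p), c(3L, 3L))
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("with all switches off the model is conv block plus head", {
  cfg <- tiny_cfg()
  es <- tiny_epochs(3, cfg)
  fl <- variant_flags(FALSE, FALSE, FALSE, FALSE)
  params <- attnmi:::init_params(cfg, fl, 3)
  probs <- model_forward(es, cfg, fl, params)

  # independent composition: conv tokens through the head formulas
  tok <- conv_block_forward(es, cfg, params)
  n <- dim(tok)[1]; tz <- dim(tok)[2]; F2 <- dim(tok)[3]
  zm <- matrix(tok, n * tz, F2)
  ln <- oracle_layernorm(zm, params$head$ln_gamma, params$head$ln_beta)
  h1 <- ln %*% params$head$w1 + rep(params$head$b1, each = n * tz)
  e1 <- ifelse(h1 > 0, h1, exp(h1) - 1)
  h2 <- e1 %*% params$head$w2 + rep(params$head$b2, each = n * tz)
  res <- zm + h2
  flat <- matrix(array(res, c(n, tz, F2)), n, tz * F2)
  logits <- flat %*% params$head$wf + rep(params$head$bf, each = n)
  want <- exp(logits - apply(logits, 1, max))
  want <- want / rowSums(want)
  expect_equal(probs, want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("zero final dense weights give the uniform distribution", {
  cfg <- tiny_cfg(n_classes = 4L)
  es <- tiny_epochs(2, cfg)
  fl <- variant_flags()
  params <- attnmi:::init_params(cfg, fl, 4)
  params$head$wf <- params$head$wf * 0
  params$head$bf <- params$head$bf * 0
  probs <- model_forward(es, cfg, fl, params)
  expect_equal(probs, matrix(0.25, 2, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("inference is deterministic: repeated passes are identical", {
  cfg <- tiny_cfg()
  es <- tiny_epochs(4, cfg)
  fl <- variant_flags()
  params <- attnmi:::init_params(cfg, fl, 5)
  p1 <- model_forward(es, cfg, fl, params)
  p2 <- model_forward(es, cfg, fl, params)
  expect_identical(p1, p2)
})

test_that("full-model gradients agree with finite differences", {
  cfg <- tiny_cfg()
  fl <- variant_flags()
  set.seed(42)
  x <- array(rnorm(4 * 3 * 16), c(4, 3, 16))
  y <- c(0L, 1L, 2L, 0L)
  params <- attnmi:::init_params(cfg, fl, 42)
  fw <- attnmi:::forward_cached(x, cfg, fl, params, training = TRUE)
  sx <- attnmi:::softmax_xent(fw$logits, y)
  gr <- attnmi:::backward_full(sx$dlogits, fw$cache, cfg, fl, params)
  loss_of <- function(p) {
    f <- attnmi:::forward_cached(x, cfg, fl, p, training = TRUE)
    attnmi:::softmax_xent(f$logits, y)$loss
  }
  eps <- 1e-6
  probe <- function(gnode, path) {
    if (is.list(gnode)) {
      for (nm in names(gnode)) probe(gnode[[nm]], c(path, nm))
      return(invisible())
    }
    for (k in unique(c(1L, length(gnode)))) {
      pp <- params
      leaf <- pp[[path]]
      leaf[k] <- leaf[k] + eps; pp[[path]] <- leaf; up <- loss_of(pp)
      leaf[k] <- leaf[k] - 2 * eps; pp[[path]] <- leaf; dn <- loss_of(pp)
      num <- (up - dn) / (2 * eps)
      # absolute tolerance handles structurally-zero gradients (e.g. batch
      # norm shifts cancelled by the following normalisation), where the
      # finite difference is pure round-off noise
      expect_equal(gnode[k], num, tolerance = 1e-3,
                   info = paste(c(path, k), collapse = "/"))
    }
  }
  probe(gr, character(0))
})
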