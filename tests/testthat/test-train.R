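test_that("a zero learning rate leaves parameters and loss unchanged", {
  cfg <- tiny_cfg()
  es <- tiny_epochs(6, cfg)
  tc <- train_config(n_epochs = 4, batch_size = 6, learning_rate = 0, seed = 3)
  fit <- train_model(es, cfg, variant_flags(), tc)
  p0 <- attnmi:::init_params(cfg, variant_flags(), 3)
  # trainable weights untouched (batch-norm running stats do move)
  expect_equal(fit$params$conv$wt, p0$conv$wt, tolerance = 1e-12)
  expect_equal(fit$params$head$wf, p0$head$wf, tolerance = 1e-12)
  expect_equal(fit$params$global$Wq, p0$global$Wq, tolerance = 1e-12)
  expect_lt(diff(range(fit$history$loss)), 1e-7)
})

test_that("identical seeds give identical loss histories", {
  cfg <- tiny_cfg(dropout_conv = 0.3, dropout_window = 0.3, dropout_attn = 0.5)
  es <- tiny_epochs(8, cfg)
  tc <- train_config(n_epochs = 5, batch_size = 4, learning_rate = 0.005,
                     seed = 11)
  f1 <- train_model(es, cfg, variant_flags(), tc)
  f2 <- train_model(es, cfg, variant_flags(), tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params$head$wf, f2$params$head$wf)
})

test_that("training reduces the loss on separable toy data", {
  scfg <- synth_config(n_trials_per_class = 8, n_channels = 4,
                       n_timepoints = 224, sampling_rate = 64, seed = 12)
  es <- generate_epochs(scfg)
  cfg <- model_config(4, 224, 64, temporal_filters = 4, depth_multiplier = 2,
                      head_dim = 4)
  tc <- train_config(n_epochs = 30, batch_size = 32, learning_rate = 0.009,
                     seed = 12)
  fit <- train_model(es, cfg, variant_flags(), tc)
  expect_lt(mean(tail(fit$history$loss, 5)), mean(head(fit$history$loss, 5)))
  acc <- mean(predict(fit, es, type = "class") == es$labels)
  expect_gt(acc, 0.45)   # well above the 0.25 chance level
})

test_that("the bare convolutional variant also learns on easy data", {
  scfg <- synth_config(n_trials_per_class = 8, n_channels = 4,
                       n_timepoints = 224, sampling_rate = 64, seed = 13)
  es <- generate_epochs(scfg)
  cfg <- model_config(4, 224, 64, temporal_filters = 4, depth_multiplier = 2,
                      head_dim = 4)
  fl <- variant_flags(FALSE, FALSE, FALSE, FALSE)
  tc <- train_config(n_epochs = 60, batch_size = 32, learning_rate = 0.005,
                     seed = 13)
  fit <- train_model(es, cfg, fl, tc)
  acc <- mean(predict(fit, es, type = "class") == es$labels)
  expect_gt(acc, 0.6)
})

test_that("model summaries expose the history and parameter count", {
  cfg <- tiny_cfg()
  es <- tiny_epochs(6, cfg)
  fit <- train_model(es, cfg, variant_flags(),
                     train_config(n_epochs = 2, batch_size = 6, seed = 1))
  expect_equal(nrow(tidy(fit)), 2)
  g <- glance(fit)
  expect_gt(g$n_parameters, 0)
  expect_equal(g$n_epochs, 2)
  pl <- autoplot(fit)
  expect_s3_class(pl, "ggplot")
})

test_that("feature extraction is deterministic and sized by the token count", {
  cfg <- tiny_cfg()
  es <- tiny_epochs(5, cfg)
  fit <- train_model(es, cfg, variant_flags(),
                     train_config(n_epochs = 2, batch_size = 5, seed = 2))
  f1 <- extract_features(fit, es)
  f2 <- extract_features(fit, es)
  expect_identical(f1, f2)
  dims <- derive_dimensions(cfg)
  expect_equal(ncol(f1), dims$n_windows * dims$window_len_with_token *
                 cfg$feature_dim)
  expect_error(extract_features(fit, es, site = "nope"), "available sites")

  # with the global stage ablated the pre-classifier site keeps the size
  fl <- variant_flags(TRUE, TRUE, TRUE, FALSE)
  fit2 <- train_model(es, cfg, fl,
                      train_config(n_epochs = 2, batch_size = 5, seed = 2))
  expect_equal(ncol(extract_features(fit2, es)), ncol(f1))
})
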