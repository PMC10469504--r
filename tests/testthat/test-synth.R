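test_that("generation is a pure function of the configuration", {
  scfg <- synth_config(n_trials_per_class = 4, n_timepoints = 224, seed = 42)
  a <- generate_epochs(scfg)
  b <- generate_epochs(scfg)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
  expect_identical(a$subject, b$subject)
})

test_that("labels are balanced and subjects form contiguous balanced blocks", {
  scfg <- synth_config(n_trials_per_class = 6, n_timepoints = 224,
                       n_subjects = 3, seed = 1)
  es <- generate_epochs(scfg)
  expect_equal(unname(table(es$labels)), rep(6L, 4), ignore_attr = TRUE)
  expect_equal(length(unique(es$subject)), 3L)
  # every subject sees every class equally often
  tab <- table(es$subject, es$labels)
  expect_true(all(tab == 2L))
})

test_that("average spectrum peaks inside the oscillation band", {
  scfg <- synth_config(n_trials_per_class = 5, seed = 3)
  es <- generate_epochs(scfg)
  d <- dim(es$data); T <- d[3]; fs <- es$sampling_rate
  pow <- rep(0, T)
  for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
    pow <- pow + Mod(stats::fft(es$data[i, ch, ]))^2
  }
  freqs <- (seq_len(T) - 1) * fs / T
  half <- freqs > 0 & freqs <= fs / 2
  peak <- freqs[half][which.max(pow[half])]
  expect_gte(peak, scfg$osc_band[1])
  expect_lte(peak, scfg$osc_band[2])
})

test_that("with no attenuation the data carry no class information", {
  scfg <- synth_config(n_trials_per_class = 30, erd_depth = 0, seed = 4)
  es <- generate_epochs(scfg)
  sp <- make_splits(es, "within_kfold", k = 4, seed = 4)
  bl <- bandpower_baseline(subset_epochs(es, sp$train[[1]]),
                           subset_epochs(es, sp$test[[1]]))
  # 30 test trials at chance 0.25: 3 binomial SDs ~ 0.24
  expect_lt(abs(bl$accuracy - 0.25), 3 * sqrt(0.25 * 0.75 / 30))
})

test_that("deep attenuation makes the band-power baseline nearly perfect", {
  scfg <- synth_config(seed = 5)   # defaults: erd 0.9, noise 0.5, 100/class
  es <- generate_epochs(scfg)
  sp <- make_splits(es, "within_kfold", k = 5, seed = 5)
  bl <- bandpower_baseline(subset_epochs(es, sp$train[[1]]),
                           subset_epochs(es, sp$test[[1]]))
  expect_gte(bl$accuracy, 0.9)
})

test_that("baseline accuracy is non-decreasing in attenuation depth", {
  depths <- c(0, 0.3, 0.6, 0.9)
  seeds <- 1:5
  acc <- matrix(0, length(seeds), length(depths))
  for (si in seq_along(seeds)) {
    for (di in seq_along(depths)) {
      scfg <- synth_config(n_trials_per_class = 25, erd_depth = depths[di],
                           seed = 100 + seeds[si])
      es <- generate_epochs(scfg)
      sp <- make_splits(es, "within_kfold", k = 5, seed = seeds[si])
      bl <- bandpower_baseline(subset_epochs(es, sp$train[[1]]),
                               subset_epochs(es, sp$test[[1]]))
      acc[si, di] <- bl$accuracy
    }
  }
  means <- colMeans(acc)
  ses <- apply(acc, 2, stats::sd) / sqrt(length(seeds))
  for (d in seq_len(length(depths) - 1)) {
    expect_gte(means[d + 1], means[d] - (ses[d] + ses[d + 1]))
  }
})

test_that("degenerately short trials warn rather than error", {
  expect_warning(generate_epochs(synth_config(n_trials_per_class = 2,
                                              n_timepoints = 64, seed = 1)),
                 "224")
})
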