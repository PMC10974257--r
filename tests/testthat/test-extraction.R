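test_that("the band-pass keeps the passband and kills DC and out-of-band tones", {
  fs <- 10
  t <- seq_len(2000) / fs
  expect_lt(max(abs(bandpass_filter(rep(7, 2000), fs))), 1e-9)
  tone <- sin(2 * pi * 0.25 * t)
  expect_equal(sd(bandpass_filter(tone, fs)) / sd(tone), 1, tolerance = 0.01)
  hi <- sin(2 * pi * 4.9 * t)
  atten <- 20 * log10(sd(bandpass_filter(hi, fs)) / sd(hi))
  expect_lt(atten, -40)
  expect_error(bandpass_filter(tone, fs, 4, 0.01, 6),
               class = "fnirsduo_config_error")
  expect_error(bandpass_filter(1:5, fs), class = "fnirsduo_data_error")
})

test_that("band splitting partitions the mode set exactly", {
  x <- two_tone(dur = 60)
  ms <- vmd_decompose(x, vmd_config(K = 5, alpha = 1500), 10)
  for (rule in c("trend", "freq-threshold")) {
    sp <- split_bands(ms, rule, f_split = 0.5)
    expect_equal(sp$lf_sum + sp$hf_sum, rowSums(ms$modes), tolerance = 1e-12)
    expect_setequal(c(sp$lf_indices, sp$hf_indices), 1:5)
  }
  # trend rule: single lowest-centroid mode is LF
  sp <- split_bands(ms, "trend")
  expect_identical(sp$lf_indices, which.min(ms$omega))
  # K = 1: the only mode is LF, HF sum is zero
  ms1 <- vmd_decompose(x, vmd_config(K = 1, alpha = 1500), 10)
  sp1 <- split_bands(ms1, "trend")
  expect_equal(sp1$hf_sum, rep(0, length(x)))
  # nine sorted modes under the trend rule: indices match the one-LF choice
  fake <- structure(list(modes = matrix(rnorm(90 * 9), 90, 9),
                         omega = sort(runif(9, 0.01, 0.45)),
                         omega_hz = NULL), class = "mode_set")
  fake$omega_hz <- fake$omega * 10
  spf <- split_bands(fake, "trend")
  expect_identical(spf$lf_indices, 1L)
  expect_identical(spf$hf_indices, 2:9)
})

test_that("constructed two-source mixtures are unmixed accurately", {
  fs <- 10
  t <- seq_len(3000) / fs
  s_sys <- sin(2 * pi * 0.25 * t)
  u <- make_evoked(stimulus_protocol(300, c(60, 160, 260), 20), fs)
  s_bfa <- u - mean(u)
  near <- 0.8 * s_sys
  far <- 0.7 * s_sys + 0.6 * s_bfa
  res <- extract_bfa(near, far, quick_extraction(), fs)
  truth <- bandpass_filter(0.6 * s_bfa, fs)
  expect_gte(pearson_r(res$bfa, truth), 0.99)
  # null case: no brain signal -> output is a few percent of the far channel
  res0 <- extract_bfa(near, 0.7 * s_sys + 1e-9 * rnorm(3000),
                      quick_extraction(), fs)
  expect_lt(sqrt(mean(res0$bfa^2)), 0.05 * sqrt(mean((far - mean(far))^2)))
})

test_that("output respects the recovered-sum identity and scale equivariance", {
  rec <- simulate_recording(quick_sim(seed = 31, snr = 1))
  cfg <- quick_extraction()
  res <- extract_bfa(rec$y_near, rec$y_far, cfg, 10)
  expect_identical(res$bfa, res$lf_component + res$hf_component)
  # positive rescaling of both channels rescales the output linearly
  res2 <- extract_bfa(3 * rec$y_near, 3 * rec$y_far, cfg, 10)
  expect_equal(res2$bfa, 3 * res$bfa, tolerance = 1e-6)
  # constant offsets are removed by the front-end filter
  res3 <- extract_bfa(rec$y_near + 5, rec$y_far - 2, cfg, 10)
  expect_equal(res3$bfa, res$bfa, tolerance = 1e-6)
})

test_that("stronger amplification never hurts the noise-free cancellation", {
  fs <- 10
  t <- seq_len(2500) / fs
  s_sys <- sin(2 * pi * 0.25 * t) + 0.5 * sin(2 * pi * 0.1 * t)
  u <- make_evoked(stimulus_protocol(250, c(50, 130, 210), 20), fs)
  near <- 0.8 * s_sys
  far <- 0.7 * s_sys + 0.6 * (u - mean(u))
  truth <- bandpass_filter(0.6 * (u - mean(u)), fs)
  rs <- vapply(c(5, 50, 500), function(kc)
    pearson_r(extract_bfa(near, far, quick_extraction(k_const = kc), fs)$bfa,
              truth), numeric(1))
  expect_true(all(diff(rs) >= -1e-3))
})

test_that("interference power is strictly reduced across seeds", {
  fs <- 10
  for (seed in 1:10) {
    rec <- simulate_recording(quick_sim(seed = seed, snr = 1))
    res <- extract_bfa(rec$y_near, rec$y_far, quick_extraction(), fs)
    truth <- bandpass_filter(rec$truth_bfa, fs)
    expect_lt(var(res$bfa - truth), var(rec$y_far - mean(rec$y_far)))
  }
})

test_that("degenerate extraction inputs are rejected", {
  rec <- simulate_recording(quick_sim(seed = 1))
  expect_error(extract_bfa(rec$y_near, rec$y_far[1:500], quick_extraction(), 10),
               class = "fnirsduo_data_error")
  expect_error(extract_bfa(rep(1, 1200), rec$y_far[1:1200], quick_extraction(), 10),
               class = "fnirsduo_data_error")
  expect_error(extract_bfa(rec$y_near[1:150], rec$y_far[1:150],
                           quick_extraction(), 10),
               class = "fnirsduo_data_error")
  # <= 2 samples of jitter are tolerated by truncation
  res <- extract_bfa(rec$y_near[1:1199], rec$y_far[1:1200],
                     quick_extraction(), 10)
  expect_length(res$bfa, 1199)
})
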