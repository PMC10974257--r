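test_that("RLS identifies an FIR relationship to steady state", {
  set.seed(10)
  ref <- rnorm(3000)
  h <- c(0.7, -0.3, 0.15, 0.05)
  des <- as.numeric(stats::filter(ref, h, method = "convolution", sides = 1))
  des[is.na(des)] <- 0
  e <- rls_extract(ref, des, rls_config(order = 8))
  tail_idx <- 501:3000
  expect_lt(sqrt(mean(e[tail_idx]^2)) / sqrt(mean(des[tail_idx]^2)), 0.01)
})

test_that("RLS passes through a component orthogonal to the reference", {
  set.seed(11)
  ref <- rnorm(3000)
  brain <- rnorm(3000)
  # growing-window least squares (forgetting 1): no spurious tracking of the
  # orthogonal component, so past the adaptation transient the error
  # reproduces it
  e <- rls_extract(ref, brain, rls_config(forgetting = 1))
  idx <- 101:3000
  expect_gt(cor(e[idx], brain[idx]), 0.95)
})

test_that("RLS degenerate and closed-form cases behave", {
  expect_error(rls_extract(rep(1, 100) * 0, rnorm(100)),
               class = "fnirsduo_data_error")
  expect_error(rls_extract(rnorm(5), rnorm(5), rls_config(order = 8)),
               class = "fnirsduo_data_error")
  # order-1, lambda = 1, proportional signals: error collapses towards zero
  ref <- rep(2, 200) + c(0.001 * sin(1:200))   # tiny variation keeps sd > 0
  des <- 3 * ref
  e <- rls_extract(ref, des, rls_config(order = 1, forgetting = 1, delta = 1e4))
  expect_lt(mean(abs(e[50:200])), 1e-3 * mean(abs(des)))
  expect_identical(e, rls_extract(ref, des,
                                  rls_config(order = 1, forgetting = 1,
                                             delta = 1e4)))
})

test_that("fast-ICA unmixes two independent tones up to sign and order", {
  t <- seq_len(4000) / 100
  s1 <- sin(2 * pi * 0.7 * t)
  s2 <- sign(sin(2 * pi * 0.31 * t))    # non-Gaussian square source
  x1 <- 0.8 * s1 + 0.4 * s2
  x2 <- 0.3 * s1 + 0.9 * s2
  res <- ica_extract(x1, x2, truth = s1, seed = 2)
  expect_false(res$flagged)
  expect_gt(cor(res$estimate, s1), 0.99)
  # deterministic given the seed
  res2 <- ica_extract(x1, x2, truth = s1, seed = 2)
  expect_identical(res$estimate, res2$estimate)
  # identical channels are degenerate and flagged
  expect_true(ica_extract(x1, x1)$flagged)
})

test_that("EMD isolates a dominant tone and EEMD reduces to EMD without noise", {
  t <- seq_len(1500) / 10
  x <- sin(2 * pi * 0.8 * t) + 0.3 * t / max(t)
  d <- emd(x)
  expect_gt(ncol(d$imfs), 0)
  expect_equal(rowSums(d$imfs) + d$residue, x, tolerance = 1e-9)
  expect_lt(abs(fft_peak_freq(d$imfs[, 1], 10) - 0.8), 0.02)
  e1 <- eemd(x, ensemble_size = 1, noise_sd = 0)
  expect_equal(e1$imfs, d$imfs, tolerance = 1e-12)
})

test_that("EEMD-RLS is seeded-reproducible and tracks plain RLS on one tone", {
  set.seed(20)
  t <- seq_len(1200) / 10
  ref <- sin(2 * pi * 0.5 * t) + 0.01 * rnorm(1200)
  des <- 0.9 * sin(2 * pi * 0.5 * t + 0.3)
  a <- eemd_rls_extract(ref, des, ensemble_size = 10, noise_sd = 0.1, seed = 4)
  b <- eemd_rls_extract(ref, des, ensemble_size = 10, noise_sd = 0.1, seed = 4)
  expect_identical(a, b)
  # with the ensemble collapsed to plain EMD, single-tone channels have one
  # dominant mode and the estimate matches plain RLS on that mode pair
  a0 <- eemd_rls_extract(ref, des, ensemble_size = 1, noise_sd = 0, seed = 4)
  dn <- emd(ref)
  df <- emd(des)
  dom_n <- which.max(apply(dn$imfs, 2, sd))
  dom_f <- which.max(apply(df$imfs, 2, sd))
  plain_imf <- rls_extract(dn$imfs[, dom_n], df$imfs[, dom_f])
  expect_lt(sqrt(mean((a0 - plain_imf)^2)) / sd(des), 0.05)
})
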