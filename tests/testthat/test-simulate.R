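test_that("oscillation components sit at their configured frequencies", {
  cfg <- sim_config(seed = 4)
  osc <- make_oscillations(cfg)
  expect_named(osc, c("a", "b", "m", "v"))
  expect_length(osc$a, 2000)
  for (i in seq_along(osc))
    expect_lt(abs(fft_peak_freq(osc[[i]], 10) - cfg$osc_freqs[[i]]), 1 / 200 + 1e-9)
  # unit amplitude sinusoids
  expect_equal(max(abs(osc$a)), 1, tolerance = 1e-3)
})

test_that("zero-duration oscillations are empty without error", {
  cfg <- sim_config(protocol = stimulus_protocol(total_duration = 0,
                                                 block_onsets = numeric(0)))
  osc <- make_oscillations(cfg)
  expect_identical(lengths(osc), c(a = 0L, b = 0L, m = 0L, v = 0L))
})

test_that("Nyquist-violating sampling rate is rejected", {
  expect_error(sim_config(sampling_rate = 2), class = "fnirsduo_config_error")
  cfg <- sim_config()
  cfg$sampling_rate <- 2   # bypass constructor check
  expect_error(make_oscillations(cfg), class = "fnirsduo_config_error")
})

test_that("scalp drift is slow, zero-mean and seed-reproducible", {
  d1 <- make_scalp_drift(200, 10, seed = 11)
  d2 <- make_scalp_drift(200, 10, seed = 11)
  d3 <- make_scalp_drift(200, 10, seed = 12)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  expect_equal(mean(d1), 0, tolerance = 1e-12)
  expect_equal(sd(d1), 0.1, tolerance = 1e-9)
  # spectral check: power above 0.01 Hz below 5% of total
  sp <- mode_spectrum(d1, 10)
  frac <- sum(sp$power[sp$frequency > 0.01]) / sum(sp$power)
  expect_lt(frac, 0.05)
})

test_that("evoked response honours the protocol contract", {
  fs <- 10
  expect_equal(make_evoked(stimulus_protocol(200, numeric(0)), fs),
               rep(0, 2000))
  u <- make_evoked(stimulus_protocol(200, 40, 20), fs)
  expect_equal(max(u), 1)
  expect_true(all(abs(u[1:390]) < 1e-6))       # zero before onset
  # block integral: area exceeds 0.8 x block duration for a 20 s block
  expect_gt(sum(u) / fs, 0.8 * 20)
  expect_error(stimulus_protocol(200, c(40, 50), 20),
               class = "fnirsduo_config_error")
  expect_error(stimulus_protocol(200, 190, 20),
               class = "fnirsduo_config_error")
})

test_that("layer concentration follows the amplitude-weighted model", {
  n <- 50
  comp <- list(a = sin(1:n), b = cos(1:n), m = sin(1:n / 3), v = cos(1:n / 7),
               u = rep(0, n))
  lay <- layer_params(1, 2, 3, 4, 5, baseline = 7)
  expect_equal(layer_concentration(lay, comp),
               7 + comp$a + 2 * comp$b + 3 * comp$m + 4 * comp$v)
  # all amplitudes zero -> constant baseline
  lay0 <- layer_params(0, 0, 0, 0, 0, baseline = 3)
  expect_equal(layer_concentration(lay0, comp), rep(3, n))
  # scalp with tau == 0 reduces to the non-scalp formula
  expect_equal(layer_concentration(lay, comp, tau = rep(0, n), is_scalp = TRUE),
               layer_concentration(lay, comp))
  # gain modulation scales the whole bracket
  tau <- rep(0.5, n)
  expect_equal(layer_concentration(lay, comp, tau = tau, is_scalp = TRUE) - 7,
               1.5 * (layer_concentration(lay, comp) - 7))
  expect_error(layer_concentration(lay, c(comp[1:4], list(u = 1:3))),
               class = "fnirsduo_data_error")
})

test_that("channel mixing follows the two-detector model", {
  cfg <- sim_config(noise_sd = 0, tau_sd = 0, seed = 3)
  # all fluctuations zero, nonzero baselines -> y_near = k1 * sum(baselines)
  layers0 <- lapply(c(1, 2, 3, 4, 5), function(b)
    layer_params(0, 0, 0, 0, 0, baseline = b))
  cfg0 <- sim_config(layers = layers0, noise_sd = 0, tau_sd = 0)
  traces0 <- lapply(layers0, function(l) rep(l$baseline, 100))
  rec0 <- mix_channels(traces0, cfg0)
  expect_equal(rec0$y_near, rep(0.8 * 6, 100))
  expect_equal(rec0$truth_bfa, rep(0, 100))

  # with noise off, y_far - (k2/k1) y_near recovers k3 * C4 fluctuation
  rec <- simulate_recording(cfg)
  resid <- rec$y_far - (cfg$k2 / cfg$k1) * rec$y_near
  expect_equal(resid, rec$truth_bfa, tolerance = 1e-10)
})

test_that("simulation is bit-reproducible and amplitude-linear", {
  cfg <- sim_config(seed = 21)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$y_far, r2$y_far)
  expect_identical(r1$y_near, r2$y_near)

  # scaling every amplitude by c scales the demeaned noise-free channels by c
  scale_layers <- function(l, c)
    layer_params(l$alpha * c, l$beta * c, l$gamma * c, l$zeta * c, l$phi * c,
                 l$baseline)
  base <- sim_config(noise_sd = 0, tau_sd = 0, seed = 5)
  scaled <- sim_config(layers = lapply(default_layers(), scale_layers, c = 2.5),
                       noise_sd = 0, tau_sd = 0, seed = 5)
  rb <- simulate_recording(base)
  rs <- simulate_recording(scaled)
  expect_equal(rs$y_near - mean(rs$y_near), 2.5 * (rb$y_near - mean(rb$y_near)),
               tolerance = 1e-9)
})

test_that("noise-free near channel has spectral peaks at all four rhythms", {
  cfg <- sim_config(noise_sd = 0, tau_sd = 0, seed = 9)
  rec <- simulate_recording(cfg)
  sp <- mode_spectrum(rec$y_near - mean(rec$y_near), 10)
  bin <- 1 / 200
  for (f in c(1.2, 0.25, 0.1, 0.04)) {
    near <- which(abs(sp$frequency - f) <= bin + 1e-9)
    far_power <- max(sp$power[sp$frequency > f + 5 * bin & sp$frequency < f + 10 * bin])
    expect_gt(max(sp$power[near]), far_power)
  }
})

test_that("set_snr achieves, keeps and scales the exact variance ratio", {
  rec <- simulate_recording(sim_config(seed = 2))
  ratio <- function(r) var(r$truth_bfa) / var(r$y_far - r$truth_bfa)
  r1 <- set_snr(rec, 1)
  expect_equal(ratio(r1), 1, tolerance = 1e-9)
  r4 <- set_snr(rec, 4)
  expect_equal(ratio(r4), 4, tolerance = 1e-9)
  # idempotent
  r1b <- set_snr(r1, 1)
  expect_equal(r1b$y_far, r1$y_far, tolerance = 1e-12)
  # doubling the target scales the truth amplitude by sqrt(2)
  r2 <- set_snr(rec, 2)
  expect_equal(r2$truth_bfa, sqrt(2) * r1$truth_bfa, tolerance = 1e-9)
  # degenerate: no truth variance
  rec$truth_bfa <- rep(0, length(rec$truth_bfa))
  expect_error(set_snr(rec, 1), class = "fnirsduo_data_error")
})

test_that("recordings round-trip through CSV", {
  rec <- simulate_recording(quick_sim(seed = 8, snr = 1))
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_recording(path)
  expect_equal(back$y_near, rec$y_near, tolerance = 1e-12)
  expect_equal(back$truth_bfa, rec$truth_bfa, tolerance = 1e-12)
  expect_equal(back$sampling_rate, 10, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})
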