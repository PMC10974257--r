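#' Per-layer hemodynamic fluctuation amplitudes
#'
#' One tissue layer of the five-layer head model (scalp, skull, cerebrospinal
#' fluid, gray matter, white matter).  The layer's oxy-hemoglobin concentration
#' is a baseline plus amplitude-weighted cardiac, respiratory, low-frequency,
#' ultra-low-frequency and evoked components.
#'
#' @param alpha Cardiac amplitude (uM), oscillation near 1.2 Hz.
#' @param beta Respiratory amplitude (uM), near 0.25 Hz.
#' @param gamma Low-frequency oscillation (Mayer wave) amplitude (uM), 0.1 Hz.
#' @param zeta Ultra-low-frequency oscillation amplitude (uM), 0.04 Hz.
#' @param phi Evoked-response amplitude (uM); nonzero only where stimulus-locked
#'   hemodynamics occur (gray matter in the default table).
#' @param baseline Baseline concentration (uM).  Only fluctuations enter the
#'   extraction problem, so the default is 0.
#' @return An object of class `layer_params`.
#' @export
layer_params <- function(alpha, beta, gamma, zeta, phi, baseline = 0) {
  amps <- c(alpha = alpha, beta = beta, gamma = gamma, zeta = zeta, phi = phi)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop_config("layer amplitudes must be finite and >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, zeta = zeta,
                 phi = phi, baseline = baseline),
            class = "layer_params")
}

#' Default five-layer amplitude table
#'
#' Amplitudes (uM) of the cardiac, respiratory, LFO, ULFO and evoked components
#' in each tissue layer of the oxy-hemoglobin model.  Only the gray-matter layer
#' carries an evoked response (15 uM).
#'
#' @return Named list of five [layer_params()]: scalp, skull, csf, gray, white.
#' @export
default_layers <- function() {
  list(scalp = layer_params(0.2,  0.6,  0.9,  1.0, 0),
       skull = layer_params(0.2,  0.63, 0.96, 1.1, 0),
       csf   = layer_params(0.02, 0.06, 0.08, 0.1, 0),
       gray  = layer_params(0.2,  0.65, 0.92, 1.1, 15),
       white = layer_params(0.2,  0.6,  0.9,  1.0, 0))
}

#' Block-design stimulation protocol
#'
#' @param total_duration Total record length in seconds.
#' @param block_onsets Stimulation onset times in seconds.
#' @param block_duration Duration of each stimulation block in seconds.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(total_duration = 200,
                              block_onsets = c(20, 60, 100, 140, 180),
                              block_duration = 20) {
  if (total_duration < 0) stop_config("total_duration must be >= 0")
  if (length(block_onsets)) {
    ons <- sort(block_onsets)
    if (any(ons < 0) || any(ons + block_duration > total_duration))
      stop_config("blocks must lie inside [0, total_duration]")
    if (length(ons) > 1 && any(diff(ons) < block_duration))
      stop_config("stimulation blocks must not overlap")
  }
  structure(list(total_duration = total_duration,
                 block_onsets = as.numeric(block_onsets),
                 block_duration = block_duration),
            class = "stimulus_protocol")
}

#' Simulation configuration
#'
#' Bundles everything needed to generate one dual-channel recording: the layer
#' amplitude table, oscillation frequencies, stimulation protocol, channel
#' mixing constants, noise levels, optional SNR target and seed.
#'
#' @param sampling_rate Sampling rate in Hz.  Must exceed twice the fastest
#'   oscillation (cardiac) frequency.
#' @param layers Named list of five [layer_params()] in the order scalp, skull,
#'   csf, gray, white.
#' @param osc_freqs Frequencies (Hz) of the cardiac, respiratory, LFO and ULFO
#'   components, in that order.
#' @param protocol A [stimulus_protocol()].
#' @param k1,k2,k3 Positive mixing constants: the near channel is
#'   `k1 * superficial`, the far channel `k2 * superficial + k3 * gray`.
#' @param noise_sd Standard deviation (uM) of the independent Gaussian
#'   measurement noise on each channel.
#' @param snr Optional variance-ratio target for the gray-matter component of
#'   the far channel; `NULL` leaves the natural ratio.
#' @param seed Integer seed; identical configurations reproduce bit-identical
#'   recordings.
#' @param tau_sd Standard deviation of the slow multiplicative scalp drift.
#' @param tau_scope Whether the scalp drift gain `(1 + tau)` multiplies the
#'   whole fluctuation bracket (`"all"`, default) or only the cardiac term
#'   (`"cardiac"`).
#' @param deterministic_phase If `TRUE` all oscillation phases are zero instead
#'   of seeded-random.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 10,
                       layers = default_layers(),
                       osc_freqs = c(cardiac = 1.2, resp = 0.25,
                                     lfo = 0.1, ulfo = 0.04),
                       protocol = stimulus_protocol(),
                       k1 = 0.8, k2 = 0.7, k3 = 0.6,
                       noise_sd = 0.1, snr = NULL, seed = 1L,
                       tau_sd = 0.1, tau_scope = c("all", "cardiac"),
                       deterministic_phase = FALSE) {
  tau_scope <- match.arg(tau_scope)
  if (length(layers) != 5) stop_config("exactly five tissue layers required")
  if (!all(vapply(layers, inherits, logical(1), "layer_params")))
    stop_config("layers must be layer_params objects")
  if (sampling_rate <= 2 * max(osc_freqs))
    stop_config("sampling_rate must exceed twice the fastest oscillation ",
                "frequency (Nyquist)")
  if (any(c(k1, k2, k3) <= 0)) stop_config("k1, k2, k3 must be > 0")
  if (!is.null(snr) && snr <= 0) stop_config("snr must be > 0 when set")
  structure(list(sampling_rate = sampling_rate, layers = layers,
                 osc_freqs = osc_freqs, protocol = protocol,
                 k1 = k1, k2 = k2, k3 = k3, noise_sd = noise_sd,
                 snr = snr, seed = as.integer(seed), tau_sd = tau_sd,
                 tau_scope = tau_scope,
                 deterministic_phase = deterministic_phase),
            class = "sim_config")
}

#' Physiological oscillation components
#'
#' Generates the four unit-amplitude sinusoids shared by all tissue layers:
#' cardiac (~1.2 Hz), respiratory (~0.25 Hz), low-frequency (0.1 Hz) and
#' ultra-low-frequency (0.04 Hz) oscillations.  Phases are seeded-uniform in
#' `[0, 2*pi)` unless `deterministic_phase` is set in the configuration.
#'
#' @param config A [sim_config()].
#' @return List with components `a` (cardiac), `b` (respiration), `m` (LFO),
#'   `v` (ULFO), each of length `total_duration * sampling_rate`.
#' @export
make_oscillations <- function(config) {
  fs <- config$sampling_rate
  if (fs <= 2 * max(config$osc_freqs))
    stop_config("sampling rate violates Nyquist for the cardiac component")
  n <- round(config$protocol$total_duration * fs)
  phases <- if (config$deterministic_phase) rep(0, 4) else
    with_seed(config$seed, runif(4, 0, 2 * pi))
  t <- seq_len(n) / fs
  out <- lapply(seq_along(config$osc_freqs), function(i)
    if (n == 0) numeric(0) else sin(2 * pi * config$osc_freqs[[i]] * t + phases[i]))
  names(out) <- c("a", "b", "m", "v")
  out
}

#' Slow random scalp drift
#'
#' A zero-mean, slowly varying random series modelling scalp-specific
#' interference uncorrelated with the deeper layers.  Built as a Gaussian
#' random walk low-pass filtered (spectrally, eighth-order magnitude roll-off)
#' at `cutoff` Hz and rescaled to `sd`; essentially all of its power lies
#' below 0.01 Hz.
#'
#' @param duration Length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed; the series is reproducible.
#' @param sd Target standard deviation (dimensionless gain fluctuation).
#' @param cutoff Low-pass corner frequency in Hz.
#' @return Numeric vector of length `duration * sampling_rate`.
#' @export
make_scalp_drift <- function(duration, sampling_rate, seed, sd = 0.1,
                             cutoff = 0.01) {
  if (duration < 0) stop_config("duration must be >= 0")
  n <- round(duration * sampling_rate)
  if (n == 0) return(numeric(0))
  w <- with_seed(seed, cumsum(rnorm(n)))
  f <- seq(0, n - 1) / n * sampling_rate
  f <- pmin(f, sampling_rate - f)              # two-sided frequency axis
  gain <- 1 / sqrt(1 + (f / cutoff)^8)
  y <- Re(fft(fft(w) * gain, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y <- y * sd / s
  y
}

# Canonical double-gamma hemodynamic impulse response sampled at fs.
hrf_kernel <- function(fs, length_s = 32, peak = 6, undershoot = 16,
                       ratio = 1 / 6) {
  t <- seq(0, length_s, by = 1 / fs)
  dgamma(t, shape = peak, rate = 1) - ratio * dgamma(t, shape = undershoot, rate = 1)
}

#' Evoked hemodynamic response
#'
#' Boxcar of the stimulation protocol convolved with a canonical double-gamma
#' hemodynamic impulse response (peak 6 s, undershoot 16 s, undershoot ratio
#' 1/6), renormalized so the response maximum is 1.
#'
#' @param protocol A [stimulus_protocol()].
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector `u(t)`; all zeros when the protocol has no blocks.
#' @export
make_evoked <- function(protocol, sampling_rate) {
  if (!inherits(protocol, "stimulus_protocol"))
    protocol <- do.call(stimulus_protocol, protocol)
  fs <- sampling_rate
  n <- round(protocol$total_duration * fs)
  if (n == 0) return(numeric(0))
  box <- numeric(n)
  t <- seq_len(n) / fs
  for (on in protocol$block_onsets)
    box[t > on & t <= on + protocol$block_duration] <- 1
  if (!any(box > 0)) return(box)
  h <- hrf_kernel(fs)
  L <- n + length(h)
  conv <- Re(fft(fft(c(box, rep(0, L - n))) * fft(c(h, rep(0, L - length(h)))),
                 inverse = TRUE)) / L / fs
  u <- conv[seq_len(n)]
  u / max(u)
}

#' Layer concentration time course
#'
#' Oxy-hemoglobin concentration of one tissue layer: baseline plus the
#' amplitude-weighted sum of the shared oscillations and evoked response.  For
#' the scalp layer the fluctuation is modulated by the slow drift gain
#' `(1 + tau(t))` — applied to the whole bracket by default, or to the cardiac
#' term only under `tau_scope = "cardiac"`.
#'
#' @param layer A [layer_params()].
#' @param components List with elements `a`, `b`, `m`, `v`, `u` of equal length.
#' @param tau Optional drift series (scalp only), same length as components.
#' @param is_scalp Apply the drift modulation?
#' @param tau_scope `"all"` or `"cardiac"`.
#' @return Numeric concentration trace (uM).
#' @export
layer_concentration <- function(layer, components, tau = NULL,
                                is_scalp = FALSE, tau_scope = "all") {
  lens <- vapply(components[c("a", "b", "m", "v", "u")], length, integer(1))
  if (length(unique(lens)) != 1)
    stop_data("oscillation components must share one length")
  if (is_scalp && !is.null(tau) && length(tau) != lens[1])
    stop_data("tau length must match the components")
  with(components, {
    bracket <- layer$alpha * a + layer$beta * b + layer$gamma * m +
      layer$zeta * v + layer$phi * u
    if (is_scalp && !is.null(tau)) {
      if (tau_scope == "all") bracket <- (1 + tau) * bracket
      else bracket <- (1 + tau) * layer$alpha * a + layer$beta * b +
          layer$gamma * m + layer$zeta * v + layer$phi * u
    }
    layer$baseline + bracket
  })
}

#' Mix layer traces into the dual-channel measurement
#'
#' The near (short-separation) channel sees the three superficial layers; the
#' far (long-separation) channel sees them plus the gray-matter layer.  White
#' matter is simulated but enters neither channel.  Independent seeded Gaussian
#' noise is added per channel.  The stored ground truth is the gray-matter
#' fluctuation as it appears in the far channel, `k3 * (C4 - baseline4)`.
#'
#' @param layer_traces List of five equal-length concentration traces in the
#'   order scalp, skull, csf, gray, white.
#' @param config A [sim_config()].
#' @return An object of class `dual_recording` with elements `time`, `y_near`,
#'   `y_far`, `truth_bfa`, `components` (n x 5 matrix), `sampling_rate`,
#'   `config`.
#' @export
mix_channels <- function(layer_traces, config) {
  if (length(layer_traces) != 5) stop_data("five layer traces required")
  lens <- vapply(layer_traces, length, integer(1))
  if (length(unique(lens)) != 1) stop_data("layer traces must share one length")
  n <- lens[1]
  eps <- with_seed(config$seed + 2L,
                   list(e1 = rnorm(n, sd = config$noise_sd),
                        e2 = rnorm(n, sd = config$noise_sd)))
  sys <- layer_traces[[1]] + layer_traces[[2]] + layer_traces[[3]]
  base4 <- config$layers[[4]]$baseline
  y_near <- config$k1 * sys + eps$e1
  y_far <- config$k2 * sys + config$k3 * layer_traces[[4]] + eps$e2
  comp <- do.call(cbind, layer_traces)
  colnames(comp) <- c("C1", "C2", "C3", "C4", "C5")
  structure(list(time = seq_len(n) / config$sampling_rate,
                 y_near = y_near, y_far = y_far,
                 truth_bfa = config$k3 * (layer_traces[[4]] - base4),
                 components = comp,
                 sampling_rate = config$sampling_rate,
                 config = config),
            class = "dual_recording")
}

#' Set the far-channel signal-to-noise ratio
#'
#' Rescales the gray-matter component of the far channel so that
#' `var(truth) / var(far - truth)` equals `target_snr` exactly, where the
#' interference term collects the superficial layers and the measurement
#' noise.  The stored ground truth and gray-matter component are updated
#' consistently.  The operation is idempotent.
#'
#' @param recording A simulated `dual_recording` (must carry ground truth).
#' @param target_snr Positive variance ratio.
#' @return The rescaled `dual_recording`.
#' @export
set_snr <- function(recording, target_snr) {
  if (is.null(recording$truth_bfa)) stop_data("recording has no ground truth")
  if (target_snr <= 0) stop_config("target_snr must be > 0")
  interference <- recording$y_far - recording$truth_bfa
  v_int <- var(interference)
  if (v_int == 0) stop_data("interference variance is zero; cannot scale")
  v_tru <- var(recording$truth_bfa)
  if (v_tru == 0) stop_data("ground-truth variance is zero; cannot scale")
  s <- sqrt(target_snr / (v_tru / v_int))
  recording$truth_bfa <- s * recording$truth_bfa
  recording$y_far <- interference + recording$truth_bfa
  if (!is.null(recording$components)) {
    base4 <- recording$config$layers[[4]]$baseline
    recording$components[, "C4"] <-
      base4 + s * (recording$components[, "C4"] - base4)
  }
  recording$snr <- target_snr
  recording
}

#' Simulate one dual-channel fNIRS recording
#'
#' Runs the full generative model: seeded oscillation phases, scalp drift,
#' evoked response, five layer concentrations, channel mixing with noise, and
#' (when `config$snr` is set) exact SNR adjustment of the far channel.
#'
#' @param config A [sim_config()].
#' @return A `dual_recording`; see [mix_channels()].
#' @examples
#' rec <- simulate_recording(sim_config(seed = 7, snr = 1))
#' range(rec$time)
#' @export
simulate_recording <- function(config = sim_config()) {
  osc <- make_oscillations(config)
  tau <- make_scalp_drift(config$protocol$total_duration, config$sampling_rate,
                          seed = config$seed + 1L, sd = config$tau_sd)
  u <- make_evoked(config$protocol, config$sampling_rate)
  components <- c(osc, list(u = u))
  traces <- lapply(seq_along(config$layers), function(i)
    layer_concentration(config$layers[[i]], components,
                        tau = if (i == 1) tau else NULL,
                        is_scalp = (i == 1), tau_scope = config$tau_scope))
  rec <- mix_channels(traces, config)
  rec$evoked <- u
  if (!is.null(config$snr)) rec <- set_snr(rec, config$snr)
  rec
}

#' @export
print.dual_recording <- function(x, ...) {
  cat("Dual-channel fNIRS recording\n")
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n", length(x$y_near),
              x$sampling_rate, length(x$y_near) / x$sampling_rate))
  cat(sprintf("  ground truth: %s\n",
              if (is.null(x$truth_bfa)) "absent (measured data)" else "present"))
  if (!is.null(x$snr)) cat(sprintf("  far-channel SNR: %g\n", x$snr))
  invisible(x)
}

#' Write a recording to a comma-separated file
#'
#' Columns `time, y_near, y_far` plus, for simulated data, `truth_bfa` and the
#' per-layer traces `C1..C5`.  The generating configuration is echoed to a JSON
#' sidecar `<path>.json`.
#'
#' @param recording A `dual_recording`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON configuration echo?
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, sidecar = TRUE) {
  df <- data.frame(time = recording$time, y_near = recording$y_near,
                   y_far = recording$y_far)
  if (!is.null(recording$truth_bfa)) df$truth_bfa <- recording$truth_bfa
  if (!is.null(recording$components)) df <- cbind(df, recording$components)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (sidecar && !is.null(recording$config)) {
    cfg <- recording$config
    cfg$layers <- lapply(cfg$layers, unclass)
    cfg$protocol <- unclass(cfg$protocol)
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a recording from a comma-separated file
#'
#' Expects at least `time, y_near, y_far` columns (header row); `truth_bfa`
#' and `C1..C5` are picked up when present, so both measured exports and
#' [write_recording()] output round-trip.
#'
#' @param path CSV path.
#' @return A `dual_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_data("recording file not found: ", path)
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("time", "y_near", "y_far")
  if (!all(need %in% names(df)))
    stop_data("recording file must have columns time, y_near, y_far")
  dt <- diff(df$time)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)))
    stop_data("time column must increase at a fixed sampling interval")
  fs <- if (length(dt)) 1 / mean(dt) else NA_real_
  comp <- intersect(paste0("C", 1:5), names(df))
  structure(list(time = df$time, y_near = df$y_near, y_far = df$y_far,
                 truth_bfa = df$truth_bfa,
                 components = if (length(comp) == 5) as.matrix(df[comp]) else NULL,
                 sampling_rate = fs, config = NULL),
            class = "dual_recording")
}
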