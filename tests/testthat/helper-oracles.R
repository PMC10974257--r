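# Independent oracles used across the suite.

# Brute-force sample entropy: plain R double loop over template pairs,
# Chebyshev distance, self-matches excluded.  Deliberately naive.
brute_sampen <- function(x, m = 1, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in seq.int(i + 1, nt)) {
      d <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (d <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

# FFT-peak oracle: frequency (Hz) of the dominant periodogram bin.
fft_peak_freq <- function(x, fs) {
  n <- length(x)
  X <- Mod(fft(x - mean(x)))^2
  half <- X[seq_len(floor(n / 2) + 1)]
  (which.max(half[-1])) / n * fs   # skip DC bin
}

# Relative L2 reconstruction error.
rel_l2 <- function(est, ref) sqrt(sum((est - ref)^2) / sum(ref^2))

# Small two-tone test signal shared by VMD/tuning tests.
two_tone <- function(f1 = 0.1, f2 = 1.2, fs = 10, dur = 200) {
  t <- seq_len(dur * fs) / fs
  sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t)
}

# A fast simulation config for pipeline tests: short record, fixed VMD.
quick_sim <- function(seed = 1, snr = NULL, duration = 120)
  sim_config(seed = seed, snr = snr,
             protocol = stimulus_protocol(total_duration = duration,
                                          block_onsets = seq(20, duration - 20,
                                                             by = 40),
                                          block_duration = 20))

quick_extraction <- function(...)
  extraction_config(tuner = "fixed", vmd = vmd_config(K = 8, alpha = 1500), ...)
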