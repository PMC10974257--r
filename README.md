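# fnirsduo — dual-detector fNIRS brain-signal extraction

Functional near-infrared spectroscopy (fNIRS) reads cortical activity
through the scalp, so a long-separation (~3 cm) source–detector channel
mixes the gray-matter hemodynamic response with much larger superficial
physiology: cardiac pulsation (~1.2 Hz), respiration (~0.25 Hz), Mayer
waves (~0.1 Hz), ultra-slow oscillations (~0.04 Hz) and scalp drift.
`fnirsduo` is for researchers who record with a dual-detector layout — a
short-separation (~1 cm) channel that sees only the superficial layers next
to the long channel — and want the cortical signal with that interference
cancelled, plus the simulation machinery to validate the whole procedure
against ground truth.

## The method

The channels are modelled as

```
y_near(t) = k1 * y_sys(t) + e1(t)
y_far(t)  = k2 * y_sys(t) + k3 * y_BFA(t) + e2(t)
```

with `y_sys` the shared superficial physiology and `y_BFA` the gray-matter
signal.  `extract_bfa()` recovers `k3 * y_BFA(t)`:

1. zero-phase 4th-order Butterworth band-pass (0.01–2 Hz) on both channels;
2. variational mode decomposition (VMD) of each channel, with the mode
   count `K` (4–10) and bandwidth penalty `alpha` (500–2500) chosen per
   channel by a genetic algorithm minimizing the sample entropy
   `S(m, r) = -ln(A_m(r) / B_m(r))` of the smoothest mode (an exhaustive
   grid scan is available as a deterministic fallback);
3. modes pooled into low- (< 0.06 Hz) and high-frequency band sums;
4. per band: `mix = k_const * near + far` (`k_const = 50`), normalize
   `mix` and `near`, subtract, rescale by the mix's normalization scale —
   the amplified near term pins the normalization to the superficial
   waveform, so the subtraction cancels it and the rescaling restores the
   gray-matter residual to physical amplitude;
5. sum the two recovered bands.

The package also provides the five-layer hemodynamic simulator with exact
SNR control (`simulate_recording()`, `set_snr()`), RLS / fast-ICA /
EEMD-RLS baselines, R / RMSE / MAE / CNR metrics, modified Beer–Lambert
conversion of dual-wavelength (735/850 nm) intensities (`mbll()`), a
seeded benchmark harness (`run_benchmark()`), and a command-line launcher
(`inst/exec/fnirsduo`).

## Worked example

```r
library(fnirsduo)

# simulate one ground-truthed recording: 200 s at 10 Hz, five 20 s blocks,
# far-channel SNR forced to 1
rec <- simulate_recording(sim_config(seed = 101, snr = 1))
res <- extract_bfa(rec$y_near, rec$y_far, extraction_config(), 10)
res
#> Dual-channel extraction result
#>   2000 samples at 10 Hz
#>   near channel: K = 9, alpha = 2500; far channel: K = 8, alpha = 710

truth <- bandpass_filter(rec$truth_bfa, 10)
compare_traces(res$bfa, truth)
#> R = 0.97764, RMSE = 0.13054, MAE = 0.10798 (n = 2000)
```

`compare_traces()` scores on mean-removed, max-abs-normalized traces: here
the recovered trace correlates at R = 0.978 with the true gray-matter
signal, while the raw far channel is dominated by interference (the same
seed gives R = 0.767 for `y_far` itself).  Across 20 seeds the benchmark
(`run_benchmark(benchmark_spec())`) gives mean R ≈ 0.984 at SNR 1 against
≈ 0.89 for the RLS baseline.

From the shell:

```sh
Rscript inst/exec/fnirsduo simulate --out rec.csv
Rscript inst/exec/fnirsduo extract --input rec.csv --out ext.csv
Rscript inst/exec/fnirsduo evaluate --input rec.csv --out cnr.csv
```

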