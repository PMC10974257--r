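test_that("sample entropy matches the brute-force counter to 1e-12", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(40:80, 1)
    x <- rnorm(n)
    m <- sample(1:2, 1)
    r <- 0.2 * sd(x)
    expect_equal(suppressWarnings(sample_entropy(x, sampen_config(m = m), r = r)),
                 brute_sampen(x, m, r), tolerance = 1e-12)
  }
})

test_that("sample entropy identities and invariances hold", {
  expect_identical(sample_entropy(rep(3.2, 60)), 0)
  # noise is strictly more irregular than a sine of the same length
  set.seed(5)
  noise <- rnorm(1000)
  tone <- sin(2 * pi * 0.02 * seq_len(1000))
  expect_gt(sample_entropy(noise), sample_entropy(tone))
  # scale invariance when r follows the series sd
  x <- rnorm(300)
  expect_equal(sample_entropy(x), sample_entropy(100 * x), tolerance = 1e-12)
  expect_error(sample_entropy(1:2), class = "fnirsduo_data_error")
  expect_error(sampen_config(r_factor = 0.5), class = "fnirsduo_config_error")
})

test_that("trend-mode fitness is deterministic and favours full decomposition", {
  x <- two_tone(0.05, 1.2, dur = 100)
  f1 <- vmd_fitness(x, 1, 1500, sampling_rate = 10)
  f2 <- vmd_fitness(x, 2, 1500, sampling_rate = 10)
  expect_identical(f2, vmd_fitness(x, 2, 1500, sampling_rate = 10))
  # under-decomposition mixes the fast tone into the trend, raising entropy
  expect_lte(f2, f1)
  # pure slow tone: fitness is close to the tone's own entropy for any K
  slow <- sin(2 * pi * 0.05 * seq_len(1000) / 10)
  expect_lt(vmd_fitness(slow, 3, 1500, sampling_rate = 10),
            sample_entropy(slow) + 0.05)
  # failures surface as worst-possible fitness
  expect_identical(vmd_fitness(rnorm(1000), 300, 1500, sampling_rate = 10), Inf)
})

test_that("genetic search is seeded, bounded and beats a coarse baseline", {
  x <- two_tone(dur = 80)
  ga <- ga_config(pop_size = 8, generations = 4, seed = 3)
  a <- ga_optimize(x, ga, sampling_rate = 10)
  b <- ga_optimize(x, ga, sampling_rate = 10)
  expect_identical(a[c("K", "alpha", "fitness")], b[c("K", "alpha", "fitness")])
  expect_true(a$K >= 4 && a$K <= 10)
  expect_true(a$alpha >= 500 && a$alpha <= 2500)
  # elitism: best-so-far trace never increases
  expect_true(all(diff(a$trace) <= 0))
  # exhaustive grid oracle: a full-budget GA gets within 5% of the global
  # grid minimum on the canonical 200 s two-tone signal
  xl <- two_tone()
  g <- grid_optimize(xl, 4:10, seq(500, 2500, length.out = 9),
                     sampling_rate = 10)
  full <- ga_optimize(xl, ga_config(seed = 3), sampling_rate = 10)
  expect_lte(full$fitness, g$fitness * 1.05 + 1e-12)
  expect_equal(g$n_evals, 63)
})

test_that("collapsed bounds return the single candidate point", {
  x <- two_tone(dur = 60)
  ga <- ga_config(pop_size = 4, generations = 1, k_bounds = c(5, 5),
                  alpha_bounds = c(1200, 1200), seed = 1)
  res <- ga_optimize(x, ga, sampling_rate = 10)
  expect_identical(res$K, 5L)
  expect_equal(res$alpha, 1200)
  g <- grid_optimize(x, 5, 1200, sampling_rate = 10)
  expect_equal(res$fitness, g$fitness)
  expect_error(grid_optimize(x, integer(0), 1000),
               class = "fnirsduo_config_error")
})
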