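#' Sample entropy settings
#'
#' @param m Template length (embedding dimension).  The default 1 follows the
#'   convention for slow hemodynamic records; 2 is the wider time-series
#'   convention and is accepted.
#' @param r_factor Match threshold as a multiple of the series' standard
#'   deviation; must lie in `[0.1, 0.25]`.
#' @return An object of class `sampen_config`.
#' @export
sampen_config <- function(m = 1, r_factor = 0.2) {
  if (m < 1 || m != round(m)) stop_config("m must be a positive integer")
  if (r_factor < 0.1 || r_factor > 0.25)
    stop_config("r_factor must lie in [0.1, 0.25]")
  structure(list(m = as.integer(m), r_factor = r_factor),
            class = "sampen_config")
}

#' Sample entropy of a time series
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within Chebyshev
#' distance `r` of each other (self-matches excluded) and `A` the same pairs
#' still matching at length `m + 1`.  Larger values indicate a more irregular
#' series; a constant series returns exactly 0 (every template matches).  When
#' no pair matches at length `m + 1`, `Inf` is returned with a warning.
#'
#' @param x Numeric vector, length > `m + 1`.
#' @param config A [sampen_config()].
#' @param r Absolute threshold; defaults to `r_factor * sd(x)`.
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' sample_entropy(rep(1, 50))                      # 0
#' sample_entropy(sin(seq(0, 20, by = 0.1)))
#' @export
sample_entropy <- function(x, config = sampen_config(), r = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_data("series contains non-finite values")
  if (length(x) <= config$m + 1)
    stop_data("series too short for sample entropy (need length > m + 1)")
  if (is.null(r)) r <- config$r_factor * sd(x)
  counts <- sampen_counts(x, config$m, r)
  A <- counts[1]; B <- counts[2]
  if (B == 0) {
    warning("no template matches at length m; sample entropy undefined")
    return(Inf)
  }
  if (A == 0) {
    warning("no template matches at length m + 1; returning Inf")
    return(Inf)
  }
  -log(A / B)
}

#' VMD trend-mode fitness
#'
#' Decomposes the signal with the given `(K, alpha)` and returns the minimum
#' sample entropy across modes — the trend mode's value, since the smoothest
#' mode has the lowest entropy.  Under-decomposition mixes interference into
#' the trend and raises this number, which is what the tuner minimizes.
#' Decomposition failures propagate as `Inf` so a search can continue.
#'
#' @param signal Numeric vector.
#' @param K,alpha Candidate decomposition parameters.
#' @param sampen A [sampen_config()].
#' @param vmd_template A [vmd_config()] supplying the remaining settings.
#' @param sampling_rate Sampling rate in Hz.
#' @return Scalar fitness (smaller is better; `Inf` on failure).
#' @export
vmd_fitness <- function(signal, K, alpha, sampen = sampen_config(),
                        vmd_template = vmd_config(), sampling_rate = 1) {
  cfg <- vmd_template
  cfg$K <- as.integer(K)
  cfg$alpha <- alpha
  ms <- tryCatch(vmd_decompose(signal, cfg, sampling_rate),
                 error = function(e) NULL)
  if (is.null(ms)) return(Inf)
  ent <- apply(ms$modes, 2, function(m) {
    if (sd(m) == 0) return(0)
    suppressWarnings(sample_entropy(m, sampen))
  })
  min(ent)
}

#' Genetic-algorithm settings for VMD tuning
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param crossover_prob,mutation_prob Per-individual crossover and per-gene
#'   mutation probabilities.
#' @param k_bounds Integer range for the mode count `K`.
#' @param alpha_bounds Range for the bandwidth penalty.
#' @param tournament Tournament size for selection.
#' @param seed Integer seed; the search is reproducible.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 12, generations = 10, crossover_prob = 0.8,
                      mutation_prob = 0.2, k_bounds = c(4, 10),
                      alpha_bounds = c(500, 2500), tournament = 3, seed = 1L) {
  if (pop_size < 2) stop_config("pop_size must be >= 2")
  if (generations < 1) stop_config("generations must be >= 1")
  if (any(c(crossover_prob, mutation_prob) < 0) ||
      any(c(crossover_prob, mutation_prob) > 1))
    stop_config("probabilities must lie in [0, 1]")
  if (length(k_bounds) != 2 || k_bounds[2] < k_bounds[1])
    stop_config("k_bounds must be a non-empty integer range")
  if (length(alpha_bounds) != 2 || alpha_bounds[2] < alpha_bounds[1])
    stop_config("alpha_bounds must be a non-empty range")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 k_bounds = as.integer(round(k_bounds)),
                 alpha_bounds = as.numeric(alpha_bounds),
                 tournament = as.integer(tournament),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Shared fitness evaluator with caching on (K, round(alpha)) so repeated
# visits to the same point do not re-run the decomposition.
make_fitness_cache <- function(signal, sampen, vmd_template, sampling_rate) {
  cache <- new.env(parent = emptyenv())
  function(K, alpha) {
    key <- sprintf("%d_%d", as.integer(K), as.integer(round(alpha)))
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- vmd_fitness(signal, K, alpha, sampen, vmd_template, sampling_rate)
    cache[[key]] <- f
    f
  }
}

#' Tune VMD parameters by genetic search
#'
#' Minimizes the trend-mode sample entropy over `(K, alpha)`: integer gene for
#' the mode count, real gene for the penalty, tournament selection, uniform
#' crossover, bounded Gaussian mutation and elitism of one.  Fitness values
#' are cached on `(K, round(alpha))`.
#'
#' @param signal Numeric vector to decompose.
#' @param ga A [ga_config()].
#' @param sampen A [sampen_config()].
#' @param vmd_template A [vmd_config()] supplying non-tuned settings.
#' @param sampling_rate Sampling rate in Hz.
#' @return List with `K`, `alpha`, `fitness`, `trace` (best fitness per
#'   generation, non-increasing) and `n_evals`.
#' @export
ga_optimize <- function(signal, ga = ga_config(), sampen = sampen_config(),
                        vmd_template = vmd_config(), sampling_rate = 1) {
  fit_fn <- make_fitness_cache(signal, sampen, vmd_template, sampling_rate)
  kb <- ga$k_bounds
  ab <- ga$alpha_bounds
  n_evals <- 0L
  eval_ind <- function(ind) {
    n_evals <<- n_evals + 1L
    fit_fn(ind[1], ind[2])
  }
  with_seed(ga$seed, {
    rand_k <- function() kb[1] + sample.int(kb[2] - kb[1] + 1L, 1L) - 1L
    pop <- replicate(ga$pop_size,
                     c(rand_k(), runif(1, ab[1], ab[2])),
                     simplify = FALSE)
    fits <- vapply(pop, eval_ind, numeric(1))
    best_i <- which.min(fits)
    best <- pop[[best_i]]
    best_fit <- fits[best_i]
    trace <- numeric(ga$generations)
    for (g in seq_len(ga$generations)) {
      select <- function() {
        idx <- sample(ga$pop_size, min(ga$tournament, ga$pop_size))
        pop[[idx[which.min(fits[idx])]]]
      }
      offspring <- vector("list", ga$pop_size)
      offspring[[1]] <- best                       # elitism
      for (i in seq.int(2, ga$pop_size)) {
        p1 <- select(); p2 <- select()
        child <- p1
        if (runif(1) < ga$crossover_prob) {
          swap <- runif(2) < 0.5
          child[swap] <- p2[swap]
        }
        # mutation mixes a local step with an occasional uniform restart so
        # the search can both refine and escape to the bound edges
        if (runif(1) < ga$mutation_prob)
          child[1] <- if (runif(1) < 0.5) rand_k()
                      else max(kb[1], min(kb[2],
                                          child[1] + sample(c(-2, -1, 1, 2), 1)))
        if (runif(1) < ga$mutation_prob)
          child[2] <- if (runif(1) < 0.5) runif(1, ab[1], ab[2])
                      else max(ab[1], min(ab[2],
                                          child[2] + rnorm(1, sd = 0.1 * diff(ab))))
        offspring[[i]] <- child
      }
      pop <- offspring
      fits <- vapply(pop, eval_ind, numeric(1))
      gen_i <- which.min(fits)
      if (fits[gen_i] < best_fit) {
        best <- pop[[gen_i]]
        best_fit <- fits[gen_i]
      }
      trace[g] <- best_fit
    }
    list(K = as.integer(best[1]), alpha = best[2], fitness = best_fit,
         trace = trace, n_evals = n_evals)
  })
}

#' Tune VMD parameters by exhaustive grid search
#'
#' Deterministic fallback to [ga_optimize()]: evaluates the trend-mode sample
#' entropy on the full `k_values` x `alpha_values` grid and returns the
#' minimizer.  Ties break toward the smaller `K`, then the smaller `alpha`.
#'
#' @param signal Numeric vector to decompose.
#' @param k_values Candidate mode counts.
#' @param alpha_values Candidate penalties.
#' @param sampen A [sampen_config()].
#' @param vmd_template A [vmd_config()].
#' @param sampling_rate Sampling rate in Hz.
#' @return List with `K`, `alpha`, `fitness`, `trace` (running best over the
#'   scan), `n_evals` and the full fitness `grid` (K x alpha matrix).
#' @export
grid_optimize <- function(signal, k_values = 4:10,
                          alpha_values = seq(500, 2500, by = 250),
                          sampen = sampen_config(),
                          vmd_template = vmd_config(), sampling_rate = 1) {
  if (!length(k_values) || !length(alpha_values))
    stop_config("k_values and alpha_values must be non-empty")
  fit_fn <- make_fitness_cache(signal, sampen, vmd_template, sampling_rate)
  grid <- matrix(NA_real_, length(k_values), length(alpha_values),
                 dimnames = list(k_values, alpha_values))
  for (i in seq_along(k_values))
    for (j in seq_along(alpha_values))
      grid[i, j] <- fit_fn(k_values[i], alpha_values[j])
  flat <- which(grid == min(grid), arr.ind = TRUE)[1, ]
  list(K = as.integer(k_values[flat[1]]), alpha = alpha_values[flat[2]],
       fitness = min(grid), trace = cummin(as.numeric(t(grid))),
       n_evals = length(grid), grid = grid)
}
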