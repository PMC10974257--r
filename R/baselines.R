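#' Recursive-least-squares filter settings
#'
#' @param order Number of filter taps.
#' @param forgetting Exponential forgetting factor in `(0, 1]`.
#' @param delta Initial inverse-correlation scale (P = delta * I).
#' @return An object of class `rls_config`.
#' @export
rls_config <- function(order = 8, forgetting = 0.99, delta = 100) {
  if (order < 1 || order != round(order))
    stop_config("order must be a positive integer")
  if (forgetting <= 0 || forgetting > 1)
    stop_config("forgetting factor must lie in (0, 1]")
  if (delta <= 0) stop_config("delta must be > 0")
  structure(list(order = as.integer(order), forgetting = forgetting,
                 delta = delta), class = "rls_config")
}

#' RLS adaptive interference cancellation
#'
#' Standard exponentially weighted recursive least squares: the tapped
#' reference (near) channel predicts the desired (far) channel and the
#' prediction error — the part of the far channel not explained by the
#' reference — is returned as the brain-signal estimate.  Deterministic.
#'
#' @param reference Reference channel (near/short-separation).
#' @param desired Desired channel (far/long-separation), same length.
#' @param config An [rls_config()].
#' @return Numeric error signal of the same length.
#' @export
rls_extract <- function(reference, desired, config = rls_config()) {
  reference <- as.numeric(reference); desired <- as.numeric(desired)
  if (length(reference) != length(desired)) stop_data("channel length mismatch")
  n <- length(desired)
  p <- config$order
  if (n <= p) stop_data("signal shorter than the filter order")
  if (sd(reference) == 0) stop_data("zero-variance reference (degenerate)")
  lam <- config$forgetting
  P <- diag(config$delta, p)
  w <- numeric(p)
  e <- numeric(n)
  xpad <- c(numeric(p - 1), reference)
  for (i in seq_len(n)) {
    x <- xpad[seq.int(i + p - 1, i)]     # current and past reference samples
    yhat <- sum(w * x)
    e[i] <- desired[i] - yhat            # a priori error
    Px <- P %*% x
    k <- Px / as.numeric(lam + crossprod(x, Px))
    w <- w + as.numeric(k) * e[i]
    P <- (P - k %*% crossprod(x, P)) / lam
  }
  e
}

#' Two-channel fast-ICA separation
#'
#' Symmetric fixed-point ICA with a `tanh` contrast on the two stacked
#' channels, after whitening.  With only two observed mixtures at most two
#' sources are separable, which is the documented limit of this baseline.  In
#' benchmark mode (`truth` supplied) the component and sign maximizing the
#' absolute correlation with the ground truth is selected — an oracle step
#' available only in simulation.
#'
#' @param near,far The two observed channels.
#' @param truth Optional ground truth for benchmark-mode selection.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param seed Seed for the random orthonormal initialization.
#' @return List with `sources` (2 x n matrix), `estimate` (selected source,
#'   `NULL` without `truth`), `converged`, and `flagged` (degenerate input).
#' @export
ica_extract <- function(near, far, truth = NULL, max_iter = 200, tol = 1e-8,
                        seed = 1L) {
  X <- rbind(as.numeric(near), as.numeric(far))
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / ncol(X)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[2] < 1e-12 * ev$values[1])
    return(list(sources = NULL, estimate = NULL, converged = FALSE,
                flagged = TRUE))
  Wh <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  Z <- Wh %*% X
  W <- with_seed(seed, {
    M <- matrix(rnorm(4), 2)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    W_new <- sym_decorrelate(W_new)
    if (max(abs(abs(diag(W_new %*% t(W))) - 1)) < tol) {
      W <- W_new; converged <- TRUE; break
    }
    W <- W_new
  }
  S <- W %*% Z
  est <- NULL
  if (!is.null(truth)) {
    cors <- apply(S, 1, function(s) cor(s, truth))
    pick <- which.max(abs(cors))
    est <- S[pick, ] * sign(cors[pick])
  }
  list(sources = S, estimate = est, converged = converged, flagged = FALSE)
}

# Cubic-spline envelope mean for one sifting pass.  The extrema are extended
# past both ends by reflection, the standard guard against envelope swing at
# the record boundaries.
envelope_mean <- function(x) {
  n <- length(x)
  d <- diff(x)
  idx <- which(d[-length(d)] * d[-1] < 0) + 1L
  maxima <- idx[x[idx] > x[idx - 1]]
  minima <- idx[x[idx] < x[idx - 1]]
  if (length(maxima) < 2 || length(minima) < 2) return(NULL)
  env <- function(pts) {
    k <- length(pts)
    xp <- c(2 - pts[2], 2 - pts[1],            # mirrored about sample 1
            pts,
            2 * n - pts[k], 2 * n - pts[k - 1])  # mirrored about sample n
    yp <- x[pts][c(2, 1, seq_len(k), k, k - 1)]
    keep <- !duplicated(xp)
    spline(xp[keep], yp[keep], xout = seq_len(n))$y
  }
  (env(maxima) + env(minima)) / 2
}

#' Empirical mode decomposition by envelope sifting
#'
#' Classic sifting: each intrinsic mode function is refined until the
#' standard-deviation criterion between successive siftings drops below
#' `sd_tol` or `max_sift` passes are reached; decomposition stops when the
#' residue has fewer than two maxima or minima, or at `max_imf` modes.
#'
#' @param x Numeric vector.
#' @param max_imf Maximum number of modes.
#' @param sd_tol Sifting stop criterion.
#' @param max_sift Maximum sifting passes per mode.
#' @return List with `imfs` (n x K matrix, possibly K = 0) and `residue`.
#' @export
emd <- function(x, max_imf = 8, sd_tol = 0.2, max_sift = 10) {
  x <- as.numeric(x)
  res <- x
  imfs <- list()
  for (k in seq_len(max_imf)) {
    h <- res
    em <- envelope_mean(h)
    if (is.null(em)) break
    for (s in seq_len(max_sift)) {
      h_new <- h - em
      sd_crit <- sum((h - h_new)^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      em <- envelope_mean(h)
      if (is.null(em) || sd_crit <= sd_tol) break
    }
    imfs[[k]] <- h
    res <- res - h
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs)
       else matrix(numeric(0), length(x), 0),
       residue = res)
}

#' Ensemble empirical mode decomposition
#'
#' Averages the modes of noise-perturbed decompositions, aligned by mode
#' index and padded to a common count.  `ensemble_size = 1` with
#' `noise_sd = 0` reduces to plain [emd()].
#'
#' @param x Numeric vector.
#' @param ensemble_size Number of noise-perturbed decompositions.
#' @param noise_sd Added-noise level as a fraction of the signal sd.
#' @param seed Ensemble noise seed.
#' @param max_imf Maximum number of modes.
#' @param ... Passed to [emd()].
#' @return List with `imfs` (n x K matrix) and `residue`.
#' @export
eemd <- function(x, ensemble_size = 50, noise_sd = 0.2, seed = 1L,
                 max_imf = 8, ...) {
  sdx <- sd(x)
  noise_scale <- noise_sd * if (sdx > 0) sdx else 1
  n <- length(x)
  acc <- matrix(0, n, max_imf)
  res_acc <- numeric(n)
  counts <- integer(max_imf)
  with_seed(seed, {
    for (e in seq_len(ensemble_size)) {
      xe <- if (ensemble_size == 1 && noise_sd == 0) x
            else x + rnorm(n, sd = noise_scale)
      de <- emd(xe, max_imf = max_imf, ...)
      K <- ncol(de$imfs)
      if (K > 0) {
        acc[, seq_len(K)] <- acc[, seq_len(K)] + de$imfs
        counts[seq_len(K)] <- counts[seq_len(K)] + 1L
      }
      res_acc <- res_acc + de$residue
    }
  })
  keep <- counts > 0
  imfs <- acc[, keep, drop = FALSE]
  for (k in seq_len(ncol(imfs))) imfs[, k] <- imfs[, k] / counts[keep][k]
  list(imfs = imfs, residue = res_acc / ensemble_size)
}

#' EEMD-RLS interference cancellation
#'
#' Ensemble empirical mode decomposition of both channels followed by RLS
#' cancellation per matched mode order (near-channel mode as reference,
#' far-channel mode as desired), with the per-mode error signals and the
#' far residue summed into the estimate.  Mode lists are aligned by index and
#' the shorter list padded with zero modes — a documented simplification of
#' the full cross-matching.  `ensemble_size = 1` with `noise_sd = 0` reduces
#' to plain EMD-RLS.
#'
#' @param near,far The two observed channels.
#' @param ensemble_size Number of noise-perturbed decompositions.
#' @param noise_sd Added-noise level as a fraction of the channel sd.
#' @param config An [rls_config()].
#' @param seed Ensemble noise seed.
#' @param max_imf Maximum number of modes per channel.
#' @return Numeric brain-signal estimate.
#' @export
eemd_rls_extract <- function(near, far, ensemble_size = 50, noise_sd = 0.2,
                             config = rls_config(), seed = 1L, max_imf = 8) {
  near <- as.numeric(near); far <- as.numeric(far)
  if (length(near) != length(far)) stop_data("channel length mismatch")
  dn <- eemd(near, ensemble_size, noise_sd, seed = seed, max_imf = max_imf)
  df <- eemd(far, ensemble_size, noise_sd, seed = seed + 1L, max_imf = max_imf)
  K <- max(ncol(dn$imfs), ncol(df$imfs))
  get_mode <- function(d, k)
    if (k <= ncol(d$imfs)) d$imfs[, k] else numeric(length(near))
  est <- numeric(length(near))
  for (k in seq_len(K)) {
    ref <- get_mode(dn, k)
    des <- get_mode(df, k)
    est <- est + if (sd(ref) == 0) des else rls_extract(ref, des, config)
  }
  est + df$residue - mean(df$residue)
}
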