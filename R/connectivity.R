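#' Canonical frequency bands
#' @return Named list of numeric length-2 band edges in Hz.
#' @export
band_definitions <- function() {
  list(theta = c(4, 8), alpha = c(8, 12))
}

#' Density grid for proportional thresholding
#'
#' @param min,max Range of densities (defaults 0.1-0.6).
#' @param n Number of grid points (default 20).
#' @return Strictly increasing numeric vector of length `n`.
#' @export
density_grid <- function(min = 0.1, max = 0.6, n = 20) {
  stopifnot(min > 0, max <= 1, min < max, n >= 1)
  seq(min, max, length.out = n)
}

#' Band-limited power envelope of an epoched series
#'
#' Band-pass filters each trial/ROI to the requested band and takes the
#' squared modulus of the analytic signal (instantaneous power).
#'
#' @param series An `epoched_series`.
#' @param band Numeric length-2 band edges in Hz, or a name in
#'   [band_definitions()].
#' @param order Band-pass filter order.
#' @return trial x ROI x sample array of power envelopes.
#' @export
band_envelope <- function(series, band, order = 4) {
  stopifnot(inherits(series, "epoched_series"))
  if (is.character(band)) band <- band_definitions()[[band]]
  if (is.null(band) || length(band) != 2)
    stop("band must be a length-2 numeric range or a known band name")
  if (band[1] <= 0 || band[2] >= series$fs / 2)
    stop("band (", band[1], "-", band[2], " Hz) outside (0, Nyquist)")
  d <- series$data
  env <- array(0, dim = dim(d))
  bf <- signal::butter(order, band / (series$fs / 2), type = "pass")
  for (tr in seq_len(dim(d)[1])) {
    for (i in seq_len(dim(d)[2])) {
      x <- as.numeric(signal::filtfilt(bf, d[tr, i, ]))
      env[tr, i, ] <- Mod(analytic_signal(x))^2
    }
  }
  env
}

#' Envelope (power) cross-correlation connectivity matrix
#'
#' Pearson correlation of power envelopes over a window's samples. With
#' `pool_trials = TRUE` the per-trial demeaned samples are concatenated before
#' a single correlation (recommended for short 50-ms subwindows); otherwise
#' per-trial correlations are averaged across trials after Fisher
#' z-transform and back-transformed. The absolute value is taken and the
#' diagonal zeroed.
#'
#' @param env trial x ROI x sample envelope array (a window block).
#' @param pool_trials Logical; see Details.
#' @return Symmetric ROI x ROI matrix with zero diagonal, entries in `[0, 1]`.
#' @export
envelope_correlation_matrix <- function(env, pool_trials = TRUE) {
  stopifnot(length(dim(env)) == 3)
  n_trials <- dim(env)[1]; N <- dim(env)[2]; n_samp <- dim(env)[3]
  if (n_samp < 3) stop("window must contain at least 3 samples")
  if (pool_trials) {
    # demean per trial so between-trial offsets do not inflate correlations
    X <- matrix(0, n_trials * n_samp, N)
    for (tr in seq_len(n_trials)) {
      block <- t(env[tr, , , drop = TRUE])
      if (N == 1) block <- matrix(env[tr, 1, ], ncol = 1)
      block <- sweep(block, 2, colMeans(block))
      X[((tr - 1) * n_samp + 1):(tr * n_samp), ] <- block
    }
    W <- safe_cor(X)
  } else {
    Z <- matrix(0, N, N)
    nz <- matrix(0, N, N)
    for (tr in seq_len(n_trials)) {
      R <- safe_cor(t(matrix(env[tr, , ], N, n_samp)))
      # Fisher z; clip perfect correlations to keep z finite
      Rc <- pmin(pmax(R, -1 + 1e-12), 1 - 1e-12)
      z <- atanh(Rc)
      ok <- !is.na(R)
      Z[ok] <- Z[ok] + z[ok]
      nz <- nz + ok
    }
    W <- tanh(Z / pmax(nz, 1))
    W[nz == 0] <- 0
  }
  W <- abs(W)
  diag(W) <- 0
  (W + t(W)) / 2
}

# correlation with zero-variance columns mapped to 0 edges + warning
safe_cor <- function(X) {
  sds <- apply(X, 2, stats::sd)
  zv <- !is.finite(sds) | sds == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance envelope(s) in window; their edges set to 0")
    X[, zv] <- stats::rnorm(nrow(X) * sum(zv)) # placeholder, zeroed below
  }
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  if (any(zv)) { R[zv, ] <- 0; R[, zv] <- 0 }
  R
}

#' Proportional density threshold
#'
#' Keeps the `ceiling(density * N(N-1)/2)` largest-weight edges of the upper
#' triangle and returns the symmetric binary adjacency. Ties crossing the cut
#' are broken by (row, column) lexicographic order, so edge sets are exactly
#' nested across densities.
#'
#' @param W Symmetric weighted matrix (diagonal ignored).
#' @param density Target edge density in `(0, 1]`.
#' @return Binary symmetric matrix with zero diagonal.
#' @export
proportional_threshold <- function(W, density) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  N <- nrow(W)
  iu <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[iu]
  k <- ceiling(density * N * (N - 1) / 2)
  ord <- order(-w, iu[, 1], iu[, 2])
  keep <- ord[seq_len(min(k, length(ord)))]
  A <- matrix(0L, N, N)
  A[iu[keep, , drop = FALSE]] <- 1L
  A + t(A)
}
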