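#' Fit a time-varying MVAR model by dual Kalman filtering
#'
#' Two coupled Kalman recursions estimate, per sample, the lag-coefficient
#' matrices of a multivariate autoregressive model: a state filter for the
#' signals (companion-form transition built from the current coefficients) and
#' a weight filter for the vectorized coefficients with random-walk dynamics
#' (process-noise scale `q`). The innovation covariance is adapted online.
#' Coefficient estimates within the burn-in (first `5 * order` samples after
#' the initial lags) should be treated as transient.
#'
#' @param X Numeric samples x channels matrix.
#' @param order Model order p (>= 1).
#' @param q Random-walk process-noise scale of the weight filter; larger
#'   values track faster changes at the cost of noisier estimates.
#' @param init_scale Initial weight-covariance scale.
#' @param r_obs State-filter observation-noise variance.
#' @param lambda Adaptation rate of the innovation-covariance estimate.
#' @param smooth Width (samples, odd) of a centred moving average applied to
#'   the coefficient trajectories; suppresses the random-walk estimation
#'   wander (which otherwise folds into a positive bias when the
#'   magnitude-based coherence is computed) at the cost of `smooth/2` samples
#'   of tracking lag. Set 1 to disable.
#' @param fs Sampling rate (stored for spectral evaluation).
#' @return A `tvmvar_model`: `A` (sample x lag x N x N array), `sigma`
#'   (innovation covariance), `innov`, `order`, `fs`, `burn_in`,
#'   `stable` (companion spectral radius < 1 at the final sample).
#' @export
fit_dekf_mvar <- function(X, order = 5, q = 4e-5, init_scale = 1,
                          r_obs = 1e-2, lambda = 0.02, smooth = 101L,
                          fs = 250) {
  X <- as.matrix(X)
  n <- nrow(X); N <- ncol(X)
  if (order < 1) stop("order must be >= 1")
  if (n <= 10 * order + N)
    stop("series too short (", n, " samples) for order ", order,
         " with ", N, " channels")
  res <- dekf_cpp(X, as.integer(order), q, init_scale, r_obs, lambda)
  W <- res$W
  if (smooth > 1) {
    # centred moving average with shrinking windows at the edges
    valid <- (order + 1):n
    h <- smooth %/% 2
    cs <- apply(W[valid, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    nv <- length(valid)
    lo <- pmax(seq_len(nv) - h, 1L); hi <- pmin(seq_len(nv) + h, nv)
    Wsm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
    W[valid, ] <- Wsm
  }
  A <- array(W, dim = c(n, N, N, order))       # W rows are vec([A_1..A_p])
  A <- aperm(A, c(1, 4, 2, 3))                  # sample x lag x N x N
  burn_in <- 5L * order
  Afin <- lapply(seq_len(order), function(r) A[n, r, , , drop = TRUE])
  Afin <- lapply(Afin, function(m) matrix(m, N, N))
  rho <- companion_spectral_radius(Afin)
  structure(list(A = A, sigma = res$sigma, innov = res$innov,
                 order = as.integer(order), fs = fs, burn_in = burn_in,
                 n_samples = n, n_channels = N, stable = rho < 1),
            class = "tvmvar_model")
}

#' Ordinary-least-squares stationary MVAR fit
#'
#' Multivariate regression of each sample on its p lags; the stationary
#' reference estimator against which the time-varying filter can be checked.
#'
#' @param X Samples x channels matrix.
#' @param order Lag order.
#' @return List: `A` (list of p N x N lag matrices), `sigma` (residual
#'   covariance), `order`.
#' @export
fit_mvar_ols <- function(X, order = 5) {
  X <- as.matrix(X)
  n <- nrow(X); N <- ncol(X)
  if (n <= order * N + order) stop("series too short for OLS MVAR fit")
  Y <- X[(order + 1):n, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(order), function(r)
    X[(order + 1 - r):(n - r), , drop = FALSE]))
  B <- solve(crossprod(Z), crossprod(Z, Y))     # (N*p) x N
  E <- Y - Z %*% B
  A <- lapply(seq_len(order), function(r)
    t(B[((r - 1) * N + 1):(r * N), , drop = FALSE]))
  list(A = A, sigma = crossprod(E) / (nrow(Y) - order * N), order = order)
}

#' Select an MVAR order by information criterion
#'
#' @param X Samples x channels matrix.
#' @param orders Candidate orders.
#' @param criterion "bic" (default) or "aic".
#' @return The selected order.
#' @export
select_order <- function(X, orders = 1:10, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- nrow(X); N <- ncol(X)
  ic <- vapply(orders, function(p) {
    fit <- fit_mvar_ols(X, p)
    neff <- n - p
    ld <- determinant(fit$sigma, logarithm = TRUE)$modulus
    k <- p * N^2
    as.numeric(ld) + (if (criterion == "bic") log(neff) * k / neff
                      else 2 * k / neff)
  }, numeric(1))
  orders[which.min(ic)]
}

# Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs); pdc[i, j] = |Abar_ij| / ||Abar_.j||
pdc_from_lag_matrices <- function(A_list, freqs, fs) {
  N <- nrow(A_list[[1]]); p <- length(A_list)
  out <- array(0, dim = c(N, N, length(freqs)))
  for (fi in seq_along(freqs)) {
    ph <- exp(-1i * 2 * pi * freqs[fi] * seq_len(p) / fs)
    Ab <- diag(N) + 0i
    for (r in seq_len(p)) Ab <- Ab - A_list[[r]] * ph[r]
    mag <- Mod(Ab)
    cn <- sqrt(colSums(mag^2))
    out[, , fi] <- sweep(mag, 2, cn, "/")
  }
  out
}

#' Time-resolved partial directed coherence from a fitted model
#'
#' Evaluates Abar(f, t) = I - sum_r A_r(t) exp(-i 2 pi f r / fs) and the
#' partial directed coherence pi_ij(f, t) = |Abar_ij| / sqrt(sum_k
#' |Abar_kj|^2). Entry `[i, j, f, t]` quantifies the directed influence of
#' source channel j on target channel i; squares sum to 1 over targets i for
#' every (source j, f, t) by construction.
#'
#' @param model A `tvmvar_model` from [fit_dekf_mvar()].
#' @param freqs Frequencies (Hz), inside (0, fs/2).
#' @param times Sample indices at which to evaluate (default: every sample
#'   after burn-in).
#' @return A `tpdc_result`: `values` (target x source x freq x time array),
#'   `freqs`, `times`, `fs`.
#' @export
tpdc_spectrum <- function(model, freqs = seq(2, 45, by = 0.5), times = NULL) {
  stopifnot(inherits(model, "tvmvar_model"))
  fs <- model$fs
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("freqs must lie in (0, fs/2)")
  n <- model$n_samples
  if (is.null(times))
    times <- seq(model$order + model$burn_in + 1L, n)
  N <- model$n_channels; p <- model$order
  TT <- length(times)
  # flatten coefficients: rows = times, cols = (target i, source j) within lag r
  A2 <- matrix(aperm(model$A[times, , , , drop = FALSE], c(1, 3, 4, 2)),
               TT, p * N * N)
  eye_flat <- as.numeric(diag(N))
  vals <- array(0, dim = c(N, N, length(freqs), TT))
  for (fi in seq_along(freqs)) {
    ph <- exp(-1i * 2 * pi * freqs[fi] * seq_len(p) / fs)
    Ab <- matrix(0 + 0i, TT, N * N)
    for (r in seq_len(p))
      Ab <- Ab + ph[r] * A2[, ((r - 1) * N * N + 1):(r * N * N), drop = FALSE]
    Ab <- matrix(eye_flat, TT, N * N, byrow = TRUE) - Ab
    mag2 <- Re(Ab)^2 + Im(Ab)^2
    # column norms per source j: flat column index = i + (j-1) N
    pi_flat <- sqrt(mag2)
    for (j in seq_len(N)) {
      cols <- ((j - 1) * N + 1):(j * N)
      nrm <- sqrt(rowSums(mag2[, cols, drop = FALSE]))
      pi_flat[, cols] <- pi_flat[, cols, drop = FALSE] / nrm
    }
    vals[, , fi, ] <- aperm(array(pi_flat, dim = c(TT, N, N)), c(2, 3, 1))
  }
  structure(list(values = vals, freqs = freqs, times = times, fs = fs),
            class = "tpdc_result")
}

#' Band-by-window summary of a TPDC array
#'
#' Mean partial directed coherence over a band's frequencies and a window's
#' time samples, per directed channel pair.
#'
#' @param tpdc A `tpdc_result`.
#' @param band Numeric length-2 frequency range (Hz) or a band name.
#' @param window_samples Integer sample indices (in the original series'
#'   indexing) defining the window; intersected with `tpdc$times`.
#' @return Data frame `source`, `target`, `value`.
#' @export
band_window_summary <- function(tpdc, band, window_samples = NULL) {
  stopifnot(inherits(tpdc, "tpdc_result"))
  if (is.character(band)) band <- band_definitions()[[band]]
  fsel <- which(tpdc$freqs >= band[1] & tpdc$freqs <= band[2])
  tsel <- if (is.null(window_samples)) seq_along(tpdc$times)
    else which(tpdc$times %in% window_samples)
  if (length(fsel) == 0 || length(tsel) == 0)
    stop("empty band/window intersection with the computed TPDC grid")
  N <- dim(tpdc$values)[1]
  M <- apply(tpdc$values[, , fsel, tsel, drop = FALSE], c(1, 2), mean)
  idx <- which(row(M) != col(M), arr.ind = TRUE)
  data.frame(source = idx[, 2], target = idx[, 1],
             value = M[idx])
}

# mean off-diagonal TPDC per directed pair for one series (samples x N);
# returns an N x N matrix S with S[i, j] = influence j -> i (diag = 0)
tpdc_pair_statistic <- function(X, order, freqs, fs, band = NULL, q = 4e-5,
                                max_times = 100L) {
  model <- fit_dekf_mvar(X, order = order, q = q, fs = fs)
  t0 <- model$order + model$burn_in + 1L
  times <- unique(round(seq(t0, model$n_samples,
                            length.out = min(max_times, model$n_samples - t0 + 1L))))
  tp <- tpdc_spectrum(model, freqs = freqs, times = times)
  if (is.null(band)) band <- range(freqs)
  fsel <- which(freqs >= band[1] & freqs <= band[2])
  S <- apply(tp$values[, , fsel, , drop = FALSE], c(1, 2), mean)
  diag(S) <- 0
  S
}

#' Time-reversal surrogate test for directed influence
#'
#' Time reversal destroys directed temporal structure while preserving power
#' spectra, so band-averaged TPDC recomputed on reversed data provides a null
#' for each directed pair. With multiple trials, each surrogate reverses the
#' trials and resamples them with replacement; with a single trial, each
#' surrogate applies an independent random circular shift per channel to the
#' reversed series to obtain distinct null draws. A directed pair is
#' significant when its observed statistic exceeds the null at level `alpha`
#' (p = (1 + #{null >= obs}) / (n_surrogates + 1)).
#'
#' @param trials A samples x channels matrix, or a list of such matrices
#'   (trials); trial statistics are averaged.
#' @param order MVAR order.
#' @param freqs Frequency grid (Hz).
#' @param fs Sampling rate.
#' @param band Optional length-2 band over which to average (default: all of
#'   `freqs`).
#' @param n_surrogates Number of surrogates (analysis default 1000; >= 19).
#' @param alpha Significance level; must satisfy `alpha >= 1/(n_surrogates+1)`.
#' @param q Weight-filter process noise passed to [fit_dekf_mvar()].
#' @param seed Integer seed for surrogate randomization.
#' @return List: `observed` (N x N, `[i,j]` = influence j on i), `pvalues`,
#'   `threshold` (per-pair (1-alpha) null quantile), `significant` (logical
#'   N x N), `n_surrogates`, `alpha`.
#' @export
time_reversal_surrogate_test <- function(trials, order = 2,
                                         freqs = seq(2, 45, by = 1),
                                         fs = 250, band = NULL,
                                         n_surrogates = 1000, alpha = 0.001,
                                         q = 4e-5, seed = 1L) {
  if (n_surrogates < 19) stop("n_surrogates must be >= 19")
  if (alpha < 1 / (n_surrogates + 1))
    stop("alpha = ", alpha, " is below the resolution 1/(n_surrogates+1) = ",
         signif(1 / (n_surrogates + 1), 3), "; increase n_surrogates")
  if (is.matrix(trials)) trials <- list(trials)
  N <- ncol(trials[[1]])
  set.seed(seed)
  stat_of <- function(trs) {
    S <- matrix(0, N, N)
    for (X in trs) S <- S + tpdc_pair_statistic(X, order, freqs, fs, band, q)
    S / length(trs)
  }
  observed <- stat_of(trials)
  rev_trials <- lapply(trials, function(X) X[nrow(X):1, , drop = FALSE])
  null_stats <- array(0, dim = c(n_surrogates, N, N))
  single <- length(trials) == 1
  for (s in seq_len(n_surrogates)) {
    if (single) {
      X <- rev_trials[[1]]
      n <- nrow(X)
      sh <- sample.int(n, N, replace = TRUE)
      Xs <- X
      for (jc in seq_len(N))
        Xs[, jc] <- X[((seq_len(n) - 1 + sh[jc]) %% n) + 1, jc]
      null_stats[s, , ] <- stat_of(list(Xs))
    } else {
      pick <- sample.int(length(rev_trials), length(rev_trials), replace = TRUE)
      null_stats[s, , ] <- stat_of(rev_trials[pick])
    }
  }
  pvals <- matrix(1, N, N)
  thr <- matrix(Inf, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    nullv <- null_stats[, i, j]
    pvals[i, j] <- (1 + sum(nullv >= observed[i, j])) / (n_surrogates + 1)
    thr[i, j] <- stats::quantile(nullv, 1 - alpha, names = FALSE)
  }
  sig <- pvals <= alpha
  diag(sig) <- FALSE
  list(observed = observed, pvalues = pvals, threshold = thr,
       significant = sig, n_surrogates = n_surrogates, alpha = alpha)
}

#' Classify directionality of each channel pair
#'
#' From the significance mask of a surrogate test (`[i, j]` = influence of j
#' on i significant), each unordered pair is classified as `"bi"` when both
#' directions are significant, `"uni"` (with orientation) when exactly one
#' is, `"none"` otherwise.
#'
#' @param significant Logical N x N mask.
#' @return Data frame `from`, `to`, `class` with class in
#'   `c("none", "uni", "bi")`; for `"uni"`, `from`/`to` give the orientation,
#'   for the others `from < to` by convention.
#' @export
classify_directionality <- function(significant) {
  N <- nrow(significant)
  rows <- list()
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ij <- significant[j, i]   # i -> j (source i, target j)
    ji <- significant[i, j]   # j -> i
    cls <- if (ij && ji) "bi" else if (ij || ji) "uni" else "none"
    if (cls == "uni" && ji) rows[[length(rows) + 1]] <-
        data.frame(from = j, to = i, class = "uni")
    else rows[[length(rows) + 1]] <-
        data.frame(from = i, to = j, class = cls)
  }
  do.call(rbind, rows)
}
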