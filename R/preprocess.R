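#' Zero-phase Butterworth band-pass filter of an epoched series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass per trial and
#' ROI. Defaults reproduce the broadband 3-45 Hz preprocessing filter. The
#' effective magnitude response is the squared single-pass response.
#'
#' Note: at 250 Hz sampling a low-pass at 125 Hz sits exactly at Nyquist and
#' is mathematically vacuous; such requests are treated as identity with a
#' warning rather than a numerically ill-posed design.
#'
#' @param series An `epoched_series` or a plain numeric matrix/vector
#'   (samples in the last dimension).
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order of the single-pass design (default 4).
#' @param fs Sampling rate; taken from `series$fs` when available.
#' @return Object of the same shape with filtered data.
#' @export
bandpass_filter <- function(series, low_hz = 3, high_hz = 45, order = 4,
                            fs = NULL) {
  if (inherits(series, "epoched_series")) {
    fs <- series$fs
  } else if (is.null(fs)) stop("fs must be supplied for plain arrays")
  nyq <- fs / 2
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq) {
    if (high_hz == nyq) {
      warning("high_hz equals Nyquist (", nyq,
              " Hz); band-pass is vacuous at this rate, returning input unchanged")
      return(series)
    }
    stop("high_hz (", high_hz, ") must be below Nyquist (", nyq, " Hz)")
  }
  if (order < 1) stop("order must be >= 1")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  filt1 <- function(x) as.numeric(signal::filtfilt(bf, x))
  if (inherits(series, "epoched_series")) {
    d <- series$data
    for (tr in seq_len(dim(d)[1]))
      for (i in seq_len(dim(d)[2]))
        d[tr, i, ] <- filt1(d[tr, i, ])
    series$data <- d
    series
  } else if (is.matrix(series)) {
    t(apply(series, 1, filt1))
  } else {
    filt1(series)
  }
}

#' Analysis window scheme: baseline plus six post-stimulus windows
#'
#' The canonical scheme: baseline (-250 to 0 ms) and T1..T6 covering 0-1500 ms
#' in contiguous 250-ms windows, each divisible into five 50-ms subwindows.
#'
#' @return Data frame with columns `name`, `start_ms`, `end_ms`.
#' @export
window_scheme <- function() {
  data.frame(
    name = c("baseline", paste0("T", 1:6)),
    start_ms = seq(-250, 1250, by = 250),
    end_ms = seq(0, 1500, by = 250),
    stringsAsFactors = FALSE
  )
}

# millisecond time (relative to stimulus) -> 0-based sample offset from onset
ms_to_offset <- function(ms, fs) as.integer(round(ms / 1000 * fs))

#' Slice an epoched series into the scheme's windows
#'
#' Window boundaries map to sample indices by `round(t * fs)` relative to the
#' stimulus-onset sample, half-open `[start, end)`; consecutive windows share
#' boundaries so concatenating the post-stimulus blocks reproduces the
#' 0-1500 ms span exactly (375 samples at 250 Hz).
#'
#' @param series An `epoched_series`.
#' @param scheme Data frame as from [window_scheme()].
#' @return Named list of trial x ROI x sample arrays.
#' @export
slice_windows <- function(series, scheme = window_scheme()) {
  stopifnot(inherits(series, "epoched_series"))
  if (nrow(scheme) == 0) return(setNames(list(), character(0)))
  n_samp <- dim(series$data)[3]
  t0 <- series$t0_index  # 1-based index of t = 0
  out <- vector("list", nrow(scheme))
  names(out) <- scheme$name
  for (k in seq_len(nrow(scheme))) {
    s0 <- t0 + ms_to_offset(scheme$start_ms[k], series$fs)      # first sample, 1-based
    s1 <- t0 + ms_to_offset(scheme$end_ms[k], series$fs) - 1L   # last sample
    if (s0 < 1 || s1 > n_samp)
      stop("window '", scheme$name[k], "' exceeds the epoch (samples ",
           s0, "..", s1, " of ", n_samp, ")")
    out[[k]] <- series$data[, , s0:s1, drop = FALSE]
  }
  out
}

#' Sample-index boundaries of a window's five 50-ms subwindows
#'
#' Boundaries are computed with the same `round(t * fs)` convention relative
#' to stimulus onset, so the subwindows exactly partition their parent window.
#'
#' @param start_ms,end_ms Parent window limits (ms relative to stimulus).
#' @param fs Sampling rate.
#' @param n_sub Number of subwindows (default 5).
#' @return Data frame `start_offset`, `end_offset` (0-based offsets from the
#'   stimulus-onset sample, half-open).
#' @export
subwindow_offsets <- function(start_ms, end_ms, fs, n_sub = 5L) {
  edges_ms <- seq(start_ms, end_ms, length.out = n_sub + 1L)
  off <- vapply(edges_ms, ms_to_offset, integer(1), fs = fs)
  data.frame(start_offset = off[-(n_sub + 1L)], end_offset = off[-1L])
}

#' Condition contrast of aligned metric tables
#'
#' Computes CS+ minus CS- (threat minus safe) per key. Both per-condition
#' tables should be retained for condition-factor ANOVAs; the contrast serves
#' analyses of threat-related change.
#'
#' @param tab_plus,tab_minus Data frames with identical key columns and a
#'   `value` column.
#' @param keys Character vector of key column names (default: all shared
#'   non-value columns).
#' @return Data frame with the keys and `value = CS+ - CS-`.
#' @export
condition_contrast <- function(tab_plus, tab_minus, keys = NULL) {
  if (is.null(keys))
    keys <- setdiff(intersect(names(tab_plus), names(tab_minus)),
                    c("value", "condition"))
  kp <- do.call(paste, c(tab_plus[keys], sep = "\r"))
  km <- do.call(paste, c(tab_minus[keys], sep = "\r"))
  if (length(kp) != length(km) || !all(sort(kp) == sort(km))) {
    missing_in_minus <- setdiff(kp, km)
    missing_in_plus <- setdiff(km, kp)
    stop("key mismatch between condition tables; missing in CS-: [",
         paste(utils::head(missing_in_minus, 5), collapse = "; "),
         "]; missing in CS+: [",
         paste(utils::head(missing_in_plus, 5), collapse = "; "), "]")
  }
  idx <- match(kp, km)
  out <- tab_plus[, keys, drop = FALSE]
  out$value <- tab_plus$value - tab_minus$value[idx]
  out
}

# analytic signal via FFT (Hilbert transform embedding)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Inter-trial phase coherence (ITPC)
#'
#' Per-sample modulus of the across-trial mean unit phasor; phases come from
#' the analytic signal of the band-filtered data. 1 means identical phase in
#' every trial, values near `sqrt(pi) / (2 sqrt(n))` are the chance level for
#' n independent trials.
#'
#' @param series An `epoched_series`.
#' @param roi ROI index.
#' @param band Numeric length-2, band edges in Hz.
#' @param order Filter order for the band-pass.
#' @return Numeric vector (one value per sample) in `[0, 1]`.
#' @export
itpc <- function(series, roi, band, order = 4) {
  stopifnot(inherits(series, "epoched_series"))
  n_trials <- dim(series$data)[1]
  if (n_trials < 2) stop("ITPC requires at least 2 trials")
  n_samp <- dim(series$data)[3]
  phasors <- matrix(0 + 0i, n_trials, n_samp)
  bf <- signal::butter(order, band / (series$fs / 2), type = "pass")
  for (tr in seq_len(n_trials)) {
    x <- as.numeric(signal::filtfilt(bf, series$data[tr, roi, ]))
    a <- analytic_signal(x)
    phasors[tr, ] <- a / Mod(a)
  }
  Mod(colMeans(phasors))
}
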