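#' Configuration for a synthetic threat-conditioning cohort
#'
#' Bundles every knob of the generator: cohort size, parcellation size,
#' sampling, epoching, per-band damped oscillators, directed coupling,
#' baseline community structure and per-condition community switching rates,
#' an optional stimulation-like perturbation at a fixed latency, and the
#' behavioural covariate model.
#'
#' The defaults emulate the instructed-threat design the analysis targets:
#' 90 ROIs at 250 Hz, epochs spanning -0.25 to 1.5 s around stimulus onset,
#' 36 CS+ and 24 CS- trials per subject, theta (6 Hz) and alpha (10 Hz)
#' oscillators, and a higher community switching rate under threat (CS+ 0.4)
#' than under safety (CS- 0.2).
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of regions (>= 2). Defaults to 90.
#' @param fs Sampling rate in Hz.
#' @param epoch_span Two-element numeric, epoch limits in seconds relative to
#'   stimulus onset.
#' @param n_trials_per_condition Named integer vector over conditions.
#' @param band_oscillators Named list; each element `c(freq, damping)` gives
#'   the centre frequency (Hz) and pole modulus (0 < damping < 1) of a damped
#'   AR(2) oscillator.
#' @param coupling_spec Data frame with columns `source`, `target` (ROI
#'   indices), `band` (name in `band_oscillators`), `coef`, and optional
#'   `onset_s`/`offset_s` delimiting when the coupling is active (seconds
#'   relative to stimulus onset; defaults cover the whole epoch).
#' @param base_partition Integer vector of length `n_rois`: the baseline
#'   community label of each ROI. Defaults to the six anatomical communities
#'   of `roi_table()` when `n_rois == 90`, else a balanced split into
#'   `min(6, n_rois)` groups.
#' @param switch_rates Named numeric vector per condition: probability that a
#'   node changes community between consecutive layers after stimulus onset.
#' @param baseline_switch_rate Switching rate during the pre-stimulus window
#'   (both conditions).
#' @param perturbation `NULL` or `list(onset_ms, duration_ms, gain,
#'   conditions)`: coupling coefficients are multiplied by `gain` during
#'   `[onset, onset + duration)` for the listed conditions. Emulates single-
#'   pulse stimulation delivered 1 s after stimulus onset.
#' @param behaviour_effects List controlling the behaviour model:
#'   `rating_effect` and `heart_effect` are CS+ minus CS- mean shifts,
#'   `rating_sd`/`heart_sd` residual scales, `rating_heart_cor` the planted
#'   correlation between ratings and heart rate, `flexibility_cor` the planted
#'   correlation between behaviour and the subject's community switching rate,
#'   `rate_sd` the between-subject SD of the switching rate.
#' @param noise_sd Innovation standard deviation of the oscillators.
#' @param seed Integer master seed; fixed seed gives bit-identical output.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_subjects = 20,
                             n_rois = 90,
                             fs = 250,
                             epoch_span = c(-0.25, 1.5),
                             n_trials_per_condition = c("CS+" = 36, "CS-" = 24),
                             band_oscillators = list(theta = c(freq = 6, damping = 0.95),
                                                     alpha = c(freq = 10, damping = 0.95)),
                             coupling_spec = NULL,
                             base_partition = NULL,
                             switch_rates = c("CS+" = 0.4, "CS-" = 0.2),
                             baseline_switch_rate = 0.05,
                             perturbation = NULL,
                             behaviour_effects = list(rating_effect = 2.0,
                                                      heart_effect = 5.0,
                                                      rating_sd = 1.0,
                                                      heart_sd = 3.0,
                                                      rating_heart_cor = 0.5,
                                                      flexibility_cor = 0.6,
                                                      rate_sd = 0.08),
                             noise_sd = 1.0,
                             seed = 1L) {
  if (n_rois < 2) stop("n_rois must be >= 2")
  if (fs <= 0) stop("fs must be positive")
  if (any(switch_rates < 0 | switch_rates > 1))
    stop("switch_rates must lie in [0, 1]")
  if (baseline_switch_rate < 0 || baseline_switch_rate > 1)
    stop("baseline_switch_rate must lie in [0, 1]")
  if (!is.null(coupling_spec)) {
    stopifnot(is.data.frame(coupling_spec),
              all(c("source", "target", "band", "coef") %in% names(coupling_spec)))
    bad <- coupling_spec$source < 1 | coupling_spec$source > n_rois |
      coupling_spec$target < 1 | coupling_spec$target > n_rois
    if (any(bad))
      stop("coupling_spec references ROI indices outside 1..", n_rois)
    if (!all(coupling_spec$band %in% names(band_oscillators)))
      stop("coupling_spec references unknown bands")
  }
  if (is.null(base_partition)) {
    base_partition <- if (n_rois == 90) roi_table()$community
      else rep_len(seq_len(min(6L, n_rois)), n_rois)
  }
  if (length(base_partition) != n_rois)
    stop("base_partition must have length n_rois")
  roi_names <- if (n_rois == 90) roi_table()$roi else sprintf("ROI%02d", seq_len(n_rois))
  be <- behaviour_effects
  if (!is.null(be$rating_heart_cor) && !is.null(be$flexibility_cor)) {
    if (be$rating_heart_cor + be$flexibility_cor^2 > 1)
      stop("rating_heart_cor + flexibility_cor^2 must be <= 1 ",
           "(shared + switching variance components exceed total)")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    fs = fs, epoch_span = epoch_span,
    n_trials_per_condition = n_trials_per_condition,
    band_oscillators = band_oscillators, coupling_spec = coupling_spec,
    base_partition = as.integer(base_partition),
    switch_rates = switch_rates, baseline_switch_rate = baseline_switch_rate,
    perturbation = perturbation, behaviour_effects = behaviour_effects,
    noise_sd = noise_sd, seed = as.integer(seed), roi_names = roi_names
  ), class = "synthetic_config")
}

# AR(2) coefficients of a damped oscillator with pole modulus r at f0 Hz:
# complex-conjugate pole pair r * exp(+- i 2 pi f0 / fs)
ar2_coefs <- function(freq, damping, fs) {
  c(2 * damping * cos(2 * pi * freq / fs), -damping^2)
}

# spectral radius of the companion matrix of an MVAR(p) coefficient set
# A: list of p (N x N) lag matrices
companion_spectral_radius <- function(A) {
  p <- length(A)
  N <- nrow(A[[1]])
  C <- matrix(0, N * p, N * p)
  for (r in seq_len(p)) C[1:N, ((r - 1) * N + 1):(r * N)] <- A[[r]]
  if (p > 1) C[(N + 1):(N * p), 1:(N * (p - 1))] <- diag(N * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a (time-varying) multivariate autoregressive process
#'
#' @param A Either a list of p lag matrices (stationary MVAR) or a function
#'   `A(t)` returning that list for sample `t` (1-based).
#' @param n Number of samples to return.
#' @param noise_sd Innovation SD (scalar or length-N).
#' @param burn_in Samples discarded at the start.
#' @param seed Optional integer seed.
#' @return An `n x N` matrix.
#' @export
simulate_mvar <- function(A, n, noise_sd = 1, burn_in = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Afun <- if (is.function(A)) A else function(t) A
  A1 <- Afun(1L)
  p <- length(A1); N <- nrow(A1[[1]])
  total <- n + burn_in
  X <- matrix(0, total, N)
  E <- matrix(stats::rnorm(total * N, sd = noise_sd), total, N)
  for (t in seq_len(total)) {
    At <- Afun(max(1L, t - burn_in))
    x <- E[t, ]
    for (r in seq_len(p)) if (t - r >= 1) x <- x + At[[r]] %*% X[t - r, ]
    X[t, ] <- x
  }
  X[(burn_in + 1):total, , drop = FALSE]
}

# Build the list of time-resolved lag matrices for the latent band-component
# MVAR implied by a config, for one condition. Latent dimension = n_rois *
# n_bands; observed signal of ROI i is the sum of its band components.
# Returns list(Afun = function(t) list(A1, A2), N_lat, mix (obs x latent)).
build_generator_model <- function(config, condition) {
  bands <- config$band_oscillators
  B <- length(bands)
  N <- config$n_rois
  N_lat <- N * B
  fs <- config$fs
  # latent index of (roi i, band b): (b-1)*N + i
  base1 <- matrix(0, N_lat, N_lat)
  base2 <- matrix(0, N_lat, N_lat)
  for (b in seq_len(B)) {
    co <- ar2_coefs(bands[[b]][["freq"]], bands[[b]][["damping"]], fs)
    idx <- (b - 1) * N + seq_len(N)
    diag(base1)[idx] <- co[1]
    diag(base2)[idx] <- co[2]
  }
  cs <- config$coupling_spec
  t0 <- -config$epoch_span[1]                 # seconds from epoch start to onset
  pert <- config$perturbation
  samp_time <- function(t) (t - 1) / fs - t0  # seconds rel. stimulus, sample t
  coup_entries <- NULL
  if (!is.null(cs) && nrow(cs) > 0) {
    bidx <- match(cs$band, names(bands))
    coup_entries <- data.frame(
      row = (bidx - 1) * N + cs$target,
      col = (bidx - 1) * N + cs$source,
      coef = cs$coef,
      onset = if ("onset_s" %in% names(cs)) cs$onset_s else config$epoch_span[1],
      offset = if ("offset_s" %in% names(cs)) cs$offset_s else config$epoch_span[2] + 1 / fs
    )
  }
  pert_active <- !is.null(pert) &&
    (is.null(pert$conditions) || condition %in% pert$conditions)
  Afun <- function(t) {
    A1 <- base1
    if (!is.null(coup_entries)) {
      tt <- samp_time(t)
      g <- 1
      if (pert_active && tt >= pert$onset_ms / 1000 &&
          tt < (pert$onset_ms + pert$duration_ms) / 1000)
        g <- pert$gain
      act <- coup_entries$onset <= tt & tt < coup_entries$offset
      if (any(act)) {
        e <- coup_entries[act, , drop = FALSE]
        A1[cbind(e$row, e$col)] <- A1[cbind(e$row, e$col)] + g * e$coef
      }
    }
    list(A1, base2)
  }
  mix <- matrix(0, N, N_lat)
  for (b in seq_len(B)) mix[cbind(seq_len(N), (b - 1) * N + seq_len(N))] <- 1
  list(Afun = Afun, N_lat = N_lat, mix = mix)
}

# stability check: worst-case configuration (all couplings active, with the
# perturbation gain if it amplifies them)
check_generator_stability <- function(config, condition) {
  model <- build_generator_model(config, condition)
  bands <- config$band_oscillators
  B <- length(bands); N <- config$n_rois; fs <- config$fs
  A1 <- matrix(0, model$N_lat, model$N_lat)
  A2 <- matrix(0, model$N_lat, model$N_lat)
  for (b in seq_len(B)) {
    co <- ar2_coefs(bands[[b]][["freq"]], bands[[b]][["damping"]], fs)
    idx <- (b - 1) * N + seq_len(N)
    diag(A1)[idx] <- co[1]; diag(A2)[idx] <- co[2]
  }
  cs <- config$coupling_spec
  if (!is.null(cs) && nrow(cs) > 0) {
    g <- 1
    if (!is.null(config$perturbation)) g <- max(1, abs(config$perturbation$gain))
    bidx <- match(cs$band, names(bands))
    for (k in seq_len(nrow(cs))) {
      r <- (bidx[k] - 1) * N + cs$target[k]
      cc <- (bidx[k] - 1) * N + cs$source[k]
      A1[r, cc] <- A1[r, cc] + g * cs$coef[k]
    }
    rho <- companion_spectral_radius(list(A1, A2))
    if (rho >= 1) {
      worst <- which.max(abs(cs$coef))
      stop(sprintf(paste0("unstable AR configuration (spectral radius %.3f >= 1); ",
                          "largest coupling %d -> %d (band %s, coef %.3f)"),
                   rho, cs$source[worst], cs$target[worst],
                   cs$band[worst], cs$coef[worst]))
    }
  }
  invisible(TRUE)
}

#' Generate one subject-condition block of epoched source series
#'
#' Each ROI is driven by damped stochastic AR(2) oscillators at the configured
#' band centres; directed coupling is injected as lagged cross-terms between
#' same-band components following `coupling_spec`; the optional perturbation
#' multiplies coupling coefficients transiently. The observed ROI signal is
#' the sum of its band components. Amplitudes are in innovation units
#' (unitless).
#'
#' @param config A `synthetic_config`.
#' @param condition Condition label, one of the names of
#'   `config$n_trials_per_condition`.
#' @param subject_seed Integer seed for this subject-condition block.
#' @return An `epoched_series` list: `data` (trial x ROI x sample array),
#'   `fs`, `t0_index` (1-based sample of stimulus onset), `roi_names`,
#'   `condition`, `subject`.
#' @export
generate_mvar_series <- function(config, condition, subject_seed,
                                 subject = NA_character_) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!condition %in% names(config$n_trials_per_condition))
    stop("invalid condition label: ", condition)
  check_generator_stability(config, condition)
  model <- build_generator_model(config, condition)
  fs <- config$fs
  n_samp <- epoch_n_samples(config$epoch_span, fs)
  n_trials <- config$n_trials_per_condition[[condition]]
  N <- config$n_rois
  set.seed(subject_seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  data <- array(0, dim = c(n_trials, N, n_samp))
  for (tr in seq_len(n_trials)) {
    Z <- simulate_mvar(model$Afun, n_samp, noise_sd = config$noise_sd,
                       burn_in = 100, seed = trial_seeds[tr])
    data[tr, , ] <- tcrossprod(model$mix, Z)  # N x n_samp
  }
  structure(list(subject = subject, condition = condition, data = data,
                 fs = fs, t0_index = stimulus_onset_index(config$epoch_span, fs),
                 roi_names = config$roi_names),
            class = "epoched_series")
}

# epoch sample grid: t_k = epoch_start + k/fs for k = 0 .. K-1 covering the span
epoch_n_samples <- function(epoch_span, fs) {
  as.integer(round(diff(epoch_span) * fs)) + 1L
}

stimulus_onset_index <- function(epoch_span, fs) {
  as.integer(round(-epoch_span[1] * fs)) + 1L
}

#' Planted dynamic community timeline
#'
#' Layer 1 equals `base_partition`; at each later layer every node
#' independently switches community with probability `switch_rate`, drawing a
#' label different from its current one (forced change), so the expected
#' nodal flexibility equals `switch_rate` exactly.
#'
#' @param base_partition Integer labels, one per node.
#' @param switch_rate Probability in `[0, 1]`.
#' @param n_layers Number of layers (>= 2).
#' @param seed Integer seed.
#' @return Integer node x layer matrix.
#' @export
generate_community_timeline <- function(base_partition, switch_rate, n_layers,
                                        seed = NULL) {
  if (switch_rate < 0 || switch_rate > 1)
    stop("switch_rate must lie in [0, 1]")
  if (n_layers < 2) stop("n_layers must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  labels <- sort(unique(base_partition))
  N <- length(base_partition)
  Q <- matrix(0L, N, n_layers)
  Q[, 1] <- as.integer(base_partition)
  for (l in 2:n_layers) {
    Q[, l] <- Q[, l - 1]
    if (length(labels) > 1 && switch_rate > 0) {
      flip <- stats::runif(N) < switch_rate
      if (any(flip)) {
        cur <- Q[flip, l - 1]
        Q[flip, l] <- vapply(cur, function(cl) {
          cand <- labels[labels != cl]
          if (length(cand) == 1) cand else sample(cand, 1L)
        }, integer(1))
      }
    }
  }
  Q
}

#' Generate and write a full synthetic cohort with ground truth
#'
#' Writes, under `out_dir`: one CSV per subject-condition block of source
#' series (long layout with a trial column, rows = trial x ROI), a metadata
#' JSON, a behaviour table (subject, condition, rating, heart_rate), and a
#' ground-truth JSON holding the planted community timelines, per-subject
#' switching rates and expected flexibility.
#'
#' The behaviour model plants: a CS+ minus CS- mean shift on ratings and heart
#' rate; a correlation between ratings and heart rate through a shared latent
#' factor; and a correlation between behaviour and the subject's community
#' switching rate (so flexibility-behaviour coupling is recoverable).
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory.
#' @param overwrite Overwrite an existing non-empty directory?
#' @param write_series Write the (large) series CSVs? Ground truth, metadata
#'   and behaviour are always written.
#' @param n_window_layers Number of planted community layers per analysis
#'   window (default 5, matching the five 50-ms subwindows per 250-ms window).
#' @return Invisibly, a list with `behaviour` (data.frame) and `ground_truth`.
#' @export
generate_cohort <- function(config, out_dir, overwrite = FALSE,
                            write_series = TRUE, n_window_layers = 5L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_subjects < 1) stop("n_subjects must be >= 1; nothing written")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir, " is non-empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  conditions <- names(config$n_trials_per_condition)
  n_sub <- config$n_subjects
  be <- config$behaviour_effects
  set.seed(config$seed)
  subj_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  n_sub * length(conditions)),
                       n_sub, length(conditions),
                       dimnames = list(NULL, conditions))
  a <- sqrt(be$rating_heart_cor)          # shared behaviour factor loading
  b <- be$flexibility_cor                 # switching-rate factor loading
  cc <- sqrt(max(0, 1 - a^2 - b^2))       # idiosyncratic residual

  behaviour <- NULL
  planted_Q <- list()
  planted_rates <- list()
  planted_flex <- list()
  n_windows_post <- 6L
  for (cond in conditions) {
    g <- stats::rnorm(n_sub); u <- stats::rnorm(n_sub)
    e_r <- stats::rnorm(n_sub); e_h <- stats::rnorm(n_sub)
    rate <- pmin(0.99, pmax(0.01,
      config$switch_rates[[cond]] + be$rate_sd * u))
    is_plus <- as.numeric(cond == "CS+")
    rating <- 5 + be$rating_effect * is_plus +
      be$rating_sd * (a * g + b * u + cc * e_r)
    heart <- 70 + be$heart_effect * is_plus +
      be$heart_sd * (a * g + b * u + cc * e_h)
    behaviour <- rbind(behaviour, data.frame(
      subject = sprintf("S%02d", seq_len(n_sub)), condition = cond,
      rating = rating, heart_rate = heart, stringsAsFactors = FALSE))
    qs <- vector("list", n_sub); fl <- numeric(n_sub)
    for (s in seq_len(n_sub)) {
      # per-window timelines: baseline at baseline_switch_rate, T1..T6 at the
      # subject's planted rate; each window contributes n_window_layers layers
      seeds <- subj_seeds[s, cond] %% (.Machine$integer.max - 10L)
      Qb <- generate_community_timeline(config$base_partition,
                                        config$baseline_switch_rate,
                                        n_window_layers, seed = seeds + 1L)
      Qw <- lapply(seq_len(n_windows_post), function(w)
        generate_community_timeline(config$base_partition, rate[s],
                                    n_window_layers, seed = seeds + 1L + w))
      Q <- do.call(cbind, c(list(Qb), Qw))
      qs[[s]] <- Q
      # expected flexibility: mean within-window change fraction over T1..T6
      fw <- vapply(Qw, function(q) node_flexibility(q)$mean, numeric(1))
      fl[s] <- mean(fw)
    }
    planted_Q[[cond]] <- qs
    planted_rates[[cond]] <- rate
    planted_flex[[cond]] <- fl
  }

  utils::write.csv(behaviour, file.path(out_dir, "behaviour.csv"),
                   row.names = FALSE)
  meta <- list(fs = config$fs, epoch_span = config$epoch_span,
               n_rois = config$n_rois, roi_names = config$roi_names,
               conditions = conditions,
               n_trials_per_condition = as.list(config$n_trials_per_condition),
               n_subjects = n_sub, seed = config$seed,
               t0_index = stimulus_onset_index(config$epoch_span, config$fs))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  gt <- list(planted_Q = planted_Q, planted_rates = planted_rates,
             planted_flexibility = planted_flex,
             base_partition = config$base_partition,
             switch_rates = as.list(config$switch_rates),
             n_window_layers = n_window_layers)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  if (write_series) {
    for (cond in conditions) {
      for (s in seq_len(n_sub)) {
        ser <- generate_mvar_series(config, cond, subj_seeds[s, cond],
                                    subject = sprintf("S%02d", s))
        write_series(ser, file.path(out_dir, sprintf(
          "series_S%02d_%s.csv", s, gsub("[+]", "plus", gsub("[-]", "minus", cond)))))
      }
    }
  }
  invisible(list(behaviour = behaviour, ground_truth = gt, metadata = meta))
}

#' Read a ground-truth JSON back into R structures
#' @param path Path to `ground_truth.json`.
#' @return List with planted timelines as integer matrices.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = FALSE)
  gt$planted_Q <- lapply(gt$planted_Q, function(qs)
    lapply(qs, function(m)
      do.call(rbind, lapply(m, function(row) as.integer(unlist(row))))))
  gt$base_partition <- as.integer(unlist(gt$base_partition))
  gt$planted_rates <- lapply(gt$planted_rates, function(v) as.numeric(unlist(v)))
  gt$planted_flexibility <- lapply(gt$planted_flexibility,
                                   function(v) as.numeric(unlist(v)))
  gt$switch_rates <- lapply(gt$switch_rates, function(v) as.numeric(unlist(v)))
  gt$n_window_layers <- as.integer(gt$n_window_layers)
  gt
}
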