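small_config <- function(...) {
  synthetic_config(n_subjects = 2, n_rois = 4,
                   n_trials_per_condition = c("CS+" = 3, "CS-" = 2),
                   band_oscillators = list(theta = c(freq = 6, damping = 0.9)),
                   ...)
}

test_that("generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  s1 <- generate_mvar_series(cfg, "CS+", subject_seed = 77)
  s2 <- generate_mvar_series(cfg, "CS+", subject_seed = 77)
  expect_identical(s1$data, s2$data)
  s3 <- generate_mvar_series(cfg, "CS+", subject_seed = 78)
  expect_false(identical(s1$data, s3$data))
})

test_that("invalid condition and unstable coupling raise labelled errors", {
  cfg <- small_config()
  expect_error(generate_mvar_series(cfg, "CS?", 1), "invalid condition")
  # one-way coupling is triangular and cannot destabilise; a strong
  # reciprocal loop pushes the companion spectral radius past 1
  bad <- small_config(coupling_spec = data.frame(
    source = c(1, 2), target = c(2, 1), band = "theta", coef = c(1.5, 1.5)))
  expect_error(generate_mvar_series(bad, "CS+", 1), "unstable AR configuration")
  expect_error(generate_mvar_series(bad, "CS+", 1), "1 -> 2")
})

test_that("uncoupled channels show near-zero lagged cross-correlation", {
  cfg <- synthetic_config(n_subjects = 1, n_rois = 4,
                          n_trials_per_condition = c("CS+" = 50, "CS-" = 2),
                          band_oscillators = list(theta = c(freq = 6, damping = 0.9)),
                          seed = 3)
  ser <- generate_mvar_series(cfg, "CS+", subject_seed = 5)
  # mean over trials of lag-1 cross-correlation between each ordered pair
  n_tr <- dim(ser$data)[1]
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))
  for (k in seq_len(nrow(pairs))) {
    r <- mean(vapply(seq_len(n_tr), function(tr) {
      x <- ser$data[tr, pairs[k, 1], ]
      y <- ser$data[tr, pairs[k, 2], ]
      cor(x[-length(x)], y[-1])
    }, numeric(1)))
    expect_lt(abs(r), 0.1)
  }
})

test_that("planted directed coupling is recovered by a stationary MVAR fit", {
  cfg <- synthetic_config(
    n_subjects = 1, n_rois = 2,
    n_trials_per_condition = c("CS+" = 10, "CS-" = 2),
    band_oscillators = list(theta = c(freq = 6, damping = 0.9)),
    coupling_spec = data.frame(source = 1, target = 2, band = "theta",
                               coef = 0.5),
    seed = 21)
  ser <- generate_mvar_series(cfg, "CS+", subject_seed = 13)
  # least-squares MVAR(2) oracle, averaged across per-trial fits
  fits <- lapply(seq_len(dim(ser$data)[1]), function(tr)
    fit_mvar_ols(t(ser$data[tr, , ]), order = 2)$A[[1]])
  A1 <- Reduce(`+`, fits) / length(fits)
  expect_lt(abs(A1[2, 1] - 0.5), 0.1)   # planted x -> y
  expect_lt(abs(A1[1, 2]), 0.1)         # no reverse coupling
})

test_that("community timeline honours switch-rate limits and expectations", {
  base <- rep(1:3, each = 4)
  expect_error(generate_community_timeline(base, -0.1, 5), "switch_rate")
  Q0 <- generate_community_timeline(base, 0, 6, seed = 1)
  expect_true(all(Q0 == Q0[, 1]))
  expect_equal(node_flexibility(Q0)$f, rep(0, 12))
  Q1 <- generate_community_timeline(base, 1, 6, seed = 1)
  expect_equal(node_flexibility(Q1)$f, rep(1, 12))
  # Monte-Carlo mean at rate 0.3 (smaller replicate count than the
  # calibration study; the full check lives in the acceptance suite)
  fl <- vapply(1:150, function(s)
    node_flexibility(generate_community_timeline(rep(1:6, each = 15),
                                                 0.3, 6, seed = s))$mean,
    numeric(1))
  expect_lt(abs(mean(fl) - 0.3), 0.03)
})

test_that("cohort generation writes behaviour, metadata and ground truth", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 7)
  cfg$n_subjects <- 3L
  res <- generate_cohort(cfg, dir, write_series = FALSE)
  expect_true(file.exists(file.path(dir, "behaviour.csv")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
  beh <- utils::read.csv(file.path(dir, "behaviour.csv"))
  expect_equal(nrow(beh), 3 * 2)  # one row per subject x condition
  # ground truth round-trips exactly
  gt <- read_ground_truth(file.path(dir, "ground_truth.json"))
  expect_identical(gt$planted_Q[["CS+"]][[2]],
                   res$ground_truth$planted_Q[["CS+"]][[2]])
  # refusing to overwrite
  expect_error(generate_cohort(cfg, dir, write_series = FALSE), "non-empty")
  # nothing written for an empty cohort
  dir2 <- withr::local_tempdir()
  cfg0 <- small_config(); cfg0$n_subjects <- 0L
  expect_error(generate_cohort(cfg0, dir2), "n_subjects")
  expect_length(list.files(dir2), 0)
})

test_that("planted behaviour effect yields a detectable paired difference", {
  # rating effect 2.0 at sd 1.0 is a very large paired effect; with 20
  # subjects the paired t-test should essentially always reject at 0.01
  hits <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    dir <- withr::local_tempdir()
    cfg <- synthetic_config(n_subjects = 20, n_rois = 4,
                            n_trials_per_condition = c("CS+" = 2, "CS-" = 2),
                            seed = 1000 + r)
    res <- generate_cohort(cfg, dir, write_series = FALSE)
    beh <- res$behaviour
    a <- beh$rating[beh$condition == "CS+"]
    b <- beh$rating[beh$condition == "CS-"]
    if (paired_ttest(a, b, alpha = 0.01)$significant) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("generated series are stationary within coupling segments", {
  cfg <- synthetic_config(
    n_subjects = 1, n_rois = 3,
    n_trials_per_condition = c("CS+" = 2, "CS-" = 2),
    coupling_spec = data.frame(source = 1, target = 2, band = "theta",
                               coef = 0.4),
    seed = 2)
  expect_silent(check <- threatnets:::check_generator_stability(cfg, "CS+"))
  expect_true(check)
  ser <- generate_mvar_series(cfg, "CS+", 4)
  expect_true(all(is.finite(ser$data)))
})
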