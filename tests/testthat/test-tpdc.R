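test_that("dual Kalman filter agrees with OLS on stationary data", {
  X <- simulate_mvar(coupled_bivar(0.5), 1000, seed = 42)
  ols <- fit_mvar_ols(X, 1)
  m <- fit_dekf_mvar(X, order = 1, fs = 250)
  est <- apply(m$A[200:1000, 1, , ], c(2, 3), mean)
  expect_lt(max(abs(est - ols$A[[1]])), 0.1)
  expect_true(m$stable)
  # zero-coupling noise: time-averaged cross terms near zero
  set.seed(43)
  X0 <- matrix(rnorm(2000), 1000, 2)
  m0 <- fit_dekf_mvar(X0, order = 2, fs = 250)
  cross <- c(apply(m0$A[100:1000, , 1, 2, drop = FALSE], 2, mean),
             apply(m0$A[100:1000, , 2, 1, drop = FALSE], 2, mean))
  expect_lt(max(abs(cross)), 0.1)
  expect_error(fit_dekf_mvar(X0[1:15, ], order = 5), "too short")
  expect_error(fit_dekf_mvar(X0, order = 0), "order")
})

test_that("filter tracks a coefficient step change", {
  n <- 1000; step_at <- 500
  Afun <- function(t) list(rbind(c(0.5, 0),
                                 c(ifelse(t >= step_at, 0.5, 0), 0.3)))
  X <- simulate_mvar(Afun, n, seed = 7)
  m <- fit_dekf_mvar(X, order = 1, fs = 250)
  est <- m$A[, 1, 2, 1]
  # sliding-window OLS oracle confirms the step is present in the data
  w_pre <- fit_mvar_ols(X[1:step_at, ], 1)$A[[1]][2, 1]
  w_post <- fit_mvar_ols(X[(step_at + 1):n, ], 1)$A[[1]][2, 1]
  expect_lt(abs(w_pre), 0.15)
  expect_lt(abs(w_post - 0.5), 0.15)
  expect_lt(which(est[step_at:n] > 0.25)[1], 200)
  expect_lt(abs(mean(est[(step_at + 200):n]) - 0.5), 0.15)
})

test_that("TPDC is column-normalized and vanishes for uncoupled models", {
  set.seed(44)
  X <- matrix(rnorm(1500), 500, 3)
  m <- fit_dekf_mvar(X, order = 2, fs = 250)
  tp <- tpdc_spectrum(m, freqs = seq(2, 45, by = 3))
  norms <- apply(tp$values^2, c(2, 3, 4), sum)
  expect_lt(max(abs(norms - 1)), 1e-10)
  # hand-built diagonal (uncoupled) model: off-diagonal PDC exactly 0
  md <- m
  md$A[] <- 0
  md$A[, 1, 1, 1] <- 0.5; md$A[, 1, 2, 2] <- 0.4; md$A[, 1, 3, 3] <- 0.3
  tpd <- tpdc_spectrum(md, freqs = c(5, 10), times = c(100, 200))
  off <- tpd$values[rep(!diag(3), 2 * 2)]
  expect_equal(max(abs(tpd$values[1, 2, , ])), 0)
  expect_equal(max(abs(tpd$values[2, 1, , ])), 0)
})

test_that("TPDC matches the closed-form PDC of the generating model", {
  # theta-band oscillator in x, coupled x -> y
  a <- threatnets:::ar2_coefs(6, 0.9, 250)
  A1 <- rbind(c(a[1], 0), c(0.5, a[1]))
  A2 <- rbind(c(a[2], 0), c(0, a[2]))
  freqs <- seq(2, 45, by = 1)
  ref <- vapply(freqs, function(f) oracle_pdc(list(A1, A2), f, 250),
                matrix(0, 2, 2))
  # known-model PDC: x -> y peaks in theta and dominates the reverse
  theta <- freqs >= 4 & freqs <= 8
  alpha <- freqs >= 8 & freqs <= 12
  expect_gt(mean(ref[2, 1, theta]), mean(ref[1, 2, theta]))
  # estimated TPDC reproduces the same ordering
  X <- simulate_mvar(list(A1, A2), 1500, seed = 45)
  m <- fit_dekf_mvar(X, order = 2, fs = 250)
  tp <- tpdc_spectrum(m, freqs = freqs)
  avg <- apply(tp$values, c(1, 2, 3), mean)
  expect_gt(mean(avg[2, 1, theta]), mean(avg[1, 2, theta]))
  expect_gt(mean(avg[2, 1, theta]), mean(avg[2, 1, freqs >= 20]))
})

test_that("band/window summaries average the requested index set", {
  set.seed(46)
  X <- matrix(rnorm(1000), 500, 2)
  m <- fit_dekf_mvar(X, order = 1, fs = 250)
  tp <- tpdc_spectrum(m, freqs = seq(2, 20, by = 2))
  sm <- band_window_summary(tp, c(4, 8), window_samples = 200:300)
  fsel <- tp$freqs >= 4 & tp$freqs <= 8
  tsel <- tp$times %in% 200:300
  for (k in seq_len(nrow(sm))) {
    expect_equal(sm$value[k],
                 mean(tp$values[sm$target[k], sm$source[k], fsel, tsel]),
                 tolerance = 1e-12)
  }
  expect_error(band_window_summary(tp, c(30, 40)), "empty")
  # constant array summarises to that constant
  tp2 <- tp; tp2$values[] <- 0.25
  sm2 <- band_window_summary(tp2, c(4, 8))
  expect_equal(sm2$value, rep(0.25, 2))
})

test_that("theta-coupled model summarises stronger in theta than alpha", {
  a <- threatnets:::ar2_coefs(6, 0.9, 250)
  A1 <- rbind(c(a[1], 0), c(0.5, a[1]))
  A2 <- rbind(c(a[2], 0), c(0, a[2]))
  X <- simulate_mvar(list(A1, A2), 1500, seed = 47)
  m <- fit_dekf_mvar(X, order = 2, fs = 250)
  tp <- tpdc_spectrum(m, freqs = seq(2, 20, by = 0.5))
  th <- band_window_summary(tp, "theta")
  al <- band_window_summary(tp, "alpha")
  i_xy <- which(th$source == 1 & th$target == 2)
  expect_gt(th$value[i_xy], al$value[i_xy])
})

test_that("time reversal is an involution and alpha resolution is enforced", {
  X <- simulate_mvar(coupled_bivar(0.5), 300, seed = 48)
  Xr <- X[nrow(X):1, ]
  Xrr <- Xr[nrow(Xr):1, ]
  expect_identical(X, Xrr)
  expect_error(time_reversal_surrogate_test(X, n_surrogates = 10), ">= 19")
  expect_error(time_reversal_surrogate_test(X, n_surrogates = 50,
                                            alpha = 0.001),
               "resolution")
})

test_that("surrogate test detects a planted coupling with correct orientation", {
  X <- simulate_mvar(coupled_bivar(0.5), 400, seed = 49)
  r <- time_reversal_surrogate_test(X, order = 2, freqs = seq(2, 45, by = 2),
                                    fs = 250, n_surrogates = 60,
                                    alpha = 0.05, seed = 1)
  expect_true(r$significant[2, 1])    # x -> y flagged
  expect_false(r$significant[1, 2])   # reverse direction not flagged
  cd <- classify_directionality(r$significant)
  expect_equal(cd$class, "uni")
  expect_equal(cd$from, 1); expect_equal(cd$to, 2)
})

test_that("directionality classification covers the full truth table", {
  states <- expand.grid(ij = c(FALSE, TRUE), ji = c(FALSE, TRUE))
  for (k in seq_len(nrow(states))) {
    sig <- matrix(FALSE, 2, 2)
    sig[2, 1] <- states$ij[k]   # 1 -> 2
    sig[1, 2] <- states$ji[k]   # 2 -> 1
    cd <- classify_directionality(sig)
    expected <- if (states$ij[k] && states$ji[k]) "bi"
      else if (states$ij[k] || states$ji[k]) "uni" else "none"
    expect_equal(cd$class, expected)
    if (cd$class == "uni") {
      if (states$ij[k]) expect_equal(c(cd$from, cd$to), c(1, 2))
      else expect_equal(c(cd$from, cd$to), c(2, 1))
    }
  }
})

test_that("order selection identifies the generating lag order", {
  a <- threatnets:::ar2_coefs(8, 0.85, 250)
  A1 <- rbind(c(a[1], 0), c(0.3, a[1]))
  A2 <- rbind(c(a[2], 0), c(0, a[2]))
  X <- simulate_mvar(list(A1, A2), 2000, seed = 50)
  expect_equal(select_order(X, orders = 1:6), 2)
})
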