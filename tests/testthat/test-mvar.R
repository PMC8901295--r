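test_that("Burg recovers AR coefficients from simulated data", {
  # AR(2) with known coefficients, unit innovation variance, n = 4000
  true <- ar_model(2, c(0.6, -0.3), 1)
  m <- mvar_model(list(matrix(0.6), matrix(-0.3)), matrix(1), fs = 1)
  x <- drop(simulate_mvar(m, 4000, seed = 101))
  fit <- fit_ar_burg(x, 2)
  expect_lt(max(abs(fit$coeffs - true$coeffs)), 0.05)
  expect_lt(abs(fit$noise_var - 1), 0.1)
  # white noise: AR(1) coefficient near zero, variance near truth
  w <- withr::with_seed(7, rnorm(4000, sd = 2))
  fw <- fit_ar_burg(w, 1)
  expect_lt(abs(fw$coeffs[1]), 0.1)
  expect_lt(abs(fw$noise_var - 4) / 4, 0.1)
})

test_that("forward least-squares AR recovers a noise-free AR(1) exactly", {
  # x(n) = 0.9 x(n-1), no innovations: the forward one-step regression is
  # solved exactly by the generating coefficient
  x <- 0.9^(0:199)
  fit <- fit_ar_ls(x, 1, demean = FALSE)
  expect_lt(abs(fit$coeffs[1] - 0.9), 1e-6)
})

test_that("degenerate and too-short inputs are rejected", {
  expect_error(fit_ar_burg(rep(1, 100), 2), "constant|degenerate")
  expect_error(fit_ar_burg(rnorm(8), 4), "too short")
  expect_error(fit_mvar(matrix(rnorm(20), 2), order = 5), "too short")
  # duplicated channel makes the regressor rank-deficient
  x <- matrix(rnorm(200), 1)
  expect_error(fit_mvar(rbind(x, x), order = 2), "singular.*lower")
})

test_that("least-squares MVAR recovers a known stable 3-channel MVAR(2)", {
  m <- random_stable_mvar(3, 2, seed = 20)
  x <- simulate_mvar(m, 5000, seed = 21)
  for (method in c("ls", "burg")) {
    fit <- fit_mvar(x, 2, method = method, fs = m$fs)
    err <- max(mapply(function(a, b) max(abs(a - b)),
                      fit$coeff_mats, m$coeff_mats))
    expect_lt(err, 0.05)
  }
  # independent white-noise channels: all coefficients near zero
  w <- withr::with_seed(5, matrix(rnorm(2 * 5000), 2))
  fw <- fit_mvar(w, 1)
  expect_lt(max(abs(fw$coeff_mats[[1]])), 0.05)
})

test_that("MVAR fit is self-consistent under re-simulation", {
  m <- random_stable_mvar(3, 2, seed = 33)
  x <- simulate_mvar(m, 5000, seed = 34)
  fit1 <- fit_mvar(x, 2, fs = m$fs)
  x2 <- simulate_mvar(fit1, 5000, seed = 35)
  fit2 <- fit_mvar(x2, 2, fs = m$fs)
  err <- max(mapply(function(a, b) max(abs(a - b)),
                    fit1$coeff_mats, fit2$coeff_mats))
  expect_lt(err, 0.1)
})

test_that("MVAR least-squares residuals are orthogonal to the regressors", {
  m <- random_stable_mvar(2, 2, seed = 44)
  x <- simulate_mvar(m, 1000, seed = 45)
  x <- x - rowMeans(x)
  fit <- fit_mvar(x, 2, demean = FALSE)
  n <- ncol(x); p <- 2
  tt <- (p + 1):n
  Z <- cbind(t(x[, tt - 1]), t(x[, tt - 2]))
  pred <- Z %*% rbind(t(fit$coeff_mats[[1]]), t(fit$coeff_mats[[2]]))
  resid <- t(x[, tt]) - pred
  rel <- max(abs(crossprod(Z, resid))) / (max(abs(Z)) * max(abs(resid)) * n)
  expect_lt(rel, 1e-6)
})

test_that("for one channel the MVAR and univariate least-squares fits coincide", {
  x <- drop(simulate_mvar(
    mvar_model(list(matrix(0.7)), matrix(1), fs = 1), 800, seed = 9))
  uv <- fit_ar_ls(x, 3)
  mv <- fit_mvar(matrix(x, 1), 3)
  expect_equal(vapply(mv$coeff_mats, function(L) L[1, 1], 1), uv$coeffs,
               tolerance = 1e-10)
})

test_that("coefficient recovery error shrinks with sample size", {
  errs <- sapply(1:20, function(s) {
    m <- random_stable_mvar(2, 1, seed = 400 + s)
    err_at <- function(n) {
      fit <- fit_mvar(simulate_mvar(m, n, seed = 900 + s), 1)
      max(abs(fit$coeff_mats[[1]] - m$coeff_mats[[1]]))
    }
    c(err_at(1000), err_at(10000))
  })
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})

test_that("AIC selects the generating order and its curve behaves", {
  hits <- vapply(1:50, function(s) {
    m <- random_stable_mvar(2, 3, seed = 6000 + s, scale = 0.6)
    x <- simulate_mvar(m, 5000, seed = 7000 + s)
    sel <- select_order_aic(x, p_max = 10)
    sel$order == 3L
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  # on one replicate the AIC curve is finite and the residual determinant
  # non-increasing in order
  m <- random_stable_mvar(2, 3, seed = 6001, scale = 0.6)
  x <- simulate_mvar(m, 5000, seed = 7001)
  sel <- select_order_aic(x, p_max = 10)
  expect_true(all(is.finite(sel$aic$aic)))
  logdet <- (sel$aic$aic - 2 * sel$aic$order * 4) / sel$n_eff
  expect_true(all(diff(logdet) <= 1e-10))

  # white noise favours the smallest candidate order
  wsel <- vapply(1:10, function(s) {
    w <- withr::with_seed(800 + s, matrix(rnorm(2 * 2000), 2))
    select_order_aic(w, p_max = 5)$order
  }, 1L)
  expect_identical(sort(table(wsel), decreasing = TRUE)[[1]],
                   sum(wsel == 1L))
  # single candidate
  expect_identical(select_order_aic(matrix(rnorm(400), 2), p_max = 1)$order, 1L)
})

test_that("mvar_model validates its invariants and serializes losslessly", {
  expect_error(mvar_model(list(matrix(c(1, 2, 3, 4), 2),
                               matrix(0, 3, 3)), diag(2), 500),
               "N x N")
  bad_cov <- matrix(c(1, 0.9, 0.2, 1), 2)
  expect_error(mvar_model(list(diag(0.5, 2)), bad_cov, 500), "symmetric")
  expect_error(mvar_model(list(diag(0.5, 2)),
                          matrix(c(1, 2, 2, 1), 2), 500),
               "semi-definite")

  m <- random_stable_mvar(3, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_mvar_model(m, path)
  back <- read_mvar_model(path)
  expect_equal(back$coeff_mats, m$coeff_mats, tolerance = 1e-15)
  expect_equal(back$noise_cov, m$noise_cov, tolerance = 1e-15)
  expect_identical(back$order, m$order)
  expect_identical(back$channel_labels, m$channel_labels)
})
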