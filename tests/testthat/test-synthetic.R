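test_that("simulate_mvar matches white-noise and AR(1) closed forms", {
  # zero coefficients, identity noise: sample covariance near identity
  m0 <- mvar_model(list(matrix(0, 2, 2)), diag(2), fs = 500)
  x <- simulate_mvar(m0, 20000, seed = 1)
  expect_lt(max(abs(tcrossprod(x) / ncol(x) - diag(2))), 0.05)
  # AR(1) with a = 0.9: lag-1 autocorrelation equals a
  m1 <- mvar_model(list(matrix(0.9)), matrix(1), fs = 500)
  y <- drop(simulate_mvar(m1, 20000, seed = 2))
  rho1 <- cor(y[-1], y[-length(y)])
  expect_lt(abs(rho1 - 0.9), 0.03)
  # determinism
  expect_identical(simulate_mvar(m1, 500, seed = 7),
                   simulate_mvar(m1, 500, seed = 7))
  # instability is refused before simulation
  bad <- structure(list(order = 1L, n_channels = 1L,
                        coeff_mats = list(matrix(1.05)), noise_cov = matrix(1),
                        fs = 500, channel_labels = "x"),
                   class = "mvar_model")
  expect_error(simulate_mvar(bad, 100, seed = 1), "unstable")
})

test_that("two-class trial sets have the declared shape and analytic ground truth", {
  spec <- sim_spec(n_channels = 10, seed = 42)
  sim <- make_two_class_trialset(spec)
  expect_identical(dim(sim$trialset$data), c(80L, 10L, 3000L))   # 40+40, 6 s @ 500 Hz
  expect_identical(sum(sim$trialset$class_labels == 1), 40L)
  expect_equal(sim$trialset$epoch_window, c(3, 9))

  # ground-truth DTFs differ exactly on the designed directed pairs
  labs <- spec$channel_labels
  g_pos <- sim$truth$pos$gamma2[[3]]     # 20 Hz
  g_neg <- sim$truth$neg$gamma2[[3]]
  i <- function(l) which(labs == l)
  expect_gt(g_pos[i("C4"), i("C3")], g_neg[i("C4"), i("C3")])   # C3->C4 only in +1
  expect_gt(g_neg[i("FC1"), i("C3")], g_pos[i("FC1"), i("C3")]) # C3->FC1 only in -1
  # channels outside every quad are identical between the class templates
  for (ch in c("FC2", "FC6"))
    expect_equal(g_pos[i(ch), ], g_neg[i(ch), ])

  # full reproducibility from spec + seed
  sim2 <- make_two_class_trialset(sim_spec(n_channels = 10, seed = 42))
  expect_identical(sim2$trialset$data, sim$trialset$data)
})

test_that("per-channel univariate spectra are class-invariant by construction", {
  # the quad wiring gives every channel the same self terms and the same
  # total inflow in both classes, so the univariate spectrum of each
  # channel is identical across class templates
  spec <- sim_spec(n_channels = 10, seed = 13, n_trials_per_class = 8,
                   trial_seconds = 3)
  tmpl <- sim_templates(spec)
  for (k in 1:2)
    expect_identical(diag(tmpl$pos$coeff_mats[[k]]),
                     diag(tmpl$neg$coeff_mats[[k]]))
  in_w_pos <- rowSums(tmpl$pos$coeff_mats[[1]]) - diag(tmpl$pos$coeff_mats[[1]])
  in_w_neg <- rowSums(tmpl$neg$coeff_mats[[1]]) - diag(tmpl$neg$coeff_mats[[1]])
  expect_identical(in_w_pos, in_w_neg)

  # empirically: Burg AR features of each channel do not separate classes
  sim <- make_two_class_trialset(spec)
  ft <- ar_features(sim$trialset, order = 4)
  pvals <- apply(ft$X, 2, function(v)
    wilcox.test(v[ft$class_labels == 1], v[ft$class_labels == -1])$p.value)
  expect_gt(min(p.adjust(pvals, "bonferroni")), 0.01)
})

test_that("fitted DTF recovers the analytic template DTF (median err < 0.1)", {
  spec <- sim_spec(n_channels = 10, seed = 77, n_trials_per_class = 6)
  sim <- make_two_class_trialset(spec)
  ts <- sim$trialset
  errs <- vapply(seq_len(n_trials(ts)), function(i) {
    truth <- if (ts$class_labels[i] > 0) sim$truth$pos else sim$truth$neg
    fit <- fit_mvar(ts$data[i, , ], order = 2, fs = ts$fs)
    d <- dtf_matrix(fit, truth$freqs)
    max(vapply(seq_along(truth$freqs), function(k)
      max(abs(d$gamma2[[k]] - truth$gamma2[[k]])), 1))
  }, 1)
  expect_lt(median(errs), 0.1)
})

test_that("class-blind channels yield indistinguishable DTF features", {
  spec <- sim_spec(n_channels = 10, seed = 19, n_trials_per_class = 20,
                   trial_seconds = 3)
  sim <- make_two_class_trialset(spec)
  ft <- dtf_features(sim$trialset, freqs = 20, mvar_order = 2)
  # directed pairs entirely within the untouched channels
  blind <- c("FC2", "FC6")
  keep <- ft$feature_names %in%
    paste0("dtf20:", c("FC2->FC6", "FC6->FC2"))
  expect_identical(sum(keep), 2L)
  pv <- apply(ft$X[, keep, drop = FALSE], 2, function(v)
    wilcox.test(v[ft$class_labels == 1], v[ft$class_labels == -1])$p.value)
  expect_gt(min(p.adjust(pv, "bonferroni")), 0.01)
})

test_that("simulation specs validate and read from YAML", {
  expect_error(sim_spec(n_channels = 10), "seed")
  expect_error(sim_spec(n_channels = 10, fs = -1, seed = 1), "positive")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_channels: 10", "n_trials_per_class: 5",
               "trial_seconds: 2", "seed: 3"), path)
  spec <- read_sim_spec(path)
  expect_s3_class(spec, "sim_spec")
  expect_identical(spec$n_trials_per_class, 5L)
  writeLines(c("n_channels: 10", "seed: 3", "typo_key: 1"), path)
  expect_error(read_sim_spec(path), "typo_key")
})
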