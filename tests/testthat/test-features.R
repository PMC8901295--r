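sim10 <- function(seed = 1, n_per_class = 6, secs = 2, ...)
  make_two_class_trialset(sim_spec(n_channels = 10, seed = seed,
                                   n_trials_per_class = n_per_class,
                                   trial_seconds = secs, ...))$trialset

test_that("ar_features has N*p columns in channel-major order and is deterministic", {
  ts <- sim10()
  ft <- ar_features(ts, order = 6)
  expect_identical(ncol(ft$X), 10L * 6L)
  expect_identical(ft$feature_names[1:6], paste0("ar:F3:a", 1:6))
  expect_identical(ft$feature_names[7], "ar:F4:a1")

  ts2 <- select_channels(ts, "pair2")
  ft2 <- ar_features(ts2, order = 6)
  expect_identical(ncol(ft2$X), 12L)
  expect_identical(ft2$feature_names,
                   c(paste0("ar:C3:a", 1:6), paste0("ar:C4:a", 1:6)))

  # duplicated trials give identical rows (pure per-trial determinism)
  dup <- trialset(ts$data[c(1, 1), , , drop = FALSE], ts$fs,
                  ts$channel_labels, c(1L, 1L))
  fd <- ar_features(dup, order = 4)
  expect_identical(fd$X[1, ], fd$X[2, ])
})

test_that("dtf_features dimensionality follows |freqs| * N * (N-1)", {
  ts <- sim10()
  ft30 <- dtf_features(ts, freqs = 30, mvar_order = 2)
  expect_identical(ncol(ft30$X), 90L)                      # 10 * 9
  expect_true(all(grepl("^dtf30:", ft30$feature_names)))
  ft2 <- dtf_features(ts, freqs = c(20, 30), mvar_order = 2)
  expect_identical(ncol(ft2$X), 180L)
  # with the diagonal included: |freqs| * N^2
  ftd <- dtf_features(ts, freqs = 30, mvar_order = 2, include_diagonal = TRUE)
  expect_identical(ncol(ftd$X), 100L)
  # frequencies above Nyquist rejected
  expect_error(dtf_features(ts, freqs = 400, mvar_order = 2), "Nyquist")
})

test_that("class-dependent coupling separates the designed DTF features", {
  # class +1 routes C3 -> C4; class -1 routes C3 -> FC1 instead
  ts <- sim10(seed = 3, n_per_class = 10, secs = 3)
  ft <- dtf_features(ts, freqs = 20, mvar_order = 2)
  v <- ft$X[, ft$feature_names == "dtf20:C3->C4"]
  expect_gt(mean(v[ft$class_labels == 1]), mean(v[ft$class_labels == -1]))
  # and the designed edges dominate within/between-class geometry
  keep <- ft$feature_names %in% c("dtf20:C3->C4", "dtf20:C3->FC1")
  mu_pos <- colMeans(ft$X[ft$class_labels == 1, keep])
  mu_neg <- colMeans(ft$X[ft$class_labels == -1, keep])
  within <- mean(apply(ft$X[ft$class_labels == 1, keep], 1,
                       function(r) sqrt(sum((r - mu_pos)^2))))
  between <- sqrt(sum((mu_pos - mu_neg)^2))
  expect_gt(between, within)
})

test_that("permuting trials permutes feature rows identically", {
  ts <- sim10(seed = 9, n_per_class = 4)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  tsp <- trialset(ts$data[perm, , , drop = FALSE], ts$fs, ts$channel_labels,
                  ts$class_labels[perm])
  for (fn in list(function(t) ar_features(t, 4),
                  function(t) dtf_features(t, 30, mvar_order = 2))) {
    a <- fn(ts); b <- fn(tsp)
    expect_identical(b$X, a$X[perm, , drop = FALSE])
  }
})

test_that("fuse_features concatenates, preserves order, and validates alignment", {
  ts <- sim10(seed = 2)
  a <- ar_features(ts, 6)
  b <- dtf_features(ts, 30, mvar_order = 2)
  f <- fuse_features(a, b)
  expect_identical(ncol(f$X), 150L)                        # 60 + 90
  expect_identical(f$provenance$kind, "fused")
  # slicing back recovers both parts exactly
  expect_identical(f$X[, seq_len(60)], a$X)
  expect_identical(f$X[, 61:150], b$X)
  # empty second table is an identity
  empty <- feature_table(matrix(0, nrow(a$X), 0), character(0),
                         a$class_labels)
  expect_identical(fuse_features(a, empty)$X, a$X)
  # misalignment errors
  b_bad <- b; b_bad$class_labels <- rev(b$class_labels)
  expect_error(fuse_features(a, b_bad), "labels differ")
  expect_error(fuse_features(a, a), "duplicated feature names")
})

test_that("standardization yields zero mean / unit sd and reuses training stats", {
  ts <- sim10(seed = 4)
  ft <- ar_features(ts, 4)
  std <- standardize_features(ft)
  expect_lt(max(abs(colMeans(std$table$X))), 1e-9)
  expect_lt(max(abs(apply(std$table$X, 2, sd) - 1)), 1e-9)
  # applying the same stats to a copy of the data reproduces the result
  again <- standardize_features(ft, std$stats)
  expect_identical(again$table$X, std$table$X)
  # constant column: zero output plus a warning
  ft2 <- feature_table(cbind(ft$X, k = 5), c(ft$feature_names, "k"),
                       ft$class_labels)
  expect_warning(s2 <- standardize_features(ft2), "zero-variance")
  expect_true(all(s2$table$X[, "k"] == 0))
  expect_error(standardize_features(ft, list(mean = 0, scale = 1)),
               "dimensionality")
})

test_that("feature tables round-trip through delimited text", {
  ts <- sim10(seed = 6)
  ft <- dtf_features(ts, c(10, 30), mvar_order = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(back$feature_names, ft$feature_names)
  expect_identical(back$class_labels, ft$class_labels)
  expect_lt(max(abs(back$X - ft$X)), 1e-12)
})
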