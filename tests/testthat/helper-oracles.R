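# Independent oracles and fixture builders, all generated in code.

# --- brute-force DTF oracle (N <= 3): builds A(f) elementwise and inverts
# by cofactors, never through solve() ---------------------------------------

cofactor_inverse <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(matrix(1 / A[1, 1], 1, 1))
  det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (n == 2L) {
    return(matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) / det2(A))
  }
  stopifnot(n == 3L)
  detA <- A[1, 1] * (A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2]) -
          A[1, 2] * (A[2, 1] * A[3, 3] - A[2, 3] * A[3, 1]) +
          A[1, 3] * (A[2, 1] * A[3, 2] - A[2, 2] * A[3, 1])
  C <- matrix(0i, 3, 3)
  for (i in 1:3) for (j in 1:3)
    C[i, j] <- (-1)^(i + j) * det2(A[-i, -j, drop = FALSE])
  t(C) / detA
}

dtf_bruteforce <- function(model, freqs) {
  N <- model$n_channels
  lapply(freqs, function(f) {
    A <- matrix(0i, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      a <- if (i == j) 1 + 0i else 0 + 0i
      for (k in seq_len(model$order))
        a <- a - model$coeff_mats[[k]][i, j] * exp(-2i * pi * f * k / model$fs)
      A[i, j] <- a
    }
    H <- cofactor_inverse(A)
    P <- Mod(H)^2
    P / rowSums(P)
  })
}

# --- random stable MVAR models ---------------------------------------------

random_stable_mvar <- function(n_channels, order, seed, fs = 500,
                               scale = 0.5) {
  withr::with_seed(seed, {
    repeat {
      cm <- replicate(order,
                      matrix(rnorm(n_channels^2, sd = scale / sqrt(order)),
                             n_channels, n_channels),
                      simplify = FALSE)
      m <- mvar_model(cm, diag(n_channels), fs = fs)
      if (is_stable(m)) return(m)
      scale <- scale * 0.8
    }
  })
}

# --- small trial-set fixture ------------------------------------------------

tiny_trialset <- function(n_trials = 3, n_channels = 2, n_samples = 10,
                          seed = 42, labels = NULL) {
  if (is.null(labels)) labels <- c("C3", "C4", "Cz", "Pz")[seq_len(n_channels)]
  x <- withr::with_seed(seed,
    array(rnorm(n_trials * n_channels * n_samples),
          dim = c(n_trials, n_channels, n_samples)))
  trialset(x, fs = 500, channel_labels = labels,
           class_labels = rep_len(c(-1L, 1L), n_trials))
}

# --- analytic magnitude response of a Butterworth band-pass -----------------
# |H(f)|^2 for an order-n band-pass designed from an analog prototype is
# 1 / (1 + (W/BW)^(2n)) with W the warped detuning; for the RMS checks we
# only need the designed digital filter's own frequency response, computed
# from its coefficients (independent of filtfilt).

butter_gain <- function(low_hz, high_hz, order, fs, f) {
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs)
    Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
        sum(bf$a * z^(seq_along(bf$a) - 1)))
  }, 1)
}
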