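#' Univariate autoregressive model
#'
#' Container for an all-pole AR(p) model in the regression convention
#' `x(n) = sum_k a_k x(n-k) + e(n)` with innovation variance `sigma^2`.
#' (The equivalent difference-equation form with a leading minus sign on the
#' coefficient sum differs only by the sign of every `a_k`; one convention
#' must rule the code and the positive regression form is used throughout.)
#'
#' @param order model order `p` (positive integer).
#' @param coeffs numeric vector `a_1..a_p`.
#' @param noise_var innovation variance `sigma^2` (> 0).
#' @return an object of class `"ar_model"`.
#' @export
ar_model <- function(order, coeffs, noise_var) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (length(coeffs) != order) stop("length(coeffs) must equal order", call. = FALSE)
  if (!all(is.finite(coeffs))) stop("coefficients must be finite", call. = FALSE)
  if (!is.finite(noise_var) || noise_var <= 0)
    stop("noise_var must be positive and finite", call. = FALSE)
  structure(list(order = order, coeffs = as.numeric(coeffs),
                 noise_var = as.numeric(noise_var)),
            class = "ar_model")
}

#' Fit a univariate AR model with the Burg algorithm
#'
#' Burg's reflection-coefficient recursion minimises the summed forward and
#' backward prediction-error power; it works well on short records, which is
#' why it is the standard choice for per-trial EEG parameter features. The
#' series is demeaned before fitting. `noise_var` is the final prediction
#' error power of the recursion.
#'
#' @param x numeric vector, the signal (length > 2 * order).
#' @param order AR order `p`.
#' @return an [ar_model()] in the positive regression convention.
#' @export
fit_ar_burg <- function(x, order) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  if (length(x) <= 2L * order)
    stop(sprintf("series too short for Burg at order %d (need > %d samples, have %d)",
                 order, 2L * order, length(x)), call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate input: constant series has no AR representation", call. = FALSE)
  fit <- stats::ar.burg(x - mean(x), aic = FALSE, order.max = order,
                        demean = FALSE)
  ar_model(order, as.numeric(fit$ar), as.numeric(fit$var.pred))
}

#' Fit a univariate AR model by (forward) least squares
#'
#' Ordinary least squares on the lagged regression
#' `x(n) ~ x(n-1) + ... + x(n-p)`, `n = p+1..N`. Unlike Burg this recovers
#' the generating coefficients exactly in the noise-free limit.
#'
#' @inheritParams fit_ar_burg
#' @param demean remove the series mean first (default `TRUE`).
#' @return an [ar_model()].
#' @export
fit_ar_ls <- function(x, order, demean = TRUE) {
  m <- fit_mvar(matrix(x, nrow = 1), order = order, demean = demean)
  ar_model(order, vapply(m$coeff_mats, function(L) L[1, 1], 1),
           m$noise_cov[1, 1])
}

## ---------------------------------------------------------------------------
## MVAR

#' Multivariate autoregressive model
#'
#' Container for `S(t) = sum_{k=1..p} Lambda_k S(t-k) + E(t)` with `N x N`
#' coefficient matrices `Lambda_k` and innovation covariance `noise_cov`.
#' The sampling rate is carried so the model can be evaluated at physical
#' frequencies.
#'
#' @param coeff_mats list of `p` numeric `N x N` matrices `Lambda_1..Lambda_p`.
#' @param noise_cov `N x N` symmetric positive-semidefinite matrix.
#' @param fs sampling rate in Hz.
#' @param channel_labels optional channel names (default `ch1..chN`).
#' @return an object of class `"mvar_model"` with fields `order`,
#'   `n_channels`, `coeff_mats`, `noise_cov`, `fs`, `channel_labels`.
#' @export
mvar_model <- function(coeff_mats, noise_cov, fs, channel_labels = NULL) {
  if (!is.list(coeff_mats) || length(coeff_mats) < 1L)
    stop("coeff_mats must be a non-empty list of N x N matrices", call. = FALSE)
  N <- nrow(coeff_mats[[1]])
  for (L in coeff_mats) {
    if (!is.matrix(L) || any(dim(L) != N) || !all(is.finite(L)))
      stop("every coefficient matrix must be a finite N x N matrix", call. = FALSE)
  }
  noise_cov <- as.matrix(noise_cov)
  if (any(dim(noise_cov) != N))
    stop("noise_cov must be N x N", call. = FALSE)
  sym_dev <- max(abs(noise_cov - t(noise_cov)))
  if (sym_dev > 1e-8 * max(1, max(abs(noise_cov))))
    stop("noise_cov must be symmetric", call. = FALSE)
  noise_cov <- (noise_cov + t(noise_cov)) / 2
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("noise_cov must be positive semi-definite", call. = FALSE)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(N))
  if (length(channel_labels) != N)
    stop("channel_labels must have one entry per channel", call. = FALSE)
  structure(list(order = length(coeff_mats), n_channels = N,
                 coeff_mats = lapply(coeff_mats, function(m) {
                   storage.mode(m) <- "double"; unname(m)
                 }),
                 noise_cov = unname(noise_cov), fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels)),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channels @ %g Hz, %s\n",
              x$order, x$n_channels, x$fs,
              if (is_stable(x)) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Companion matrix of an MVAR model
#'
#' The `Np x Np` companion form whose spectral radius decides stability of
#' the stochastic recursion.
#'
#' @param model an [mvar_model()].
#' @return an `Np x Np` matrix.
#' @export
companion_matrix <- function(model) {
  N <- model$n_channels; p <- model$order
  C <- matrix(0, N * p, N * p)
  C[seq_len(N), ] <- do.call(cbind, model$coeff_mats)
  if (p > 1L)
    C[(N + 1):(N * p), seq_len(N * (p - 1))] <- diag(N * (p - 1))
  C
}

#' Is an MVAR model stable?
#'
#' @param model an [mvar_model()].
#' @return `TRUE` iff the companion-matrix spectral radius is < 1.
#' @export
is_stable <- function(model) {
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values)) < 1
}

# build stacked one-step regression for t in (p+1)..n (or a fixed window):
# Y rows = S(t)', Z rows = [S(t-1)', ..., S(t-p)']
.mvar_design <- function(x, p, t_start = p + 1L) {
  n <- ncol(x)
  tt <- t_start:n
  Y <- t(x[, tt, drop = FALSE])
  Z <- matrix(NA_real_, length(tt), nrow(x) * p)
  for (k in seq_len(p))
    Z[, ((k - 1) * nrow(x) + 1):(k * nrow(x))] <- t(x[, tt - k, drop = FALSE])
  list(Y = Y, Z = Z)
}

#' Fit a multivariate autoregressive model to one trial
#'
#' The default estimator is multichannel least squares: the coefficient
#' matrices minimise the one-step-ahead squared prediction error over
#' `t = p+1..n`, and `noise_cov` is the residual covariance with denominator
#' `n - p`. A multichannel Burg estimator (Vieira-Morf normalised
#' reflection coefficients) is available as an alternative; it is typically
#' preferable only for very short records. Channel means are removed before
#' fitting.
#'
#' @param x numeric matrix, channels x samples.
#' @param order MVAR order `p` (>= 1).
#' @param method `"ls"` (least squares, default) or `"burg"` (Vieira-Morf
#'   multichannel Burg).
#' @param fs sampling rate carried into the model (default 1; set it when
#'   the model will be evaluated at physical frequencies).
#' @param channel_labels optional channel names.
#' @param demean remove per-channel means first (default `TRUE`).
#' @return an [mvar_model()].
#' @export
fit_mvar <- function(x, order, method = c("ls", "burg"), fs = 1,
                     channel_labels = NULL, demean = TRUE) {
  method <- match.arg(method)
  if (!is.matrix(x)) stop("x must be a channels x samples matrix", call. = FALSE)
  p <- as.integer(order)
  if (p < 1L) stop("order must be >= 1", call. = FALSE)
  N <- nrow(x); n <- ncol(x)
  if (n <= N * p + 1L)
    stop(sprintf("trial too short: %d samples cannot support %d channels at order %d",
                 n, N, p), call. = FALSE)
  if (demean) x <- x - rowMeans(x)
  if (method == "ls") .fit_mvar_ls(x, p, fs, channel_labels)
  else .fit_mvar_vm(x, p, fs, channel_labels)
}

.fit_mvar_ls <- function(x, p, fs, channel_labels) {
  N <- nrow(x); n <- ncol(x)
  d <- .mvar_design(x, p)
  qr_z <- qr(d$Z)
  if (qr_z$rank < ncol(d$Z))
    stop(sprintf("singular MVAR fit (regressor rank %d < %d); try a lower order",
                 qr_z$rank, ncol(d$Z)), call. = FALSE)
  B <- qr.coef(qr_z, d$Y)                       # (N*p) x N
  resid <- d$Y - d$Z %*% B
  noise_cov <- crossprod(resid) / (n - p)
  coeff_mats <- lapply(seq_len(p), function(k)
    t(B[((k - 1) * N + 1):(k * N), , drop = FALSE]))
  mvar_model(coeff_mats, noise_cov, fs, channel_labels)
}

# Vieira-Morf multichannel Burg: normalised partial-correlation recursion.
.fit_mvar_vm <- function(x, p, fs, channel_labels) {
  N <- nrow(x); n <- ncol(x)
  f <- x; b <- x                                # forward / backward residuals
  A <- list(); Psi <- list()                    # forward / backward coeffs
  lchol <- function(M) {
    M <- (M + t(M)) / 2
    t(chol(M + diag(1e-12 * max(diag(M)), N)))
  }
  for (m in seq_len(p)) {
    tt <- (m + 1):n
    Fm <- f[, tt, drop = FALSE]
    Bm <- b[, tt - 1L, drop = FALSE]
    Pf <- tcrossprod(Fm); Pb <- tcrossprod(Bm); Pfb <- Fm %*% t(Bm)
    Lf <- lchol(Pf); Lb <- lchol(Pb)
    Rho <- forwardsolve(Lf, Pfb)
    Rho <- t(forwardsolve(Lb, t(Rho)))
    Am <- Lf %*% Rho %*% solve(Lb)              # reflection: f - Am b(t-1)
    Bcf <- Lb %*% t(Rho) %*% solve(Lf)
    A_new <- vector("list", m); Psi_new <- vector("list", m)
    A_new[[m]] <- Am; Psi_new[[m]] <- Bcf
    if (m > 1L) for (k in seq_len(m - 1L)) {
      A_new[[k]] <- A[[k]] - Am %*% Psi[[m - k]]
      Psi_new[[k]] <- Psi[[k]] - Bcf %*% A[[m - k]]
    }
    A <- A_new; Psi <- Psi_new
    f_new <- f; b_new <- b
    f_new[, tt] <- f[, tt, drop = FALSE] - Am %*% b[, tt - 1L, drop = FALSE]
    b_new[, tt] <- b[, tt - 1L, drop = FALSE] - Bcf %*% f[, tt, drop = FALSE]
    f <- f_new; b <- b_new
  }
  resid <- f[, (p + 1):n, drop = FALSE]
  noise_cov <- tcrossprod(resid) / (n - p)
  mvar_model(A, noise_cov, fs, channel_labels)
}

#' Select the MVAR order by the Akaike information criterion
#'
#' Fits every order `1..p_max` on a common sample window
#' (`t = p_max+1..n` in each trial, so residual counts are comparable) and
#' returns the minimiser of
#' `AIC(p) = n_eff * log(det(noise_cov_p)) + 2 * p * N^2`,
#' where `n_eff` is the total number of regression rows and `2 p N^2`
#' penalises the free coefficients. Ties break toward the smaller order.
#'
#' @param x a [trialset()] (all trials pooled) or a channels x samples matrix.
#' @param p_max largest candidate order (default 20).
#' @param method passed to [fit_mvar()].
#' @return a list with `order` (selected p), `aic` (data frame of per-order
#'   AIC values) and `n_eff`.
#' @export
select_order_aic <- function(x, p_max = 20L, method = c("ls", "burg")) {
  method <- match.arg(method)
  p_max <- as.integer(p_max)
  if (p_max < 1L) stop("p_max must be >= 1", call. = FALSE)
  trials <- if (inherits(x, "trialset")) {
    lapply(seq_len(n_trials(x)), function(i) {
      m <- x$data[i, , , drop = TRUE]
      if (n_channels(x) == 1L) m <- matrix(m, nrow = 1L)
      m - rowMeans(m)
    })
  } else list(x - rowMeans(x))
  N <- nrow(trials[[1]]); n <- ncol(trials[[1]])
  if (n <= N * p_max + 1L)
    stop("data too short for p_max = ", p_max, call. = FALSE)

  aic <- rep(NA_real_, p_max)
  n_eff <- length(trials) * (n - p_max)
  for (p in seq_len(p_max)) {
    ds <- lapply(trials, .mvar_design, p = p, t_start = p_max + 1L)
    Y <- do.call(rbind, lapply(ds, `[[`, "Y"))
    Z <- do.call(rbind, lapply(ds, `[[`, "Z"))
    qr_z <- qr(Z)
    if (qr_z$rank < ncol(Z)) next               # singular at this order
    resid <- Y - Z %*% qr.coef(qr_z, Y)
    sigma <- crossprod(resid) / n_eff
    ld <- determinant(sigma, logarithm = TRUE)
    if (ld$sign <= 0) next
    aic[p] <- n_eff * as.numeric(ld$modulus) + 2 * p * N^2
  }
  if (all(is.na(aic)))
    stop("order selection failed: every candidate fit was singular", call. = FALSE)
  list(order = which.min(aic), aic = data.frame(order = seq_len(p_max), aic = aic),
       n_eff = n_eff)
}

## ---------------------------------------------------------------------------
## Serialization for fixture reuse

#' Write / read an MVAR model as a JSON document
#'
#' Coefficient matrices are stored row-major; round trip preserves values to
#' full double precision.
#'
#' @param model an [mvar_model()].
#' @param path output (input) file path.
#' @return `path` invisibly (`write_mvar_model`); an [mvar_model()]
#'   (`read_mvar_model`).
#' @export
write_mvar_model <- function(model, path) {
  obj <- list(order = model$order, n_channels = model$n_channels,
              coeff_mats = lapply(model$coeff_mats, function(m)
                as.vector(t(m))),
              noise_cov = as.vector(t(model$noise_cov)),
              fs = model$fs, channel_labels = model$channel_labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mvar_model
#' @export
read_mvar_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- obj$n_channels
  cm <- lapply(seq_len(obj$order), function(k) {
    v <- if (is.list(obj$coeff_mats)) obj$coeff_mats[[k]] else obj$coeff_mats[k, ]
    matrix(as.numeric(v), N, N, byrow = TRUE)
  })
  mvar_model(cm, matrix(as.numeric(obj$noise_cov), N, N, byrow = TRUE),
             obj$fs, obj$channel_labels)
}
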