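#' Simulate a multichannel signal from an MVAR model
#'
#' Iterates `S(t) = sum_k Lambda_k S(t-k) + E(t)` from zero initial
#' conditions with Gaussian innovations drawn from the model's
#' `noise_cov`, discarding a burn-in transient. Deterministic for a given
#' seed.
#'
#' @param model a stable [mvar_model()].
#' @param n_samples number of samples to return.
#' @param seed integer seed.
#' @param burn_in transient samples discarded (default 500).
#' @return numeric matrix, channels x `n_samples`.
#' @export
simulate_mvar <- function(model, n_samples, seed, burn_in = 500L) {
  stopifnot(inherits(model, "mvar_model"))
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (!is_stable(model))
    stop("model is unstable (companion spectral radius >= 1); refusing to simulate",
         call. = FALSE)
  N <- model$n_channels; p <- model$order
  n_tot <- n_samples + burn_in + p
  L <- t(chol(model$noise_cov + diag(1e-14, N)))
  E <- withr::with_seed(seed, L %*% matrix(stats::rnorm(N * n_tot), N, n_tot))
  x <- matrix(0, N, n_tot)
  cm <- model$coeff_mats
  for (t in (p + 1):n_tot) {
    s <- E[, t]
    for (k in seq_len(p)) s <- s + cm[[k]] %*% x[, t - k]
    x[, t] <- s
  }
  x[, (burn_in + p + 1):n_tot, drop = FALSE]
}

## ---------------------------------------------------------------------------
## Two-class templates

# diagonal AR(2) resonance block: pole radius rho at frequency f0
.resonant_ar2 <- function(f0, rho, fs) {
  c(2 * rho * cos(2 * pi * f0 / fs), -rho^2)
}

#' Build an MVAR template from per-channel resonances plus directed edges
#'
#' Every channel gets an AR(2) self-term with a spectral peak at its
#' `resonance_hz` (pole radius `rho`); each row of `edges`
#' (`from`, `to`, `lag`, `weight`) adds a directed coupling coefficient.
#' When the directed-edge graph is acyclic the companion eigenvalues are
#' exactly the per-channel pole pairs, so stability is inherited from
#' `rho < 1` whatever the coupling weights.
#'
#' @param channel_labels channel names.
#' @param edges data frame with columns `from`, `to` (channel names),
#'   `lag` (1-based), `weight`; `NULL` for no coupling.
#' @param resonance_hz per-channel peak frequency (recycled).
#' @param rho pole radius in (0, 1) (recycled).
#' @param fs sampling rate in Hz.
#' @param order model order (>= 2 and >= max lag).
#' @param noise_cov innovation covariance (default identity).
#' @return an [mvar_model()].
#' @export
mvar_template <- function(channel_labels, edges = NULL, resonance_hz = 20,
                          rho = 0.9, fs = 500, order = 2L,
                          noise_cov = NULL) {
  N <- length(channel_labels)
  resonance_hz <- rep_len(resonance_hz, N)
  rho <- rep_len(rho, N)
  order <- max(as.integer(order), 2L, if (!is.null(edges)) max(edges$lag) else 1L)
  cm <- replicate(order, matrix(0, N, N), simplify = FALSE)
  for (j in seq_len(N)) {
    a <- .resonant_ar2(resonance_hz[j], rho[j], fs)
    cm[[1]][j, j] <- a[1]
    cm[[2]][j, j] <- a[2]
  }
  if (!is.null(edges) && nrow(edges)) {
    fi <- .match_labels(edges$from, channel_labels)
    ti <- .match_labels(edges$to, channel_labels)
    for (r in seq_len(nrow(edges)))
      cm[[edges$lag[r]]][ti[r], fi[r]] <-
        cm[[edges$lag[r]]][ti[r], fi[r]] + edges$weight[r]
  }
  if (is.null(noise_cov)) noise_cov <- diag(N)
  mvar_model(cm, noise_cov, fs, channel_labels)
}

# class-dependent edge sets: "quad" wiring. Each quad has two source and two
# target channels; the classes differ only in which source feeds which
# target, so every channel's univariate spectrum is identical across
# classes while the directed connectivity differs.
.quad_edges <- function(quads, weight, class) {
  do.call(rbind, lapply(quads, function(q) {
    if (class > 0)
      data.frame(from = c(q[1], q[2]), to = c(q[3], q[4]),
                 lag = 1L, weight = weight, stringsAsFactors = FALSE)
    else
      data.frame(from = c(q[1], q[2]), to = c(q[4], q[3]),
                 lag = 1L, weight = weight, stringsAsFactors = FALSE)
  }))
}

# default quads per montage size; sources first, targets last
.default_quads <- function(n_channels) {
  base <- list(c("C3", "FC5", "C4", "FC1"),
               c("F3", "F4", "Fz", "Cz"))
  switch(as.character(n_channels),
         "10" = base,
         "32" = c(base, list(c("P3", "P7", "P4", "P8"),
                             c("O1", "PO9", "O2", "PO10"))),
         stop("no default coupling layout for ", n_channels,
              " channels; supply class_templates", call. = FALSE))
}

#' Specification of a synthetic two-class motor-imagery trial set
#'
#' Describes the generator that emulates a two-class (left/right) imagery
#' experiment: `n_trials_per_class` epochs per class, each
#' `trial_seconds` long at `fs` Hz over `n_channels` channels with
#' 10-20-system labels. Classes share identical per-channel spectral
#' colouring (an AR(2) resonance) and differ in their directed coupling:
#' channels are wired in "quads" of two sources and two targets, and the
#' two classes differ only in which source drives which target. This keeps
#' every univariate spectrum class-invariant — so single-channel AR
#' features carry no class signal — while the directed network differs
#' strongly. Setting `colour_contrast_hz > 0` additionally shifts the
#' resonance of the quad channels up (class +1) or down (class -1),
#' giving the AR features their own class signal for fusion experiments.
#'
#' @param n_channels 2, 10 or 32 for the built-in layouts (custom layouts
#'   via `class_templates`).
#' @param fs sampling rate in Hz (default 500).
#' @param trial_seconds epoch length in seconds (default 6, the 3-9 s
#'   imagery window).
#' @param n_trials_per_class trials per class (default 40).
#' @param edge_weight coupling coefficient of every class-dependent edge
#'   (default 0.5; the class contrast on a directed pair equals this
#'   weight).
#' @param resonance_hz shared per-channel spectral peak (default 20).
#' @param rho pole radius of the resonance (default 0.9).
#' @param colour_contrast_hz class-dependent resonance shift in Hz on the
#'   quad channels (default 0 = spectra identical across classes).
#' @param noise_cov innovation covariance (default identity).
#' @param class_templates optional list with elements `pos` and `neg`:
#'   either [mvar_model()]s or edge data frames (`from`, `to`, `lag`,
#'   `weight`) overriding the built-in quad wiring.
#' @param channel_labels optional explicit labels (default: built-in
#'   montage of size `n_channels`).
#' @param seed integer seed (mandatory).
#' @return an object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_channels = 10L, fs = 500, trial_seconds = 6,
                     n_trials_per_class = 40L, edge_weight = 0.5,
                     resonance_hz = 20, rho = 0.9, colour_contrast_hz = 0,
                     noise_cov = NULL, class_templates = NULL,
                     channel_labels = NULL, seed) {
  if (missing(seed)) stop("an explicit seed is mandatory", call. = FALSE)
  if (fs <= 0 || trial_seconds <= 0)
    stop("fs and trial_seconds must be positive", call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- switch(as.character(n_channels),
                             "2" = .montage_presets$pair2,
                             "10" = .montage_presets$motor10,
                             "32" = .montage_presets$full32,
                             paste0("ch", seq_len(n_channels)))
  }
  spec <- structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         trial_seconds = trial_seconds,
         n_trials_per_class = as.integer(n_trials_per_class),
         edge_weight = edge_weight, resonance_hz = resonance_hz, rho = rho,
         colour_contrast_hz = colour_contrast_hz,
         noise_cov = noise_cov, class_templates = class_templates,
         channel_labels = channel_labels, seed = as.integer(seed)),
    class = "sim_spec")
  tmpl <- sim_templates(spec)      # validates stability now
  for (cl in c("pos", "neg"))
    if (!is_stable(tmpl[[cl]]))
      stop("class template '", cl, "' is unstable", call. = FALSE)
  spec
}

#' Materialise the two class templates of a simulation spec
#'
#' @param spec a [sim_spec()].
#' @return list with [mvar_model()]s `pos` (class +1) and `neg` (class -1).
#' @export
sim_templates <- function(spec) {
  labs <- spec$channel_labels
  ct <- spec$class_templates
  if (!is.null(ct) && inherits(ct$pos, "mvar_model"))
    return(list(pos = ct$pos, neg = ct$neg))

  if (spec$n_channels == 2L && is.null(ct)) {
    # a pair admits no spectrum-preserving wiring; fall back to the
    # direction swap C3 -> C4 (class +1) vs C4 -> C3 (class -1)
    edges <- list(
      pos = data.frame(from = "C3", to = "C4", lag = 1L,
                       weight = spec$edge_weight),
      neg = data.frame(from = "C4", to = "C3", lag = 1L,
                       weight = spec$edge_weight))
    quad_channels <- labs
  } else if (is.null(ct)) {
    quads <- .default_quads(spec$n_channels)
    edges <- list(pos = .quad_edges(quads, spec$edge_weight, +1),
                  neg = .quad_edges(quads, spec$edge_weight, -1))
    quad_channels <- unique(unlist(quads))
  } else {
    edges <- ct
    quad_channels <- unique(c(ct$pos$from, ct$pos$to, ct$neg$from, ct$neg$to))
  }
  res <- function(shift) {
    r <- rep_len(spec$resonance_hz, length(labs))
    r[labs %in% quad_channels] <- r[labs %in% quad_channels] + shift
    r
  }
  make <- function(e, shift)
    mvar_template(labs, e, resonance_hz = res(shift), rho = spec$rho,
                  fs = spec$fs, noise_cov = spec$noise_cov)
  list(pos = make(edges$pos, +spec$colour_contrast_hz),
       neg = make(edges$neg, -spec$colour_contrast_hz))
}

#' Generate a two-class trial set with analytic ground-truth connectivity
#'
#' Simulates every trial from its class's MVAR template (class order and
#' per-trial seeds derived deterministically from `spec$seed`) and returns
#' the trial set together with each template's analytic DTF — the ground
#' truth that recovery tests compare fitted connectivity against.
#'
#' @param spec a [sim_spec()].
#' @param truth_freqs frequencies (Hz) at which the analytic ground-truth
#'   DTF is evaluated (default `c(10, 15, 20, 25, 30)`).
#' @return a list with `trialset` (a [trialset()] of
#'   `2 * n_trials_per_class` trials, classes interleaved), `truth`
#'   (list of `"dtf_matrix"` objects `pos`, `neg`) and `templates`.
#' @export
make_two_class_trialset <- function(spec, truth_freqs = c(10, 15, 20, 25, 30)) {
  stopifnot(inherits(spec, "sim_spec"))
  tmpl <- sim_templates(spec)
  for (cl in c("pos", "neg"))
    if (!is_stable(tmpl[[cl]]))
      stop("class template '", cl, "' is unstable", call. = FALSE)
  n_samp <- floor(spec$trial_seconds * spec$fs)
  n_tr <- 2L * spec$n_trials_per_class
  labels <- rep(c(1L, -1L), spec$n_trials_per_class)    # interleaved
  data <- array(NA_real_, dim = c(n_tr, spec$n_channels, n_samp))
  for (i in seq_len(n_tr)) {
    model <- if (labels[i] > 0) tmpl$pos else tmpl$neg
    trial_seed <- (as.numeric(spec$seed) * 1009 + i) %% 2147483647
    data[i, , ] <- simulate_mvar(model, n_samp, seed = trial_seed)
  }
  ts <- trialset(data, spec$fs, spec$channel_labels, labels,
                 epoch_window = c(3, 3 + spec$trial_seconds))
  list(trialset = ts,
       truth = list(pos = dtf_matrix(tmpl$pos, truth_freqs),
                    neg = dtf_matrix(tmpl$neg, truth_freqs)),
       templates = tmpl)
}

#' Read a simulation spec from a YAML document
#'
#' Accepts the scalar fields of [sim_spec()] as top-level keys; unknown
#' keys are an error.
#'
#' @param path YAML file path.
#' @return a [sim_spec()].
#' @export
read_sim_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  allowed <- c("n_channels", "fs", "trial_seconds", "n_trials_per_class",
               "edge_weight", "resonance_hz", "rho", "colour_contrast_hz",
               "channel_labels", "seed")
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown))
    stop("unknown simulation-spec key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  obj$channel_labels <- if (!is.null(obj$channel_labels))
    unlist(obj$channel_labels)
  do.call(sim_spec, obj)
}
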