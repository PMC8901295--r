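---
title: "Directed Transfer Function network features for motor-imagery EEG: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTF network features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dtfnet)
```

This vignette is the package's account of its own methods: the models it
fits, the conventions and numerical choices it makes, what the synthetic
generator does and does not emulate, and what the validation therefore
does and does not show about real EEG.

## 1. The estimation chain

### Univariate AR features

Each channel of each trial is modelled as an all-pole process. We use the
regression convention

$$x(n) = \sum_{k=1}^{p} a_k\, x(n-k) + \varepsilon(n),
\qquad \varepsilon \sim \text{white},\ \operatorname{Var} = \sigma^2 .$$

The difference-equation form with a leading minus on the sum is the same
model with every $a_k$ negated; since only squared transfer magnitudes
are ever used downstream, the choice is immaterial scientifically, but a
single convention must rule the code, and the positive regression form
matches the multivariate equation below. `fit_ar_burg()` estimates the
coefficients by Burg's forward–backward reflection recursion (via
`stats::ar.burg`), which is the standard choice for short EEG epochs.
One property worth knowing: Burg's criterion averages forward and
backward prediction error, so on a *noise-free* geometric decay
$x_n = r^n$ it converges to $2r/(1+r^2)$, not $r$. The exact noise-free
recovery property therefore holds for the forward-only least-squares fit
(`fit_ar_ls()`), and that is what the corresponding test asserts; Burg is
validated on stochastic data against the generating process.

AR features use a fixed order (default $p = 6$, a common choice for
sensorimotor EEG) rather than per-trial AIC, because the classifier needs
a fixed feature dimensionality; the order is a tunable argument.

### MVAR and DTF

An $N$-channel trial $S(t)$ is fitted with

$$S(t) = \sum_{k=1}^{p} \Lambda_k S(t-k) + E(t),$$

by default with multichannel least squares over $t = p+1..n$ (residual
covariance with denominator $n - p$). A Vieira–Morf multichannel Burg
estimator is provided as an alternative (`method = "burg"`); univariate
Burg's precision caveats for long, high-order data apply to it as well,
which is why least squares is the default. Channel means are removed per
trial before fitting; AR theory assumes zero-mean data and EEG amplifier
offsets are physiologically meaningless.

The frequency-domain characteristic matrix and transfer matrix are

$$A(f) = I - \sum_{k=1}^{p} \Lambda_k e^{-j 2\pi f k \Delta t},
\qquad H(f) = A(f)^{-1}, \qquad \Delta t = 1/f_s,$$

(equivalently the $\Lambda_0 = -I$ summation form up to a global sign,
which cancels in $|H|^2$), and the DTF is

$$\gamma^2_{ij}(f) = \frac{|H_{ij}(f)|^2}{\sum_{m=1}^{N} |H_{im}(f)|^2}.$$

Rows index the receiving channel; $\gamma^2_{ij}$ is the fraction of
inflow into $i$ attributable to $j$, including flow mediated by other
channels. Two consequences are used as hard invariants: every row sums
to 1 and every entry lies in $[0,1]$; and $\gamma^2$ depends only on the
coefficient matrices and $f_s$, never on the innovation covariance.

Numerical choices: frequencies are evaluated pointwise at exact Hz values
(the experimental design names discrete frequency components, not bands;
`dtf_band()` offers band averaging as an optional smoother). A
near-singular $A(f)$ (1-norm condition estimate above $10^{12}$) raises
an error rather than returning NaN — a stable fitted model cannot produce
it, so hitting it means the fit is broken and silence would hide that.
The squared form $\gamma^2$ (not its square root) is the feature value,
matching the definition above; a square-root variant would be a
monotone reparametrisation and is not provided.

### Order selection

`select_order_aic()` minimises

$$\mathrm{AIC}(p) = n_{\mathrm{eff}} \log \det \hat\Sigma_p + 2\,p\,N^2,$$

where $2pN^2$ counts the free coefficients. All candidate orders
$1..p_{\max}$ are fitted on the common sample window
$t = p_{\max}+1..n$, so $n_{\mathrm{eff}}$ is constant across candidates
and the residual log-determinants are comparable (and non-increasing in
$p$); ties break toward the smaller order. Default $p_{\max} = 20$ for
standalone use. Inside `dtf_features()` the order policy is either a
fixed integer or `"aic"`, which selects once on a calibration subset
(the first `min(10, trials)` trials, $p_{\max} = 10$) and then holds the
order fixed for every trial — per-trial selection would change the
meaning, though not the number, of features across trials, and the
calibration subset keeps the cost of the sweep bounded.

### Features, fusion, classification

`dtf_features()` fits one MVAR per trial (features must exist per trial
to train a per-trial classifier) and vectorises the off-diagonal
$\gamma^2$ entries per frequency — $N(N-1)$ directed pairs; the
self-flow diagonal is excluded by default because "flow between
electrodes" reads as directed pairs, and an `include_diagonal` flag
restores it. `fuse_features()` concatenates feature tables column-wise
over identical trials. `standardize_features()` z-scores each feature;
inside evaluation the statistics are always fitted on the training fold
and applied to the test fold, so no test-set information reaches the
classifier. Zero-variance features get unit scale and a warning rather
than an error, since a constant feature is harmless to the SVM.

`train_eval()` uses a linear-kernel soft-margin SVM
($f(x) = \mathrm{sgn}(w \cdot x + b)$, `e1071`/libsvm) with cost
$C = 1$ by default; no hyperparameter search is performed, and the kernel
is deliberately not tunable beyond the linear inner product — the SVM is
an off-the-shelf component here, not a contribution. Two resampling
protocols are implemented because the usual description of this
experiment conflates them: stratified ten-fold cross-validation repeated
`n_repeats` times (the default), and repeated stratified 50/50
train/test splits. Both stratify by class so the balanced 40/40 design
stays balanced in every fold; accuracies are reported in percent and the
headline number is the arithmetic mean over all folds and repeats.
`compare_pipelines()` evaluates AR-only, per-frequency DTF, and fused
configurations on *shared* fold assignments, so differences between
configurations are paired comparisons.

## 2. The synthetic generator

Real motor-imagery recordings of this design (7 subjects, 32 channels,
500 Hz, 80 trials each) are not redistributable, so validation runs on
synthetic trial sets whose ground truth is known exactly.

`sim_spec()` defaults encode the emulated study conditions: 500 Hz
sampling, 6-second epochs (the 3–9 s imagery window of the acquisition
protocol, kept as the `[3, 9)` epoch metadata), 40 trials per class, and
10–20-system channel labels for the 2-, 10- and 32-channel montages.
Every channel carries an AR(2) resonance (default peak 20 Hz, pole
radius 0.9 — a sharp sensorimotor-band rhythm); innovations are Gaussian
with identity covariance, the standard concrete realisation of the
zero-mean white noise the model assumes. Each simulated trial discards a
500-sample burn-in from zero initial conditions.

Class-dependent coupling uses a **quad** wiring: a quad is two source and
two target channels, with lag-1 coupling weight 0.5, and the two classes
differ only in *which source feeds which target* (class +1: $s_1 \to
t_1, s_2 \to t_2$; class −1: $s_1 \to t_2, s_2 \to t_1$). This has two
properties the validation leans on. First, each target receives exactly
one inflow of the same weight from an identically coloured source in
both classes, so every channel's univariate spectrum is exactly
class-invariant — single-channel AR features are provably uninformative,
and the DTF pathway alone carries the class. A naive direction swap
(C3→C4 vs C4→C3) would not have this property: the driven channel gains
inflow power, leaking class information into univariate spectra. Second,
the directed-edge graph is acyclic, so the companion eigenvalues are
exactly the per-channel pole pairs and stability is inherited from the
pole radius whatever the coupling weight. The 10-channel layout uses
quads (C3, FC5 → C4, FC1) and (F3, F4 → Fz, Cz), leaving FC2 and FC6
untouched as negative-control channels; the 32-channel layout adds
parietal and occipital quads so discriminative edges also live outside
the motor strip, which is what makes the 2 → 10 → 32-channel montage
sweep informative. For fusion experiments, `colour_contrast_hz` shifts
the resonance of the quad channels up (class +1) or down (class −1),
giving AR features their own class signal; the default is 0.

What the generator does **not** emulate: volume conduction and common
reference (which inflate zero-lag correlations in real EEG), 1/f
background and non-stationary ERD/ERS envelopes, ocular/muscular
artifacts, and inter-subject variability. Passing tests on this
generator therefore demonstrates that the estimation chain is correct
and that connectivity differences of the designed size are recoverable
and classifiable — not that any particular accuracy will be reached on
real recordings, where the above nuisances are the dominant difficulty.
The ceiling accuracies on the synthetic sets reflect the generator's
clean separability, not a claim about real data.

## 3. Input handling

Trial sets round-trip through a native serialization container
(bit-exact) or a delimited-text directory (one TSV per trial plus a YAML
sidecar, exact to better than 1e-12). Compact read-only readers for
BrainVision triplets (INT_16 / IEEE_FLOAT_32, multiplexed or vectorized)
and plain continuous EDF are included, with epoching by explicit onsets
or BrainVision markers; epoch indexing is half-open with sample index
$\lfloor t f_s \rfloor$, so a 3–9 s window at 500 Hz is exactly 3000
samples. Channel-name matching is case-insensitive and
whitespace-stripped because vendor files disagree on both. A zero-phase
(forward–backward) order-4 Butterworth band-pass is available but **off
by default**: on this pipeline filtering before feature extraction has
been reported to cost accuracy, so the unfiltered path is the standard
one and the filter exists for sensitivity analyses. No re-referencing or
artifact rejection is performed; channels are used as recorded.

## 4. Validation design and problem sizes

The test suite validates each stage against an independent oracle:
cofactor-inversion DTF for $N \le 3$ (100 random stable models, agreement
to 1e-9), closed forms for scalar transfer gains and AR
autocorrelations, the generating process for coefficient / order / DTF
recovery, and construction-based expectations for the classifiers
(separable blobs at 100%, permuted labels at chance). The end-to-end
checks run at the emulated study scale — 80 trials of 6 s at 500 Hz, 10
or 32 channels, MVAR order 2, DTF at 30 Hz, ten-fold CV — with medians
taken over 20 replicate seeds; `scripts/acceptance.R` recomputes the
same quantities from scratch from a single command-line seed. These
sizes keep the full suite and the acceptance script each within a few
minutes on one CPU while leaving estimation error well inside the
asserted tolerances (e.g. median per-trial DTF recovery error ≈ 0.09
against a 0.1 bound at 3000 samples).

## 5. Known limitations

* DTF, like all MVAR-based measures, assumes linear, stationary dynamics
  within an epoch; time-varying or nonlinear coupling is out of scope.
* No significance thresholding of $\gamma^2$ edges (surrogate or
  analytic): raw values feed the classifier directly.
* No Partial Directed Coherence, dDTF/ffDTF, or graph-theoretic summary
  features; no feature selection; no multiclass support.
* The EDF reader handles plain continuous EDF with a single sampling
  rate; EDF+ discontinuous records and annotation-based epoching are not
  supported.
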