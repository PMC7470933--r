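---
title: "Decoding behaviour from spike trains: models, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding behaviour from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spikedecode` treats neural decoding as a supervised regression problem:
given the spike counts of $N$ neurons, predict a continuous behavioural
variable (2-D cursor velocity, 2-D animal position) continuously in time.
This vignette describes the models the package implements, the evaluation
pipeline, and the design decisions taken where more than one reasonable
choice existed. The package surface is tidyverse-flavoured — evaluation
reports are tibbles with `tidy()`/`glance()`/`autoplot()` methods — while
the numerical objects (design matrices, sequence tensors, filters) remain
plain matrices and arrays, the natural currency of the underlying
mathematics.

## From spike times to supervised-learning problems

Spike times are counted in half-open bins $[tR, (t+1)R)$ of width $R$
seconds (a boundary spike belongs to the later bin; the trailing partial
bin is dropped so that integer spike conservation can be asserted).
Outputs are averaged within the same bins; empty bins are filled by linear
interpolation between neighbouring bin values, and leading/trailing gaps
are held at the nearest value — binning by within-bin mean is the
conventional default, and interpolation preserves the continuity that the
state-space decoders assume.

A lag window (`lag_spec`) selects which bins of activity predict the
output at bin $t$: `bins_before` preceding bins, optionally the concurrent
bin, and `bins_after` following bins, $B$ bins in total. Motor decoding
typically uses preceding activity (e.g. the concurrent bin plus 13 before,
$B = 14$, at $R = 50$ ms); hippocampal position decoding uses a window
surrounding the output (concurrent, 4 before, 5 after, $B = 10$, at $R =
200$ ms). The first `bins_before` and last `bins_after` output bins cannot
be predicted, leaving $K$ usable rows.

Two layouts serve the two decoder classes:

* **flat** — a $K \times (N B)$ design matrix whose row $k$ concatenates
  all neurons at each lag (lag-major, neuron-minor; any fixed order works
  since the flat decoders are column-order-invariant, but the order is
  documented and the sequence tensor flattens to it exactly);
* **sequence** — a $K \times N \times B$ tensor for recurrent networks,
  which read the window one bin at a time and predict from the hidden
  state after the final bin.

Preprocessing follows the convention that every statistic is learned on
training rows only: inputs are z-scored with training means and SDs,
outputs are mean-centred (z-scored inside the SVR, which is sensitive to
target scale), and validation/test rows reuse the stored training
parameters verbatim. A zero-variance training column has its scale clamped
to 1 with a warning rather than producing NaNs.

## The eleven decoders

**Wiener filter** — ordinary least squares from the flat layout; the
classical linear decoder. Implemented by QR; an exactly rank-deficient
design falls back to the minimum-norm SVD solution with a warning. Ridge
regularisation is exposed as an optional hyperparameter but defaults to 0.

**Wiener cascade** — per output dimension, a linear stage followed by a
static polynomial fitted by least squares on a Vandermonde expansion of
the stage-1 training predictions. The polynomial degree (default 3, search
range 1–5: small enough to avoid Runge-type extrapolation blow-ups) is a
validation-set hyperparameter. Degree 1 reproduces the Wiener filter
exactly, and training MSE is non-increasing in degree.

**SVR** — `e1071` radial-basis eps-regression, one independent fit per
output dimension. Kernel SVR training cost grows roughly quadratically
with rows, so a `max_train` hyperparameter can cap the training set by an
evenly spaced subsample for desk-scale runs.

**Boosted trees** — `xgboost` squared-error regression, one fit per
output; depth/rounds/learning-rate exposed (search ranges 2–8, 100–1000,
0.01–0.3).

**Feedforward network** — two hidden layers of equal width with ReLU,
dropout on the hidden activations, linear output, trained by Adam on MSE
summed over output dimensions. Implemented natively in R with BLAS-backed
matrix maths; gradients are analytic backpropagation verified against
central finite differences in the test suite.

**Simple RNN, GRU, LSTM** — standard cells unrolled over the $B$-bin
window; the hidden state after the final bin feeds a linear readout.
Dropout is applied to the input features with one mask per sample shared
across time steps (the convention of the major deep-learning frameworks);
the LSTM forget-gate bias is initialised at 1. Also native R with
finite-difference-verified backpropagation through time. Default search
ranges: 50–1000 units (feedforward) or 50–400 (recurrent), dropout 0–0.5,
epochs 2–20; registry defaults are 200/64 units, dropout 0.2, 10 epochs,
Adam at $10^{-2}$ with minibatches of 128.

**Kalman filter** — linear-Gaussian state space whose hidden state is the
kinematics: position, velocity and acceleration per axis ($s = 6$ for 2-D
tasks). Even when only position or velocity is reported, carrying all
kinematic orders improves prediction. Missing orders are derived by
central finite differences on the bin grid (one-sided at segment ends, and
differentiation never crosses a fold boundary, so no held-out information
leaks into training statistics). $A, W, H, Q$ are least-squares/residual
estimates; decoding runs the standard predict/update recursion from the
training-mean state. A scalar `noise_scale` multiplies the transition
noise $W$ at decode time — 1 gives the classical filter, and tuning it on
the validation set trades smoothness against responsiveness. A signed
`lag` offsets observations against states (default search −2…+2 bins).

**Naive Bayes** — per-neuron Poisson encoding models on a discretised
output grid (default 100 cells in 1-D, 30×30 in 2-D — small enough for
exhaustive posterior enumeration), combined under conditional independence
with an occupancy prior and an optional Gaussian transition prior whose
bandwidth defaults to the empirical per-bin displacement SD. Counts are
summed over the same lag window the other decoders see, so the exposure
time of the Poisson model is the window duration. Tuning curves are
occupancy-normalised, Gaussian-smoothed over the grid (bandwidth 1 cell by
default), and floored at 0.01 expected spikes per window so log
densities stay finite; the posterior is computed entirely in log space and
the argmax breaks ties toward the lowest grid index.

**Ensemble** — a second-tier model stacked on the predictions of the
eight flat/sequence decoders (the Kalman filter and Naive Bayes are
excluded: their input/output formats differ). The stacker — a small
feedforward network by default, plain least squares optionally — is
trained on the bases' *validation*-set predictions, rows the bases never
trained on; training it on base training-set predictions would teach it
the bases' overfitting. With the linear stacker, training R² can never
fall below the best single base.

## Evaluation pipeline

Temporally adjacent bins are strongly dependent, so rows are never
shuffled. `make_fold_plan(K, J)` gives each of $J$ folds a contiguous test
block (the $J$ blocks tile the recording exactly once, rotating from the
end backwards), a contiguous validation block adjacent to it, and the rest
for training — 80/10/10 at $J = 10$. When $J$ is too small for a 10%
validation block the plan degrades gracefully (50/25/25 at $J = 2$) with a
warning. Rows whose lag windows straddle a block boundary are retained, as
is conventional; the overlap affects a $B$-bin sliver per boundary.

Scores use fraction-of-variance $R^2 = 1 - \mathrm{SS}_{res} /
\mathrm{SS}_{tot}$, averaged over output dimensions; it is negative
whenever a decoder does worse than predicting the mean. Because training
sets of different folds overlap, fold scores are correlated and the naive
$\sigma/\sqrt{J}$ understates uncertainty; the reported error bar is the
corrected $\sigma\sqrt{1/J + 1/(J-1)}$. For single-split analyses the
block bootstrap cuts the test set into 20 contiguous segments and
resamples them with replacement 1000 times; percentile intervals of the
resampled $R^2$ respect the temporal correlation that row-level
resampling would destroy. The default interval is 95% (68% approximates
an SEM).

Hyperparameters are chosen by validation-set $R^2$ only — never test —
with three strategies: grid, random (Latin hypercube), and Bayesian
optimization. No Bayesian-optimization package being part of the package's
dependency tier, the Bayesian strategy is a compact Gaussian-process
surrogate: squared-exponential kernel on the unit cube (lengthscale 0.2),
standardised responses, expected improvement maximised over a dense random
candidate set, seeded and reproducible. Every evaluation is logged, and
`run_comparison` retains the logs plus the fold indices and preprocessing
statistics in an `audit` attribute so that leakage-freedom is mechanically
checkable.

## The synthetic generators

The generators exist so that every decoder and every evaluation procedure
can be exercised against known ground truth without any data download.

`simulate_cortical` draws smooth 2-D velocity (independent
Ornstein–Uhlenbeck processes, correlation time 0.4 s) and cosine-tuned
Poisson neurons: $\lambda_i(t) = \mathrm{softplus}(b + b_i + m_i\,
s(t)\cos(\theta(t) - \theta_i))$. The softplus link bounds rates away
from the explosions an exponential link produces; the shared offset $b$
is calibrated by root finding so the population mean rate hits the target
(default 6.7 spikes/s in 50 ms bins, the scale of a typical motor-cortex
array recording). Because $s\cos(\theta - \theta_i)$ is an inner product
with the velocity vector, the drive is *linear* in velocity: at a
comfortable operating point the count-to-velocity inverse map is nearly
linear too, and all decoder families tie. The *strongly nonlinear* regime
used for the decoder-ordering analyses pushes the baseline low and the
modulation deep (`mean_rate = 2`, `tuning_depth = 12`), so that most bins
are rectified to near-silence and the softplus curvature dominates — there
the nonlinear decoders separate from the Wiener filter, mirroring what
happens on real recordings.

`simulate_hippocampal` draws a reflected random walk in the unit box
(per-bin displacement one fifth of the field width, so successive bins
sample fields densely) and Gaussian place fields whose time-averaged rates
follow a log-normal across neurons — median pinned to the 0.2 spikes/s
target exactly, mean matching 1.7 spikes/s in expectation (the heavy tail
makes any finite-sample mean noisy). Most neurons are therefore nearly
silent most of the time, reproducing the median ≪ mean sparsity of real
hippocampal populations. `simulate_linear_gaussian` draws exact
linear-Gaussian trajectories for the Kalman oracle and recovery tests.

What the generators do *not* emulate: spike-history dependence
(refractoriness, bursting, theta phase), non-Poisson count dispersion,
nonstationarity, and correlated noise across neurons. Tests passing on
these data therefore certify the pipeline's correctness and the decoders'
relative behaviour under known ground truth, not performance on any real
recording.

## Numerical choices and degenerate inputs

* Design-matrix solves use QR, with an SVD minimum-norm fallback (and a
  warning) for exactly collinear features.
* Filtered covariances are symmetrised every step; if numerical error
  produces a negative eigenvalue the covariance is eigen-clipped at zero
  with a warning.
* The Naive Bayes posterior is computed in log space, so underflow cannot
  zero it; finiteness is asserted.
* Network training aborts with a `fit-failure` condition if the loss goes
  non-finite rather than returning garbage.
* All stochastic components (initialisation, minibatch order, dropout
  masks, bootstrap draws, search proposals, generators) draw from R's RNG
  under caller-supplied seeds; identical seeds give bit-identical results.

## Problem sizes used in the shipped analyses

The packaged analyses run at desk scale, chosen to finish comfortably on
one CPU: comparisons use 8000–10 000 bins of 30 cortical-like neurons or
10 000 bins of 40 place cells, 10-fold cross-validation, registry-default
hyperparameters (search budget 1), and an SVR training cap of 2000 rows.
These sizes are an order of magnitude below the recordings that motivate
the package, which is why the shipped numbers are read as orderings and
sanity ranges rather than as reproductions of any published value.

## Known limitations

* The native network trainer is single-threaded R; it is entirely adequate
  at desk scale but not a substitute for a GPU framework on long
  recordings.
* The Naive Bayes grid is exhaustive, so output dimension is capped at 2.
* Only offline decoding is addressed; closed-loop use changes the problem.
* Classification decoding is out of scope; all decoders here regress
  continuous outputs.
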