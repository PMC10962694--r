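---
title: "Continuous-time deconvolutional regression with neural impulse responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time deconvolutional regression with neural impulse responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cdrnn)
```

## The modelling problem

Many time series in the behavioral and brain sciences consist of two
misaligned streams: a sequence of events (words read, sounds heard) at
irregular times $t_1, \dots, t_N$ with predictor vectors
$\mathbf{x}_1, \dots, \mathbf{x}_N$, and a sequence of response samples
(button-press latencies, fMRI volumes) at times $\tau$ that need not coincide
with the events. Because the underlying system responds in continuous time,
the influence of an event on a response depends on the *signed delay*
$d_n = \tau - t_n$, and responses superpose the influences of many temporally
overlapping events. Discrete-time regression (lagged predictors, epoching,
finite impulse response designs) must force this structure onto an index
scale and loses the distinction between an event 100 ms ago and one
1000 ms ago.

This package estimates the mapping from event history to the *full response
distribution* with a small feedforward neural network playing the role of a
continuous-time impulse response function (IRF). For each response sample,
every in-horizon event is mapped through the network

$$\mathbf{G}_n = f_{\mathrm{IRF}}(d_n,\ t_n,\ \mathbf{x}'_n)$$

to an $S \times (J{+}1)$ matrix of convolution weights, and the parameters of
the response distribution are the sum

$$\mathbf{s} = \mathbf{s}_0 + \sum_{n=1}^{N} \mathbf{G}_n\,
\mathrm{diag}(\mathbf{b})\, [1;\ \mathbf{x}'_n], \qquad
y \sim \mathcal{F}(\mathbf{s}),$$

with $\mathcal{F}$ a normal distribution whose location *and* scale are both
rows of $\mathbf{s}$ (scale through a softplus link). The leading coefficient
slot is the *rate* term — a constant 1 convolved like a predictor — which
captures the baseline response to any event regardless of its properties: a
deconvolutional intercept, distinct from $\mathbf{s}_0$ in that it is
convolved over time. The factorization of $\mathbf{G}_n$ (shape) against
$\mathbf{b}$ (scale) keeps the read-out additive over events, which is what
makes the model interpretable: the exact causal contribution of any single
event can be read off by evaluating the network, with no reference to a
hidden state.

Input processing $f_{\mathrm{in}}$ is the identity throughout (impulses equal
predictors, $J = K$); `input_transform()` also implements the feedforward
variant for standalone use, but the fitting path assumes identity, which is
the configuration of interest here because effect nonlinearities and
interactions are already captured by $f_{\mathrm{IRF}}$.

### Constraints define null models

Because every simplifying assumption of classical regression corresponds to
deleting an input or a row:

* removing $t_n$ from the network inputs enforces **stationarity**;
* removing $\mathbf{x}'_n$ (wholly or per predictor) enforces **linearity**
  — the excluded predictors still act linearly through the convolution
  product;
* restricting the network to the location row and making the scale a single
  free constant enforces **homoscedasticity**;
* zeroing the output for $d < 0$ enforces **causality** ($d = 0$ counts as
  past-and-present and is retained);
* replacing the network by an indicator on $d = 0$ (`irf = "dirac"`) removes
  continuous time entirely: with identity $f_{\mathrm{in}}$ the model *is* a
  linear regression, and `coef()` returns the implied raw-scale intercept and
  slopes for direct comparison with `lm()`.

`build_null()` applies these edits compositionally, so any null hypothesis
expressible as a constraint yields a fittable model, and the difference in
held-out likelihood between the full and constrained fits is the test
statistic.

### Mixed effects

All model parameters are the sum of a fixed part and per-level random
deviations, $v = v_0 + Vz$, with the deviations of each grouping factor
constrained to sum to zero across levels (a hard projection applied after
every epoch, on top of L2 shrinkage toward zero). `parameter_store()`,
`compose_params()` and `center_ranef()` implement the general composition
for any parameter block. The fitting path estimates random effects for the
location intercept ($\mathbf{s}_0$) and the coefficient vector
($\mathbf{b}$) — the analogues of random intercepts and slopes in linear
mixed models; random deviations in the network weights themselves are
composable and predictable through the same machinery but are not fitted by
default, a scope choice that keeps the training path fully vectorized over
samples.

## Estimation

Predictors, event timestamps, delays, and the response are z-standardized by
training-set statistics before entering the network; every reported quantity
(likelihoods, effect estimates, coefficients) is mapped back to the raw
scale exactly, the likelihood via the change-of-variables constant
$-\log \hat\sigma_y$ per sample. Standardization keeps all network inputs
$O(1)$ and makes one set of optimizer defaults serviceable across datasets.

The penalized negative mean log likelihood is minimized by Adam over
minibatches of response samples, with analytic backpropagation through the
read-out and the network. Defaults: learning rate $10^{-3}$, batch size
1024, up to 2000 epochs, L2 penalty 0.01 on network weights and 1.0 on
random-effect deviations. These are the package's own defaults; the fits in
the test suite use a learning rate of $3\times10^{-3}$ and batch size 250,
which converge faster at the sample sizes used there.

**Monte Carlo dropout** (default rate 0.1 on hidden units) is active during
training and doubles as the approximate posterior over network weights:
`posterior_sample()` draws stochastic forward parameterizations by
resampling the masks (one mask vector per hidden layer, shared across
evaluation rows within a draw), and credible bands are empirical quantiles
over draws, pooled across ensemble members when present.

**Two-phase schedule.** With masks resampled to the last step, the scale
head absorbs the mask-induced prediction noise and the point estimate never
reaches the deterministic-prediction limit used at evaluation: on the
quick-start regime this inflates $\hat\sigma$ by roughly 15–25% over the
realized residual scale. Training therefore ends with a refinement phase
(default: the final 30% of the epoch budget) in which dropout is switched
off and the step size is multiplied by 0.3, letting location and scale
converge to the limit actually evaluated. Dropout draws for uncertainty are
still taken at the configured rate after refinement.

**Initialization.** Glorot-uniform weights with the output layer scaled by
1/10 — the read-out sums over whole event histories, so an unscaled random
output layer would start the optimization from absurdly large convolution
weights. Coefficients $\mathbf{b}$ start at 1 (the network output carries
the shape), the location intercept at the standardized response mean (0) and
the scale at softplus$^{-1}$(1).

Gradients are clipped to a global norm of 10 before each Adam step — cheap
insurance against the occasional unstable minibatch early in training.

**Convergence** follows a time–loss criterion: after each epoch the Pearson
correlation between the metric (per-epoch training log likelihood) and
cumulative training time, computed over the trailing 100 evaluations, is
tested at level $\alpha = 0.5$; the criterion fires at the first epoch where
at least half of the last 100 such tests fail to reject the null of no
correlation. The correlation is deliberately windowed: over the full history
an early improvement ramp keeps the correlation significant indefinitely,
so a model that has plateaued would never register as converged. Constant
or degenerate stretches count as failures to reject, and convergence is
never declared before 100 evaluations exist. `check_convergence()` exposes
the criterion on any metric series; `fit_cdrnn()` stops when it fires unless
`stop_on_convergence = FALSE`, in which case the full epoch budget runs and
only the firing epoch is recorded — the mode used by the package's own
validation studies, whose budgets are fixed for comparability. At
$\alpha = 0.5$ the criterion is intentionally eager (a metric that merely
wanders satisfies it about half the time per test), which suits monitoring
long real-data runs more than short simulation studies.

## Effect queries

All interpretation is perturbation-based. A query builds one synthetic event,
evaluates the response-distribution parameters with the queried predictor at
a value of interest and at the reference point, and reports the difference
of the targeted parameter. By additivity of the read-out, context events
cancel exactly in this difference, so single-event queries characterize the
IRF completely. The reference point is the training-set mean of each
predictor (0 after standardization), and "+1 SD" means one training standard
deviation above it. Location effects are differences of location
contributions; scale effects are differences of linked scales
$\sigma(\mathbf{s}_0 + c) - \sigma(\mathbf{s}_0 + c_{\mathrm{ref}})$, so a
homoscedasticity-constrained model yields an exactly zero scale effect.

The query family mirrors the standard panels of this model class: IRF curves
over delay (`irf_curve()`, with `"rate"` for the baseline response), effect
surfaces over value × delay (`effect_surface()`), functional-form slices at
a fixed delay (`functional_form_slice()`), pairwise interaction surfaces
(`interaction_surface()`), scale-parameter IRFs (`sigma_irf()`) and
nonstationarity curves over event onset (`nonstationarity_curve()`).
Default grids span delays 0–1 s for the event-aligned (reading-like) regime
and predictor values ±2.5 training SDs; point estimates are means over
dropout draws and ensemble members, bands are pointwise empirical quantiles.
An open modelling choice is whether to hold the other predictors at the
reference or to marginalize over their empirical distribution; the package
holds at reference, which matches the single-event reading of the IRF.

## Hypothesis testing

Model comparison is generalization-based: ensembles of independently seeded
fits (default 10) are trained on the training partition for the full and the
constrained specification; each ensemble's predictive density is the
equal-weight mixture of its members (log-mean-exp of pointwise log
likelihoods); and the paired permutation test flips the per-sample
likelihood differences' signs independently with probability ½
(`n_perm = 10000` by default), using the absolute total difference as the
two-sided statistic and add-one smoothing for the p-value. Swapping is
per response sample by default; a `cluster` argument swaps whole groups
(e.g. participants) instead, for users who consider samples within a group
exchangeable only jointly.

Partitioning follows modular arithmetic that respects the dependence
structure of the data: sentence-cycled for event-aligned reading-like data
(`(e + u) mod 4` over sentence `e` and participant `u`, outputs 0–1 train,
2 exploratory, 3 test) and chunk-cycled for fixed-interval data, where the
cycling unit is a block of `chunk_len` consecutive samples within a
participant (`(floor(i / chunk_len) + u) mod 4`; the default 15 corresponds
to 30 s at a 2 s sampling interval). The chunk formula is our reading of a
compressed notation in the source protocol: chunk index plus participant,
cycled mod 4, which realizes "cycling 30 s chunks"; `chunk_len` is exposed
as configuration.

For the reading-data exclusion filters, two protocol ambiguities were
resolved as follows: the saccade-length filter treats the printed bound as a
strict inequality on the (absolute) incoming saccade length, regressive or
not, since the protocol does not distinguish direction; and the 100-response
participant minimum is counted after the sentence-boundary exclusion, with
the alternative count (boundary filter ignored) included in the exclusion
report so users can see whether the ordering matters for their data.

## The synthetic generator

`sim_config()` / `generate_events()` / `generate_responses()` define the
study conditions under which the package's claims are tested: variably
spaced events (exponential inter-arrival, mean 0.3 s, emulating word-by-word
presentation) or fixed spacing; standard-normal predictors; responses
sampled at the events themselves (reading-like) or at a fixed 2 s interval
(fMRI-like); and ground-truth kernels — exponential decays, an HRF-like
difference of gamma densities (peak at 5 s, undershoot ratio 1/6, the
canonical hemodynamic shape), or Dirac indicators for the discrete-time
reduction. Optional complications: heteroscedastic noise
$\sigma = \sigma_0 e^{\gamma x_1}$ of the coincident event (event-aligned
sampling only), a linear nonstationary gain ramp on the predictor kernels,
and per-participant random intercepts. The generator records the exact
generating moments, so the oracle likelihood — the upper bound no fitted
model can beat beyond sampling noise — is computable for any subset.

The quick-start fixture (`quickstart_fixture()`) is the canonical small
regime: 2000 events over 4 participants, two predictors with exponential
kernels (amplitude 1 at rate 2/s; amplitude −0.5 at rate 5/s), an event-rate
kernel (0.25 at 3/s), intercept 5, noise SD 0.5, sentence-cycled partition.
These values were chosen once to give a realistic reading-like
signal-to-noise regime (response SD ≈ 1.4 against noise 0.5) at a size that
fits and evaluates in minutes on one CPU.

The validation studies in the test suite use the following designs. *Kernel
recovery*: a 3-member ensemble trained for 2000 epochs on the train and
exploratory partitions (once hyperparameters are fixed, the final model may
use all non-test data; the test partition stays held out for the oracle
comparison), with a 2 s history horizon — the quick-start kernels carry
under 2% of their mass beyond 2 s, and every superfluous in-horizon event
contributes estimation noise, so the horizon is set where the
truncation/variance trade-off favors precision. *Heteroscedasticity
recovery*: 2000 events at 1.0 s mean spacing (the noise map is tied to the
coincident event, and at denser spacings a smooth impulse response cannot
separate a scale effect at zero delay from its neighbors — the target would
be unidentifiable by design rather than hard to estimate), fitted as a
3-member ensemble for 2000 epochs with a weight penalty of 0.003, credible
bands pooled over members and dropout draws. *Linear reduction*: 2000
events with
Dirac kernels, fitted as the discrete-time reduction and compared against
`lm()`.

What the generator does *not* emulate: serially correlated residuals,
non-normal responses, eye-movement mechanics, fMRI physiology or drift, or
predictors with realistic correlation structure. Passing tests on these
conditions therefore demonstrate correct inference under the model's own
assumptions — kernel recovery, constraint degeneracies, test calibration —
not robustness to the full messiness of real recordings.

## Numerical choices and degenerate inputs

* Scale link: softplus with an additive floor of $10^{-4}$, for positivity
  with stable gradients; `softplus_inv()` ignores the floor.
* History horizon: the convolution is truncated to $0 \le d \le d_{\max}$
  (both signs when non-causal), default 10 s for the reading-like regime
  (32 s is the natural choice for HRF-like kernels). The horizon is a
  bias–variance dial, not only a speed knob: every in-horizon event passes
  through the network, so events whose true contribution is negligible
  still inject estimation noise. `kernel_mass_beyond()` reports the
  fraction of a fitted curve's absolute area beyond any horizon as a
  truncation diagnostic.
* Responses with no in-horizon events receive the intercept alone — valid
  inputs, not errors.
* Simultaneous events are permitted and processed in stable input order;
  their contributions add.
* Degenerate convergence inputs (constant metric, fewer than 3 points) count
  as failures to reject the no-correlation null.
* A non-finite training objective halts the run with an error naming the
  epoch rather than continuing from poisoned state.
* Unknown random-effect levels at prediction time fall back to the
  population parameters (z = 0) with a warning.

## Limitations

Multivariate responses are treated as independent families per dimension:
`fit_cdrnn()` models one response column, and a Y-dimensional response is
fitted as Y independent models sharing the same event stream — there is no
cross-dimension covariance model.

The fitting path is CPU-bound, dense linear algebra; it is comfortable at
$10^3$–$10^5$ response samples with tens of events per sample but makes no
attempt at accelerator or distributed execution. MC dropout is a coarse
posterior approximation: bands are approximate credible intervals whose
empirical coverage should be (and, for the scale-effect study in the test
suite, is) checked by simulation. The stateless additivity that buys
interpretability also limits expressiveness: effects of events on the
response are independent by construction, so genuinely history-dependent
nonlinear integration is out of scope. Only the normal response family is
implemented; the likelihood interface is the extension point for others.
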