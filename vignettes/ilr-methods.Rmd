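---
title: "Input layer regularization for myelin water fraction estimation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Input layer regularization for myelin water fraction estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilrmwf)
```

## The estimation problem

Multi-echo transverse relaxometry of brain tissue measures a decay signal
at echo times $t_1 = 0 < t_2 < \dots < t_N$. Under the two-compartment
(biexponential) model the unit-normalized clean signal is

$$G(p)_n = c_1 e^{-t_n/T_{2,1}} + (1 - c_1)\, e^{-t_n/T_{2,2}},
\qquad p = (c_1, T_{2,1}, T_{2,2}),$$

where $c_1$ is the myelin water fraction (MWF): the share of signal from
water trapped within myelin lamellae, which relaxes fast
($T_{2,1} \approx$ 10–60 ms), against the slower intra/extracellular pool
($T_{2,2} \approx$ 60–300 ms). Magnitude MRI corrupts $G$ with Rician
noise,
$s_n = \sqrt{(G_n + \xi_n)^2 + \eta_n^2}$ with
$\xi_n, \eta_n \sim N(0, \sigma^2)$, and on the unit-normalized scale we
take $\sigma = 1/\mathrm{SNR}$, so the three study noise levels SNR 5, 50
and 100 correspond to $\sigma = 0.2, 0.02, 0.01$.

Recovering $p$ from $s$ is severely ill-posed: distinct parameter triples
produce nearly identical curves whenever the two relaxation times are
close, or when the fast component is sampled by only a few early echoes.
The consequence, reproduced by this package's benchmarks, is that plain
constrained nonlinear least squares (NLLS) estimates of $c_1$ barely
improve between SNR 5 and SNR 100.

The package implements a hybrid classical/learned pipeline around this
model:

1. **Fitting** — box-constrained NLLS and Tikhonov-regularized NLLS
   (TR-NLLS), $\min_{p \in F} \|G(p) - s\|_2^2 + \lambda\|\tilde p\|^2$,
   solved by bounded Levenberg–Marquardt with analytic Jacobians
   (`nlls_fit()`, `tr_nlls_fit()`).
2. **Per-signal selection of $\lambda$** — a bilevel oracle
   (`lambda_oracle()`), nonlinear generalized cross-validation
   (`lambda_gcv()`), and a trained selector network
   (`train_lambda_net()` / `predict_lambda()`).
3. **Input layer regularization (ILR)** — a parameter-estimation network
   fed the concatenation $x = [s;\ G(p^*_{\lambda(s)}(s))]$ of the noisy
   signal and the clean curve synthesized from its regularized fit
   (`build_concat_input()`, `train_pe_network()`).
4. **Voxel mapping** — AIC-based mono/biexponential voxel filtering, SNR
   estimation, and MWF map construction (`classify_voxels()`,
   `estimate_mwf_map()`).

## Synthetic study conditions

The synthetic generator defines the conditions under which everything here
is trained and benchmarked; they were fixed once, by the reasoning below,
and all defaults flow from them.

**Echo schedule.** 64 echoes, uniformly spaced at 11.3 ms, first echo at
$t = 0$ (`echo_schedule()`). This emulates a standard 64-echo
multi-spin-echo protocol with an acquisition window of about 712 ms: long
enough that the slow pool is observed through most of its decay, while
the myelin pool is caught by only the first handful of echoes. Both
properties matter — the former makes $T_{2,2}$ identifiable so that
regularization acts as a stabilizer rather than a steamroller; the latter
is the physical source of the MWF's ill-determination.

**Parameter prior.** Independent uniforms, remapped to the canonical
fast-first order: $c_1 \sim U(0, 0.6)$, $T_{2,1} \sim U(10, 60)$ ms,
$T_{2,2} \sim U(60, 300)$ ms (`prior_config()`). The fraction range spans
physiological MWF (rarely above 0.45 in vivo) with headroom while keeping
the slow pool the majority compartment; the relaxation ranges meet at
60 ms so near-degenerate pairs occur with positive probability. Two
consistency checks anchor the fraction range: a trained network must be
able to beat the best constant predictor (RMSE $0.6/\sqrt{12} = 0.173$ at
the hardest noise level, which our low-SNR networks do only narrowly —
the expected regime for this severely ill-posed problem), and under a
much wider range the oracle-regularized fit would not beat NLLS on $c_1$
at low SNR at all.

**Noise.** Rician, with per-signal deterministic substreams of the
dataset seed, so any subset of a dataset regenerates identically
(`generate_dataset()`).

## Scale-equalized parameter coordinates

The triple mixes a dimensionless fraction with times that are numerically
two orders of magnitude larger. All $\lambda$-coupled computations
therefore work in scale-equalized coordinates
$\tilde p = (c_1, T_{2,1}/100, T_{2,2}/100)$, i.e. $Bp/\max(B)$ with
$B = \mathrm{diag}(100, 1, 1)$:

* the TR-NLLS penalty is $\lambda \|\tilde p\|^2$;
* the GCV influence trace uses the Jacobian with respect to $\tilde p$
  (equivalently, the metric $\mathrm{diag}(1, 10^{-4}, 10^{-4})$ in raw
  coordinates — see `gcv_objective(penalty_metric = "scaled")`);
* the selector network's labels and the benchmark $W_1$ distances are on
  this $\lambda$ scale.

Only with this normalization is $\lambda$ dimensionless relative to the
unit-normalized signal energy, which is what makes a single search space
$[10^{-7}, 10^3]$ meaningful across noise levels: at SNR 5 selected
weights concentrate around $10^{-1}$–$10^0$, at SNR 100 around
$10^{-4}$–$10^{-3}$, with heavy right tails for near-degenerate signals.
Because the matrix is $B$ up to a scalar, the scalar is a pure
reparameterization of $\lambda$; every fit path is identical to the
raw-$B$ convention after rescaling $\lambda$ by $10^4$. The weighted loss
for the parameter networks, by contrast, uses $B$ itself
(`weighted_param_loss()`), where the factor 100 on the fraction is the
point: errors in $c_1$ of 0.1 should weigh like errors in $T_2$ of 10 ms.

The upper-level norm of the bilevel oracle is, by default, the literal
unweighted Euclidean norm on $(c_1, T_{2,1}, T_{2,2})$ in milliseconds.
This is a deliberate, documented asymmetry: the oracle then chiefly
repairs the relaxation times (whose errors dominate that norm), and the
fraction improves collaterally, so the oracle's $c_1$ accuracy is good
but not exact even at high SNR. A
`norm = "scaled"` variant (fraction-dominated) is provided; it makes the
oracle's $c_1$ nearly exact at high SNR and is the right choice if the
oracle is used as a pure $c_1$ reference.

## Solvers and numerical choices

**Inner solver.** Both fits run bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) on the stacked residual
$[G(p) - s;\ \sqrt{\lambda}\,\tilde p]$ with the analytic model Jacobian;
one solver serves both problems and `tr_nlls_fit(lambda = 0)` is exactly
`nlls_fit()`. Box constraints: $c_1 \in [0, 1]$ and
$T_2 \in [10^{-3}, 2000]$ ms — the floor avoids the $T_2 = 0$ singularity
of the model, the cap is a numerical stand-in for $T_2 \ge 0$'s
unbounded side. Multi-start policy: four deterministic initializations
spanning the prior box plus one seeded random draw; the best local
minimizer wins. Because the penalty weighs the two component labelings
differently through the $c_1$ term, both labelings of the winning
solution are evaluated and the cheaper kept, with ties resolved to the
canonical order — so unregularized fits are always canonical, and
regularized fits never report the worse labeling.

**$\lambda$ search.** Both the oracle and GCV objectives can be
multimodal in $\lambda$, so raw scalar minimization is unreliable. The
protocol is: evaluate on a 50-point $\log_{10}$-spaced grid over
$[10^{-7}, 10^3]$, then refine with Brent's method on $\log_{10}\lambda$
inside the bracketing triple of the grid argmin. The search runs on the
log scale because the distribution of useful weights spans ten decades.
Inner fits along the search are warm-started from the last and the
incumbent-best solutions (with a periodic fresh mid start); failed
evaluations are recorded in the trace and skipped.

**GCV degeneracies.** The influence-trace denominator is computed from
the $3 \times 3$ normal matrix; a denominator below $10^{-12}$ (possible
only for a degenerate Jacobian) raises an error rather than returning a
spurious minimum. At $\lambda = 0$ with a full-rank Jacobian it equals
$(N-3)^2$; as $\lambda \to \infty$ it tends to $N^2$ — both limits are
exercised in the test suite against an independent SVD route.

## The learned components

The two networks are trained with a compact, fully deterministic
feed-forward engine written for this package (dense and 1-D convolutional
layers, Adam, seeded initialization and shuffling); the engine is
gradient-checked against finite differences in the test suite.

**Selector network.** Four 1-D convolutional layers (channels 8, 8, 16,
16; kernel 5, ReLU) over the echo axis with average pooling after the
first two, a flatten, one dense layer and a softplus scalar head;
trained with the L1 loss against bilevel-oracle labels, with decoupled
weight decay and best-validation-epoch early stopping. The pooling and
regularization matter at desk-scale training sizes: the label is a
strongly noise-dependent functional of the signal, and an unregularized
flatten-dense head memorizes the training draws without beating the
constant-median baseline on held-out signals. L1 is chosen because the label distribution spans orders of
magnitude and squared error would be dominated by the tail. Predictions
are on the raw $\lambda$ scale to match that loss exactly (a log-scale
option exists, off by default). A trained selector must beat the best
constant predictor (the label median) in held-out L1, or training is
rejected — a selector that cannot is not signal-dependent.

**Parameter networks.** Fully connected (default four hidden layers of
width 256 at full scale; the shipped benchmark configurations use
smaller widths, see below) from the length-$2N$ concatenated input to
three outputs constrained to the feasible set by a sigmoid ($c_1$) and
scaled softplus ($T_2$, scale 100 ms) head — no post-hoc clipping. The
loss is the $B$-weighted squared error; a combined weighted-MSE +
Wasserstein-1 loss (`loss = "mi_ml"`, mixing weight 1 by default) is
provided for the distribution-matching benchmark variant. Inputs enter
unnormalized beyond the model's $s(0) = 1$ convention, since the noise
level itself is informative. The no-ILR reference `(ND, ND)` duplicates
the noisy vector, eliminating input length as a confounder. Three input
variants are tagged and enforced at prediction time: `ndnd`,
`ndreg_gcv`, `ndreg_network` (plus `ndreg_oracle` for diagnostics).

## The voxel pipeline

Gray matter is essentially monoexponential; feeding it to a biexponential
estimator yields noise-determined fractions. Each in-mask voxel is
therefore fit with both a monoexponential and a free-amplitude
biexponential model, compared by Gaussian-residual AIC
$n \ln(\mathrm{RSS}/n) + 2k$ (AICc optional), with ties going to the
simpler model; only strictly-better biexponential voxels enter MWF
estimation. Both candidate models carry a nonnegative constant baseline
by default ($k = 3$ vs $k = 5$): magnitude data plateau at the Rician
noise floor where the signal has decayed away, and without the baseline
the larger model's second exponential fits the floor, classifying
essentially every voxel biexponential (the literal offset-free $k = 2$
vs $k = 4$ comparison is available via `offset = FALSE`, and does
exactly that in Monte-Carlo). In-vivo magnitudes are not
unit-normalized, hence the free amplitude for classification, while each
signal is divided by its first echo before entering the 3-parameter
estimators. Voxel SNR is estimated as the fitted $t = 0$ value over a
residual standard deviation computed from high-signal echoes only
(tail residuals against the noise floor have Rayleigh-compressed
variance and would bias the estimate), and the mapping stage routes $\lambda$ selection by the
median SNR over biexponential voxels: GCV below 50 (where the oracle
distribution is broad and multimodal and GCV tracks its low modes
better), the selector network above. The AIC formula, the $k$ counts
(2 and 4), and the residual-based SNR estimator are this package's
choices where the methodology leaves them open; F-tests or BIC are noted
alternatives.

## Benchmark scale and runtime choices

The shipped benchmark configurations are desk-scale: test ensembles of
500 signals per SNR, training sets of 800–1500 signals, three training
seeds for network comparisons, and hidden widths of 128. These sizes
were chosen so the full benchmark suite completes in minutes on one CPU
core while leaving the method orderings stable across seeds; they are
deliberately smaller than what one would use for a production training
run (tens of thousands of signals, wider nets), and point accuracy of the
learned estimators at this scale sits a few percent above its large-data
asymptote.

## What the synthetic benchmarks do and do not show

The generator emulates: biexponential decay with the canonical label
convention, Rician magnitude noise with the $\sigma = 1/\mathrm{SNR}$
convention, a flat prior over the physiological parameter box, and
voxel images as independent per-voxel signals. It does not emulate:
spatial correlation of noise or parameters, $B_1$ inhomogeneity or
stimulated echoes, more than two water pools, non-uniform echo spacing,
or partial-volume mixtures. Passing benchmarks here therefore show that
the pipeline's components are correct and that ILR's advantage over
plain networks and classical fitting holds under the model's own
assumptions — not that any particular in-vivo accuracy will be attained,
where reference standards are themselves surrogates.

Two measured properties of the frozen study conditions deserve explicit
mention, because they shape any comparison against external benchmarks
of this problem: (i) with the oracle defined on the literal unweighted
norm, the oracle-regularized fit's RMSE in $c_1$ improves sharply with
SNR (to below 0.1 at SNR 100) rather than sitting at a nearly
SNR-independent plateau — per-signal oracle tuning is genuinely powerful
when the slow relaxation time is well sampled; and (ii) at SNR 100 the
selected-$\lambda$ ensembles concentrate over a narrow range, so
Wasserstein-1 distances between selector and oracle ensembles are orders
of magnitude smaller than at SNR 5, even though their ordering (network
closer than GCV) is preserved. Both are reported exactly as measured.

## Reproducing the numbers

`scripts/acceptance.R` regenerates every benchmark quantity from scratch
(data generation, fitting, selection, training, evaluation) under a
single seed; the README describes how to run it. The test suite
(`tests/testthat/`) contains the oracle-equivalence checks (grid-search
oracles, finite-difference Jacobians, transport-enumeration Wasserstein,
projector-trace GCV limits) at tight tolerances and the ordering
properties at benchmark scale.
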