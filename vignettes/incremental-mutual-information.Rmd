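---
title: "Incremental mutual information: model and implementation notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental mutual information: model and implementation notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incmi)
```

## The problem

Extracellular recordings give spike trains from pairs of neurons, and the
question is what the connection between them looks like: how strong it is and
with what delay and duration one neuron influences the other. The classical
answer, the cross-correlation function $C_{XY}[\delta]$, measures the *total*
linear dependency between $X[n]$ and $Y[n-\delta]$ and therefore conflates the
connection with every other source of dependency: temporal correlations inside
each train (stimulus drive, intrinsic dynamics, refractoriness) and inputs
shared between the neurons. A broad cross-correlogram can mean a dynamic
connection, or a static connection seen through autocorrelated activity; a
weak connection can disappear entirely under a strong shared input.

`incmi` implements a conditional, delay-resolved information measure that
removes the predictable part of both trains before asking what remains between
them.

## The measure

Work with binarized trains ($X[n], Y[n] \in \{0,1\}$, at most one spike per
bin). For a delay $\delta$, collect the *conditioning vector*

$$V_\delta[n] = \big(X[n-\omega..n-1],\; X[n+1..n+\omega],\;
  Y[n-\delta-\omega..n-\delta-1],\; Y[n-\delta+1..n-\delta+\omega]\big),$$

the windowed past **and** future of both trains around the two samples of
interest, excluding those samples themselves: $4\omega$ binary variables. The
incremental mutual information at delay $\delta$ is the additional entropy
reduction contributed by $Y[n-\delta]$ once $V_\delta$ is known:

$$\Delta I[\delta] = H\!\big(X[n] \mid V_\delta[n]\big) -
  H\!\big(X[n] \mid V_\delta[n], Y[n-\delta]\big),$$

in bits; equivalently the conditional mutual information
$I(X[n]; Y[n-\delta] \mid V_\delta[n])$. The normalized form divides by the
maximum the increment could possibly be, the remaining uncertainty
$H(X[n] \mid V_\delta)$, giving a dimensionless value in $[0,1]$ analogous to
a partial correlation coefficient (`normalized_imi()`).

Three design points deserve explicit statement, because the defining equations
leave them open:

* **Window anchoring.** The $X$-window is centred on $n$ and the $Y$-window on
  $n-\delta$, each excluding its centre. Anchoring the $Y$-window at
  $n-\delta$ makes the excluded sample exactly the one whose incremental
  contribution is being measured, and it produces the characteristic
  self-masking behaviour: for a static connection at delay $\delta^*$, the
  profile at $|\delta - \delta^*| \le \omega$ conditions on $Y[n-\delta^*]$
  itself and the increment collapses — which is what makes the peak sharp.
  Both anchorings can be exercised through `build_conditioning_words()`;
  this one is the package-wide default.
* **Edge handling.** Samples whose windows overrun either end of the trains
  are dropped (no padding), so the sample count is
  $N - 2\omega - |\delta|$ and differs across delays. Profiles are *not*
  re-aligned to a common sample set: each delay uses all data available to
  it, matching the independent per-delay computation, and the count is
  reported in the `n` column.
* **Word encoding.** Windows are packed into a single integer with a fixed
  bit order (X-past oldest first, X-future, Y-past oldest first, Y-future),
  so entropy tables are bit-reproducible across runs and platforms.

The *past-only* variant (`past_only_imi()`) conditions on
$X[n-\omega..n-1]$ and $Y[n-\delta-\omega..n-\delta-1]$ only — the
transfer-entropy relative of the measure. It removes slow dependencies
correctly for delays below the true connection delay but leaks them above it:
once $Y[n-\delta^*]$ is no longer inside the conditioning window, the
autocorrelated $Y[n-\delta]$ still predicts $X[n]$ through it. The test suite
demonstrates this asymmetry on the static-connection scenario; it is the
reason the full past-and-future conditioning is the default.

## Linear comparators

`cross_correlation()` is the Pearson coefficient between $X[n]$ and
$Y[n-\delta]$ over the overlap. `partial_cross_correlation()` is its
conditional analogue: both variables are residualized by least squares on the
$4\omega$ window variables (as real regressors) and the residuals are
correlated. Residualization is the standard equivalent formulation of partial
correlation; collinear regressor columns (which arise naturally, e.g. for
deterministic copies) are dropped with a warning via the QR decomposition.
With $\omega = 0$ the regressor set is empty and the measure reduces exactly
to the cross-correlation on the same sample set — a property the tests pin.

## Trial-based decomposition

With repeated trials of identical stimulation, dependency splits into a
stimulus-locked and a trial-variable part. For correlation this is the
classical shift-predictor: `signal_correlation()` correlates $X^i[n]$ with
$Y^j[n-\delta]$ pooled over ordered trial pairs $i \ne j$, and
`noise_correlation()` is the within-trial total minus the signal part. The
pooling convention (moments accumulated over pairs and time, then one Pearson
coefficient) makes signal + noise = total hold exactly by construction. All
ordered pairs are used up to 50 trials; beyond that 2000 seeded random pairs.

The information analogue replaces the correlation by the incremental entropy
reduction. With $V^i$ built entirely from trial $i$:

$$\Delta I_{sig} = H(X^i[n] \mid V^i) - H(X^i[n] \mid V^i, Y^j[n-\delta]),
\qquad
\Delta I_{noise} = H(X^i[n] \mid V^i, Y^j[n-\delta]) -
                   H(X^i[n] \mid V^i, Y^i[n-\delta]).$$

The three entropy terms are shared between the two differences, so
$\Delta I_{sig} + \Delta I_{noise}$ telescopes to the within-trial total
exactly — at machine precision, with or without bias correction. When the
stimulus correlations are slow relative to the bin size, the within-trial
context already predicts the stimulus-locked component and
$\Delta I_{sig} \approx 0$ even where the signal correlation is broad; the
connection, being fast, survives in $\Delta I_{noise}$.

## Entropy estimation

All entropies are plug-in estimates on discrete words,
$\hat H = \log_2 n - \tfrac1n \sum_k c_k \log_2 c_k$, in bits throughout (the
base is a convention; bits make the deterministic-copy limit exactly 1).
Conditional entropies are computed as $H(T,C) - H(C)$ on packed joint codes.

The plug-in estimator is biased downward by roughly $(K-1)/(2N\ln 2)$ for $K$
occupied states. With $\omega = 2$ the joint words span up to $2^{10}$ states,
and at experimentally realistic $N$ the bias is material. The correction fits
the sample-size dependence

$$\hat H(N') = H_\infty + \frac{a}{N'} + \frac{b}{N'^2}$$

exactly through three points: the full sample, the average of the two
contiguous halves, and the average of the four contiguous quarters, giving the
closed form $H_\infty = (8\hat H_1 - 6\hat H_2 + \hat H_4)/3$. Contiguous
rather than interleaved blocks preserve any residual temporal structure within
each fraction. Because the extrapolation is linear in the three fitted values,
correcting $H(T,C)$ and $H(C)$ separately and subtracting is identical to
extrapolating the conditional entropy directly.

Two honest caveats, both verified numerically in the test suite:

* The correction pays for bias removal with variance. On a *binary* alphabet
  the plug-in bias ($\approx 7 \times 10^{-4}$ bits at $N = 2^{10}$) is far
  below the sampling noise, and the extrapolated estimate is *not* closer to
  the truth in the typical replicate — no subsampling scheme can win there,
  since the correction's own spread is of the order of the bias it removes.
  The correction earns its keep exactly where this package uses it: on
  word-valued conditional entropies with hundreds of states, where the bias
  dominates (on 256-state word sources with known entropy it beats the raw
  estimate in ~90% of replicates and cuts the mean error several-fold).
* Corrected increments can come out slightly negative under the null. Raw
  $\Delta I$ profiles keep their sign for diagnostics; clipping to $[0,1]$ is
  applied only in the normalized output, and never to the resampled null
  values used for significance thresholds (the shuffle leaves the common
  denominator $H(X|V)$ unchanged, so clipping the null would shrink its
  spread and inflate the flag rate).

`imi()` refuses to bias-correct fewer than 8 valid samples (the quarter
splits degenerate) and names the minimum train length in the error.

## Statistical inference

Two bootstrap procedures operate on the aligned triples
$(X[n], Y[n-\delta], V_\delta[n])$ *after* the vectors are formed, so the
temporal structure captured by the words is preserved:

* **Confidence intervals** (`bootstrap_ci()`): whole triples are resampled
  with replacement (default 100 resamples) and the interval is the mean
  $\pm 2$ standard deviations of the resampled measure.
* **Significance** (`significance_threshold()`): $Y[n-\delta]$ is resampled
  separately from the $(X, V)$ pairs, destroying the X–Y dependency while
  preserving each marginal; the threshold is the null mean $+ 2$ SD, and an
  observed value above it is flagged. The default shuffle is a permutation
  (sampling without replacement), which preserves the Y marginal exactly;
  i.i.d. resampling with replacement is available via `shuffle = "resample"`.

No multiple-testing correction is applied across delays: each delay is
reported against its own 2-SD threshold, and with ~2% one-sided false-flag
probability per delay occasional isolated flags on null profiles are
expected. The per-delay flag rate under the independence null is checked in
the suite (< 15% across 50 seeded replicates).

## The simulator

`simulate_pair()` implements a dichotomized-Gaussian two-neuron circuit:
$Y[n] = \mathbf 1\{s_y[n] \ge \theta\}$ and
$X[n] = \mathbf 1\{s_x[n] + \varepsilon\,\mathrm{drive}[n] \ge \theta\}$,
where the drive is $Y[n-\delta^*]$ (static connection) or the convolution of
$Y$ with a causal Gaussian kernel (dynamic connection), and $s_x, s_y$ are
unit-variance Gaussian inputs. With $\theta = 1$ each train spikes with
probability $1 - \Phi(1) \approx 0.16$ per bin. Conventions:

* The connection kernel `gaussian_filter(peak_delay, half_width)` reads "half
  width" as half-width at half-maximum
  ($\sigma = \mathrm{hw}/\sqrt{2\ln 2}$), is truncated at $4\sigma$ and at
  negative lags, and is normalized to unit peak so $\varepsilon$ keeps its
  meaning as connection strength.
* Temporally correlated *inputs* are white noise smoothed with a symmetric
  zero-centred Gaussian kernel and rescaled to exactly unit variance by the
  kernel norm. The symmetry matters: a causal half-kernel would leave a sharp
  autocorrelation edge at lag zero — a fast, unpredictable component of the
  shared input that no finite conditioning window can remove — and the
  weak-connection scenario would wrongly peak at $\delta = 0$. Causality is
  physically meaningful for the connection drive, not for noise shaping,
  where only the autocorrelation shape matters.
* In the shared-input modes the correlation between the two raw sources is
  imposed before filtering; identical filters preserve the lag-zero
  coefficient.

Four presets (`circuit_preset()`) cover the canonical scenarios: a strong
dynamic connection under white inputs (`"dynamic"`); a strong static
connection at 4 bins behind a temporally correlated input to Y
(`"static_correlated"`, $\varepsilon = 0.5$); a weak static connection at 3
bins under a shared correlated input (`"weak_shared"`, $\varepsilon = 0.25$,
source correlation 0.5); and the same circuit with the shared input made
white (`"weak_shared_white"`), where the shared input *cannot* be conditioned
out and the profile legitimately shows two peaks, at 0 and at the connection
delay.

`simulate_trials()` freezes one slow stimulus realization (half-width 10 bins
by default) across trials and mixes it with per-trial noise as
$\sqrt{w}\,u + \sqrt{1-w}\,e^i$, keeping unit variance so the marginal rate
is unchanged; $w = 0.5$ by default. The limits behave as expected: $w = 1$
gives identical trials, $w = 0$ independent ones.

What the generator does **not** emulate: refractoriness and bursting,
nonstationary rates, non-Gaussian stimulus statistics, spike-sorting
contamination, and more than two neurons. Passing tests on these circuits
shows the estimators recover known ground truth under controlled
correlations; it does not certify performance on data whose violations of
these assumptions are severe.

## Problem sizes and numerical choices

The packaged checks run the two headline scenarios at $2^{20}$ samples with
$\omega = 2$ over delays $-10..10$ (matching the simulation scale at which
the scenarios are defined), and the significance scenario at $2^{18}$ samples
with 100 permutation resamples per delay — sizes chosen to make the full
suite complete in a few minutes on one core while keeping every effect far
above its null spread. Property checks (oracle equivalence against
brute-force histogram conditional MI, decomposition identities at
$10^{-9}$, calibration of the 2-SD flag) run at $2^{10}$–$2^{14}$ samples.
Degenerate inputs fail loudly rather than silently: non-binary values, bins
with two spikes, trains too short for the windows, and constant trains (for
correlation measures) are all errors; a vanishing normalization denominator
yields 0 by convention rather than NaN, with $10^{-9}$ as the tolerance.

## Limitations

The measure needs the dependency of interest to be *fast* relative to the
bin size and the nuisance dependencies to be *slow*: a shared input white at
the bin scale is indistinguishable from a zero-delay connection (the
`"weak_shared_white"` scenario shows precisely this). Conditioning is
restricted to one pair of neurons; dependencies routed through unobserved
third neurons at bin-scale speed will contaminate the profile. Sample-size
requirements grow exponentially in $\omega$ ($2^{4\omega}$ context states),
which is why $\omega$ of 2–4 with millisecond-scale bins is the practical
range, and why the entropy tables are capped at $2^{24}$ states.
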