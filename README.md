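# incmi

Delay-resolved, model-free measures of the strength and dynamics of the
connection between two neurons, from binned binary spike trains.

## The problem

Functional connectivity between simultaneously recorded neurons is usually
read off the cross-correlation function C_XY[δ]. But C_XY measures *total*
linear dependency: temporal correlations within each train (stimulus drive,
intrinsic dynamics) and inputs shared between neurons all fold into the same
curve as the connection itself. A broad correlogram may reflect connection
dynamics or input autocorrelation; a weak connection can be masked entirely
by a shared input.

`incmi` implements **incremental mutual information (IMI)**: condition out
the windowed past and future of *both* trains first, then measure, delay by
delay, the additional entropy reduction that the other neuron contributes.
With the conditioning vector

    V_δ[n] = (X[n−ω..n−1], X[n+1..n+ω], Y[n−δ−ω..n−δ−1], Y[n−δ+1..n−δ+ω])

the measure is

    ΔI[δ] = H(X[n] | V_δ)  −  H(X[n] | V_δ, Y[n−δ])        (bits)

and the normalized form ΔĨ[δ] = ΔI[δ] / H(X[n] | V_δ) ∈ [0, 1] is the
information analogue of a partial correlation coefficient. Dependencies that
are slow relative to the bin size are predictable from the windows and drop
out; dependencies at the bin scale — the connection — remain. No linearity
assumption, no repeated trials required.

The package also provides the linear comparators (cross-correlation, partial
cross-correlation by residualization), trial-based signal/noise
decompositions of both correlation and IMI (exact telescoping identity),
quadratic-extrapolation bias correction for the entropy estimates, bootstrap
confidence intervals and permutation significance thresholds, and a
dichotomized-Gaussian circuit simulator for validation.

## Worked example: unmasking a weak connection

Simulate two neurons sharing a temporally correlated input (source
correlation 0.5) with a weak static connection Y → X at a delay of 3 bins
(ε = 0.25) — the scenario where correlation analysis fails:

```r
library(incmi)
pair <- simulate_pair(circuit_preset("weak_shared", n_samples = 2^18, seed = 42))
prof <- normalized_imi(pair$x, pair$y, deltas = -6:6, omega = 2)
prof
#> # Delay profile: normalized_imi (fraction), omega = 2, bias-corrected
#> # A tibble: 13 × 3
#>    delta    value      n
#>    <int>    <dbl>  <int>
#>  1    -6 0.000866 262134
#>  2    -5 0.000295 262135
#>  3    -4 0.000974 262136
#>  4    -3 0.00139  262137
#>  5    -2 0.00139  262138
#>  6    -1 0.00136  262139
#>  7     0 0.000553 262140
#>  8     1 0.000504 262139
#>  9     2 0.00642  262138
#> 10     3 0.0288   262137
#> 11     4 0.00799  262136
#> 12     5 0.000845 262135
#> 13     6 0.000599 262134
```

The normalized IMI profile has a single sharp peak at the true connection
delay of 3 bins: about 2.9% of the remaining uncertainty in X is resolved by
Y at that delay, and an order of magnitude less anywhere else. The
cross-correlation of the same pair peaks near zero delay (value ≈ 0.32,
driven entirely by the shared input) and shows no local maximum at 3:

```r
glance(cross_correlation(pair$x, pair$y, deltas = -6:6))
#> # A tibble: 1 × 6
#>   measure           peak_delta peak_value n_deltas omega bias_corrected
#>   <chr>                  <int>      <dbl>    <int> <int> <lgl>
#> 1 cross_correlation          1      0.319       13    NA NA
```

Results are tibbles, so they pipe into dplyr/ggplot2 directly; `autoplot()`
draws a profile with its confidence band and significance threshold, and
`tidy()`/`glance()` give broom-style summaries.

A thin command-line wrapper over the same functions is installed at
`inst/cli/imitool.R` (`simulate`, `imi`, `xcorr`, `pxcorr`, `signal-noise`,
`reproduce`), writing delimited-text profiles with YAML metadata sidecars.

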