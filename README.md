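# mftfcca

Directed spectral information flow between mixed-frequency time series.

Many paired recordings are sampled at different rates — electrophysiology
against calcium imaging, monthly price indices against quarterly GDP. The
question "does X drive Y, and at which oscillatory frequency?" is normally
answered with spectral Granger causality (GC) from a vector autoregressive
(VAR) model, but VAR machinery needs a common clock, and mixed-frequency
VAR extensions are slow and linear. **MF-TFCCA** is a nonparametric
alternative: the fast channel X is turned into a short-time Fourier
transform X̃(t, ω) aligned to the slow channel's clock and z-scored per
frequency; the canonical correlation (CC) between X̃ and the slow channel Y
is computed at every signed lag Δ on the slow sample grid,

ρ(Δ) = max<sub>u,v</sub> corr(X̃(t)u, Y(t − Δ)v),

and the asymmetry of the lag-CC curve encodes directionality: high CC at
negative lag (X̃'s history preceding Y) is evidence for X → Y, at positive
lag for Y → X. The canonical coefficient profile over frequency identifies
the driving rhythm, a band-stop "filter-one-frequency-out" re-run quantifies
each band's contribution as a relative CC gain, and phase-randomized
surrogates (amplitude spectrum preserved, phases randomized) provide the
null distribution and the direction call.

The package also ships the machinery to validate all of this from scratch:
the benchmark VAR systems with known analytic spectral-GC ground truth
(Geweke decomposition, including conditional trivariate causality),
nonlinear generators (phase–amplitude coupling, memoryless amplitude
modulation, the two-species logistic map, the coupled Rössler–Lorenz
system), multi-trial VAR fitting, and a multi-trial mixed-frequency VAR
Granger test as the parametric baseline.

## Worked example

Simulate the unidirectional X → Y benchmark (X carries fast and slow
oscillations and drives Y), decimate Y to 40 Hz, and run the pipeline:

```r
library(mftfcca)

model <- var_unidirectional_xy()
ts <- simulate_var(model, n_trials = 20, duration = 10, seed = 42)
ts <- decimate(ts, "y", 5)

fit <- mftfcca(ts, x = "x", y = "y", window_len = 0.15,
               lag_range = c(-0.4, 0.4), n_surrogates = 50, seed = 1)
summary(fit)
#> MF-TFCCA: x (200 Hz) vs y (40 Hz), 20 trials, window 0.15 s, mode 'complex'
#>   peak CC at negative lag: 0.346 at -0.150 s (x -> y side)
#>   peak CC at positive lag: 0.214 at +0.325 s (y -> x side)
#>   direction call: x_to_y (50 surrogates)
#>   x -> y peak: p = 9.689e-13 (t-test vs surrogate null)
#>   y -> x peak: p = 0.1344 (t-test vs surrogate null)
```

The profile is asymmetric toward negative lags and only the X → Y side
survives the surrogate test: information flows from the fast channel to the
decimated one. Where does it flow spectrally?

```r
driving_frequency_report(fit, peak_lag = peak_lags(fit)$neg_lag,
                         bands = list(c(10, 16), c(78, 86)))
#> Driving-frequency report at lag -0.150 s (grid step 0.781 Hz)
#>   coefficient peaks:
#>      14.84 Hz  magnitude 0.226
#>   filter-one-frequency-out CC gains:
#>     [10, 16] Hz: -43.7%
#>     [78, 86] Hz: +0.8%
```

The coefficient profile peaks near 15 Hz — the system's low-frequency pole
band that survives decimation — and band-stopping that band costs 44% of
the CC, while removing the fast band (suppressed by the anti-alias filter)
costs nothing. The analytic ground truth from the same coefficient matrices
confirms the directional structure:

```r
analytic_sgc(model, "x", "y")
#> Spectral GC x -> y: peak 2.0267 at 83.37 Hz; time-domain GC 0.5392
max(analytic_sgc(model, "y", "x")$value)   # null direction
#> [1] 0
```

`plot(fit)` draws the lag-CC curve with the surrogate envelope and the
window-length boundary markers.

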