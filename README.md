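# micronue

Microbial **nitrogen use efficiency (NUE)** from ¹⁵N isotope pool dilution,
and the stoichiometric threshold analysis that locates the switch between
carbon and nitrogen limitation of decomposer communities in soil and
decomposing plant litter.

Heterotrophic microbes take up organic N (mostly free amino acids) at a
gross rate *U*<sub>N</sub> and partition it between growth
(*G*<sub>N</sub>) and release as ammonium (gross N mineralization,
*M*<sub>N</sub>):

    NUE = (U_N − M_N) / U_N,   0 ≤ NUE ≤ 1

High NUE means efficient sequestration of organic N into biomass and low
mineralization; low NUE means excess N is shed as ammonium.  For a
(near-)homeostatic community the mass balance couples NUE to carbon use
efficiency (CUE) and the resource and biomass C:N mass ratios,

    B_C:N = R_C:N · CUE / NUE,

and the **threshold elemental ratio** — the resource C:N at which
metabolic control switches from C limitation (below) to N limitation
(above) — is

    TER_C:N = (NUE / CUE) · B_C:N.

The package is aimed at soil ecologists and biogeochemists working with
¹⁵N pool-dilution assays and ecological stoichiometry.  It provides:

* **`gross_rates_kb()` / `simulate_ipd_forward()`** — the two-point
  analytical pool-dilution estimator for gross production and consumption
  of an N pool (amino acids, ammonium, nitrate), with a numerical ODE
  integrator of the same system as an independent oracle.
* **`compute_nue()`, `compute_nue_inorg()`, `imbalance()`, `ter()`,
  `cue_at_ter()`, `mass_balance_solve()`, `fit_homeostasis()`** — the NUE
  statistic, its inorganic-N extension, C:N imbalance, the TER/CUE
  algebra, and the log–log homeostasis regression.
* **`fit_piecewise()`, `fit_regression_tree()`, `fit_saturating()`,
  `fit_linear()`** — threshold and curve models of NUE against resource
  C:N or C:N imbalance: continuous two-segment (break-point) regression
  with profiled least squares, a single-predictor CART with 1-SE pruning,
  a saturating rectangular hyperbola, and ordinary least squares.
* **`kruskal_wallis()`, `dunn_test()`** — nonparametric substrate
  comparison with tie correction and family-wise significance.
* **`generate_dataset()`** — a synthetic-data generator emulating a
  93-sample litter/soil survey (36 mineral, 19 organic, 38 litter;
  resource C:N 9–62; biomass C:N 4–25) with ground-truth tables, so every
  pipeline stage is testable by parameter recovery.
* **`read_sample_table()`, `read_tracer_table()`,
  `nue_sample_records()`, `analyze_nue()`** — validated CSV/TSV I/O and
  the end-to-end pipeline.

## Worked example

Generate a synthetic survey, run the full pipeline from tracer time
courses to fitted threshold models:

```r
library(micronue)

ds  <- generate_dataset(generator_config(), seed = 1)
rec <- nue_sample_records(ds$samples, ds$tracer)  # IPD rates -> NUE
analyze_nue(rec, tree_seed = 1)
```

```
== Substrate comparison of NUE ==
Kruskal-Wallis: H(2) = 59.6, P = 1.14e-13  (n = 38/19/36)
  group_i group_j        Q   p_adjusted significant
1  litter organic 3.590218 9.912053e-04        TRUE
2  litter mineral 7.701853 4.023209e-14        TRUE
3 organic mineral 2.759627 1.736024e-02        TRUE

== Homeostasis ==
Stoichiometric homeostasis regression (log10 biomass C:N ~ log10 resource C:N)
  slope 0.09478 (se 0.0354), intercept 0.8264, R^2 0.094, P 0.00935, n 71
  classification: homeostatic (slope < 0.25)

== NUE ~ resource C:N ==
Regression tree (1-SE pruned): 4 leaf/leaves
  splits at: 12.45, 18.208, 29.898
  leaf means: 0.3732, 0.6343, 0.7988, 0.9424
  cv relative error 0.364, R^2 equivalent 0.735, n 93
Two-segment (break-point) regression
  break point: 18.81 (se 1.11), y at break: 0.7857
  slopes: 0.04857 (below) / 0.005217 (above); R^2 0.722, F(3,89) = 76.92, P 1.24e-24, n 93

== NUE ~ C:N imbalance ==
Saturating regression: y = a x / (k + x)
  a (asymptote) = 1.267 (se 0.0856), k (half-saturation) = 1.749 (se 0.358)
  R^2 0.540, F(1,69) = 80.96, P 3.01e-13, n 71

== Litter only ==
Linear fit: y = 0.921 + 0.0004772 x; R^2 0.001, F(1,36) = 0.05161, P 0.822, n 38
```

Reading the output: NUE rises steeply with resource C:N up to a break
point near 19 (the generator's truth is 20), where NUE ≈ 0.79, and is
nearly flat above it — microbial communities on N-poor substrates retain
essentially all organic N they take up, while on N-rich mineral soils a
large fraction is mineralized.  The log–log homeostasis slope (≈ 0.09,
well below 0.25) says biomass C:N barely tracks resource C:N.

The TER/CUE desk algebra works off printed numbers alone:

```r
ter(NUE = 0.83, CUE = 0.22, B_CN = 5.4)
#> TER_C:N = 20.37  (NUE = 0.83, CUE = 0.22, biomass C:N = 5.4)
cue_at_ter(NUE = 0.83, B_CN = 5.4, TER_CN = 20)
#> [1] 0.2241
solve_saturating_inverse(saturating_model(1.03, 0.92), 0.83)
#> [1] 3.818348
```

i.e. a community with NUE 0.83 and biomass C:N 5.4 at a threshold of 20
implies CUE ≈ 0.22, and on the saturating NUE–imbalance curve that
threshold sits ≈ 3.8× above biomass C:N.

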