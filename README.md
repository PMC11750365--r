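# herbcomp

Tools for asking a deceptively simple ecological question: **when does being
eaten make a plant better off?** A herbivore that feeds on two competing
plant species can benefit the focal species by suppressing its competitor
more than it suppresses the focal species itself. `herbcomp` implements the
quantitative machinery for the canonical freshwater test system — a
free-floating macrophyte (duckweed, counted in fronds), a planktonic green
alga (counted in 10^6 cells ml^-1), and a grazing pond snail — but the
engine is unit-agnostic and applies to any two-competitors/one-grazer
configuration.

## The model

Two Lotka–Volterra competitors share a constant-abundance herbivore `Nh`:

    dN1/dt = r1 N1 (1 − a11 N1 − a12 N2 − β1 Nh)
    dN2/dt = r2 N2 (1 − a22 N2 − a21 N1 − β2 Nh)

with intrinsic growth rates `r_i`, intra-/interspecific competition
coefficients `a_ii`, `a_ij`, and per-herbivore consumption coefficients
`β_i`. The invasion growth rate of the focal species into the resident
competitor's equilibrium, with herbivory (`IGRw = r1(1 − a12 N2w − β1 Nh)`,
`N2w = (1 − β2 Nh)/a22`) and without (`IGRwo = r1(1 − a12/a22)`), yields the
density-independent **benefit condition**

    β1/β2 < a12/a22  ⇔  herbivory raises the focal species' invasion fitness

(valid while the resident persists under herbivory, `β2·Nh < 1`). The
package provides:

- `simulate_model()` — compiled adaptive Runge–Kutta 4(5) integration with
  reset events (the laboratory practice of re-adjusting a background
  species to a nominal density);
- `isocline()`, `invasion_analysis()`, `herbivory_benefit()`,
  `classify_outcome()`, `collapse_search()` — phase-plane and
  mutual-invasibility analysis, including the minimal herbivore number that
  collapses both species;
- `estimate_all()` / `bootstrap_params()` — estimation of all eight
  coefficients from monoculture gradients, fixed-competitor assays and 24 h
  feeding assays, with percentile bootstrap confidence intervals and a
  significance-zeroed variant;
- `per_capita_growth()`, `normalized_fitness()`, `fit_calibration()` — the
  field/laboratory summary statistics (log growth rate, bounded
  herbivory-vs-control coverage contrast, OD750-to-cell-count reference
  line);
- `gen_assay_table()`, `gen_microcosm()`, `gen_field_series()`,
  `write_fixtures()` — a synthetic-data generator with known ground truth
  and a controlled lognormal noise model, so the whole pipeline is testable
  end to end without any external data;
- `herbcomp_cli()` — subcommands `synth`, `estimate`, `bootstrap`,
  `simulate`, `predict`, `phase` for reproducible scripted runs.

## Worked example

```r
library(herbcomp)

truth <- fixture_params()          # benefit regime, a21 = 0, collapse at 2
tab   <- gen_assay_table(truth, design_spec(4),
                         noise_model(cv = 0.1, seed = 7))
best  <- bootstrap_params(tab, n_boot = 200, seed = 11)
best
#> Coefficient estimates (method: ode-fit)
#>            point       lower      upper     zeroed
#> r1    0.31275000  0.30072000 0.32471000 0.31275000
#> r2    0.70907000  0.69947000 0.71844000 0.70907000
#> a11   0.00099884  0.00093047 0.00107980 0.00099884
#> a12   0.10322000  0.07491900 0.12819000 0.10322000
#> a21   0.00012454 -0.00013660 0.00026022 0.00000000
#> a22   0.10162000  0.09860800 0.10541000 0.10162000
#> beta1 0.57079000  0.33397000 0.89976000 0.57079000
#> beta2 0.99535000  0.78891000 1.16230000 0.99535000
#> percentile bootstrap: n_boot = 200, seed = 11, failed = 0
```

The interval for `a21` spans 0, so the zeroed variant treats the focal
species' effect on its competitor as statistically absent — the asymmetric
competition the system is known for. Feeding the (zeroed) estimates back
into the analysis:

```r
est <- as_model_params(c(as.list(best$zeroed), Nh = 1))
invasion_analysis(est)
#> Invasion analysis (focal = species 1)
#>   resident sp2 equilibrium: N2wo = 9.84069 (no herbivore), N2w = 0.0457206
#>   IGRwo = -0.00492338, IGRw = 0.132761 per day
#>   verdict: benefit (margin a12/a22 - beta1/beta2 = 0.4422853)
collapse_search(est, max_herbivores = 5)$min_collapse_Nh
#> [1] 2
```

One snail flips the focal species from a losing invader (`IGRwo < 0`) to a
winning one (`IGRw > 0`); two snails drive both growth brackets negative
and collapse the whole beaker. Exact numbers vary with the noise seed; the
verdict, the zeroing of `a21` and the collapse threshold are the designed
regime of the fixture.

## Documentation

The methods vignette (`vignettes/herbivory-competition-model.Rmd`) explains
the model, its assumptions, the estimation and bootstrap design choices,
what the synthetic generator does and does not emulate, and known
limitations.
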