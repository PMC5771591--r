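# cardiomef

Multiscale simulator of mechano-electric feedback (MEF) in a contracting
cardiac left ventricle. A human mid-myocardial ventricular myocyte ionic
model (TNNP 2004 formulation) is extended with a stretch-activated
channel (SAC), coupled to a Negroni–Lascano-style myofilament model, and
embedded in a fiber-ring ventricle with isotropic monodomain propagation
and lumped (Windkessel) haemodynamics. Stretch changes the electrics
through the SAC; the electrics drive contraction through calcium — the
loop closes every time step.

The package is tidyverse-native: simulations return tibbles (or objects
with `tidy()`/`glance()` methods and `autoplot()` helpers), and the
numerical core is compiled C++ (Rcpp). Everything is deterministic — no
random numbers anywhere.

## Worked example

Single cell: steady stretch with the SAC enabled, control vs 20 %
stretch.

```r
library(cardiomef)

sc <- run_single_cell_stretch(lambdas = c(1.0, 1.2, 1.3))
sc$markers
#> # A tibble: 3 × 5
#>   lambda    at    rt   apd repolarization_failed
#>    <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1    1   0.411  282.  281. FALSE
#> 2    1.2 0.376  276.  275. FALSE
#> 3    1.3 0.361  274.  273. FALSE
```

Stretch opens the SAC and shortens the action potential moderately
(about 8 ms at λ = 1.3). With the fixed SAC conductance the effect is
deliberately not tuned larger — see the limitations section of the
methods vignette for a quantitative analysis of how strong the channel
would need to be to produce resting-potential elevation of ~10 mV or
stretch-induced repolarization failure.

Tissue: a full contracting-ventricle beat at resting length, with
activation/recovery markers for all 480 wall elements and the
pressure–volume loop.

```r
sim <- simulate_ventricle(duration = 700)
summarize_markers(ventricle_markers(sim))
#> # A tibble: 1 × 9
#>   n_fibers n_activated n_failed earliest_at latest_at first_rt last_rt min_apd
#>      <int>       <int>    <int>       <dbl>     <dbl>    <dbl>   <dbl>   <dbl>
#> 1      480         480        0        4.29      61.6     301.    340.    278.
#> # ℹ 1 more variable: max_apd <dbl>

glance(generate_pv_loop(sim))
#> # A tibble: 1 × 5
#>     edv   esv stroke_volume ejection_fraction peak_pressure
#>   <dbl> <dbl>         <dbl>             <dbl>         <dbl>
#> 1  99.9  60.2          39.7             0.397          112.
```

The preload study (the package's headline protocol) compares the
per-fiber APD extrema across initial stretches for the control and
heart-failure parameter sets:

```r
tab <- run_ventricle_preload(preloads = c(0, 10, 15, 20, 25))
tab
#> # A tibble: 5 × 5
#>   stretch_ratio min_apd_control min_apd_hf max_apd_control max_apd_hf
#>           <dbl>           <dbl>      <dbl>           <dbl>      <dbl>
#> 1          1               278.       270.            297.       293.
#> 2          1.1             276.       269.            294.       291.
#> 3          1.15            275.       269.            293.       290.
#> 4          1.2             274.       268.            291.       289.
#> 5          1.25            273.       267.            290.       289.
```

With the frozen remodeling factors the heart-failure arm has slightly
*shorter* APD than control (the calcium-current and exchanger factors
outweigh the potassium-current reductions); the methods vignette
discusses this direction and why the factors are shipped untouched as a
calibration artifact.

## Command-line interface

```sh
cardiomef single-cell --lambda 1.2 --out out/
cardiomef single-cell --lambda 1.3 --no-sac --out out/
cardiomef ventricle   --preload 20 --hf --out out/
cardiomef pv-loop     --preload 10 --out out/
cardiomef ventricle   --config my-config.yaml --out out/
```

`--config` takes a YAML file mirroring
`inst/extdata/default-config.yaml`; omitted keys keep their defaults and
unknown keys are rejected. Every output CSV carries a provenance header
(package version and all settings).

## Package layout

* `R/cell*.R` — ionic model, parameters, heart-failure remodeling.
* `R/sac.R` — stretch-activated channel.
* `R/myofilament.R` — cross-bridge/troponin force model.
* `R/ventricle.R` — geometry, diffusion, coupled simulation, PV loops.
* `R/markers.R` — AT/RT/APD extraction and summaries.
* `R/protocols.R` — the standard study protocols with CSV output.
* `R/config.R` — YAML configuration round-trip.
* `exec/cardiomef` — the CLI.
* `src/` — the compiled numerical core.
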