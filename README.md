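# speckleflow

Laser speckle contrast imaging (LSCI) analysis for blood-flow mapping, with a
physics-grounded dynamic-speckle simulator so the whole pipeline can be
validated without instrument data.

LSCI records the interference pattern of coherent light backscattered from
tissue. Moving red blood cells decorrelate the speckle field on a time scale
τ<sub>c</sub>, and a camera exposure *T* blurs the pattern in proportion to
*x = T/τ<sub>c</sub>*. The blurring is measured by the speckle contrast
*K = σ/⟨I⟩* and related to the decorrelation time through the speckle
correlation model

> K²(T) = βρ² (e<sup>−2x</sup> + 2x − 1)/(2x²)
> &nbsp;+ 4βρ(1−ρ) (e<sup>−x</sup> + x − 1)/x²
> &nbsp;+ ϑ<sub>n</sub>,  x = T/τ<sub>c</sub>

with speckle-averaging factor β, dynamic-light fraction ρ, and a
noise/nonergodic floor ϑ<sub>n</sub>. Since scatterer speed is
v = λ/(2πτ<sub>c</sub>), fitting K²(T) across several exposures
(multi-exposure speckle imaging, MESI) yields relative flow estimates
τ<sub>0</sub>/τ<sub>c</sub>, and inverting a single-exposure contrast map
yields per-pixel 1/τ<sub>c</sub> flow maps.

The package is aimed at people building or validating LSCI instruments and
analysis pipelines: it covers frame quality control (motion-artifact
rejection, exposure-validity masking), the three standard contrast schemes
(spatial, temporal, noise-reduced), model evaluation/inversion/fitting,
vessel cross-section profiling with laminar-parabola checks, paired pre/post
comparisons, relative-flow linearity regression, and synthetic phantoms
(capillary tube, laminar vessels, motion-blur injection) with known ground
truth.

## Worked example: a multi-exposure capillary flow study

Simulate the standard syringe-pump experiment — seven flow rates
(10–100 µL/min) × four exposures (4.96–27 ms), 80 frames per stack, tube
τ<sub>c</sub> inversely proportional to flow rate — and run the full
pipeline: motion QC → noise-reduced 5×5 contrast → tube-ROI mean K² →
baseline joint fit of (β, τ<sub>0</sub>, ϑ<sub>n</sub>) with ρ = 1 →
τ<sub>c</sub>-only fits per rate → relative-τ table and linearity
regression.

```r
library(speckleflow)

phantom <- make_capillary_phantom(seed = 7)   # 28 stacks, tau_0 = 15 ms
result  <- run_capillary_workflow(phantom)
result
#> <capillary_result> 7 rates x 4 exposures; tau_0 = 15.6 ms; linearity R^2 = 0.9993

result$table
#> # A tibble: 7 × 5
#>   flow_rate tau_c_s tau_c_ms relative_tau relative_flow
#>       <dbl>   <dbl>    <dbl>        <dbl>         <dbl>
#> 1        10 0.0156     15.6          1              1
#> 2        15 0.0102     10.2          1.53           1.5
#> 3        20 0.00761     7.61         2.05           2
#> 4        30 0.00496     4.96         3.15           3
#> 5        50 0.00296     2.96         5.27           5
#> 6        75 0.00187     1.87         8.35           7.5
#> 7       100 0.00139     1.39        11.3           10
```

The recovered decorrelation times track the 1/Q ground truth (true
τ<sub>c</sub> at 30 µL/min is 5 ms; the fit returns 4.96 ms), the baseline
row is normalized to 1 by construction, and relative τ rises linearly with
relative flow (R² = 0.9993). `glance(result$baseline_fit)` and
`tidy(result$baseline_fit)` expose the fit diagnostics;
`autoplot(result)` draws the linearity panel and
`autoplot(result$baseline_fit)` the K²-vs-exposure fit.

Motion QC with known ground truth:

```r
st <- simulate_stack(matrix(1e-3, 32, 32),
                     sim_config(1e-3, n_frames = 100, noise_floor = 1, seed = 7))
st <- inject_motion_blur(st, seq(16, 96, by = 16), blur_px = 8)
reject_motion_frames(st)
#> <qc_report> 94 retained, 6 rejected (metric < 0.369)
```

All six injected frames are rejected, leaving 94 artifact-free frames —
comfortably above the 80 frames the noise-reduced scheme wants.

A thin command-line surface over the same functions lives at
`system.file("cli/speckleflow", package = "speckleflow")`, with subcommands
`simulate`, `qc`, `contrast`, `fit`, `profile`, `linearity`,
`run-capillary` and `run-retina`.

## Further reading

The methods vignette (`vignettes/speckle-methods.Rmd`) documents the model
and its assumptions, the simulator's design and what it does and does not
emulate, the numerical choices (series branches, bisection, multi-start
fitting, border and masking policy), and known limitations.
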