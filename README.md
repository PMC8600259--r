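# rtsprt

Statistically driven early stopping for real-time block-design task fMRI.

A conventional task fMRI run scans for a fixed duration regardless of
whether the data already answer the question, wasting scanner time and
accumulating late-run head motion. `rtsprt` is for researchers who want the
alternative: analyse every brain volume the moment it arrives, decide per
voxel whether it is task-active, and terminate each stimulus condition as
soon as a predetermined percentage of voxels has been classified. The
package contains the complete statistical engine plus a synthetic BOLD
generator and a volume-streaming harness, so the entire real-time loop can
be run and validated without a scanner.

## The statistics

Per voxel, the signal up to scan *t* follows a GLM, `Y_t = X_t β + E_t`,
where `X_t` holds an intercept, one double-gamma-HRF-convolved regressor
per stimulus condition, and five slow cosine drift regressors (periods
`2T, T, T/1.5, T/2, T/2.5` for run duration `T`). A contrast `cβ`
(condition versus rest) is estimated incrementally by OLS as each volume
arrives, with a model-free sandwich variance

```
var[cβ̂] = c (X'X)⁻¹ [ Σᵢ rᵢ² xᵢxᵢ' ] (X'X)⁻¹ c'
```

(HC0 by default; optional Newey–West lags for serial correlation). Each
voxel then runs a truncated, two-stage Wald SPRT: after a first stage of
78 or 154 scans during which no decisions are made, the alternative is
calibrated as `θ₁ = z_t √var̂` (default `z_t = 3.10`) and held fixed, and
the statistic

```
Λ_t = [ (cβ̂ − θ₀)² − (cβ̂ − θ₁)² ] / (2 var̂[cβ̂])
```

is compared each scan to the boundaries `A = log((1−β_E)/α_E)`,
`B = log(β_E/(1−α_E))` (defaults `α_E = 0.001`, `β_E = 0.1`, i.e.
`A = 6.80`, `B = −2.30`): `Λ ≥ A` classifies the voxel active, `Λ ≤ B`
nonactive, decisions are absorbing. A condition's stimulus stream stops
once the classified fraction of in-mask voxels reaches the global rule
threshold (70/80/90%; default 80%). See the methods vignette
(`vignettes/early-stopping-methods.Rmd`) for assumptions, conventions and
limitations.

## Worked example

```r
library(rtsprt)
protocol <- make_paper_protocol()   # 6 easy + 6 hard 36 s blocks, TR 3 s, 238 scans
sim <- simulate_run(simulation_config(seed = 1), protocol)
sim
#> Simulated run: 20x20x10 grid, 238 scans
#>   easy: 1000 active voxel(s), effect 1.128
#>   hard: 1000 active voxel(s), effect 1.109
report <- run_realtime(run_config(sim$series, protocol = protocol,
                                  sprt = sprt_config(first_stage_scans = 154,
                                                     max_scans = 238),
                                  threshold = 0.8))
report
#> Real-time SPRT run report
#>   easy: stop at scan 159 | 81.2% classified (887 active, 2359 nonactive, 754 undecided, 0 degenerate)
#>   hard: stop at scan 178 | 81.1% classified (865 active, 2380 nonactive, 755 undecided, 0 degenerate)
```

The simulation plants 25% truly active voxels per condition at an effect
equivalent to z = 6 at full duration, under AR(1) noise and random
low-frequency drift. With a 4-block (154-scan) first stage and the 80%
rule, both conditions stop roughly 60–80 scans (3–4 minutes) before the
238-scan horizon: at scan 159 the easy contrast has classified 81.2% of
the 4000 voxels (887 active, 2359 nonactive) and stops; the remaining 754
voxels sit in the SPRT's indifference zone. Maps (`write_maps()`), a
per-scan trace, and JSON stop sentinels are written when an output
directory is configured, and `overlap_metrics()` compares early-stop
against full-duration activation maps.

The design-based z-equivalence across stopping points is available
directly:

```r
X <- build_design_matrix(protocol, design_spec())
rescale_z_equivalent(X, 154, 238, contrast(X, "easy"), 3.1)
#> [1] 3.866971
```

i.e. a threshold of z = 3.1 applied at scan 154 targets the same
activation magnitude as z ≈ 3.87 at scan 238.

A thin command-line front end covering simulation, the real-time loop,
re-reporting and map overlap lives at `inst/cli/rtsprt.R`
(`Rscript rtsprt.R <simulate|run|report|overlap> ...`).

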