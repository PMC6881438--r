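# matriex

Multi-area two-photon calcium imaging with a compound objective: one
low-magnification dry objective (DO) coupled to several gradient-index
(GRIN) rod lenses used as miniaturized objectives (MOs), each inserted over
a different brain region. A single raster scan of the DO field then images
several circular fields of view (FOVs) — e.g. visual cortex, motor cortex
and hippocampal CA1 — simultaneously, at single-cell resolution, in one
frame. `matriex` implements the computable core of this approach for
R users who want to design such assemblies, generate fully ground-truthed
synthetic recordings, and run the standard calcium-signal analysis:

* **Design engine** (`grin_lens_spec()`, `back_working_distance()`,
  `solve_pitch_for_depth()`, `optical_coupling()`, `scan_geometry()`):
  paraxial GRIN propagation, NA coupling and the depth-conjugation solver.
* **Simulator** (`activity_params()`, `synth_traces()`, `render_movie()`,
  `write_fixture()`): multi-FOV 16-bit movies with known cells, events,
  correlations, neuropil, rigid motion and inter-FOV crosstalk.
* **Analysis pipeline** (`motion_correct()`, `extract_trace()`,
  `compute_dff()`, `detect_events()`, `fit_lognormal()`,
  `pairwise_correlations()`, `neuropil_comparison()`,
  `state_comparison()`).

## The model in brief

A GRIN lens of pitch `P` and index-distribution coefficient `√A` has
length `Z = 2πP/√A` and back working distance

```
L2 = [-(n1·n2/√A)·sin(Z√A) − n2·N0·L1·cos(Z√A)] /
     [n1·N0·cos(Z√A) − N0²·L1·√A·sin(Z√A)]
```

for an object `L1` in front of the lens in water (`n1`), imaging into air
(`n2`). The DO excitation cone (half-angle `θ0`, `NA_DO = sin θ0`) is
angularly demagnified by the MO (`M_a = θ0/θ1`), giving a compound NA

```
NA_comp = n1·sin(θ1) ≈ (1.33 / M_a) · NA_DO,     NA_eff = min(NA_comp, NA_MO)
```

and a lateral magnification `M_L = n1/(M_a·n2) ≈ ×8`. MOs with different
pitches place object planes at different tissue depths on one common image
plane: `Z(P) + L2(P) = H + (depth − L1)`, where `H` is the height of the DO
object plane above the brain surface; `solve_pitch_for_depth()` inverts
this relation by bracketed root finding, rejecting designs whose lens would
be fully embedded in tissue.

Analysis follows the field's conventions: rigid integer-pixel alignment
minimizing the sum of squared differences against a frame-averaged
template; Δf/f = (f − f0)/f0 with f0 the 25th percentile of the whole
recording; event amplitudes fitted by a base-10 log-normal law
(μ = 10^mean(log10 a), σ = 10^sd(log10 a)); Pearson correlations
cov(X,Y)/(σX·σY) bucketed into intra- and inter-regional pairs; results
reported as `median\25th–75th percentiles`.

## Worked example

```r
library(matriex)

std <- lens_template("table1_standard")
lens_length(std$pitch, std$sqrt_a)        # 5.485 mm
back_working_distance(std)                # 16.05 mm -> the catalogue's 16 mm
optical_coupling(dry_objective_spec(2, 0.055, "Mitutoyo x2"), std)
#> NA coupling: NA_DO 0.055, M_a 0.1675 -> NA_comp 0.437, NA_eff 0.437

# a lens reaching 1.2 mm below the surface under a 21.4 mm assembly
solve_pitch_for_depth(1.2, 21.4, std)
#> pitch 0.2602, Z 5.467 mm, L2 16.983 mm, protrusion 4.42 mm

# simulate a three-region recording and recover the amplitude laws
p  <- activity_params(state = "anesthetized", n_cells_per_region = 5,
                      event_rate_hz = 0.1, driver_amp = 0.03,
                      noise_sd = 0.02, seed = 42)
gt <- synth_traces(p, duration_s = 120, rate_hz = 10)
mv <- render_movie(gt, simple_layout(160, p$regions$region), p,
                   psf_fwhm_um = psf_fwhm_lookup(4)[["lateral_um"]])
cells <- mv$truth$centroids
amps <- list()
for (i in seq_len(nrow(cells))) {
  r   <- roi_disk(cells$cell[i], cells$region[i], cells$x[i], cells$y[i],
                  cells$radius_px[i], 160)
  dff <- compute_dff(extract_trace(mv, r), 10)
  amps[[cells$region[i]]] <- c(amps[[cells$region[i]]],
                               detect_events(dff)$amplitude)
}
fit_lognormal(amps$V1)
#> log-normal fit: mu = 10^-0.407 (= 0.392), sigma = 10^0.154, N = 61
fit_lognormal(amps$CA1)
#> log-normal fit: mu = 10^-0.106 (= 0.783), sigma = 10^0.442, N = 58
```

The fitted exponents recover the generating laws (V1 generated at
μ = 10^−0.46, σ = 10^0.14; CA1 at μ = 10^−0.13, σ = 10^0.41) up to the
sampling error of ~60 events per region; the small residual gap is the
detection threshold censoring the faintest events, exactly as in real
recordings.

A command-line wrapper covering design → simulate → analyze → report lives
at `inst/cli/matriex.R`:

```sh
Rscript inst/cli/matriex.R design --depth 0.5 --out out/
Rscript inst/cli/matriex.R simulate --preset fig4_three_region --out out/
Rscript inst/cli/matriex.R analyze --movie out/movie.tif --out out/
```

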