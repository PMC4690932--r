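# settleflux

Modelling the thickening and settling of activated sludge in secondary
clarifiers.

Secondary settlers (clarifiers) separate activated sludge from treated
effluent and return concentrated sludge to the aeration basin; they are a
common bottleneck of the whole activated-sludge process. `settleflux`
implements a compact, calibratable model family for the sludge blanket that
plant operators can drive from two easily measured quantities — the
thickening time *t*<sub>s</sub> and the sludge volume index (SVI):

- **Thickening model** — the bottom (thickened) sludge concentration follows
  a power law, *X*<sub>d</sub> = *a* · *t*<sub>s</sub><sup>*b*</sup>
  (*a* in g/L, *t*<sub>s</sub> in min), fitted by log–log least squares.
  The return sludge concentration is *X*<sub>r</sub> = *k* · *X*<sub>d</sub>
  with *k* = 0.7 for scraped withdrawal (0.5–0.7 for suction).
- **SVI link** — across plants, *a* = α · ln(SVI) + β with α < 0: sludge
  that settles poorly thickens less. Two provenance-tagged presets ship
  (`svi_link_refit()`, the default, and `svi_link_printed()`), because the
  published coefficients are not reproducible from the published panel.
- **Compression settling** — the blanket mass balance
  *x* · *X*<sub>d</sub> = *x*<sub>0</sub> · *X*<sub>0</sub> turns the
  thickening law into a compression settling velocity
  *v*<sub>cs</sub> = (*b x*<sub>0</sub> *X*<sub>0</sub>/*a*) ·
  (*X*/*a*)<sup>−(1+*b*)/*b*</sup>; at the fleet-mean *b* = 0.0465 the
  exponent is −22.5.
- **Integrated settling law** — Vesilind hindered settling
  *v* = *v*<sub>0</sub>e<sup>−*nX*</sup> below the compression-onset
  concentration *X*<sub>c</sub>, the compression law above it. *X*<sub>c</sub>
  is located on a batch settling curve by the classical graphical
  construction: the bisector of the angle between the hindered and
  compression tangents, intersected with the curve.
- **Solids-flux analysis** — total flux (*v*(*X*) + *u*) · *X* and its
  limiting minimum, for both the integrated and the hindered-only model;
  hindered-only analysis overestimates permissible loading.
- **Floc morphometry** — two-, three-dimensional and boundary fractal
  dimensions (*A* ∝ *P*<sup>*D*2</sup>, *V* ∝ *P*<sup>*D*3</sup>,
  *A* ∝ *P*<sup>2/*D*B</sup>) from grayscale images or measurement tables,
  and their trend against SVI.
- **Synthetic data** — seeded generators for every input family, with
  recorded ground truth, so the whole toolkit is testable without lab data.

## Worked example

```r
library(settleflux)

# calibrate the thickening law from a (synthetic) 90-min thickening test
tc  <- gen_thickening_curve(a = 6.493, b = 0.0465, noise_level = 0.01, seed = 42)
fit <- fit_power_law(tc)
fit
#> Power-law thickening fit (log-log scale)
#>   X_d = 6.535 * t_s^0.04391   [a g/L at 1 min, t_s min]
#>   R^2 = 0.9613, slope p = 2.61e-21, n = 30

# bottom and return concentrations after 90 min of thickening
xd <- predict_bottom_concentration(fit, 90, X0 = 6.600)   # 7.963 g/L
return_concentration(as.numeric(xd), return_sludge_spec("scrape"))
#> [1] 5.574  # g/L

# cross-plant SVI link (default preset, refit from the built-in panel)
svi_link_refit()
#> SVI link [refit]: a = -3.96 * ln(SVI) + 27.72
#>   R^2 = 0.9954, p = 0.00231, mean b = 0.04645

# compression onset from a batch settling curve
bc  <- gen_batch_settling_curve(v = 0.6, t_star = 20, noise_level = 0.002, seed = 7)
est <- detect_compression_onset(bc)
est
#> Compression onset: t_c = 22 min, h_c = 0.7989 m, X_c = 8.261 g/L

# integrated settling model and limiting solids flux
X     <- c(2.010, 3.025, 4.100, 5.180, 6.425)
ves   <- fit_vesilind(X, 11.043 * exp(-0.364 * X))
model <- integrated_settling_model(ves,
           compression_law_from_fit(fit, x0 = 1, X0 = 6.600), X_c = est$X_c)
limiting_flux(model, u = 0.3)
#> integrated 2.56 vs hindered-only 5.14 kg/(m^2 h): hindered-only analysis
#> overestimates the permissible loading

# floc fractal dimensions from a synthetic image
set <- gen_floc_image_set(12, roughness = 0.15, seed = 3)
fit_fractal_dimensions(measure_flocs(set$image))
#> Fractal estimates (n = 12 flocs):
#>   D2 = 1.907 (se 0.029), D3 = 2.860 (se 0.043), DB = 1.049 (se 0.016)
```

Reading these numbers: the fitted `(a, b)` reproduce the generator's truth
within the expected noise; 7.963 g/L is the blanket concentration after 90
min and 5.574 g/L what a scraped underflow actually returns; the detected
onset (22 min, 8.26 g/L) sits within 15% of the constructed transition at
20 min; the flux comparison shows why ignoring compression settling
overstates clarifier capacity; and mildly rough synthetic flocs score close
to the smooth-shape limits (*D*2, *D*3, *D*B) = (2, 3, 1).

## Command line

```sh
Rscript inst/cli/settleflux predict-xr --a 6.493 --b 0.0465 --t 1 --k 0.7 --X0 6.600
#> X_r = 4.620 g/L (X_d = 6.600 g/L, clamped to X0)
```

Subcommands: `fit-thickening`, `fit-svi`, `predict-a`, `predict-xr`,
`fit-vesilind`, `detect-onset`, `velocity`, `flux`, `fractal
measure|fit|trend`, `simulate thickening|batch|panel|flocs`; every command
has a `--json` mode.

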