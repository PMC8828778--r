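# cici

Quantitative analysis of **chemically induced chromosomal interactions
(CICI)** in budding yeast.

In a CICI experiment, two genomic loci carry LacO/TetO repeat arrays bound
by repressor fusions (LacI-FKBP12, TetR-FRB) that dimerize in the presence
of rapamycin, while separate LacI-GFP and TetR-mCherry fusions render the
loci as a green and a red chromatin dot. Adding the drug switches on an
attraction between the loci; the readout is the 2-D distance between the
dots in projected fluorescence images, with dots within 0.4 µm scored as
co-localized. This package is for researchers analyzing such data: it turns
raw two-channel z-stacks and single-cell distance traces into encounter
kinetics, event calls, and the companion assay statistics.

## What it computes

* **Spot detection** — masked maximum-intensity projection, per-cell dot
  detection with sub-pixel aperture centroids, minimum green–red distance,
  co-localization calls (`max_project`, `detect_dots`, `measure_image`).
* **Event calling** — contact formation (first run of ≥ 3 co-localized
  frames) and disruption (distance > 0.6 µm, or two losses within 4
  frames), division-relative disruption times, persistence through
  division (`call_events`, `disruption_relative_to_division`).
* **Population kinetics** — the two-step Poisson convolution model

  P(t) = a₁ + a₂/(k₂−k₁) · [ (1−e^(−k₁t))/k₁ − (1−e^(−k₂t))/k₂ ]

  fitted with k₂ fixed at 0.2 min⁻¹, yielding t₁/₂ = ln2/k₁ and the
  efficiency (P∞ − P₀)/(1 − P₀) (`fit_timecourse`).
* **Formation-time mixtures** — one/two-component exponential mixture MLE
  with AIC model selection, and joint fits sharing (t₁, t₂) across
  cell-cycle groups (`fit_exponential_mixture`, `joint_mixture_fit`).
* **Hi-C correlation** — OLS R² of contact metrics against curated Hi-C
  bin-pair signals (`regress_r2`).
* **Replication timing** — ΔCt relative copy number, t = 0 normalization,
  30–40 min window means, anchor-based drift correction, strain t-tests
  (`qpcr_curves`, `drift_correct`, `compare_timing`).
* **Donor usage** — gel band-intensity fractions for mating-type switching
  (`hmr_usage_fraction`).
* **Synthetic data** — generators with ground truth for every input:
  confined-diffusion (Ornstein–Uhlenbeck) distance traces with binding and
  division events, Gaussian-PSF z-stacks with Poisson noise, binomial
  population time courses, sigmoidal qPCR Ct tables
  (`simulate_distance_trace`, `render_zstack`, `simulate_qpcr`).

## Worked example

Simulate a population time course at the model's typical scale
(a₁ = 0.4, a₂ = 0.006 min⁻², k₁ = 0.1 min⁻¹, 500 cells per timepoint),
fit it, and fit a cohort of 773 single-cell formation times:

```r
library(cici)

tt <- c(0, 5, 10, 15, 20, 30, 45, 60, 90, 120)
tc <- simulate_population_timecourse(0.4, 0.006, 0.1, 0.2, tt, 500, seed = 7)
fit_timecourse(tc)
#> Convolution-model co-localization fit
#>   a1 = 0.401  a2 = 0.005929  k1 = 0.09816 /min  (k2 fixed = 0.2 /min)
#>   P(0) = 0.401  P(inf) = 0.703  efficiency = 0.504  t1/2 = 7.06 min

x <- sample_formation_times(13, 73, 0.5, 773, seed = 7)
fit_exponential_mixture(x, 2)
#> Double-exponential fit: t1 = 13.63, t2 = 71.02 min, A1 = 52.0% (n = 773, AIC = 7165.0)

g <- list(G1 = sample_formation_times(13, 73, 0.54, 480, seed = 8),
          budded = sample_formation_times(13, 73, 0.20, 255, seed = 9))
joint_mixture_fit(g)
#> Joint double-exponential fit: shared t1 = 14.24, t2 = 68.56 min
#>   G1: A1 = 50.0% (n = 480)
#>   budded: A1 = 16.5% (n = 255)
```

The time-course fit recovers the generating parameters within binomial
error: the baseline co-localization is ~40%, the plateau ~70%, so about
half of the initially separated pairs are driven together
(efficiency ≈ 0.5), with a ~7 min encounter half-time. The mixture fit
recovers the fast (~13 min) and slow (~73 min) encounter phases and shows
the fast fraction dropping from ~50% in G1 cells to ~17% in budded cells —
the signature of constrained chromosome motion after replication.

A command-line front end covers the text-based workflows:

```sh
Rscript -e 'cici::cici_cli()' simulate traces --n-cells 50 --seed 1 --out traces.csv
Rscript -e 'cici::cici_cli()' events --traces traces.csv --out events.csv
```

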