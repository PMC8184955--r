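# ramanplex

Multiplexed live-cell Raman profiling by linear spectral unmixing.

Narrow-band Raman reporters — antibody- and aptamer-conjugated Raman dots,
isotope-labeled metabolites, alkyne tags — let a single spontaneous Raman
spectrum of a whole live cell carry a dozen and more quantitative channels
at once: surface-protein abundance, size-resolved endocytic uptake, and
metabolic activity. `ramanplex` is the analysis side of such an
experiment, for anyone who has (or wants to simulate) per-cell spectra and
a probe panel: it turns wide CSV tables of single-cell spectra into
per-cell, per-probe feature tables and population-level phenotypes.

The core model is per-window linear unmixing against a reference library.
With **M** the matrix of unit-max normalized reference spectra on a
window's wavenumber grid and **I** a background-corrected cell spectrum
trimmed to that window,

    I_silent = M_silent · Θ_silent + N        (2000–2300 cm⁻¹)
    I_amide  = M_amide  · Θ_amide  + N        (1500–1700 cm⁻¹)

and Θ ≈ M⁺·I is recovered per cell by least squares (QR) or non-negative
least squares (default), with per-cell fidelity scored as the Pearson
correlation R between the spectrum and its reconstruction M·Θ. The default
panel has 16 components — 14 probe channels plus the endogenous ¹²C amide
envelope and the polystyrene carrier band — with 3 amide-window and 13
silent-window columns.

Around the unmixing core the package provides:

* a parametric reference-library builder (Lorentzian/Gaussian/pseudo-Voigt
  lineshapes, YAML panel configs, resolvability and condition-number
  checks);
* a seeded single-cell simulator (log-normal heterogeneity with a shared
  cell-brightness factor, treatment fold changes, smooth baselines,
  additive noise, corrupted-outlier spectra) standing in for the
  instrument;
* preprocessing and QC: window trimming, background removal (iterative
  polynomial or asymmetric least squares), and outlier exclusion of cells
  whose spectra correlate below 0.95 with their sample group;
* single-cell analytics: control-normalized population means, fold-change
  radar profiles, box statistics with half-IQR whiskers and two-group
  tests, t-SNE embedding, Gaussian-mixture BIC cluster-number selection,
  hierarchically ordered correlation heatmaps, and inverse-correlation
  network graphs (edge length 1/|r|) with centrality and betweenness.

## Worked example

Simulate an endocytosis-inhibitor experiment (six arms × 150 cells, three
nanoparticle sizes), run the full pipeline, and read off the recovered
inhibition phenotype:

```r
library(ramanplex)

cfg <- pipeline_config(design = preset_inhibitors(n_cells = 150),
                       seed = 1, out_dir = "demo_run",
                       analyses = c("clusters", "correlation", "network"))
res <- run_pipeline(cfg)

res$qc
#> <qc_report> 900 cells in, 13 excluded (r < 0.95, reference = loo-mean)

round(res$fold_changes[, c("Endo40", "Endo70", "Endo120")], 2)
#>           Endo40 Endo70 Endo120
#> CPZ         0.45   0.51    0.40
#> Nystatin    1.07   0.55    0.40
#> Cold4C      0.25   0.26    0.21
#> CytoD_6h    0.55   0.61    0.50
#> CytoD_60h   1.59   1.80    1.65

median(res$features$fidelity_r)
#> [1] 0.9986
```

The 13 excluded cells are exactly the simulator's planted corrupted
spectra. The fold-change matrix recovers the designed phenotype: the
clathrin inhibitor (CPZ) suppresses uptake of all particle sizes, the
caveolae inhibitor (nystatin) spares 40 nm particles while halving 70 and
120 nm uptake, cold block suppresses everything, and long cytochalasin D
exposure enhances uptake. Median reconstruction fidelity of 0.9986 says
the 16-component model accounts for essentially all spectral variance at
the default noise level. `demo_run/` holds every artifact as CSV/GraphML
plus a provenance JSON and run log.

Cell-type discrimination works the same way from the other presets:
`preset_endocytosis()` (three cell lines, three channels) yields a
selected cluster number of 3 and `preset_surface()` (two cell lines, two
surface channels) yields 2, via `select_cluster_number()`.

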