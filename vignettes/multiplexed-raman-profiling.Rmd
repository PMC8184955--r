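---
title: "Multiplexed live-cell Raman profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplexed live-cell Raman profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanplex)
```

## The measurement model

A whole-cell Raman spectrum acquired from a probe-stained live cell carries,
on top of a smooth background, the superimposed narrow bands of every
Raman-active reporter attached to or inside the cell. Because spontaneous
Raman bands are narrow (an order of magnitude narrower than fluorescence
emission), ten and more reporters can share the cell-silent window
(2000–2300 cm⁻¹), where endogenous cellular species have no bands, and the
protein amide window (1500–1700 cm⁻¹) carries the endogenous amide I/II
envelope and its ¹³C-shifted counterpart reporting new protein synthesis.

`ramanplex` works with the linear mixing model, per window:

\[
\mathbf{I}_{\mathrm{silent}} = \mathbf{M}_{\mathrm{silent}}\,\Theta_{\mathrm{silent}} + \mathbf{N},
\qquad
\mathbf{I}_{\mathrm{amide}} = \mathbf{M}_{\mathrm{amide}}\,\Theta_{\mathrm{amide}} + \mathbf{N},
\]

where the columns of **M** are unit-maximum normalized reference spectra of
the panel components, Θ is the per-cell weight vector, and **N** is noise.
Because the references are unit-max, each recovered weight reads directly as
a peak height in the input's intensity units.

The default panel has 16 components: 14 probe channels (seven
surface-protein probes against HER2, CD44, EGFR, CD55, MUC1, EpCAM and
nucleolin; three endocytic nanoparticle probes of 40/70/120 nm diameter;
¹³C-amide, ¹³C-EdU, 17-ODYA and the CoQ analog AltQ2 for metabolic
activity) and two auxiliary components that must be modeled but are not
reported as channels: the endogenous ¹²C amide envelope and the polystyrene
C=C band of the nanoparticle carrier. The amide window holds 3 components,
the silent window 13.

## Reference spectra

Reference spectra are rendered parametrically as sums of Lorentzian peaks
(the standard condensed-phase Raman lineshape; Gaussian and pseudo-Voigt
are selectable), each with a center (cm⁻¹), FWHM (default 15 cm⁻¹) and
relative amplitude, rescaled to unit maximum. The silent-window probe
centers are 2052, 2065, 2079, 2092, 2118, 2133, 2153, 2175, 2194, 2207,
2218, 2250 and 2290 cm⁻¹; the amide components put amide II/I at 1574/1659
cm⁻¹ (¹²C) and 1534/1619 cm⁻¹ (¹³C, a uniform 40 cm⁻¹ isotope downshift),
with an amide I : amide II amplitude ratio of 1.5 : 1. The ¹³C-EdU
(2065), 17-ODYA (2250), AltQ2 (2290) and PS C=C (1602 cm⁻¹) centers are
placeholders chosen for mutual resolvability, not calibrated values; they
are plainly exposed in the panel YAML and in `default_panel(centers = ...)`
and should be replaced when measured reference positions are available.

With these defaults the closest pair of silent-window centers is 11 cm⁻¹
apart (2207/2218), below one FWHM, so the library columns overlap
substantially; `check_resolvability()` reports the minimum center
separation and the maximum column correlation, and `build_library()`
refuses rank-deficient configurations and logs the condition number of
each window matrix (≈ 1.7 amide, ≈ 3.1 silent for the default panel —
comfortably well-posed).

## Unmixing

The window matrices are tall (201 × 3 and 301 × 13 at the default 1 cm⁻¹
grid), so the formal matrix inverse of the square case becomes least
squares: `unmix_window(..., mode = "ls")` solves min‖I − MΘ‖₂ by QR
factorization. Because abundances are physically non-negative, the default
for feature tables is `mode = "nnls"` (Lawson–Hanson non-negative least
squares via `pracma::lsqnonneg`). Plain least squares is retained because
it is linear in the data — the property-based tests (linearity,
unbiasedness under zero-mean noise, equality with an independently coded
normal-equations solve) all exercise it — and because it mirrors the
algebraic model directly.

Each cell receives a reconstruction fidelity score: the Pearson correlation
between the measured spectrum and M·Θ over the two windows concatenated.
On noiseless synthetic mixtures the round trip `unmix(render(Θ)) = Θ` is
exact to below 10⁻⁶ relative error and fidelity is 1.0; at the simulator's
default noise it stays above 0.99.

## The simulator

`simulate_experiment()` stands in for the instrument. Its statistical
choices, and what they do and do not emulate:

* **Abundances** are log-normal with the designed mean and CV (default
  0.35) — positive and right-skewed, matching cytometry practice. Each
  population's log-abundances share a common correlation `common_rho`
  (default 0.9), i.e. most cell-to-cell spread is a shared brightness
  factor (cell size, staining and uptake capacity) and the residual
  per-channel spread has CV ≈ 0.11. This reproduces two things seen in
  real multiparameter data: predominantly positive cross-channel
  correlations, and spectral *shapes* that are stable enough within a
  sample for the correlation-based QC rule to be meaningful. Planted
  structure for network analyses is injected through `latent_cor`
  (indefinite requests are repaired by eigenvalue clipping).
* **Spectra** are exactly M·Θ within each window (the gap between windows
  carries baseline only), plus a smooth per-cell baseline (low-order
  polynomial by default, amplitude 20) and additive Gaussian noise
  (σ = 2 per grid point). With typical weights of 20–250 this puts peak
  SNR between ~10 and ~125; no instrument noise figure is targeted — the
  defaults are set so that recovery at low SNR remains demonstrable, not
  matched to hardware.
* **Outliers**: each cell is corrupted with probability
  `outlier_fraction` (default 0.02) by replacing its spectrum with a
  random smooth broad-band curve of comparable magnitude — a stand-in
  for debris and mis-parked acquisitions. The corruption is constructed
  so the cell's correlation with its group mean falls far below the 0.95
  QC threshold (observed ≲ 0.5, versus ≳ 0.96 for intact cells).
* Shipped presets (`preset_surface`, `preset_endocytosis`,
  `preset_inhibitors`, `preset_drugs`) encode the qualitative contrasts
  of the target experiments — e.g. clathrin inhibition suppressing uptake
  of all particle sizes while caveolae inhibition spares 40 nm particles;
  a protein-synthesis inhibitor suppressing the ¹³C-amide channel. All
  magnitudes are plausible placeholders, not measured values.

What the simulator does **not** model: optical point-spread and
illumination profiles, detector etaloning, shot-noise scaling (a Poisson
mode is deliberately out of scope), wavenumber miscalibration, probe
cross-reactivity, and any pharmacology beyond static fold changes. Tests
passing on simulated data therefore certify the *analysis* — unmixing,
QC, statistics — under the stated generative assumptions, not instrument
behavior.

## Preprocessing and QC

Spectra are trimmed to the two windows (inclusive bounds). Background is
removed before unmixing; two estimators are provided:

* `"polynomial"` (default): iterative low-order polynomial fit (degree 3)
  that discards points more than one residual s.d. above the current fit
  and refits to convergence, with a 15% retention floor. On this panel the
  silent window is peak-crowded (13 peaks over 300 cm⁻¹ at FWHM 15), so
  the spectrum's lower envelope between peaks never returns to baseline;
  an envelope-tracking estimator is then biased upward by the overlapped
  Lorentzian tails, while peak exclusion anchored in the peak-free
  1700–2000 cm⁻¹ gap is not. Measured on full-panel synthetic cells with
  known baselines, the polynomial estimator recovers peak heights to a
  few percent where the envelope tracker errs by tens of percent — this
  measurement is why it is the default.
* `"als"`: asymmetric least squares (iteratively reweighted penalized
  smoothing, smoothness λ = 10⁶, asymmetry p = 0.01), appropriate for
  sparse spectra and non-polynomial backgrounds.

Outlier cells are excluded by the Pearson rule: each cell is correlated,
over the concatenated background-corrected windows, against its group's
mean spectrum computed without the cell itself (a pairwise-median
comparator is selectable); cells with r **strictly below** 0.95 are
excluded. The rule is deliberately strict-less-than, so a cell sitting
exactly at the threshold is retained. Filtering is idempotent on clean
data and monotone in the threshold.

## Single-cell analytics

* **Feature table**: cells × 14 probe channels in fixed panel order
  (alphabetical within window, C-locale, so Θ indices are stable across
  platforms), auxiliaries carried in a side table, QC-failed cells absent.
* **Control normalization** divides each channel by the control arm's
  mean, so population means read as fold changes (log2 optional for
  heatmap display). Normalization is invariant to global intensity
  rescaling.
* **Box statistics** use the half-IQR whisker convention (whiskers at the
  most extreme data within 0.5·IQR of the quartiles). The two-group test
  is Mann–Whitney U by default — robust to log-normal skew — with Welch's
  t selectable; p-values are per-comparison (Benjamini–Hochberg can be
  applied by the user via `p.adjust`).
* **Embedding and cluster counting.** t-SNE (perplexity 30, 1000
  iterations, fixed seed) is used for visualization only. The number of
  phenotypic clusters is chosen by Gaussian-mixture BIC over k = 1…8 on
  the features themselves, never on the embedding, since t-SNE distorts
  densities. Features are arcsinh-transformed (cofactor 5, the
  flow/mass-cytometry convention) and z-scored first: intensity
  populations are log-normal-like, and without variance stabilization a
  Gaussian mixture splits single skewed populations into spurious
  components. With stabilization, the three-cell-line endocytosis preset
  selects k = 3 and the two-cell-line surface preset k = 2 in ≥ 90% of
  seeded replicates (verified over 20 seeds in the test suite).
* **Correlation networks.** Pairwise Pearson correlations across cells
  are ordered by average-linkage hierarchical clustering on 1 − r for
  heatmap display. The network is the complete graph on the 14 channels
  with target edge length 1/max(|r|, 0.05) — edge length as the inverse
  of correlation degree; the floor avoids unbounded lengths for
  near-zero correlations, and 1 − |r| is selectable. Node positions come
  from a Sammon stress-minimizing embedding initialized from classical
  MDS (both deterministic, so layouts need no seed). Centrality is the
  weighted degree Σⱼ|rᵢⱼ|; betweenness on an |r| ≥ 0.3 thresholded graph
  serves module/bridge analysis.

## Numerical and design notes

* Problem sizes used throughout the tests are desk-scale by design: 150
  cells per arm for the presets, 301-point windows, 20 seeded replicates
  for the cluster-recovery claims — large enough for the statistical
  claims, small enough to run on one CPU in minutes.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical spectra, truth tables and feature tables. Layouts and
  hierarchical orderings are deterministic by construction.
* Degenerate inputs fail loudly and early: zero-variance vectors in the
  fidelity metric, rank-deficient libraries, groups smaller than three in
  QC, control means of zero in normalization, cluster counting on fewer
  than 20 cells.
* Ties in `which.max`-style argmax reporting resolve to the lower
  wavenumber (R's `which.max` convention); at 1 cm⁻¹ grid steps the
  rendered maxima coincide with the specified centers exactly.

## Known limitations

The reference spectra are parametric idealizations — a measured library
(with secondary bands, asymmetric lineshapes, instrument response) can be
substituted by editing the panel YAML, but empirical library acquisition
is out of scope. The unmixing is unregularized; for panels much denser
than 13 silent-window colors, or grids much coarser than 1 cm⁻¹, a
penalized variant would be needed. The QC comparator assumes each sample
group is predominantly one phenotype; a group that is itself a balanced
mixture of very distinct spectral phenotypes would need a cluster-aware
reference. Network edge lengths are a layout metric, not a statistical
model; no significance is attached to topology differences between arms.
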