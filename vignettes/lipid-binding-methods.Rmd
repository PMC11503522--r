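---
title: "Methods: quantifying membrane protein-lipid binding from native MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying membrane protein-lipid binding from native MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidnms)
```

## The problem

Native nano-electrospray mass spectrometry can transfer an intact membrane
protein complex — together with the lipids bound to it — into the gas phase,
so that the mass spectrum resolves the apo complex and every
lipid-bound stoichiometry `PL0, PL1, ..., PLn` as separate peak series.
Because peak intensities report species populations, a titration of lipid
against a fixed protein concentration turns the spectrometer into a binding
assay: the mole fraction of each bound state at each lipid concentration
constrains the ladder of equilibrium dissociation constants.

Getting from a raw m/z spectrum to those constants takes four steps, each
of which is a module of this package:

1. **Deconvolution** (`deconvolve()`): collapse the multiply charged m/z
   spectrum to a zero-charge (neutral mass) spectrum and a charge-state
   marginal.
2. **Assignment** (`assign_species()`, `average_charge()`): integrate the
   zero-charge spectrum in windows at `base_mass + i * ligand_mass` to get
   per-stoichiometry intensities, normalise to mole fractions, and compute
   the intensity-weighted average charge state Zavg.
3. **Equilibrium modelling** (`binding_system()`, `species_distribution()`,
   `fit_sequential_kds()`): predict mole fractions from a sequential
   binding model and estimate its per-site Kd values from titration data.
4. **Orchestration and I/O** (`run_pipeline()`, the readers/writers): run
   the chain reproducibly from a config, with seeds and a manifest.

A fifth module, the simulator (`simulate_spectrum()`,
`simulate_titration()`, `simulate_plate()`), generates synthetic data with
known ground truth; it is the package's test bed and a stand-in for
instrument files. A sensitized-emission FRET module provides the orthogonal
plate-based binding readout.

## The sequential binding model

Lipid binding to the complex is modelled as a ladder of sequential
equilibria,

$$PL_{i-1} + L \rightleftharpoons PL_i, \qquad
  K_{d,i} = \frac{[PL_{i-1}][L]}{[PL_i]}, \qquad i = 1..n,$$

with macroscopic (occupancy-level) constants in micromolar. The mole
fraction of the $i$-bound state at free lipid concentration $L$ is the
normalised $i$-th term of the binding polynomial,

$$F_i(L) = \frac{L^i / \prod_{j \le i} K_{d,j}}
                {\sum_{k=0}^{n} L^k / \prod_{j \le k} K_{d,j}}.$$

Terms are accumulated in log space so ladders spanning many orders of
magnitude neither overflow nor underflow.

**Lipid depletion is modelled.** At 1 uM protein with up to 7 sites and
lipid titrated over 0-25 uM, bound lipid is a non-negligible share of the
total, so evaluating the model at total lipid would bias the constants.
The free concentration is the root of the mass balance

$$g(L) = L + P_{tot} \sum_i i\,F_i(L) - L_{tot} = 0,$$

which is strictly increasing on $[0, L_{tot}]$; `solve_free_lipid()` uses
bisection to an absolute half-width of $10^{-12}\max(1, L_{tot})$, chosen
for robustness (the residual is monotone, so convergence is guaranteed) and
verified against the one-site closed-form quadratic to $10^{-9}$ over a
$20^3$ grid of $(K_d, P_{tot}, L_{tot}) \in [0.01, 100]^3$ uM.

### Fitting

`fit_sequential_kds()` minimises the sum of squared residuals over **all**
mole-fraction entries (every titration point, every bound state),
parameterised in $\log_{10} K_d$ with box bounds $[-3, 3]$ (1 nM - 1 mM),
using `stats::nlminb` from 10 random starts drawn uniformly within the
bounds under the caller's seed; the best objective wins, ties going to the
earliest start. $R^2$ is computed on the same entries against their grand
mean. Replicates are fitted independently and summarised as mean +/- sample
sd (`replicate_summary()`), matching the usual n = 3 reporting convention;
pooling replicates into one objective would understate between-replicate
variability.

Observed rows are renormalised to unit sum on ingest because deconvolution
output is only approximately normalised; deviations above 0.01 warn and
above 0.05 are an error. A titration with a single point (or only
`l_total = 0`) is accepted but non-identifiable: the returned constants are
whatever the bounded optimiser settles on, and the degenerate $R^2$ is
reported as computed.

## Deconvolution

`deconvolve()` infers the neutral-mass distribution by iterative
proportional allocation. Each retained m/z sample $i$ (zero-intensity
samples carry no information and are dropped) starts with its intensity
spread uniformly over the candidate charges $z \in [z_{min}, z_{max}]$.
Each iteration then:

1. projects every allocation through $M = z\,(m/z - m_H)$ onto the mass
   grid with a Gaussian kernel of width $z \cdot \mathrm{fwhm}_{m/z}$ (an
   m/z-domain peak width maps to the mass domain in proportion to the
   charge), using grid-normalised kernels so intensity is conserved
   exactly;
2. reads the mass estimate back at each sample's candidate masses, pools
   the evidence over +/- 1 neighbouring charge (`charge_smooth_width`) to
   favour charge-state *series* that agree on one mass, and re-allocates
   the sample's intensity across charges in proportion.

Two numerical choices matter and are worth stating plainly:

* **Width correction.** The read-back of the mass estimate is a
  kernel-weighted *density*. Kernels narrow as charge drops, so low-charge
  hypotheses would look systematically taller than high-charge ones for
  the same integrated signal. The evidence is therefore multiplied by the
  kernel width (proportional to $z$), turning the comparison into one of
  integrated intensity.
* **Sharpening.** A multiply charged spectrum admits harmonic
  explanations: every even charge state of mass $M$ is also a valid charge
  series of $M/2$. Proportional allocation alone converges to a mixture of
  the true mass and its harmonics (they all reproduce the data; the
  likelihood is degenerate). Raising the re-allocation weights to a power
  (`sharpen`, default 2) progressively concentrates each sample on the
  hypothesis with the most support — the true mass, which accumulates
  intensity from its *entire* charge-state series while any harmonic is
  fed by a subset. On baseline-resolved synthetic spectra of the 99.6 and
  166.0 kDa reference complexes this recovers species masses to within
  1 Da on a 1 Da grid, abundance ratios to within 1%, and Zavg to within
  0.01 charges.

Iteration stops when the relative change of the mass estimate falls below
`tol` ($10^{-6}$) or after `n_iterations` (50); the synthetic fixtures
converge in 10-15 iterations. Total intensity is conserved to $10^{-6}$
relative at all times, and the charge marginal (the column sums of the
final allocation) sums to the same total.

One genuine ambiguity remains: a spectrum containing a *single* peak is
explained equally well by every candidate charge, and no allocation scheme
can break that tie. The single-charge identity (all intensity at $z$, mass
peak at $z(m/z_{apex} - m_H)$) holds when the configured charge range
brackets only the true charge, which is how it is tested. Charge is
assumed to arise from proton adduction only ($m_H = 1.00728$ Da); salt or
charge-reducer adducts are not modelled. The peak fwhm (default 0.85) is
interpreted in Thomson, the usual convention for these processing settings.
Zavg is computed from the full charge marginal of the analysed complex,
including all lipid-bound states.

## The simulator

`simulate_spectrum()` places, for each species of mass $M$ and charge $z$,
a Gaussian of area `abundance * P(z)` at $(M + z\,m_H)/z$ with the stated
m/z fwhm, sums, and samples on a regular grid. Gaussian peak shape is the
simplest shape consistent with a stated fwhm. The charge model is a
discretised Gaussian over an integer support (default +/- 4 sigma around
`z_center`); charge reduction is emulated by lowering `z_center`. Noise
models: none, additive Gaussian (clamped at zero), or ion counting — the
total signal redistributed as multinomial draws, which is also how
`simulate_titration()` perturbs mole fractions (a multinomial of `n_ions`
ions per titration point, divided by `n_ions`, so rows sum to exactly 1).
Replicates use deterministic sub-streams of the seed, and identical seeds
give byte-identical serialised output.

What the simulator deliberately does **not** emulate: the broad detergent
micelle background at low m/z, detergent/charge-reducer adduct tails,
collisional activation and subunit dissociation, or instrument-specific
peak shapes. Passing round-trip tests therefore demonstrates correctness of
the inference chain on clean, baseline-resolved inputs — not robustness to
every pathology of real membrane-protein spectra. Ion-count noise levels in
the fixtures (1000-5000 ions/point) were chosen once to produce replicate
scatter comparable to published error bars and are not calibrated to any
instrument.

Default study conditions mirror the experimental design the package
targets: protein at 1 uM (99.6 kDa tetramer) or 2 uM (166.0 kDa complex),
lipid titrated 0-25 uM, a generic 750 Da lipid mass (lipid masses are user
inputs, not constants), up to 7 bound lipids analysed, charge centers
11-17, three replicates.

## FRET correction

The plate assay reads three channels: donor (530/580 nm),
acceptor (620/675 nm) and FRET (530/675 nm). The standard two-factor
sensitized-emission correction is used: from single-label controls,
`d_bleed = I_fret/I_donor` (donor-only) and `a_cross = I_fret/I_acceptor`
(acceptor-only), then

$$F_c = I_{fret} - d_{bleed} I_{donor} - a_{cross} I_{acceptor}.$$

Blank (buffer + detergent) wells are subtracted channel-wise before factor
computation — the plate-reader convention. By construction $F_c$ of a
single-label control corrected with its own factors is exactly zero, and
under the simulator $F_c$ is linear in the bound fraction with noise off;
both are tested. Results are reported in corrected-intensity units
normalised to the largest response (`normalize_to_max()`, idempotent, no
conversion to FRET efficiency), with the normalisation scope taken as the
set of conditions passed in — per figure panel, in practice. Negative
$F_c$ values are reported as-is.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `deconv_config(z_range)` | 5-30 | charge | brackets native charge states of 100-170 kDa complexes |
| `deconv_config(mass_step)` | 1 | Da | mass sampling of the zero-charge grid |
| `deconv_config(peak_fwhm)` | 0.85 | Th | m/z peak width of the instrument/processing |
| `deconv_config(sharpen)` | 2 | - | harmonic suppression; 1 reverts to plain proportional allocation |
| `fit_sequential_kds(bounds)` | [-3, 3] | log10 uM | Kd positive, spanning nM-mM |
| `fit_sequential_kds(n_starts)` | 10 | - | multi-start against local minima |
| `assign_species(window_halfwidth)` | 0.4 x ligand mass | Da | widest symmetric window that can never overlap |
| `simulate_titration(n_ions)` | Inf | ions | counting noise per titration point |

## Problem sizes used by the test suite

The tests run the full chain at sizes a desk machine handles in minutes:
deconvolution round-trips on 0.25 Th grids over m/z 2000-20000 with
charges 5-30; the one-site oracle on a $20^3$ parameter grid; free-lipid
agreement with brute-force root finding on 100 random systems of up to 10
sites; noiseless recovery of 2-7-site ladders spanning two orders of
magnitude (within 0.1%); 50-seed noisy recovery at 1000 ions/point on a
3-site ladder titrated to 100 uM so the weakest site is appreciably
occupied; and the 7-site, 2000-ion, 3-replicate titration whose sequential
fit reaches $R^2 \ge 0.99$.

## Known limitations

* No correction for lipid partitioning into detergent micelles: the
  fitted constants are apparent constants for the stated detergent
  environment.
* Macroscopic constants only — no statistical-factor (intrinsic) Kd
  conversion, and no cooperative or allosteric schemes beyond the
  sequential ladder.
* The deconvolution targets baseline-resolved spectra; heavily adducted
  or overlapping charge series (which practitioners exclude from analysis
  anyway) are out of scope, as are isotope-resolved data and ion mobility.
* mzML ingestion is not provided; spectra enter as two-column delimited
  text.
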