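---
title: "Models and methods behind lareims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lareims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the scientific models implemented in `lareims`, the
assumptions behind them, the constants a user may want to move, and the
choices that were genuinely open when the package was designed. Everything
quantitative stated here is computed by the package's own test suite or
examples; nothing is an external measurement.

## 1. The interface simulator

### Free-jet flow field

The atmospheric interface is modeled as an underexpanded free jet of
nitrogen (molar mass 0.028 kg/mol, γ = 1.4, μ = 1.8·10⁻⁵ Pa·s, molecular
diameter 3.7·10⁻¹⁰ m) expanding from a capillary of bore *d* at stagnation
state (*P₀*, *T₀*) into background pressure *P₁*. Defaults — *P₀* = 101325 Pa,
*P₁* = 600 Pa, *d* = 0.6 mm, *T₀* = 300 K — describe an atmospheric inlet
into a rough-vacuum first stage. They are calibrated package defaults, not
measured values of any particular instrument; with them the Mach disk falls
at 5.22 mm, in the few-millimetre range where REIMS impactors actually sit.

The model is deliberately algebraic rather than a kinetic gas solution:

* Mach-disk position from the standard empirical correlation
  *x_M* = 0.67 *d* √(*P₀*/*P₁*), valid for pressure ratios above the
  critical ratio ((γ+1)/2)^(γ/(γ−1)); subcritical ratios raise an error.
* Centerline Mach number from the Ashkenas–Sherman far-field correlation
  *M* = 3.65 ((z − 0.40 d)/d)^(γ−1) (γ = 1.4 constants), ramped linearly to
  the stagnation value *M* = 0 at the capillary exit below the sonic point
  so the *T* → *T₀* limit is exact at *z* = 0.
* A single normal shock at *x_M*: downstream of it the gas is a uniform
  subsonic drift at the Rankine–Hugoniot post-shock state. Total
  temperature is conserved everywhere, so the isentropic identity
  *T*(1 + (γ−1)/2 *M*²) = *T₀* holds at every evaluated point (tested to
  1·10⁻¹²).
* Off axis, the Mach number decays with a Gaussian radial profile whose
  half-width grows as *d*/2 + 0.2 *z*. The 0.2 slope is a qualitative jet
  spreading rate, exposed as `build_flow_field(spread = )`. Radial gas
  velocity is neglected; droplet beam spreading therefore comes only from
  launch jitter, which keeps the impact fraction near one for surfaces of
  millimetre radius. This is the main idealization on the gas side.

### Droplet transport

Droplets follow slip-corrected Stokes drag with relaxation time
τ = ρ d² C_c(Kn)/(18 μ), Kn = 2λ/d. Velocity is integrated semi-implicitly
(unconditionally stable for stiff drag: the update relaxes exactly onto the
local gas velocity when dt ≫ τ), with the default step τ/20 clamped to
[1 ns, 1 µs]. Brownian kicks with per-axis variance 2 k_B T dt/(m τ) are on
for particles below 100 nm (relevant for the 2.2 nm secondary ions,
negligible for micron droplets) and can be forced either way. Surface
impact is detected by exact segment intersection (quadratic for the
sphere, crossing for the plane) or bisection to 10⁻¹² m (cone), so impact
positions do not suffer step-size bias. Evaporation, droplet charging,
particle–particle interaction and two-way gas coupling are out of model.

The mechanistically important behaviour, verified in the tests, is droplet
inertia at the Mach disk: a 1 µm droplet retains over 80 % of its peak
speed just behind the disk while the gas itself drops below half of that
speed across the shock. Impact speed, not gas speed, is what the
declustering model sees.

### Declustering yield

No first-principles model of surface-induced declustering is attempted.
The yield is a declared five-constant parametric form,

Y(T_s, v) = Y_max · σ((T_s − T₅₀)/ΔT) · exp(−(T_s/T_d)^p),
T₅₀ = T₅₀ref − α v²,

with shipped constants Y_max = 1, T₅₀ref = 700 K, ΔT = 80 K,
α = 10⁻³ K/(m/s)², T_d = 1600 K, p = 4. The logistic factor is thermal
activation of cluster breakup, lowered by impact kinetic energy; the
envelope is thermal degradation of the analyte. The constants are
calibrated so the net curve has a single interior optimum between 800 and
1200 K at the impact speeds the default jet produces (a few hundred m/s) —
i.e. near 1000 K — and the package treats that as a calibration target of
the model, not a prediction. All five constants live in
`default_config()$declustering`.

### Collisional stabilization — a declared capture-side term

With a frozen flow field and an abstract ion guide, nothing in the chain
would distinguish a surface placed just before the Mach disk from one just
behind it: impact speeds differ by a few percent at most. Physically the
two placements differ starkly on the ion side: upstream of the disk the
static pressure at the surface is a few pascal and a nascent ion desorbed
into the supersonic stream is swept and lost, while just behind the disk
the post-shock gas (~600 Pa here) thermalizes and entrains it. The package
represents this as a survival probability

P(survive) = p_loc / (p_loc + p_half),

with `p_half` = 100 Pa and `p_loc` the local gas pressure at the emission
point. The form is the simplest saturating law with a single scale; the
scale was fixed at design time (a ~6 % survival at the 7 Pa pre-disk
pressure versus ~85 % at the post-shock pressure). This term is the
package's own model and is the mechanism by which the sweep optimum lands
*behind* the disk rather than marginally before it.

### Shape-dependent impact-speed retention

A one-way-coupled simulation cannot form the detached bow shock and
stagnation cushion that a bluff surface erects in a supersonic jet, which
decelerates incoming droplets more strongly for flat-faced bodies than for
a sphere. This is represented by a per-shape retention factor on impact
speed (`default_config()$retention`): sphere 0.95, cone 0.85, plane 0.75,
motivated by the ordering of shock stand-off distances for these bodies
and fixed at design time. It is the term that makes the spherical impactor
strictly the best shape in the sweep; users who prefer the raw
one-way-coupled physics can set all three to 1.

### Ion guide and capture

The ring-electrode guide is abstracted to a DC axial field E_z = 3000 V/m
plus an effective radial pseudopotential well U(r) = U* (r/r₀)² with
U* = 2 V and r₀ = 2.5 mm, in stationary background gas at 100 Pa, 300 K —
declared defaults in the right ranges for a travelling-wave ion guide
region. An ion is captured when it crosses the exit plane inside r₀, lost
on reaching r₀. RF phase dynamics, space charge and fringe fields are out
of scope; consequently capture is close to unity for the default 1 kDa,
+1, 2.2 nm ion, and the claim the model supports is exactly that — such
ions are captured efficiently — not a transmission coefficient. Capture
probability is non-decreasing in U* and the Wilson 95 % interval reported
with every efficiency has ≥ 93 % empirical coverage (both tested).

### The sweep

`run_sweep()` evaluates shape × stand-off × temperature grids with 2000
droplets per cell under common random numbers: one droplet population and
one set of per-droplet uniforms (yield, survival) and emission draws are
shared by every cell, and transport is reused across the temperature grid.
Differences between cells are therefore systematic, not Monte Carlo noise,
and ties are broken deterministically (smaller z_s, then lower T_s, then
sphere < plane < cone). The shipped grid spans 2–12 mm in 1 mm steps and
400–1500 K in 100 K steps; with the default physics the optimum is the
sphere at 6 mm (the first grid point behind the 5.22 mm Mach disk) around
900 K. Stub-physics overrides (`config$overrides`) let the tests verify
the sweep bookkeeping against analytic indicators independently of the
physics.

## 2. The imaging statistics pipeline

* **Lock mass.** Single-point multiplicative recalibration against the
  most intense peak within ±0.5 Da of 554.2615 (negative-mode leucine
  enkephalin). The factor carries forward over scans without a lock peak
  (warning); identity before any lock is seen. The conventional constant
  554.2615 is used verbatim; the isotope-mass sum for C₂₈H₃₇N₅O₇ [M−H]⁻
  gives 554.2620, and the package deliberately does not derive the
  calibration constant from its own `compute_mz()`.
* **Binning.** Half-open 0.1 Da bins labelled by lower edge over
  [50, 1200); intensities summed (not averaged), conserving in-range total
  intensity to 1·10⁻⁹. Values sitting exactly on a bin edge (to within
  1·10⁻⁹ of a bin width) are assigned to the upper bin, so the half-open
  convention survives floating-point representation.
* **Normalization.** TIC (sum-to-one); all-zero spectra are an error.
* **Raster.** Unidirectional row-major pixel order with row flyback;
  serpentine behind a flag. Oversampling (pixel pitch below spot size) is
  a generator-side concept; no deconvolution is attempted.
* **Correlation maps.** Pearson correlation of each pixel's binned vector
  against the reference-region mean. Pearson (rather than cosine or a
  kernel) is a declared choice.
* **Annotation.** Monoisotopic masses from CODATA isotope masses with
  electron-mass bookkeeping; [M−H]⁻ subtracts a proton, [M+Cl]⁻ adds Cl
  plus an electron. Matching is nearest-|ppm| within 10 ppm, `"unknown"`
  otherwise. Two shipped lipid entries (PE 36:1, TG 52:2 [M+Cl]⁻) differ
  from commonly printed image labels by more than display precision; the
  computed values are kept and the discrepancy is documented rather than
  forced.

## 3. Classification and univariate analysis

PCA is mean-centering plus SVD, computed from the sample Gram matrix when
bins outnumber samples (exact, and necessary at 11 500 bins), with
component signs fixed by the largest-magnitude loading and degenerate
(zero-variance) components re-orthonormalized by QR. LDA operates on the
first k = 10 principal scores (capped at samples − classes), with the
within-class scatter ridge-regularized by 10⁻⁶ of its trace;
classification is nearest class centroid in discriminant space under the
Euclidean metric — a declared, deterministic rule rather than a
posterior-probability rule. Agreement with an independent LDA
implementation on separated Gaussian data is part of the test suite.

"Leave-20%-out" is interpreted as repeated (25×) stratified random 80/20
splits rather than 5-fold partitioning: it matches the name literally and
averages away split luck at small specimen counts. When the feature matrix
carries a grouping unit (specimen), whole groups are held out to prevent
leakage; otherwise the spectrum is the sampling unit. Pooled confusion
over repeats yields sensitivity/specificity for a designated positive
class and per-class percent correct.

The volcano uses the Mann–Whitney U test (two-sided, normal
approximation) on TIC-normalized bins with Benjamini–Hochberg correction;
significance requires q < 0.05 **and** |log₂FC| > 1, with the means ratio
zero-protected by ε = 10⁻¹². The test and correction are declared choices.
Note that TIC normalization couples bins: planting extra intensity in one
class deflates its other bins by the class's total, so fold changes are
interpreted on the normalized scale.

## 4. What the synthetic data emulate — and what they do not

`gen_phantom()` produces deterministic labeled regions (stripes, nested
rectangles, Voronoi blobs) over tumor / normal / fibrous classes.
`gen_msi_dataset()` gives every pixel its class profile built from the
shipped marker panel (nucleobases, amino acids, PE species, a TG, and the
lock-mass compound), with

* multiplicative lognormal peak noise (σ = 0.3 laser, 0.4 diathermy),
* ~25 additive low-level noise peaks per scan,
* a slow sinusoidal mass drift of 30 ppm amplitude across the scan index
  (exercising the lock-mass correction; residual after correction is
  under 1 ppm),
* planted differential bins at 4× in the tumor class (the volcano's ground
  truth), plus a sub-threshold 1.5× nucleobase enrichment,
* per-species lognormal gain (σ = 0.1) for the diathermy modality.

The fibrous class is triglyceride-rich and phospholipid-poor; tumor and
normal share every species except the planted bins, so the tumor/normal
contrast isolates exactly the planted ground truth. These phantoms have
centroided stick peaks, no isotope envelopes, no peak shape, no spatial
texture within regions and no biological covariance between species.
Passing the classification and recovery tests therefore demonstrates that
the pipeline is correct and well-calibrated on its own generative model —
it does not demonstrate clinical-grade performance on patient tissue,
whose published sensitivities and specificities depend on real biological
and instrumental variation not emulated here.

Droplet populations (`gen_aerosol()`) are lognormal (median 0.8 µm,
GSD 1.6, density 1000 kg/m³) launched across the capillary bore with the
local gas speed plus 2 m/s isotropic jitter (axial component half-normal:
the aerosol moves forward out of the bore). Ablation plume chemistry and
size–charge correlations are not modeled.

## 5. Numerical conventions and test scales

Degenerate inputs are defined rather than accidental: a zero-diameter
particle is drag-free; `d = 0` gives a Mach disk at 0; Kn = 0 gives
C_c = 1 by the continuous limit; empty ion ensembles are an error for
efficiency summaries; `laser_dose(0, ...)` is 0 W and 0 J/cm². All
generators and simulations are pure functions of their seed; ensemble
Brownian streams derive from a single seed, and single-trajectory runs use
seed + index conventions for decorrelated substreams.

The test suite runs the full shipped sweep (two shapes × 11 positions ×
12 temperatures × 2000 droplets) in about 1–2 minutes and the phantom
cross-validation (18 × 18 phantom, 25 repeats over 11 500 bins) in under a
minute; these sizes were chosen as the package's standard demonstration
conditions — large enough that binomial noise does not move the sweep
argmax under common random numbers, small enough to run routinely. The
guide tracer uses dt = 2·10⁻⁷ s in the sweep (about τ/2 for the default
ion); a refinement test confirms the capture fraction is stable to finer
steps, as expected for a semi-implicit scheme in the overdamped regime.

## 6. Known limitations

* One-way coupling: the surface does not perturb the jet; the bow-shock
  physics enters only through the declared retention factors, and the
  ion-side pressure contrast only through the stabilization law.
* The exact gas-side constants (capillary bore, stage pressure) of any
  given commercial REIMS source are proprietary; the defaults are
  representative, and conclusions should be read as relative (optimum
  *just behind the Mach disk*) rather than absolute millimetre positions.
* PCA-LDA is the only classifier; no feature selection or alternative
  models are provided.
* imzML support is continuous-mode only, sufficient for round-tripping the
  package's own grids; it is not a general reader.
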