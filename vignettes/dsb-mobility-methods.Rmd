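---
title: "Models and methods behind dsbmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dsbmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbmotion)
```

## What is being measured

A fluorescently tagged chromosomal locus — in the motivating application,
an HO-endonuclease-induced double-strand break bound by Ddc2-GFP — is
followed in 3D through a 20-minute movie (41 frames at 30 s, 15 optical
slices at a 0.3 µm z-step). An mCherry-tagged spindle-pole body in the
same nucleus serves as a fiducial: subtracting its coordinates from the
focus coordinates frame by frame removes whole-cell and whole-nucleus
motion, leaving the locus's motion relative to its nuclear anchor. Two
summaries are computed from the corrected, mean-centered track:

* the **time-averaged mean-squared displacement** at multiples of the
  frame interval, averaged across cells (mean ± SEM over cells), and
* the **radius of confinement**

  $$R_C = \sqrt{\tfrac{5}{4}\left(2\sigma^2 + \Delta r_0^2\right)},$$

  where $\sigma^2$ is the mean of the per-axis position variances
  ($n-1$ denominator, the convention of a per-axis normal fit) and
  $\Delta r_0^2 = \Delta x_0^2 + \Delta y_0^2$ is the mean squared
  deviation from the mean position ($n$ denominator). Both use only the
  lateral axes (see *Dimensionality* below).

The factor $5/4$ makes the estimator exact for a uniform ball: if
positions are uniform in a sphere of radius $R$, each axis has variance
$R^2/5$, so $2\sigma^2 + \Delta r_0^2 = 4R^2/5$ and $R_C = R$. This is
the identity the test suite exploits — uniform point clouds and long
confined-diffusion simulations must both return the generating radius
(the former within 1%, the latter within 3% over 50-cell cohorts).

$\sigma^2$ and $\Delta r_0^2$ estimate the same second moment and differ
only in their denominators; the formula is implemented literally as the
field reports it rather than algebraically simplified, so printed
$\sigma^2$ and $\Delta r_0^2$ columns match what practitioners expect.

## The synthetic experiment

Because raw two-channel movies for published experiments are not
deposited in machine-readable form, the package carries a generative
model of the whole experiment, used both for validation and as a
documented statement of assumptions.

**Locus motion.** Reflected Brownian motion inside a hard sphere:
per-axis Gaussian steps of variance $2D\,\Delta t$, with excursions
beyond the radius folded back across the surface (iterated for steps
longer than the diameter). Each 30-s frame interval is integrated in 10
sub-steps by default so the per-substep RMS step stays well below the
radius; the discretized walk's stationary distribution then approaches
uniform-in-the-ball, the regime in which $R_C$ is exact. A hard sphere
was chosen over a harmonic tether precisely because the $R_C$ estimator's
geometry is exact for it; a tethered (Ornstein–Uhlenbeck) locus would
make the recovered $R_C$ a model-dependent effective radius. Defaults:
$R = 0.8$ µm (mid-range of reported confinement radii for yeast loci,
roughly 0.5–1.1 µm), $D = 10^{-3}$ µm²/s (30-s MSD increments of order
0.1 µm², as observed for tagged loci).

**Drift and fiducial.** Whole-nucleus motion is a per-frame Gaussian
random walk (default step 0.05 µm) added *bit-exactly* to both channels;
the spindle-pole body itself is fixed at a configurable offset. Because
the drift is shared, the focus-minus-fiducial difference cancels it
exactly — the package's drift-invariance tests demand agreement to
$10^{-9}$ µm, and any fiducial-correction regression would break them.

**Imaging.** Spots are rendered as 3D Gaussians (lateral σ 1.3 px, axial
σ 1.0 slices) on a uniform background, with Poisson photon noise and
Gaussian read noise. Voxel coordinates are 0-based voxel centers. The
magnitude of localization noise in published trackers is not reported,
so the noise defaults (peak 200 photons, background 10, read noise 2)
were chosen to give a comfortably realistic signal-to-noise ratio rather
than to match a specific microscope; the test suite additionally probes
a peak-SNR≈5 regime.

**What the generator does not emulate:** photobleaching and blinking,
multiple cells per field, out-of-focus light, chromatic offsets between
channels, and any biology (no resection–mobility coupling). Passing
tests therefore demonstrate the correctness of the estimators under the
stated stochastic model, not robustness to every imaging artifact.

## Tracking

The published analyses in this field rely on unpublished interactive
MATLAB trackers, so the package ships a deliberately auditable
replacement: difference-of-Gaussian band-pass (σ and 2σ), local maxima
over the 26-neighborhood above `median + 5·MAD` of the filtered volume,
merging of peaks closer than a minimum separation (brightest wins), and
subpixel refinement by intensity-weighted centroid of the
background-subtracted raw volume in a fixed window. Detections are
restricted to the volume interior (border voxels ride on filter edge
effects). Linking is greedy nearest-neighbor with a hard displacement
gate and a bounded frame gap; ties are broken by intensity then row
index so results are bit-reproducible. There is no interpolation:
missing frames stay missing, and MSD pairs never span them.

Channel pairing selects the fiducial track sharing the most frames with
the focus track (ties to the nearer one — with two spindle-pole bodies
in view the closer one is the usable fiducial) and requires both tracks
to cover at least 80% of frames. The 80% floor is this package's own
inclusion rule; published work does not state one. Likewise 0-based
frame indices, and z kept in slice units until the mobility stage,
are package conventions recorded here.

## MSD details

For lag $k$ frames the estimator averages squared displacements over all
overlapping windows of $k{+}1$ consecutive *observed* frames. Requiring
the whole window (not just its endpoints) keeps the pair count
non-increasing in lag and avoids silently bridging detection gaps; a
non-overlapping mode is available for sensitivity analysis. The
implementation is pinned to a brute-force double-loop oracle at
$10^{-12}$ tolerance in the tests. SEM is taken across cells, not across
pairs, matching how ensemble MSD curves are reported.

**Dimensionality.** MSD and $R_C$ default to the lateral plane (x, y):
the $R_C$ formula is defined in terms of $\sigma_x, \sigma_y$ only, and
axial localization from 0.3-µm slices is several-fold worse than
lateral. 3D MSD is available via `dims = 3` and is labeled as such in
outputs. Whether published MSD values are 2D or 3D, and overlapping or
not, is generally unstated; both options are exposed and neither is
claimed to replicate any specific study.

## Finite-sampling bias of $R_C$

A 41-frame movie observes only a handful of relaxation times
($\tau \sim R^2/D \approx 10$–20 frames at the defaults), so the sample
variances — and hence $R_C$ — are biased low, increasingly so for larger
true radii. With the default generator the acceptance computation
measures a bias of roughly −7% at $R = 0.6$ µm, −10% at 0.8 µm and −18%
at 1.0 µm for the 41-frame geometry, vanishing (< 1.5%) for 2000-frame
tracks. Two practical consequences: (i) reported $R_C$ values from
20-minute movies compress the true dynamic range, and (ii) comparisons
between conditions acquired with the same geometry remain valid because
the bias is monotone — the test suite verifies that the ordering of
cohorts by true radius survives the bias.

A second, much smaller bias comes from discretizing the reflected walk:
the folded-step boundary behaves like a slightly soft wall, shrinking
the stationary variance by about $0.1\,\sigma_{\text{step}}/R$. With the
default 10 sub-steps per frame this is below 1% and is why sub-stepping
exists at all.

## qPCR resection and cutting assays

Resection converts double-stranded DNA to single-stranded DNA, which a
restriction enzyme cannot cut. Comparing quantification cycles between a
digested and a mock-digested aliquot at a probe site spanning the
restriction site therefore measures the fraction of molecules resected
past that site:

$$x = \frac{2}{\left(\frac{E_{RS}^{\Delta C_q(RS)}}{E_{ADH1}^{\Delta C_q(ADH1)}} + 1\right) f}$$

with $\Delta C_q = \bar C_q(\text{digest}) - \bar C_q(\text{mock})$,
primer efficiencies $E \in (1, 2]$ (inputs, default 2; no standard-curve
fitting is implemented), and $f$ the fraction of cells actually cut.
Technical triplicates are averaged at the Cq level *before* differencing
— aggregation order is unstated in the assay literature, and this choice
is recorded here. Values $x > 1$, possible with noisy cycles or small
$f$, are reported raw with a QC flag rather than clamped. Cutting is
quantified as $2^{-(\Delta C_t - \Delta C_{t,0h})}$ on an amplicon
flanking the cut site; the conversion of that fold value to the $f$ of
the resection formula ($f = 1 - \text{fold}$, clipped to $[0,1]$) is an
explicit package convention, since the assay descriptions leave it
unstated. The synthetic Cq generator is built as the exact algebraic
inverse of the estimator, and the round trip is held to $10^{-12}$ at
zero noise.

## Statistics

Condition-versus-reference comparisons follow the conventions of the
figure legends this kind of analysis feeds: pooled-variance two-sided
t-tests (Welch behind a flag; "unpaired t-test" in point-and-click
software means the pooled form), one-way ANOVA with Dunnett's
many-to-one adjustment, and tier coding ns/*/**/*** at 0.05/0.01/0.001.
The Dunnett rectangle probability is evaluated by a deterministic
two-dimensional Gauss–Legendre quadrature over the shared
reference-group variate and the pooled scale, using the product
correlation structure $\rho_{ij} = \lambda_i\lambda_j$,
$\lambda_i = \sqrt{n_i/(n_i + n_0)}$, which is exact for the
many-to-one design, balanced or not. The quadrature agrees with
`mvtnorm`/`multcomp` to ~$10^{-6}$ in the cross-check tests, and its
family-wise error under a simulated global null is verified at the
nominal 0.05. No normality or equal-variance diagnostics are applied
beyond warnings — the tests are applied unconditionally, as they are in
practice. Day-paired filtering restricts each contrast to acquisition
days on which both the condition and the reference contributed cells,
reflecting that microscope throughput varies day to day.

Cohort sizes below 10 cells trigger a warning (the conventional floor
for reporting a condition) but are not refused.

## Numerical and design choices

* Units are µm and seconds everywhere after ingestion; pixel/slice
  conversions happen only at the boundary (`correct_coordinates()`).
* One seeded generator per `simulate_*` call, no global RNG state; the
  same seed and configuration give bit-identical tracks, stacks and
  tables, and `run_pipeline()` reruns are byte-identical.
* TIFF stacks are written as multi-page 32-bit float with a JSON sidecar
  recording the (time, channel, z, y, x) page order, dimensions and the
  affine intensity mapping; the `tiff` package does not persist custom
  TIFF tags, so the sidecar is the metadata channel.
* Degenerate inputs are defined, not crashed on: all-identical positions
  give $R_C = 0$ with a flag; a fully-cut qPCR well is emitted at a
  documented Cq ceiling (40) and flagged; two constant equal groups give
  p = 1 with a flag.
* Problem sizes in the test and acceptance computations (50–200 cells,
  2000-frame "long" tracks, $10^4$ null replicates, $10^5$-point
  uniform clouds) were chosen so that Monte-Carlo error is several-fold
  smaller than each assertion's tolerance.

## Known limitations

* The hard-sphere model ignores tethering and viscoelasticity; $R_C$
  from real loci is an effective radius whose interpretation leans on
  the uniform-ball identity.
* The detector assumes one spot per channel per cell (cropped fields);
  there is no scene segmentation, Kalman/LAP tracking, or bleaching
  correction.
* Primer efficiencies are user inputs; no raw-fluorescence processing
  or Cq calling.
* The Dunnett variant used by commercial packages is not publicly
  specified; outputs record this package's method string
  (`dunnett_mvt_quadrature`) rather than claiming equivalence.
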