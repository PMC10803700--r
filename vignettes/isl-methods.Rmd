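---
title: "Synthetic lesion insertion for PET system comparison: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic lesion insertion for PET system comparison: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petisl)
```

## The problem

Deciding whether one PET/CT scanner detects more lesions than another is
hard to do on patients, because patient images come with no ground truth:
nobody knows how many true lesions an exam contains. Insertion of
synthetic lesions (ISL) sidesteps this by adding simulated focal uptake of
known position, size and contrast into real (or, here, simulated)
scan–rescan image pairs acquired on the two systems. Every inserted lesion
is a known true positive, so per-system detection rates — and their ratio,
the relative true-positive rate (RTPR) — become measurable on clinically
realistic images.

`petisl` implements that workflow end to end in image space: a compartment
phantom stands in for the patient, spheres are inserted with
partial-volume accuracy and system-specific point-spread-function (PSF)
blur, the second exam is decayed and count-matched, SUV metrics are
extracted, and reader results are reduced to the study statistics (RTPR
with CI, exact binomial inter-observer agreement, relative differences of
SUV metrics).

## Core model

**Contrast and insertion.** A lesion is a sphere specified by world-mm
centre, diameter $d$ and contrast
$C = (\mathrm{AC}_{lesion} - \mathrm{AC}_{bg})/\mathrm{AC}_{bg}$.
The local background $\mathrm{AC}_{bg}$ is the mean over a 2 cm³ spherical
VOI (radius $(3V/4\pi)^{1/3} = 7.8159$ mm) measured *before* insertion;
the lesion AC is then $\mathrm{AC}_{bg}(1 + C)$. The delta image —
fractional sphere occupancy times $\Delta\mathrm{AC}$ — is blurred with
the system PSF and added. Because the blur kernel is normalized and the
boundary rule conservative, the inserted activity
$\Delta\mathrm{AC}\cdot V_{sphere}$ survives the blur to better than
$10^{-6}$ relative, which the tests assert.

**Batch semantics.** When several lesions go into one volume, all
background VOIs are measured on the pristine volume first, then deltas are
added. This makes multi-lesion insertion order-invariant (asserted as a
property test) and matches the protocol of measuring backgrounds prior to
simulation.

**Matched pairs.** The same lesion (same world centre, same contrast) is
inserted into both exams; each exam contributes its own measured
background, so the lesion AC tracks the decay and noise of that exam. On a
pair differing only by the decay factor, the two lesion ACs differ by
exactly that factor — a test pins this at $2^{-25/109.77} = 0.854$ for a
25-min delay.

## Numerical choices

**Sphere rasterization.** Each voxel's occupancy is estimated from
supersampling³ sub-cells (default 3). A hard inside/outside count
converges slowly (a few percent error at default settings), so each
sub-sample instead contributes a linear antialiasing ramp of width $w$
across the surface, with $w$ twice the sub-cell extent so it spans the
sample lattice pitch. A planar ramp overestimates a convex sphere by
exactly $(\pi/3) r w^2$ in volume; ramping at the effective radius that
solves $(4/3)r_e^3 + (1/3)r_e w^2 = (4/3)r^3$ cancels the bias. The
resulting volumes are within 0.4 % of $(\pi/6)d^3$ for diameters in the
design range [5, 11] mm on both study voxel grids (tested at 1 %).

**PSF blur.** Separable Gaussian parameterized by FWHM, applied as
per-axis convolution matrices with a half-sample symmetric
(edge-repeating) boundary. For a symmetric kernel this boundary makes
every column of the convolution matrix sum to one, so total activity is
conserved to machine precision — the property the insertion accounting
relies on. Effective FWHM defaults are 5.0 mm for the BGO-like reference
system and 4.0 mm for the digital TOF-capable system; the reconstructed
resolution of the study systems is not published, so these are explicit
configuration, never asserted in tests.

**Coordinates.** World mm in an axis-aligned RAS+ frame; voxel indices
0-based in the world mapping. NIfTI-1 is the interchange format (RNifti
backend) with scan metadata in a JSON sidecar; a missing sidecar yields a
degraded-mode flag rather than an error.

**VOI conventions.** Measurement VOIs (background, SUV search regions)
use voxel-centre inclusion, mimicking clinical VOI tools; lesion
rasterization uses fractional occupancy, because insertion needs
sub-voxel accuracy while measurement does not.

## Count matching

The second exam starts ~25 min after the first, so its expected counts are
lower by radioactive decay. The expected counts of an acquisition are
$\int_{t_0}^{t_0+T} e^{-\lambda t}\,dt$; equating exam 2 to exam 1 gives
the closed form
$t_2 = -\ln\!\big(1 - e^{\lambda\,\mathrm{delay}}(1 - e^{-\lambda t_1})\big)/\lambda$,
e.g. $t_1 = 2$ min and a 25-min delay give $t_2 = 2.3446$ min for F-18
($T_{1/2} = 109.77$ min). Matching is on expected counts; the sub-1 %
agreement of realized counts is checked by Monte-Carlo at $\ge 10^6$
expected counts. Infeasible configurations (decay too deep for any finite
duration) raise an error reporting the attainable count fraction. The
model is single-bed; multi-bed plans are per-bed independent, since
2 min/bed is the only granularity the protocol states.

## SUV metrics

$\mathrm{SUV} = \mathrm{AC}\,(\mathrm{kBq/mL}) \times \mathrm{weight}\,
(\mathrm{kg}) / \mathrm{activity\ at\ scan\ start}\,(\mathrm{MBq})$.
The three per-lesion metrics are measured in a search sphere of diameter
$d + 2\times$`margin_mm` (default margin 8 mm):

* **SUVmax** — maximum voxel;
* **SUVmean** — mean over voxels ≥ 50 % of SUVmax (isocontour VOI). The
  study's reading workstation does not document its SUVmean VOI, so a
  standard isocontour is used and is configurable; published SUVmean
  medians are therefore not regression targets.
* **SUVpeak** — largest mean over a 1 cm³ sphere positioned at any voxel
  centre of the search region (the EANM-style definition; the study names
  the metric without defining it).

The semi-quantitative comparison is the signed relative difference
$\mathrm{RD} = (\mathrm{SUV}_{cmp} - \mathrm{SUV}_{ref})/\mathrm{SUV}_{ref}
\times 100$, summarized per metric by mean, sample SD ($n-1$; a single
lesion yields SD 0 plus a degeneracy flag), median, min and max over the
lesions detected on both systems.

## Detection statistics

**RTPR.** Ratio of detection rates over the same lesion set. The CI uses
the paired asymptotic log-ratio method,
$\mathrm{var}(\log \mathrm{RTPR}) = (b + c)/(x_1 x_2)$ with $b, c$ the
discordant counts of the 2×2 cross-classification, whenever per-lesion
pairing is available; otherwise the Katz independent log method. The
method label is always carried in the result, because the source study
does not name its CI method: the published intervals are reproduced by
the paired method after rounding, and approximately by Katz.

**IOA.** Reader concordance with a Clopper–Pearson exact CI from beta
quantiles (cross-checked in the tests against `binom.test`), plus the
80 % adequacy flag.

**Consensus.** The study's readers reached consensus by discussion, which
no algorithm reproduces. The sheet format therefore accepts an explicit
consensus column that overrides the algorithmic rule; absent that, the
default is the conservative AND of readers, with OR configurable.

**Natural-lesion reference.** With no ground truth for natural lesions,
the denominator is the union of lesions reported by at least one reader
on either system, deduplicated by id.

**Sample size.** The planning model for a paired detection comparison is
fully parameterized by the target rate ratio, the probability that the
two systems agree on a lesion (both detect or both miss) and the
reference detection rate (defaulting to the balanced value
$1/(1+\mathrm{RTPR})$, where every agreement level below
$1-|p_2-p_1|$ is feasible). Cell probabilities follow, and
the returned $n$ is the smallest with asymptotic McNemar power at the
requested level (a Connor-type closed form seeds the search). The
original study's sample-size reference and its "probability of agreement"
are not specified precisely enough to recover its $n = 58$, so the
implementation is validated by Monte-Carlo power (±3 %) instead of by
that number.

## The synthetic phantom and the simulated reader

No patient data accompany the study, so the phantom module emulates the
features the statistics consume: a torso ellipsoid (1.5 kBq/mL), two lung
ellipsoids (0.4), a liver box (4.0) and a mediastinal box (2.0), chosen so
that lesions at the design contrasts [2, 14] span roughly the published
lesion-AC range (≈2.3–30 kBq/mL); Poisson noise applied voxelwise to
expected counts in image space (reconstruction-domain noise correlation is
out of scope, and image-space Poisson preserves the count-matching logic
under test); and the TOF/digital advantage of the comparison system
encoded as a ×2 sensitivity multiplier — a free parameter, never asserted
as a measured gain.

Synthetic lesions are drawn uniformly over the design ranges (diameter
[5, 11] mm, contrast [2, 14]) and placed by rejection sampling so the
lesion and its measurement shell sit on a homogeneous compartment
background, mirroring placement at relevant anatomical sites away from
organ interfaces.

The simulated reader detects a lesion when its contrast-to-local-noise
index — lesion-core mean minus shell median, in units of the shell MAD
scaled by $\sqrt{n_{core}}$ — reaches a threshold (default 4). The base
count sensitivity (3×10⁻⁴) is set so that sub-centimetre, low-contrast
lesions sit near this threshold on the reference system: the phantom has
none of the anatomical clutter that limits human reading, so difficulty
is restored through count statistics rather than background complexity.
End-to-end checks use 20-phantom batches (60 matched lesions each, 64 ×
64 × 40 voxel grids) — sizes chosen to give stable detection-rate
estimates from a simulation a laptop runs in minutes.

## What passing tests do and do not show

The simulator reproduces the *mechanics* of the study — insertion
accounting, decay and count matching, the statistical estimators, and the
direction of the system comparison (RTPR > 1 for the sharper,
more sensitive system, monotone in the sensitivity gap). It does not
reproduce the study's numerical detection rates: those depend on human
readers, real anatomy, and reconstruction physics that are outside scope
(raw-data/sinogram insertion, attenuation and scatter, respiratory
motion, per-organ uptake kinetics between exams). Published RTPR point
estimates and IOA intervals are reproduced from the published counts
through the estimator code, not re-measured from images.

## Known limitations

* Image-space insertion with a Gaussian PSF stands in for the
  vendor raw-data pipeline; absolute detectability numbers are therefore
  simulator-specific.
* Phantom ACs are static between exams apart from decay; differential
  uptake during the inter-exam delay (noted as a limitation in the source
  study as well) is not modelled.
* The consensus model (AND/OR/external) brackets, but cannot reproduce,
  reader discussion.
* Diameter and volume columns of the published lesion table are not
  mutually consistent at the lower end; the manifest validator warns
  rather than errors on range violations for this reason.
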