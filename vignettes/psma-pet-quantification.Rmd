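---
title: "Automated lesion detection and uptake quantification in PSMA PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lesion detection and uptake quantification in PSMA PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

PSMA-targeted PET tracers (such as [^18^F]DCFPyL) accumulate strongly in
prostate-cancer lesions, but also physiologically in the kidneys, urinary
bladder and liver, and circulate in the blood pool. Standardised reporting of
such scans needs three quantitative ingredients:

1. **Reference uptake** in blood pool (thoracic aorta) and liver, against
   which lesion uptake is graded;
2. **Detection** of candidate lesions in bone, lymph-node soft tissue and
   the prostate, without being swamped by physiological uptake;
3. **Pre-segmentation and quantification** of each candidate (SUVmax,
   SUVpeak, SUVmean, uptake volume).

`psmaquant` implements this downstream pipeline. It deliberately starts from
an *organ label map* given as input: in clinical deployments that map comes
from a CT segmentation model, which is out of scope here. A synthetic trunk
phantom generator supplies co-registered inputs with known ground truth so
that every stage can be validated quantitatively.

## Reference quantification

Both reference organs are first **eroded** by a physical radius (default
4 mm for the aorta, 8 mm for the liver, both configurable) so that boundary
voxels — subject to spill-over and small mis-registrations — never enter the
statistics. Erosion is a spherical morphological erosion converted per axis
by the voxel spacing.

The **blood-pool reference** is the mean of the SUVs inside the eroded
thoracic aorta restricted to the interquartile band. Percentiles use linear
interpolation between order statistics with inclusive bounds; conventions
differ between software stacks, so the choice is stated explicitly and the
implementation is tested against an independent sort/interpolate/filter
oracle to 1e-9. Only the thoracic aorta label is used: the manual comparator
for blood pool is a fixed sphere in the descending thoracic aorta.

The **liver reference** must tolerate regions of artifactually low uptake
(breathing attenuation near the dome). A plain mean over a liver with a 30%
low-uptake region at half uptake is biased low by about 15%. Instead, a
two-component Gaussian mixture is fitted to the eroded-liver intensities by
EM and the mean of the *higher-mean* component is reported: the artifact is
a low-uptake nuisance, so the dominant *uptake* mode is the component with
the larger mean, not necessarily the larger weight. Two guards apply:

* if the higher-mean component carries weight < 0.2, the larger-weight
  component is used instead (a tiny high tail should not define the
  reference), with a warning;
* if the converged means are closer than 0.1 SUV, the fit is declared
  unimodal and the overall mean is returned, flagged.

The EM fit is deterministic: means initialised at the 25th/75th percentiles
of the data, equal weights, common SD at the sample SD, SD floor 1e-3 SUV,
log-likelihood tolerance 1e-6, at most 500 iterations. Both reference
statistics are exactly scale-equivariant, which the tests check by doubling
an image.

A fixed-sphere VOI emulator (`sphere_roi_reference()`, 1 cm in the aorta,
3 cm in the liver, with configurable placement jitter in the experiments)
stands in for manual readers in the variability experiments.

## Detection

Detection runs per tissue **compartment**:

* **bone** — union of the five skeletal regions (femur, pelvic region,
  lumbar vertebrae, thoracic vertebrae, thorax; a 51-bone vocabulary
  collapses onto these), searched on the raw PET;
* **lymph** — soft-tissue body volume (largest connected component of
  SUV > 0.2 x blood pool) minus all labelled organs, searched on the
  *suppressed* PET;
* **prostate** — the prostate label (skipped with a warning
  post-prostatectomy), also on the suppressed PET.

**Physiological-uptake suppression.** For liver, kidneys and bladder a
template is built as the organ mask dilated by 2 mm and blurred by a 6 mm
FWHM Gaussian (matching a typical PET point-spread function); its amplitude
is fitted to the PET by least squares within the dilated organ, and the
clamped sum of fitted templates is subtracted before the soft-tissue search.
This is the simplest model with a testable residual contract: after
suppression the mean kidney/bladder signal drops below 10% of its original
value, while a lesion 40 mm from a kidney edge keeps its SUVmax to within
5%.

**Blob detection** is scale-normalised (gamma = 2) Laplacian-of-Gaussian
filtering over physical scales, by default blob diameters
{4, 6, 8, 12, 16, 25} mm with sigma = d / (2 sqrt(3)), the scale at which
the operator responds maximally to a uniform ball of diameter d. Candidates
are local maxima of the 4D scale-space (26-connectivity in space plus the
two adjacent scales) inside the compartment mask, above a per-compartment
response threshold. Blurring uses normalised convolution (the kernel is
renormalised where it overhangs the grid boundary) so flat fields produce no
boundary artifacts; plateau ties break lexicographically, making candidate
lists byte-deterministic. Response thresholds (bone 0.45, lymph 0.45,
prostate 0.9 SUV) were tuned once on the packaged phantom suite: spurious
responses on lesion-free phantoms stay below ~0.4 away from excretory
organs, while the weakest in-scope lesion (8 mm at 3x contrast) responds
above 0.65.

**Filtering** applies, in order: a location rule (seed inside the urinary
bladder or kidneys, grown by a 9 mm margin so the blurred halo just outside
an excreting organ is also excluded), minimum SUVmax
(`max(2, 1.5 x blood pool)` by default), minimum SUVmean (off by default),
and a volume window (0.1 mL to infinity). Every rejection records the first
failed rule. These cut-offs are package defaults, not clinical constants,
and all are configurable.

A fixed-SUV-threshold baseline (`threshold_detect()`, connected components
of SUV >= t) is included because fixed thresholds of SUV 4.3 and SUV 3.0
have been used as lesion-selection rules; the packaged `threshold_comparison`
experiment shows blob detection strictly dominating the SUV 4.3 rule
whenever lesions with realised SUVmax below 4.3 are present — such lesions
are invisible to the threshold by construction.

## Segmentation and quantification

Each accepted candidate is pre-segmented by **fast marching**: a first-order
upwind Eikonal solver propagates a front from the seed with speed

    F(x) = max(eps, (SUV(x) - floor) / (SUV_seed - floor))^q

with q = 2 and floor = 0.5 x blood pool. Tissue as hot as the seed travels
at unit speed, background essentially stops the front, and the segment is
the region with arrival time <= T (default 15; time is in mm at unit speed),
clipped to a 40 mm radius. At the half-contrast surface of a blurred lesion
the speed has dropped to about 0.25, so the default T lands the boundary
near the true edge of an isolated lesion: on a blurred 10 mm sphere at 5:1
contrast the segment reproduces the true voxel set. Cold gaps act as
barriers, which is exactly the failure mode of 50%-of-SUVmax region growing:
for a 2:1 lesion near a hot structure the 50% cut sits at the background
level and the grown region floods across, while the fast-marching segment
stays on the lesion. Narrow-band ties break by voxel index, so segmentation
is deterministic. Raising T can only grow a segment (tested property).

**Quantification** reports SUVmax and SUVmean over the mask, volume as voxel
count x voxel volume, and SUVpeak as the maximum over 1 mL spheres centred
on each in-mask voxel of the sphere mean *restricted to in-mask voxels* —
the restriction keeps the peak from being diluted by non-lesion background
and guarantees SUVmean <= SUVpeak <= SUVmax; definitions of SUVpeak vary in
the field, so this one is stated and oracle-tested. Lesions smaller than
1 mL fall back to SUVpeak = SUVmean and are flagged.

## The phantom: what it emulates, and what it does not

The generator builds a 128 x 128 x 160 grid at 3 mm spacing (a trunk-scale
384 x 384 x 480 mm box, comfortably desk-fast) with a fixed non-overlapping
geometry: liver and lung ellipsoids, kidneys, bladder and prostate, thoracic
and abdominal aorta tubes, femoral tubes, pelvic ring, lumbar/thoracic spine
columns and a rib-cage shell. Default mean uptakes (background 0.8, blood
pool 1.8, liver 6.0, kidneys 30, bladder 60, bone 1.0, lungs 0.4, prostate
1.5) reproduce the PSMA biodistribution ordering the suppression model
assumes: excretory >> liver >> blood pool >> bone/background. Lesions are
uniform spheres painted at their peak SUV, the superior fraction of the
liver (default 30%) is multiplied by 0.5 to emulate breathing attenuation,
the image is blurred with a 6 mm FWHM Gaussian PSF, and Gaussian noise with
sd = 0.1 x sqrt(SUV) (a variance-scaling surrogate for Poisson counting
noise) is added, seeded. Ground truth stores each lesion's true mask and
the realised (post blur/noise) SUVmax, since that is what detection sees.

The multi-patient suite draws per-patient organ uptakes (blood pool
N(1.8, 0.2), liver N(6.0, 1.2), and so on) and lesion configurations
(2-6 lesions, diameters uniform on 8-20 mm, peak SUV uniform on 4-12,
placed in bone, soft tissue clear of organs, or prostate, with >= 12 mm
separation) — a PSMA-avid metastatic population in which the smallest,
dimmest lesions sit near the detectability edge rather than safely above it.

What the phantom does *not* emulate: attenuation and scatter, sinogram-level
noise correlation, anatomical texture, ureter activity (a known confounder
for pelvic lymph nodes), respiratory motion beyond the liver artifact, and
segmentation errors in the input label map. Passing tests therefore
demonstrate the pipeline's *algorithmic* correctness and its behaviour under
controlled contrast/noise/artifact conditions — not clinical sensitivity on
patient data, which requires reader studies on real scans.

## Numerical and design choices

* All grids are column-major arrays with 0-based voxel indexing in world
  computations and voxel centres at (i - 0.5) x spacing; masks must share
  the PET frame exactly.
* Negative SUVs (possible after scanner reconstruction) are clamped to zero
  on load with a logged count; SUV statistics assume nonnegative uptake.
* Dice of two empty masks is defined as 1 (perfect agreement on absence),
  with a warning; empty-vs-nonempty is 0.
* Truth matching is greedy one-to-one in descending detection response;
  a detection matches a truth lesion if the truth centre lies inside the
  detected mask or the centroid distance is at most max(true radius, 10 mm).
  The clinical reference process was human review, so the criterion is a
  package definition, configurable and logged.
* Sensitivity intervals are Wilson score intervals; Pearson intervals use
  the Fisher z-transform; "ICC2" is fixed to Shrout-Fleiss ICC(2,1)
  (two-way random effects, absolute agreement, single measurement), computed
  from the two-way ANOVA mean squares.
* The packaged experiments run at n = 50 patients (reference variability)
  and n = 20 patients (detection), sizes at which the assertions are stable
  across seeds while a full run stays comfortable on a laptop.
* Determinism: phantoms are reproducible from their seed; the analysis
  pipeline itself uses no randomness, so repeated runs on the same input
  are byte-identical — the reproducibility experiment confirms ICC(2,1) = 1
  for SUVmax, SUVpeak and SUVmean across two runs.

## Known limitations

* The label vocabulary's integer ids and 51-bone list are package
  definitions; clinical label maps must be mapped onto them.
* Suppression is a per-organ amplitude fit of a blurred template; it
  flattens excretory organs well but leaves small residual edges at which
  low-response false positives can appear (they are reported, and the
  margin-grown location rule removes the peri-excretory ones). High false
  positive counts in soft tissue are an accepted property of
  high-sensitivity blob detection in this domain.
* Fast marching with an uptake-ratio speed under-segments very
  high-contrast lesions slightly (the half-contrast surface criterion is
  calibrated for moderate contrast); T and q are configurable.
* Primary prostate tumour delineation is not evaluated, and DICOM decoding,
  SUV calibration, registration and CT segmentation are out of scope.
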