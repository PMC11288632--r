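---
title: "Quantifying sperm-content dynamics in meiotic embryos: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sperm-content dynamics in meiotic embryos: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioquant)
```

## The measurement problem

During female meiosis in *C. elegans*, cytoplasmic streaming moves the
sperm contents (paternal DNA, the maternal ER ring that envelops it, and
the paternal mitochondria cloud) around the zygote while the meiotic
spindle sits near one pole. Three families of quantities describe what can
go right or wrong in this period:

1. **How far do the sperm contents move?** Per meiotic phase (MI, AI, MII,
   AII), from a manually tracked 2-D trajectory of the ER ring sampled
   every 5 s.
2. **How scattered are the paternal mitochondria around the sperm DNA?**
   From fixed z-stacks, as a weighted distribution of punctum-to-DNA
   distances.
3. **Is the sperm DNA captured by the spindle?** From paired time-lapse
   tracks, using a centre-to-centre distance threshold plus a
   stopped-moving condition.

The package implements each measurement exactly as it is defined for real
data, and a synthetic-zygote generator that emulates the imaging scenarios
so that every stage can be exercised and verified without microscope data.

## Coordinate conventions and geometry

All physical quantities are in micrometres and seconds. Pixel and frame
indices are 0-based; lateral positions are `index × pixel_size_um`
(default 65 nm pixels) and axial positions `index × z_step_um` (default
1 µm). The canonical embryo frame has its origin at the embryo centre, the
long axis along x, and the spindle-containing pole at negative x at the
first frame; `normalize_orientation()` applies the rigid (distance
preserving) transform that brings an annotated recording into this frame.
Embryos measured at 35 µm or less along the long axis are excluded from
tracking (`qc_embryo_length()`, strict inequality: 35.0 fails): shorter
apparent length indicates a tilted embryo whose in-plane track would
under-measure motion.

`ellipsoid_volume()` and `volume_ratio()` implement the ellipsoid volume
(4/3)πabc and its ratio between species' zygotes; ratios are reported raw
and rounded half-up to the nearest integer, the form in which such
comparisons are usually quoted (a sphere of 80 µm diameter is 16× the
50 × 25 × 25 µm ellipsoid; 120 µm is 55×).

## Track metrics

For each phase window (inclusive of both endpoint frames):

- *maximum axis displacement*: max − min of x (and of y) coordinates;
- *net displacement*: Euclidean distance from the first to the last point;
- *path length*: sum of consecutive step distances;
- *maximum average velocity*: frame-to-frame speeds (step distance divided
  by the actual time gap, so tracking gaps are handled), averaged over
  trailing windows of 3 consecutive speeds, maximum taken;
- *duration*: (last − first frame) × 5 s.

Two genuinely open details were resolved as follows. The moving average is
**trailing** over consecutive speeds (with k speeds there are k − 2
windows); a centred window would differ only at the window edges, and the
trailing convention matches how a per-frame velocity table is naturally
scanned. Phases yielding fewer than 3 speeds have no defined maximum
average velocity; the metric is reported as `NA` rather than extrapolated.
Incompletely filmed phases and phases at which cell-cycle arrest occurred
are excluded from quantification: `phase_windows()` carries a `complete`
flag and `track_metrics()` skips incomplete sub-tracks (a window extending
beyond the filmed range is automatically incomplete).

## Mitochondrial scatter

The scatter statistic mirrors the manual ROI workflow:

1. every punctum is measured with a circular ROI of 18 pixels diameter at
   65-nm pixels (1.17 µm; `roi_diameter_px()` converts for other
   calibrations). A pixel belongs to a disk ROI iff its centre lies
   strictly within the radius — a deterministic rule chosen because ROI
   semantics differ between tools;
2. one background ROI per embryo (cytoplasm without mitochondria; the
   automated route places it at the lowest-intensity in-embryo position)
   is subtracted from every measurement. Negative corrected intensities
   are retained for ratios and statistics but floored at zero before
   multiplicity computation, where a negative count is meaningless;
3. each amorphous mass is covered by non-overlapping punctum-sized ROIs;
   each tile's corrected mean is divided by the average corrected mean of
   all distinct puncta in that embryo and **rounded half-up with a floor
   of 1** to give its integer multiplicity (a measured fluorescent region
   represents at least one mitochondrion; the rounding convention for
   exact halves is unspecified in the original description, and half-up is
   the common hand-calculation default);
4. each measurement contributes its 3-D Euclidean distance to the sperm
   DNA `multiplicity` times; the per-embryo weighted list is summarised by
   its mean and **sample** SD (n − 1; per-embryo distributions are
   samples, and the spreadsheet/Prism tool family this workflow comes from
   defaults to sample SD). Metaphase I embryos are excluded — immediately
   after fertilisation there has been no time for scattering to develop —
   and a single-measurement profile is flagged degenerate (`sd_um = NA`).

Automated detection (`detect_puncta()`) smooths each plane with a 0.2-µm
Gaussian, takes 3-D local maxima (26-neighbourhood) above a floor of
median + max(10 robust SDs, 0.1 % of the dynamic range), merges maxima
closer than one ROI diameter into the brighter one, and discards
detections outside the embryo ellipsoid (labelled sperm outside the embryo
must not contaminate the statistic).

**Punctum vs mass.** The criterion separating a punctum from a mass is not
specified quantitatively in the original workflow (masses were recognised
visually as large amorphous bright regions). We experimented with a
footprint-area criterion (connected region larger than ~3 ROI areas) and
found it unreliable on synthetic data: above any fixed threshold the
footprint of a diffraction-limited punctum grows with its brightness
(Gaussian tails), so bright puncta masquerade as masses and compact masses
pass as puncta. The package instead classifies a detection as a mass when
its background-corrected ROI mean exceeds `mass_cutoff` (default 1.75)
times the cohort median — directly matching the observation that mass
fluorescence is "typically much greater" than punctum fluorescence — and
then tiles the mass's above-threshold footprint for measurement.

## Capture classification

A recording is scanned for *below-threshold episodes* of the per-frame
sperm–spindle centre distance (2-D projected centres, matching
single-focal-plane live acquisition; threshold 5.5 µm). An episode is
**stable** when it persists to the end of the series and contains a run of
`stuck_window_frames` = 6 consecutive frames (30 s at 5-s intervals) whose
cumulative relative displacement is below `stuck_disp_um` = 1 µm — our
operationalisation of "stopped moving relative to the spindle", which the
original description leaves qualitative; both parameters are exposed in
`capture_config()` and echoed in every result. An episode that ends with
the distance rising back above threshold is **transient**; the final label
summarises the sequence (`none`, `transient`, `stable`,
`transient_then_stable`). Episodes interrupted by tracking gaps longer
than 3 frames are split. Group tallies (`capture_contingency()`: stable
and transient-then-stable count as captured) feed Fisher's exact test.

## Statistics layer

`normality_gate()` applies Shapiro–Wilk at α = 0.05 to every group; the
comparison is parametric only when **all** groups pass (the conservative
all-pass rule matches common practice in the tool family this workflow
uses; groups with n < 3 or zero variance cannot be tested and force the
nonparametric branch). Dispatch: two groups → Welch's t-test or
Mann–Whitney; three or more → Welch's ANOVA or Kruskal–Wallis. The
original description says only "ANOVA" for the parametric k-group branch;
we use the Welch-type ANOVA for consistency with the choice of Welch's
t-test for two groups (both are robust to unequal variances). The
Mann–Whitney test is exact when both groups have n ≤ 8 with no ties
(two-sided p = min(1, 2 × one-sided), the doubling convention), otherwise
the tie-corrected normal approximation with continuity correction;
Kruskal–Wallis uses the tie-corrected χ² approximation. Fisher's exact
test reports the probability-mass two-sided p (sum of tables no more
probable than the observed) plus the one-sided p. No multiple-testing
correction is applied across metrics — raw p-values are reported, as in
the workflow this mirrors — and pairwise post-hoc tests after
Kruskal–Wallis are available to the user but not run by default. Stars:
`*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001.

## The synthetic zygote generator

The generator's job is to produce data with *known* answers, in the
geometry and calibration of the real experiments: a 50 × 25 × 25 µm
ellipsoidal embryo, 65-nm pixels, 1-µm z-steps, 5-s frames, and a phase
schedule MI → AI → MII → AII (defaults 480/300/480/300 s, in the range of
a ~25-min meiosis; the true per-phase durations vary between embryos and
none of the metrics depends on the exact values).

**Mitochondria cloud.** Punctum positions are drawn from an isotropic 3-D
Gaussian (σ = `cloud_sigma_um`, default 1 µm) around the sperm DNA,
rejection-sampled into the embryo (bounded at 10 000 attempts per point).
Masses are k-fold clusters (k ≥ 2, mean `mass_intensity_factor`) of
punctum-equivalents spread over ~0.5 µm, so their summed intensity is
about k times a punctum and their ground-truth multiplicity is an integer
— which is what makes the rounding rule testable. Each focus is rendered
as a 3-D Gaussian (lateral σ 0.3 µm, axial σ 0.75 µm) whose voxel sum
equals its integrated intensity, plus background, Gaussian read noise and
integer quantisation. Because the cloud is an isotropic Gaussian, the
population mean of punctum-to-DNA distances is 2σ√(2/π) (the χ₃ mean),
giving a closed-form parameter-recovery check for the whole scatter
pipeline.

**Streaming.** Streaming in this system is characterised
phenomenologically (jostling, short-axis rotation, long-axis rotation),
so trajectories are modelled as
regime-dependent kinematics rather than hydrodynamics: a zero-mean random
walk with Rayleigh step lengths (mean step = amplitude × frame interval)
for jostling; a circular arc (motion predominantly in y) for short-axis
rotation; a cosine excursion along x for long-axis rotation — each plus
seeded jitter and confined to the embryo. No quantitative streaming
velocity distributions are available to emulate, so the control amplitude
(0.05 µm/s) is a free parameter chosen to give control max-axis
displacements of a few micrometres per phase, with depletion multipliers
(katanin-like 3×, kinesin-13-like 2.5×, ataxin-2-like cloud dispersion
3×, the double depletion compounding the last two) that reproduce the
*direction* and rough magnitude of the depletion phenotypes. Streaming
subsides after meiosis I (amplitude × 0.4 in MII/AII) except in
kinesin-13-like depletions, which maintain elevated streaming into MII.
The spindle track is nearly stationary near the left pole.

**Capture scenarios.** `stable` programs one monotone approach below the
5.5-µm threshold followed by frozen relative position (tiny jitter);
`transient` dips below, departs above, then re-approaches and sticks (two
below-threshold episodes); `none` streams normally but rejects steps that
would bring the sperm closer than 8 µm to the spindle, guaranteeing a
clean negative. These scenarios give the capture classifier programmed
positives and negatives for sensitivity/specificity measurement.

**What the generator does not emulate.** ER texture (sheet/tubule
transitions used for manual phase calling), yolk granules and other
organelles, pronuclear formation, photobleaching, flat-field
inhomogeneity, and z-drift. Passing tests on synthetic cohorts therefore
demonstrate that the *measurements and classifiers are correct given
annotated inputs*, not that detection or phase calling would be robust on
every real image.

## Numerical choices and degenerate inputs

- Rounding of multiplicities and volume ratios is half-up
  (`floor(x + 0.5)`), not banker's rounding.
- ROI membership is strict (`< r`), so an ROI never gains pixels from
  floating-point ties; ROIs that touch the image border are an error, not
  silently truncated.
- The detection floor has both an absolute (10 robust SDs) and a relative
  (0.1 % of dynamic range) component; the latter guards noise-free images
  against FFT round-off from the Gaussian blur.
- Tracks with missing frames are allowed everywhere; speeds divide by the
  actual time gap, and below-threshold episodes split at gaps > 3 frames.
- Degenerate statistics are explicit: single-measurement profiles have
  `sd_um = NA`; constant groups give Brown–Forsythe statistic 0, p = 1;
  zero-variance groups in the parametric branch fall back to
  nonparametric with a warning.

## Problem sizes used in the shipped tests and acceptance script

Scatter recovery uses 50 embryos × 30 puncta; direction checks use 50 + 50
embryos (scatter) and 15 per group (displacement, mirroring realistic
cohort sizes); the capture fidelity check uses 50 programmed positives and
50 negatives; oracle-equivalence checks use 1000 random tracks;
Kruskal–Wallis size uses 1000 null simulations of 3 × 20 observations.
These sizes make every Monte-Carlo bound comfortably stable under the
fixed seeds while keeping the whole suite fast on a laptop.

## Limitations

Automated punctum detection is tuned for the generator's PSF scale and
SNR; real data with different optics should adjust `smooth_sigma_um`,
`intensity_floor` and `merge_radius_um`. The mass/punctum intensity
criterion assumes most detections in an embryo are single puncta (the
median is the reference). Capture calls are 2-D, as in the live
acquisition they mirror; a spindle displaced strongly in z would bias
distances upward. The statistics layer reports raw p-values only.
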