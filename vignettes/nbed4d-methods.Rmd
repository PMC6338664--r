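---
title: "Methods: 4D-STEM mosaicity mapping with nbed4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D-STEM mosaicity mapping with nbed4d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbed4d)
```

# The problem

Protein and peptide micro/nanocrystals are not the monolithic lattices
that whole-crystal diffraction assumes: they are mosaics of sub-domains
that differ slightly in orientation. Because any whole-crystal
measurement averages over these domains, mosaicity is usually a refined
nuisance parameter rather than an observed quantity. Scanning nanobeam
diffraction (4D-STEM) makes it observable: a ~6 nm probe steps across
the crystal in 20 nm increments, a full diffraction pattern is recorded
at each step, and position-resolved analysis of those patterns maps
thickness and lattice tilt at the scale of tens of nanometres. The
price is dose: a beam-sensitive crystal tolerates roughly 1 e⁻/Å² per
position, so each pattern carries only a few thousand electrons and
every processing stage must respect counting statistics.

This vignette documents the models and the numerical choices behind
each stage of the package, what the synthetic-data generator does and
does not emulate, and the limits of what the test suite shows.

# Hybrid electron counting

A raw analog frame from a strip-readout direct detector is modelled as

* per-strip dark offsets (vertical column blocks; default strip width
  32 columns on the desk-scale detector, since the hardware reads in
  column banks and the true width is configuration-dependent),
* a Gamma-distributed charge pulse per primary electron
  (`single_electron_gain`, default 15 counts, shape 400), and
* Gaussian read noise (σ = 2 counts).

Counting proceeds scan-at-a-time: strip offsets are the per-strip
medians over all frames (medians are robust to the sparse electron
events); a Gaussian is fitted by least squares to the histogram of the
pooled offset-subtracted pixel values; the counting threshold is
μ + 5σ. Each pixel then contributes ⌊value/threshold⌋ counts.

Numerical choices worth stating:

* The histogram for the background fit excludes values above the 99.5th
  percentile **and** is binned over a window of ±10 robust standard
  deviations (MAD) about the median. Without the windowing, a handful of
  kilocount central-beam pixels stretches the bin range until the whole
  background falls into one bin and the fit is meaningless. The fit
  falls back to an error (not a silent guess) if it cannot converge, and
  a zero-variance strip is reported by name.
* Whether the threshold means μ + 5σ or 5σ about zero after perfect
  dark subtraction is ambiguous in practice; μ ≈ 0 after subtraction so
  the difference is small, and both are supported
  (`threshold_mode = "5sd"`).
* Floor division uses the full threshold as the per-electron divisor
  even though the single-electron gain differs from it. With the default
  gain/threshold ratio of 1.5, an isolated electron (the overwhelmingly
  common case outside the central disc at ≤ 2 e⁻/Å²) is counted exactly
  once, because the one-count window [θ, 2θ) is centred on the gain;
  pixels holding n coincident electrons report ≈ ⌊1.5 n⌋. The linearity
  assumption is knowingly approximate — that is intrinsic to the
  algorithm — and the package's thickness stage is insensitive to it
  because a common linear miscount cancels in the intensity **ratio**
  I/I₀.
* The desk-scale detector (256 × 272) concentrates the full probe
  current into a 5-px central disc, which makes the centre strongly
  coincident; counting-fidelity tests therefore run at the
  instrument-native geometry (1792 × 1920, 46-px beam disc), where the
  per-pixel occupancy outside the centre is genuinely low.

# Shift correction

The diffraction pattern drifts across the detector as the beam scans.
Single patterns are too noisy to track, so the correction is separable:
average all patterns sharing one scan index, measure the transmitted
beam's centre of mass per strip average, and translate every frame of
that strip by the (integer) offset to the geometric frame centre; then
the other axis; repeat the pair of passes until the residual COM
deviation is below 0.5 px (at most `max_rounds`, default 3). Integer
translations of the sparse coordinate lists preserve counting
statistics exactly — no interpolation is ever applied. The COM is
computed inside a disc of 1.5 × the beam radius around a running centre
(three refinements), because an unwindowed COM is biased by Bragg
peaks. Diagonal drift couples the two separable passes, which is what
the iteration absorbs; empirically two to three rounds suffice for
drifts of a few pixels.

# Thickness mapping

Thickness follows the log-ratio formula used for inelastic scattering,
Z_xy = −λ ln(I_xy / I₀), with λ = 332 nm for these peptide crystals.
I_xy integrates the central disc plus 4-px discs at all Bragg positions
(discs overlapping the central disc are excluded; overlapping Bragg
discs credit each pixel to the nearer peak). I₀ is the mean central-disc
integral over vacuum positions minus two (population) standard
deviations — the subtraction compensates central-beam intensity
fluctuations; it is implemented verbatim and can be disabled
(`sd_correction = FALSE`). Positions with I ≥ I₀ clip to Z = 0; empty
positions flag as opaque (Z = ∞) rather than erroring. Bragg positions
come from the indexing stage's peak set when available, else from a
local-maximum search above 5σ of the azimuthal background of the
scan-average pattern.

# Pattern classification

Features are the flattened frames after sum-binning (default 8-fold)
and masking the central disc — without the mask, cluster maps simply
reproduce the thickness map, since the transmitted beam dominates the
Euclidean distance. No per-pattern normalisation is applied: total
intensity differences are part of the signal. k-means uses k-means++
seeding and plain Lloyd iterations on the within-cluster sum of squares,
stopping at 100 iterations or when the relative WCSS change over one
iteration falls below 10⁻⁶ ("stagnation"; the exact value is a
reproducibility choice, not a sensitivity). An empty cluster is
re-seeded at the pattern farthest from its current centre, never
stealing a cluster's last member. K is chosen by G-means: a cluster's
members are projected onto the axis joining its two 2-means children and
tested for normality by the Anderson–Darling statistic (case 3,
estimated mean and variance, via `nortest`) at α = 0.001; failing
clusters split. Masked vacuum patterns are nearly empty, their
projections are grossly non-Gaussian, and without a brake they split
indefinitely — hence the global stop once ≥ 80 % of the current clusters
test Gaussian. Children inherit only their parent's members (standard
G-means); a manual K override is available for scans where automatic
selection is unstable.

# Kinematic simulator and template library

The simulator is a kinematic model: reciprocal-lattice points within the
resolution cutoff (default 1.4 Å) are projected through the rotation
(tilt_x about the detector x axis, then tilt_y), and each reflection's
intensity is a Gaussian envelope in its excitation error
s = −g_z − λₑ|g|²/2 (λₑ = 0.0197 Å at 300 kV). The envelope width is

σ_s(g, t) = sqrt( (1 / 10 t)² + (|g| sin σ_mosaic)² ),

the first term the relrod of a crystal t nm thick, the second an
angular broadening (default σ_mosaic = 0.2°) representing beam
convergence plus the continuous orientation spread inside one probe
position — the phenomenon the pipeline exists to map. Without that
floor, a 300 nm crystal's rocking width (~0.06° at |g| ≈ 0.3 Å⁻¹) is
far narrower than the 0.25° library step and off-grid orientations
would have no RMSD basin to descend; with it, neighbouring library
entries still differ by about one envelope width and remain
distinguishable. Structure factors default to uniform (geometry-only);
a per-reflection amplitude table can be supplied. Thickness attenuates
the whole elastic pattern by exp(−Z/λ) with the same λ = 332 nm the
thickness stage uses, so the thickness round-trip closes by
construction. Vacuum positions carry an unattenuated central disc;
carbon support attenuates without diffracting. The default
`bragg_strength` (0.01 per fully excited reflection) puts roughly 5–10 %
of the counted electrons into Bragg peaks at 300 nm, matching the
observed ratio of Bragg to total electrons per pattern.

The template library shares this engine. Its entries span a regular
tilt grid (the experimental design is ±4° in 0.25° increments; desk-scale runs
use ±2.25°) crossed with a thickness set from the 10–600 nm range.
Rather than storing dense frames, each entry stores its max-scaled
intensities on the common peak set — RMSD matching never consumes
anything else, a dense ±2° library would occupy ~0.5 GB, and
`render_library_entry()` materialises any full pattern on demand. The
peak set is the union of detector projections of every reflection
reachable anywhere in the tilt range (reachability symmetrised over
Friedel pairs, whose excitation errors differ only by the Ewald
curvature term), excluding a disc of twice the beam radius. Peak
positions are fixed at the mean orientation: a 2° tilt moves a spot by
about 2.5 px on the desk-scale detector, well inside the 4-px
integration radius. Ties in the RMSD argmin break toward smaller |tilt|,
then smaller thickness. The scan's mean orientation is the
1/(RMSD + 10⁻⁶)-weighted mean of the per-cluster assignments; at tilts
of a few degrees arithmetic and circular means coincide to numerical
precision.

# HRTEM counterpart

Real-space lattice images are tiled into non-overlapping 128 × 128
sub-images (margins dropped by the floor rule). K comes from the elbow
method — formalised as the k maximising the discrete second difference
of WCSS(k) under fixed seeds, since the name alone does not define an
estimator — which is more stable than the normality test on noisy image
data. Tile clustering is k-means where the tile-to-centre distance is
minimised over all integer shifts in a 5 × 5 window, compared on the
overlap region and normalised by its area (a declared boundary-handling
choice); each tile enters its cluster average at its best shift. Class
averages are Fourier-filtered: coefficients below mean + 2 SD of the
magnitude spectrum (DC excluded from the statistics, always retained)
are zeroed before inverse transformation.

# Synthetic study conditions and problem sizes

The generator's defaults are the experimental operating point: 6 nm
FWHM probe, 1.5 × 10⁶ e⁻/s, 2.5 ms dwell (3750 electrons, ~1 e⁻/Å²,
400 patterns/s), 20 nm step, triclinic peptide cell
(4.94, 10.34, 31.15 Å; 94.21°, 92.36°, 102.2°), λ = 332 nm. The default
detector is a desk-scale 256 × 272 with the strip structure, gain and
noise of the full 1792 × 1920 instrument, which is also supported and
used where geometry matters (counting fidelity). Test and acceptance
scans are 12 × 12 to 6 × 11 positions with 1–4 tilt domains spanning the
±0.5° to ±2° regimes against a ±2.25°, 0.25°-step, 3-thickness library;
these sizes keep the full suite under a minute of simulation while
leaving every recovery margin (one grid step, 5 % thickness, 0.5 px
residual) statistically meaningful.

What the phantom does **not** emulate: dynamical (multislice)
scattering and thickness fringes, structure-factor contrast between
reflections, inelastic/plasmon backgrounds beyond flat attenuation,
detector saturation and the resulting central-beam undercounting,
radiation damage over time, and continuous intra-domain tilt gradients
(domains are piecewise constant). Passing tests therefore demonstrate
that the algorithms are implemented correctly and are statistically
well-behaved at the stated dose — not that the kinematic intensities
match experimental ones, which is why the library format accepts
externally simulated (e.g. multislice) patterns as a drop-in.

# Degenerate inputs and edge policies

Degenerate cells (no consistent 3-D embedding) error at construction;
a detector too small to catch any reflection warns and returns the
central beam only. Rendering requires an explicit seed — there is no
silent RNG state. Zero-variance backgrounds error naming the strip.
Empty strips in shift correction are interpolated from neighbours.
Empty patterns integrate to I = 0 and map to opaque thickness. All-zero
intensity lists make a cluster unindexable (rendered neutral grey in
the orientation map) rather than erroring. Coordinates are 1-based
(row = k_y, column = k_x; scan row-major), as is idiomatic in R, and
the plain-text sparse export states this in its header.

# Known limitations

Floor-division counting over-reports heavily coincident pixels by up to
the gain/threshold ratio (1.5) — accepted as intrinsic to the published
algorithm and harmless to ratio-based stages. Indexing assumes known
cell constants; there is no ab initio mode. The shift model is
separable per scan axis; a per-frame (non-separable) drift field is out
of scope. Cluster boundaries are hard assignments and can look sharper
than the underlying continuous orientation change; the HRTEM module
reproduces the published procedure without asserting that its clusters
differ measurably on real images.
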