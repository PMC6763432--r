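---
title: "Models and methods behind prismr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prismr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`prismr` analyses sequential multiplexed fluorescence images of neuronal
culture — one grayscale plane per target per imaging round — and
single-molecule localization tables from DNA-PAINT movies. This vignette
documents the models, the parameters that matter, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Flat-field correction

Spinning-disk illumination inhomogeneity is multiplicative, so each plane
is divided by a per-channel illumination profile. The profile is estimated
from the data themselves: every field is opened with a disc structuring
element (default radius 100 px) — grayscale opening removes all structure
smaller than the disc and leaves the smooth background, which is modulated
by the illumination field — and the backgrounds of all fields from one
channel and plate are averaged and rescaled to spatial mean 1, so
correction preserves average intensity and corrected intensities remain
comparable across plates. Profiles are estimated per plate, because
illumination varies between experiments.

Two numerical points. First, the opening takes a near-minimum over a disc
of ~31,000 pixels, so the background level must exceed roughly 4.3 times
its own noise SD or the estimate collapses toward the camera floor; this
holds for any realistic diffuse background. Second, the averaged
background is Gaussian-smoothed (default SD 10 px) before normalization:
the illumination field is a smooth optical property, and smoothing
stabilizes profiles estimated from few fields and removes isolated
zero-count pixels that would otherwise make the multiplicative profile
degenerate. Both the disc radius and the smoothing SD are exposed.

## Inter-round registration

Lateral stage drift between rounds is rigid at the integer-pixel level.
`estimate_xy_drift` returns the integer (dx, dy) maximizing the normalized
cross-correlation between the reference channel (MAP2, re-imaged every
round) of the reference round and of the moving round, over a
±`max_shift` window (default 50 px). For every candidate shift the
Pearson correlation is computed over the overlap region only, with the
cross term obtained by FFT and the overlap moments by integral images, so
the estimator is exactly the exhaustive search at any image size (a
property the test suite verifies against a literal double loop). Exact
ties break toward the smallest |dx| + |dy|, then lexicographically.
Integer shifts avoid interpolation, which would distort the intensity
quantification downstream; a parabolic sub-pixel refinement is available
behind `subpixel = TRUE` but is not used by the pipeline. Shifted-in
pixels are zero-filled and flagged in per-round masks, and masked pixels
are excluded from segmentation.

The package processes single 2D planes. Where acquisition produces small
axial stacks, the maximum-intensity projection (or a chosen plane) should
be formed before `prismr` sees the data; no axial registration is
attempted.

## Punctae segmentation

The segmentation recipe is: (1) saturate the lowest and highest 1% of
pixel intensities and rescale to the full range of an 8-bit gray scale;
(2) adaptive Wiener denoising in 5×5 windows — local mean/variance
shrinkage with the noise floor estimated as the image-mean local variance,
so flat background collapses to its local mean while structured regions
pass through; (3) white top-hat with a disc of radius 8 px, which removes
everything wider than the disc (dendrite shafts, nuclei, the smooth
diffuse background); the result is rounded to integer gray levels.

The rounding is deliberate and placed *after* the top-hat: the
Wiener-flattened, top-hatted background fluctuates well below half a gray
level and therefore rounds to exactly zero, so the subsequent threshold
scan ranges over punctae intensities, not the noise floor. Rounding
earlier (between Wiener and top-hat) leaves the smooth background at a
fractional level whose rounding boundary speckles into 0/1 patches the
opening cannot track. This zero-background regime requires the bright-IF
dynamic range that antibody staining at second-scale exposures occupies —
as a rule of thumb, the 99th intensity percentile must exceed ~130× the
background noise SD. Dim, noise-dominated images put the object-count
maximum at the noise percolation threshold and the method degrades; this
is a property of the algorithm, faithfully reproduced.

The threshold itself is chosen by an object-feature scan: 100
quantile-spaced candidates over the nonzero enhanced pixels (quantile
spacing makes the choice invariant to detector gain and robust to
intensity variation across channels); for each candidate the 8-connected
components of at least 2 px are counted, and the candidate maximizing the
count wins, ties going to the *lowest* such threshold — the most inclusive
segmentation, which matters because punctae areas are measured at this
threshold. The 2 px floor keeps single-pixel noise from dominating the
count. Touching punctae are then separated by a watershed on the negated
Euclidean distance transform (seeds = local maxima of the distance map
within a 3 px neighbourhood; minimum basin depth 0.5 px), which assigns
every foreground pixel to exactly one label and so conserves area.
8-connectivity is used throughout, matching the diagonal boundaries the
watershed produces.

Area, integrated intensity and intensity-weighted centroid are measured on
the corrected, *un-enhanced* image: the top-hat distorts intensities, so
measuring on the enhanced image would bias the quantification.

Synapses are synapsin-I punctae strictly larger than 0.42 µm² whose
centroid lies outside the nuclear mask (intranuclear synapsin punctae are
mostly not synapses). At 187 nm pixels the gate sits between 12 px
(0.4196 µm², excluded) and 13 px (0.4546 µm², included). The nuclear mask
recipe — Otsu threshold on the DAPI channel, hole filling, removal of
objects under 20 µm², 1 px dilation — is a package choice; only the
exclusion itself is prescribed by the workflow.

Punctae of other synaptic channels attach to synapses by intensity-weighted
centroid distance strictly below 1 µm, matched greedily in order of
increasing distance (ties: lower synapse id, then lower punctum id), so
each synapse receives its nearest available punctum and each punctum is
used at most once.

## Single-synapse statistics

The feature table has one row per synapse: integrated intensity and area
per synaptic channel, with **zero assigned to both when no colocalized
punctum exists**; mean intensity = integrated/area (0 where area is 0);
for non-synaptic channels (MAP2, Tuj-1) the mean corrected intensity
within the synapsin punctum, with no area. Well summaries average in two
stages — synapses within an image, then images within a well, unweighted —
so images with many synapses do not dominate the well value.

Correlation networks: Pearson correlations between channel intensities are
computed per culture batch and averaged over batches; an edge is drawn
when the mean r is strictly greater than 0.35. Whether "intensity" means
integrated or mean intensity is configurable; integrated is the default.
Treatment comparisons express well values relative to the untreated group
mean and use the two-tailed two-sample Student's t-test with pooled
variance (Welch behind a flag), with 95% confidence intervals of the
relative means. For correlation changes, each well's per-pair r is
centered on its replicate's untreated mean before a two-tailed t-test of
treated versus untreated differences — the centering removes batch-level
offsets exactly. p-values are reported raw, with no multiplicity
adjustment, matching the workflow this package implements; users running
many channels should bear the implied family-wise error in mind (an
optional BH adjustment is a one-liner with `p.adjust`).

For embedding and clustering, each feature is transformed as log(x + 1) —
the pseudocount makes the log defined at the zeros the absent-punctum rule
guarantees — then divided by its SD and shifted to minimum zero; that
order satisfies both normalization constraints (SD 1, minimum 0)
simultaneously. t-SNE runs the exact gradient (theta = 0) with perplexity
40, 5000 iterations and PCA initialization by default, on a seeded random
subsample of at most 10,000 synapses; results are reproducible under a
fixed seed and, as the tests check on planted sub-types, qualitatively
stable over a wide perplexity range. Density maps use a Gaussian KDE with
Scott's-rule bandwidth (none is prescribed by the workflow); candidate
sub-type centres are grid local maxima above a density quantile, and the
mode count is flagged low-confidence when it changes under a 1.5×
bandwidth — featureless clouds fail this stability probe. Hierarchical
clustering uses Euclidean distance with Ward's linkage over both synapses
and features; duplicated channels (the same target re-imaged in two
rounds) merge at the lowest feature-linkage height, which the tests
reproduce on a simulated duplicate.

## PAINT post-processing

The module consumes localization tables (frame, x, y in nm); spot
localization itself is upstream. Fiducials are found by greedy
nearest-neighbour linking within 100 nm frame to frame (tracks stale for
more than 50 frames are closed); tracks present in at least half of all
frames are fiducials — transient binding events live a few frames and
never qualify. Fiducial identification is not specified by the source
workflow, so the linker is deliberately simple and its parameters exposed.

Drift is estimated per fiducial by locally weighted regression (tricube
weights, degree 1, span 0.1 — the workflow names LOESS but no span) of x
and y against frame separately; each smooth is centered at its value at
the reference frame (frame 0 — where the trajectory is anchored is a
package choice), curves are averaged over fiducials, and the average is
interpolated to every frame. Tracks under 10 frames are excluded.
Correction subtracts the trajectory per frame; the same trajectory aligns
tables from different rounds that share fiducials.

Rendering is a 2D histogram with 5.4 nm bins followed by Gaussian
smoothing (default SD 1 bin); the raw histogram conserves the localization
count exactly and the smoothed mass fraction is reported. The radial
cross-correlation between two rendered channels is
C(r) = ⟨A(x)B(x+r)⟩ / (⟨A⟩⟨B⟩), computed by zero-padded FFT with
overlap-area edge correction and averaged over displacement angle, so
independent images sit at baseline 1. The decay length is the smallest r
at which C(r) − 1 falls below (C(0) − 1)/e — the 1/e convention is a
package definition (half-maximum is available), calibrated by the closed
form for isotropic Gaussian structures: a cluster of SD σ decays at 2σ, so
a structure of "scale" s = 2σ reads out as s. Size readouts should use
*cross*-channel correlations (e.g. synapsin × PSD-95): the autocorrelation
of a finite set of docking sites carries a repeat-localization self-spike
at r ≈ 0 that contaminates the 1/e reference. Trans-synaptic profiles
project localizations inside an oriented box onto its axis and report the
histogram (10 nm bins), the median, and the Gaussian-fit FWHM
(2√(2 ln 2)·σ̂, nonlinear least squares with moment fallback); channels
with fewer than 20 localizations in the box omit the FWHM.

## LNA probe design

Imaging probes derive from the PAINT probe sequences by appending two
adenines at the 3′ end and replacing three nucleotides with LNA. Because
LNA raises duplex stability, substitutions inside regions of partial
complementarity with non-cognate docking strands would strengthen
crosstalk. The optimizer enumerates every maximal ungapped
reverse-complement match of at least 4 nt between the anchored probe and
each docking strand (an exact scan over all alignment offsets — at 11–13
nt this is the deterministic equivalent of a short-word BLAST search, and
configurable mismatch tolerance is provided), excluding the cognate
strand's intended duplex (its longest complementary region) but keeping
any unintended self-panel complementarity. The cost of a substitution
scheme is, per docking strand, Σ over regions length^β · (LNA-in-region)^α
with α = 2, β = 1 by default, and the scheme's assigned cost is the
maximum over strands. Only the monotonicities — more LNAs in a region cost
more, longer occupied regions cost more, worst strand governs — are
prescribed by the workflow; the power-law form and exponents are package
choices and are exposed. All C(13, 3) = 286 position sets are evaluated,
so the optimum is global by construction (verified against an independent
brute-force enumerator), with ties broken toward the lexicographically
smallest set. The shipped docking panel is synthetic demonstration data.

## What the generators emulate — and what they do not

The confocal generator plants synapses as isotropic 2D Gaussians
(σ 2.0–2.8 px, i.e. areas in the 0.5–2 µm² range real synapsin punctae
occupy) along piecewise-linear dendrite backbones, with per-channel
integrated intensities drawn from a multivariate lognormal (default
meanlog log(150000) a.u., sdlog 0.3) whose correlation matrix has the
pre-/post-synaptic block structure seen in excitatory synapses; sub-types
suppress chosen channels to near background. Illumination is a Gaussian
vignette of amplitude 0.4 normalized to mean 1; drift is an integer shift
per round (±8 px); noise is Poisson shot noise on a diffuse background of
50 counts plus Gaussian read noise (SD 1), clamped at zero like unsigned
camera counts. Under these defaults every punctum's peak
signal-to-background-noise ratio is far above 5.

Three generator choices are driven by identifiability rather than realism,
and limit what passing tests prove about real data. (1) Planted synapses
keep a hard-core separation of 26 px (≈4.9 µm; 30 dendrites across a
512 px field give a line density of ~0.14 synapses/µm, at the sparse end
of mature cultures): closer pairs bridge at the single-gray-level skirt of
the enhanced image, no diffraction-limited pipeline can separate them, and
ground-truth matching at the 1 µm radius becomes ambiguous. Real cultures
contain closer pairs; on real data the watershed separates some of them
and merges the rest, and recall against an (unknowable) ground truth would
be lower. (2) Synapses are planted outside nuclei, where real synapses
live; the decoy punctae planted *inside* nuclei exercise the
nuclear-exclusion rule instead. (3) The intensity spread (sdlog 0.3) is
narrow enough that all punctae keep supra-gate areas at the chosen
threshold; broader, more realistic spreads (sdlog ≥ 0.5) cost recall in
the faint tail — again a property of the area-gated method itself. The
generator also makes no attempt at optical PSF physics, 3D structure, or
realistic dendrite morphology beyond line segments.

The PAINT generator emits one-frame binding events (fast dissociation)
Poisson-thinned per site, plus fiducials detected in 98% of frames, with
Gaussian localization noise and either linear or smoothed-random-walk
drift anchored at frame 0. It does not model multi-frame on-times,
photophysics, or localization-precision heterogeneity.

## Problem sizes and determinism

Everything is seeded, and identical configurations reproduce byte-identical
outputs. The shipped tests run the confocal pipeline at 512 px / 200
synapses (the default conditions), the correlation recovery at 5,100
synapses, the treatment comparison at 12 wells × 2 images × 60 synapses
over 20 replicate simulations, PAINT drift at 5,000 frames with 2
fiducials, rendering/radial analyses at 10–15 thousand localizations, and
the probe optimizer over full 286-scheme enumerations — sizes chosen so
each stage's statistical tolerances are meaningful while the whole suite
runs in a few minutes on one core.
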