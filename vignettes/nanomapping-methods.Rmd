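---
title: "Methods: HS-AFM DNA nanomapping with Cas9 nanoparticle labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HS-AFM DNA nanomapping with Cas9 nanoparticle labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the measurement
model, the synthetic world used to validate it, the parameters that matter,
the numerical decisions taken where the design was genuinely open, and what
a green test does and does not establish.

## The measurement model

A high-speed AFM raster-scans a sharp tip over DNA molecules deposited flat
on mica and records a height image (nm-valued grid, pixels of 2–2.5 nm
here). On such images the bare double helix appears as a ridge of roughly
0.3 nm apparent height; a Cas9–sgRNA ribonucleoprotein bound at its 20-bp
target appears as a bump of roughly 3 nm. Because Cas9 binding is
sequence-programmed, the ordered arc positions of the bumps along a
molecule's backbone constitute a physical map of that single molecule.

The pipeline is: flatten the image line by line, segment candidate
molecules by adaptive height thresholding, thin each component to a
backbone, fit a spline and measure contour length, sample the height
profile along the spline and call label peaks, convert nm to bp with a
fixed calibration, then match the per-molecule label pattern against
reference maps (orientation, site assignment, translocation calling) and
pool statistics over molecules.

Two headline capabilities anchor the expectations: pooling ~15,000
measurements per species separates amplicons differing by 2 bp in the
140–150 bp range, and on ~12.9 kb molecules inter-label spacings carry a
single-molecule precision on the order of ±100 bp s.d.

## Calibration

All genomic quantities derive from one constant: **2.94 bp/nm**, the
canonical rise of B-DNA in solution (0.340 nm/bp). The simulator uses the
same constant as its rise so that simulated and analyzed quantities
round-trip exactly; `convert_length()` is the only conversion point.

## The synthetic world (`simgen`)

The generator emulates what the instrument sees, not how it sees it:

- **Conformation.** Deposited molecules equilibrate in two dimensions, so
  backbones are discrete worm-like chains whose tangent angle diffuses with
  per-step variance $\Delta s/\ell_p$, giving the 2D tangent correlation
  $\langle \cos\theta(s)\rangle = e^{-s/2\ell_p}$ with $\ell_p = 50$ nm
  (the textbook value for dsDNA in physiological salt). A `"3d"` convention
  ($e^{-s/\ell_p}$) is exposed for comparison. The arc length equals
  `length_bp / 2.94` exactly.
- **Flow elongation.** Molecules much longer than a few persistence lengths
  almost surely self-cross as free 2D chains, but long amplicons are
  deposited with a flow-elongation protocol precisely so they lie extended.
  `align_corr_nm` adds a mean-reverting pull of the tangent toward the flow
  axis with a 25 nm correlation length; we enable it for molecules over
  ~1.5 kb.
- **Resolvability conditioning.** Adsorbed strands cannot overlap on the
  surface, and two stretches closer than the tip-broadened footprint plus
  one pixel (~8 nm at the defaults) cannot be resolved as separate ridges —
  in practice such images are discarded. `sim_molecule()` therefore
  rejection-samples conformations until no two non-adjacent stretches come
  closer than this physics-derived gap. This conditions the WLC ensemble
  (it is in effect a surface self-avoiding WLC); tangent-correlation tests
  use the unconditioned sampler.
- **Labels.** Each perfect site binds with probability 0.9, each
  single-mismatch site with 0.5 (the observed occupancies); off-target
  labels are Poisson with uniform positions. Occupancy is frozen into the
  per-molecule truth table.
- **Rendering.** The backbone is a 0.3-nm-high cylinder of 1 nm lateral
  half-width; a spherical tip of radius 5 nm touching it records
  $h(d) = h_{DNA} + \sqrt{R^2 - \max(0, d - r_0)^2} - R$ at perpendicular
  distance $d$ — this tip-contact model gives the ridge its realistic 2–3 px
  apparent width without a separate dilation pass. Labels are Gaussian
  bumps (FWHM 10 nm) reaching exactly 3 nm at their apex; the whole frame
  is then grayscale-dilated by the spherical tip (which broadens the tall
  label bumps but barely affects the low backbone), and per-scan-line
  offsets (s.d. 0.1 nm) and per-pixel Gaussian noise (s.d. 0.1 nm, the
  instrument's ~sub-300 pm floor) are added.
- **Determinism.** One integer seed; per-molecule streams are split with a
  multiplicative hash (`derive_seed`) so truth is bit-reproducible.

What the generator does **not** emulate: scanner drift and scars,
correlated 1/f line noise, tip asymmetry or double-tip artifacts,
molecule–molecule adhesion, and any wet-lab variability beyond Bernoulli
site occupancy. A green end-to-end test therefore establishes correctness
of the computation under an idealized but physically scaled instrument — it
does not certify performance on real, artifact-laden images.

## Image conditioning and segmentation

**Flattening.** Each scan line carries an unknown offset/tilt. A
provisional all-pixel per-line detrend is removed first so that molecules
and line offsets do not corrupt the classification; foreground is then
classified on a Gaussian-smoothed copy at median + 2.5·MAD (which separates
even the 0.3 nm backbone from the noise floor), and the final per-line
polynomial (order 0–2, default 1) is fit to background pixels only. Lines
with no background fall back to a global fit, with a warning. Flattening is
exactly idempotent on noise-free images; on noisy images a second pass only
reshuffles fits at the $\sigma/\sqrt{n}$ level.

**Segmentation.** The idea named in the field is adaptive height
thresholding; the realization here is per-tile robust statistics
(median + k·MAD on a σ = 1 px smoothed copy) with hysteresis: seeds at
k = 5, growth at k = 2, closing with radius 2 px to bridge dim backbone
stretches, and a minimum area equivalent to a 50 bp footprint. The MAD is
floored at 0.02 nm so noise-free synthetic frames do not degenerate to a
zero threshold. Raising the threshold can only shrink the foreground
(monotonicity is tested).

## Tracing and contour length

The component is thinned (Zhang–Suen); the skeleton graph (8-connected,
diagonal edges dropped when bridged orthogonally, so junction and cycle
detection is meaningful) is pruned to the maximum-length geodesic between
endpoint pairs, with near-ties broken by smaller mean curvature and then
lexicographic endpoint order. Flags: `branched` (an off-path fragment
longer than a 6 px spur), `looped` (a 2-core component larger than 8 px —
small thinning artifacts are ignored), `edge_clipped` (component within
2 px of the border), `too_short`. Flagged molecules are excluded from
measurement, standing in for the manual curation of automation errors.

The ordered skeleton is refined before measuring:

1. thinning retracts free line ends, so each end is recovered by a **ridge
   follower** that steps outward, re-centres on the height crest, and stops
   at half the backbone plateau (with guards against U-turning back onto
   the molecule);
2. every point is **re-centred sub-pixel** on the crest by a parabolic fit
   across the local normal (two passes, shift capped at 0.6 px);
3. a short moving average (window 4 on quiet images, 5 on noisy ones —
   bandwidth matched to the noise level) removes refinement jitter, and an
   interpolating parametric cubic spline through the result carries the
   geometry. A smoothing spline with RMS-targeted stiffness was implemented
   first and systematically cut corners on wiggly molecules; the
   pre-averaged interpolating spline measured closer to truth at every
   size, so it is the default (the design note had envisaged the smoothing
   spline).
4. molecule **ends are localized sub-pixel by template matching**: the
   cross-section profile T(d) (height vs distance to the backbone) is
   estimated super-resolved from the phase diversity of raw pixels along
   the molecule interior, and the end position is the truncation point that
   best explains the raw pixels around the end — the same tip broadening
   acts along and across the backbone, so this is a self-contained tip
   deconvolution. Bent ends fall back to a curve-distance variant, and only
   degenerate cases to a half-height crossing corrected by the measured
   ridge half-width.

Contour length is the spline arc length (composite Simpson on a ~0.25 nm
grid) between the fitted ends. On noise-free renders this is within 2% of
truth for ≥95% of molecules across 300–13,000 bp; the residual failures are
sub-pixel kinks and end curls of short free chains — with 2.5 nm pixels a
102 nm molecule leaves a total error budget of ±2 nm, which is the
resolution limit of any tracer here. For the same reason contour length is
rotation-invariant to ±0.5% for smooth shapes, while wiggly chains re-grid
with ~±1% conformational re-trace noise.

## Label calling

Heights are interpolated along the spline (1 nm steps, maximum over a
±1 px normal window so an apex slightly off the centerline is kept). Local
maxima with topographic prominence ≥ 1 nm are called: the threshold sits
far above the 0.3 nm backbone and far below 3 nm labels, giving a
sensitivity ≥ 0.99 at ≤ 0.01 false calls per molecule on synthetic frames
at the default noise. Peaks closer than 10 nm (twice the tip radius) merge
into one call flagged `merged`. Positions are prominence-weighted centroids
within the half-prominence window — sub-pixel localization, needed to
approach ~20 bp pooled resolution. Positions are reported from endpoint A
(the lexicographically smaller end); biological orientation requires a map
and is resolved later. Whether a reported position includes or excludes
the label footprint is a convention; the centroid convention is used
throughout (simulator and caller agree by construction).

## Population statistics

- **Gaussian population fit**: one-pass 3·MAD trim about the median, then
  mean and s.d. of the retained values; the s.d. is divided by the known
  ±3σ truncation factor (≈0.9866) so the estimator stays consistent, and
  the 95% CI of the mean uses the t quantile — with the plain 1.96 the
  trimmed estimator undercovers by ~1% at n ≈ 100. (The design note wrote
  "± 1.96 s.e."; the t quantile is the deviation that keeps the also-
  required 95% ± 2% coverage.) Fewer than 8 values fall back to
  median/MAD with a warning.
- **Logit statistics**: a label bisects its molecule; the long-segment
  share p is mapped to `ln(p/(1−p))`, analyzed with normal theory, and
  back-transformed via `e^l/(1+e^l)`. p ∈ {0, 1} has no logit and is
  excluded with the count surfaced (no Haldane correction — auditable
  rather than silent). `outlier_pct` is the share outside the
  back-transformed population interval (mean ± 1.96 s.d. on the logit
  scale); the CI of the mean is reported separately.
- **Off-target rule**: a detected label farther than 2 position-s.d. from
  every expected site, with each site's s.d. estimated from its own
  assigned population (the trim mitigates the mild circularity).
- **Ladder resolution**: species are fit separately; the resolved step is
  the smallest true step such that every adjacent pair at or below that
  step has disjoint 95% CIs of the mean; `Inf` marks "unresolved".
  Resolution is monotone in sample size.

## Map matching

- `find_guide_sites()` scans both strands for the 20-mer protospacer with
  ≤ k mismatches followed by an exactly matching IUPAC PAM (`NGG`);
  positions are 1-based protospacer centers (11th base) in forward
  coordinates. Sites from both strands merge into one map — a bound Cas9
  bump is strand-agnostic in a height image. Center-vs-PAM-edge offsets
  (≤ 10 bp) are below measurement noise.
- `orient_and_assign()` scores both orientations by an optimal one-to-one
  matching of sorted label positions to sorted site positions (dynamic
  program; for L1 costs on a line the optimal matching is non-crossing, so
  the DP attains the exhaustive minimum — tested against full enumeration).
  Matching a pair costs its |residual| (gated at tol = 300 bp, ~3× the
  single-molecule precision); skipping a site costs its expected occupancy
  × tol (0.9 perfect / 0.5 mismatch — missing an often-labeled site is more
  surprising); skipping a label costs tol. Orientations within 2·tol of
  each other are `ambiguous` and excluded from per-site statistics.
- `call_translocation()` tests each molecule as prefix-of-A + suffix-of-B
  over every label split and both orientations, keeps the best fit only if
  it beats the best single-map explanation (wild-type gate), intersects the
  per-molecule breakpoint bounds spanned by the innermost matched sites,
  and emits a call only at ≥ 10 supporting molecules (falling back to
  component-wise medians if measurement noise empties the intersection).

## Interfaces

Height images are whitespace-delimited ASCII matrices with a JSON sidecar
carrying `pixel_size_nm` and `origin_nm`; a missing pixel size is an error,
never a guess. TIFF is deliberately not supported in this build — no TIFF
reader is part of the dependency set, and the ASCII form is lossless for
testing. Run configurations are JSON with unknown keys rejected. The
pipeline driver writes a measurements TSV and a JSON report with the
package version and a config hash; outputs are never overwritten without
an explicit flag; everything is byte-reproducible under a fixed seed.

## Known limitations

- Crossing or self-touching molecules are excluded, not untangled.
- Frame displacement for stitching is trusted metadata; there is no
  registration fallback.
- Sub-pixel kinks of short free chains limit noise-free contour accuracy
  to ~±1–2 nm per molecule end; population statistics absorb this, single
  short molecules may not.
- The noise model is white plus per-line offsets; real instruments add
  correlated noise and drift the pipeline has not been tuned against.
- The end-labeled ladder analysis here is measurement-level (lengths drawn
  about truth); the imaging pipeline is exercised by the multi-kb
  label-spacing path instead.
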