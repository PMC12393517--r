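---
title: "Measuring sequence-dependent poloidal bias in DNA minicircles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sequence-dependent poloidal bias in DNA minicircles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicircle)
```

## The problem

When a short double-stranded DNA (here 105 bp) is ligated into a covalently
closed minicircle, every base-pair step is forced to bend. Bending is
anisotropic — rolling toward the grooves is cheaper than tilting — so the
duplex prefers to present particular faces of the helix toward the circle's
center. The rotational register of the helix about its own axis as it runs
around the circle is the *poloidal* angle (the toroidal coordinate runs along
the circle). A sequence-dependent equilibrium bias in this angle means that a
chemical label at a fixed position in the sequence sits preferentially inside
or outside the ring, and that this preference rotates by ~34° per base pair
as the label is moved along the sequence, with the ~10.5-bp helical period.

This package implements the complete computational side of that measurement:

1. **geometry** — build ideal three-site-per-nucleotide (sugar S, phosphate
   P, base B) coarse-grained duplexes on perfect helices, bend them into
   planar, uniformly twisted minicircles, and close the bonded topology so
   the structure can seed an external MD engine (the package writes and
   reads the MD file formats; it does not integrate dynamics).
2. **poloidal** — a global-morphology poloidal angle per conformation, with
   circular statistics and a signed horizontal displacement.
3. **afm_analysis** — segmentation of particles in height images, a
   deterministic DNA / protein / complex classification, the
   centroid-to-center-of-mass offset distance δ, and the count-based
   relative affinity α = N~DP~/(N~D~·N~P~).
4. **phase_fit** — fixed-period (10.5 bp) weighted sinusoidal fits of δ- or
   x-versus-insert-position series, peak lags, and lag→degree conversion.
5. **synthetic_data** — generators for every input the pipeline consumes,
   with recorded ground truth.

## The geometry model

Each of the six site classes i (S/P/B × two strands) lies on a perfect
helix,

$$x_{i,n} = r_i\cos(n\Delta\theta+\theta_{i,0}),\quad
  y_{i,n} = r_i\sin(n\Delta\theta+\theta_{i,0}),\quad
  z_{i,n} = n\Delta z+z_{i,0},$$

with common step twist Δθ (default 34.3°) and rise Δz (default 0.34 nm).
Default radii/offsets are canonical-B-DNA-like placeholders
(`default_helix_parameters()`); `derive_helix_parameters()` recovers all
parameters from any reference model built on these equations (exactly, for
an ideal reference; consistently, for a noisy one).

**Twist quantization.** A seamless circle needs the total twist to be an
integer number of turns; `quantize_twist(34.3, 105)` returns
10·360/105 = 34.2857°/bp.

**Bending.** The model is translated so its center of mass sits at (0, R, 0)
with R = n·Δz/2π (the unique radius closing the centerline — R is otherwise
a free parameter), then

$$(x, y, z) \mapsto \bigl(x,\; y\cos(z/R),\; y\sin(z/R)\bigr).$$

The cross-section at height z is carried rigidly to toroidal angle z/R. This
map preserves each atom's x-coordinate and its distance y from the bending
axis exactly, and with quantized twist the virtual image of base pair n~bp~
coincides with base pair 0 to machine precision (`closure_gap()`). A
per-atom-arc-length variant of the map (toroidal angle z/y instead of z/R)
is sometimes quoted; it does *not* close the duplex — an atom at
y = R + r·sinθ₀ misses its own image by 2π|y−R|, nanometers — so this
package uses z/R.

**Closure terms.** Each nucleotide carries its 5′ phosphate; the 5′-terminal
phosphate of each strand is left unbonded in the linear model and is consumed
when `close_topology()` seals the junction with, per strand, three bonds
(SP, PS, BB-intra), three angles (SPS, 3PSB5, 5PSB3) and eight dihedrals
(2×SPSP, 2×PSPS, SPSB53, SPSB35, PSBB53, PSBB35) — 6 bonds, 6 angles, 16
dihedrals in total. After closure every sugar (and phosphate) has the same
bonded degree as an interior one. Note one labeling subtlety: the junction
phosphate carries the base-pair-0 label while sitting geometrically at the
junction, so "spanning the junction" is guaranteed through closure-bond
usage, not base-pair labels.

## The poloidal angle

For a reference base pair, four equidistant phosphates P₀, P₁∕₄, P₁∕₂, P₃∕₄
are selected (indices by round-half-up, so 105/2 = 52.5 → 53). The frame's
x-axis runs along P₀→P₁∕₂ (toward the far side of the ring), the in-plane
normal comes from the cross product with P₁∕₄→P₃∕₄, and the axes are
re-orthogonalized keeping x exact. The origin O is the centroid of the 10-bp
segment flanking P₀ (five base pairs on each side, excluding P₀'s own pair,
all six sites — equal atom counts per side), projected along ẑ onto the x–y
plane through P₀. The poloidal angle is `atan2(ŷ·(P₀−O), x̂·(P₀−O))` in
[0°, 360°), and the signed horizontal displacement is x = x̂·(P₀−O).

Conventions chosen here (any fixed convention shifts all angles by a
constant): 0° is the inward equator and 180° the outward one, so
sign(x) = sign(cos angle) and "positive x = inside" holds; the handedness is
fixed so the measured angle *increases* with the helical construction phase.
With the opposite cross-product order the angle would decrease with phase.

**Circular statistics.** `circular_stats()` uses resultant-vector
arithmetic: mean = atan2(mean sin, mean cos), mean resultant length R̄, and
circular standard deviation √(−2 ln R̄) (the alternative √(2(1−R̄)) agrees at
small dispersion and differs at large; we use the former). R̄ = 0 raises an
explicit undefined-mean error. `mean_center()` maps a sample to circular
mean 0 in (−180°, 180°], the convention for mean-centered histograms. A
numerical note: √(−2 ln R̄) has unbounded slope at R̄ = 1, so for
near-degenerate samples the std is reproducible only to ~√ε ≈ 1e-6 degrees
across implementations; tests compare R̄ at 1e-12 and σ at that conditioning
floor.

**An estimator property worth knowing.** O is the projected centroid of a
10-bp *arc*; a chord centroid sits inside its arc, here by
R(1 − mean cos(kΔz/R)) ≈ 0.11 nm for the 105-bp geometry. The measured angle
is therefore a smooth, strictly monotone, but *anharmonic* function of the
helical construction phase: raw phase shifts are recovered only to within
about ±14° (the bias is zero at the equators and maximal near ±90°). This is
a property of the published estimator, not of this implementation; it is
invisible in practice because experiments compare angles across insert
positions (shifts of hundreds of degrees) rather than absolute registration.

**The calibrated generator.** `simulate_poloidal_trajectory()` promises
ensembles whose *measured* poloidal angle follows a prescribed von Mises
law VM(μ, κ). Because of the anharmonicity above, applying the drawn angle
directly as a construction phase would warp the distribution (Kolmogorov
distance ≈ 0.14 from the target at κ = 10). The generator therefore
tabulates the measured angle over a fine phase grid once
(`poloidal_calibration()`, monotone spline inverse, forward error
~1e-10 degrees) and places each frame at the phase whose noise-free
measurement equals the drawn target. `calibrate = FALSE` restores the raw
placement for anyone who wants the distortion itself. κ = ∞ places every
frame exactly at μ; κ = 0 is the uniform circular law. Isotropic Gaussian
coordinate noise is added after placement. The per-frame ground truth
(target angle, applied phase) is stored in the trajectory metadata.

## AFM image analysis

Height images are flattened by subtracting a least-squares 2D polynomial
(order 2 by default: tilt + bow). Segmentation thresholds the flattened
image and takes 8-connected components (4-connectivity available); a
`min_area_px` filter removes single-pixel noise speckles. For each blob the
unweighted mask centroid r~centroid~ and the intensity-weighted center of
mass r~COM~ are computed over the same pixels (pixel centers at integer
coordinates), and δ = ‖r~centroid~ − r~COM~‖·pixel_size, in nm.

Classification replaces manual inspection with a deterministic rule set:
area below the window → lone protein; above → aggregate (excluded; circular
dimers from ligation fall here); in-window and dimmer than the intensity
window → DNA only; in-window and within it → DNA–protein complex. The
area/intensity windows are instrument- and generator-dependent
configuration, not constants of nature; the workflow defaults
(25–200 nm², ≥0.9 nm mean intensity at a 0.5-nm threshold) separate the
synthetic generator's populations with 100% accuracy at signal-to-noise 5.

The relative affinity α = N~DP~/(N~D~·N~P~) is a count-based proxy for the
association constant (undefined when either single-species count is zero);
`affinity_fold()` compares two scans. Note α is not scan-size invariant:
duplicating a scan halves α — the exact scaling is asserted in the tests.

**What δ measures.** For a complex whose marker carries a fraction f of the
integrated intensity at distance d from the ring center, r~COM~ sits at f·d
from the center, so δ → f·d as the marker's mask footprint becomes small.
With a finite footprint the marker's pixels also drag the unweighted
centroid toward themselves, lowering δ below f·d (ratio ~0.75–0.95 at the
scene defaults, 0.98–1.08 with a 0.4-nm marker width at 0.25-nm pixels).
δ(outside) > δ(on-ring) > δ(inside) always holds, which is the ordering the
colocalization argument uses.

## Synthetic scenes and series

`simulate_afm_scene()` renders rings as Gaussian-profile annuli (default
radius 5.7 nm = 105·0.34/2π, the centerline radius; apparent AFM radii are
tip-dependent and configurable), free proteins as Gaussian spots, and
complexes as ring + bound marker. The point-spread function is applied
analytically (widths add in quadrature). Bound markers touch the ring:
"inside"/"outside" place the marker one spot-diameter inside/outside the
ring line — a marker rendered deep inside the ring would segment as a
separate particle, which is not what a bound complex looks like. The marker
amplitude is scaled so it carries exactly the configured mass fraction
(default 0.3; the true protein/DNA volume ratio is unspecified
experimentally). Placement is rejection-sampled with non-overlap
constraints; ground truth (type, center, marker offset) is returned.

What the generator deliberately does **not** emulate: tip convolution
(beyond the Gaussian PSF), surface-interaction bimodality of δ, the
flexible biotin linker (which broadens real δ distributions), height
calibration artifacts, scan-line noise. A green count-recovery test
establishes that the segmentation/classification logic is correct on scenes
matching its assumptions — not that the default windows suit any particular
instrument.

`simulate_delta_series()` draws per-position samples from
C + A·cos(2π(p−p\*)/10.5) + noise and reports the per-position median, sd
and n — medians being the plotted central tendency for δ; simulation x
series conventionally use means, and the sign of x is inverted on ingestion
when it should trend with δ (a documented flag in how series are prepared,
not a hidden transformation).

## Phase fitting

`fit_sinusoid()` performs weighted least squares in the linear basis
{1, sin(2πp/T), cos(2πp/T)} with weights 1/sd² ("weighted by the standard
deviation" read as standard error-weighted WLS); points with sd = 0 get the
series' median weight; an all-zero-sd series is unweighted. The linear
solution is re-parameterized as C + A·cos(2π(p−p\*)/T) with A ≥ 0,
p\* ∈ [0, T) so the peak position is a direct output. The period is fixed
at T = 10.5 bp for both δ and x series (stated experimentally only for the
simulation series; fixing both is the configurable default here — a free
period would be a model-selection exercise, an explicit non-goal).
`peak_lag(a, b)` = (p\*~b~ − p\*~a~) mod T and
`lag_to_degrees(lag, T)` = 360·lag/T: a 5.5-bp lag at 10.5 bp is 188.57°,
i.e. 189° at nearest-degree rounding; fits peaking at insert positions 4
and 10.5 lag by 6.5 bp.

```{r phase-example}
p <- seq(0, 12, 2)
s601 <- data.frame(position = p, value = 1.6 + 0.4 * cos(2 * pi * (p - 1.3) / 10.5))
satr <- data.frame(position = p, value = 1.6 + 0.4 * cos(2 * pi * (p - 6.8) / 10.5))
lag <- peak_lag(fit_sinusoid(s601), fit_sinusoid(satr))
c(lag_bp = lag, phase_deg = lag_to_degrees(lag, 10.5))
```

## Numerical and design choices, collected

* Angles: degrees in user-facing fields ([0°, 360°), mean-centered output in
  (−180°, 180°]); radians internally. Lengths in nm throughout.
* Round-half-up for the reference-quadruple indices (52.5 → 53); base R's
  round-half-even would pick 52.
* Equilibration: trajectories carry an `equilibration_fraction` metadata
  field (synthetic generators set 0 — they draw equilibrium samples;
  external MD dumps default to 5%).
* The von Mises sampler is Best–Fisher rejection sampling; all generators
  are deterministic given (configuration, seed).
* Workflow configuration is JSON; unknown keys are rejected, and the
  resolved configuration is echoed next to the report for provenance.
  Reruns are byte-identical.
* Degenerate inputs raise classed errors (`minicircle_*_error`) rather than
  returning silent zeros: undefined circular mean (R̄ = 0), undefined COM
  (zero total intensity), undefined affinity (N~D~·N~P~ = 0), bending across
  the axis (y ≤ 0), double closure, underdetermined/rank-deficient fits.

## Known limitations

* The package builds, writes and reads MD inputs/outputs but performs no
  dynamics, minimization or force-field evaluation; equilibrium poloidal
  statistics of *real* sequences must come from an external engine.
* The poloidal estimator's anharmonic registration bias (±14° for the
  default geometry) is inherent to the published 10-bp-centroid origin;
  absolute angles from different geometries (n_bp, site radii) are not
  directly comparable at the degree level, though differences across insert
  positions are.
* AFM classification windows are configuration, calibrated only for the
  synthetic generator's populations.
* Only unimodal (von Mises) poloidal laws are generated; asymmetric or
  bimodal distributions (observed for some repeat sequences) are out of
  scope.
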