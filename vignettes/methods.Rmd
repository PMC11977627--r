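---
title: "Models and methods of the mapet toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the mapet toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mapet` is a desk-scale computational model of a preclinical PET scanner
built from a single monolithic LYSO annulus with fourteen flat outer
facets, each read out by four 4 x 4 SiPM arrays. The package covers the
whole chain: photon-pair Monte Carlo, scintillation-light modelling,
trigger/coincidence logic, photon-distribution harmonization and neural
event positioning, projection onto virtual pseudo-detectors, SSRB-FBP and
list-mode MLEM reconstruction, and the NEMA NU4-2008 analyses. This
vignette records the models, their assumptions, the numerical choices,
and what the synthetic studies do and do not demonstrate.

## Geometry

The annulus has a 30 mm bore radius, a 72 mm length, and fourteen facets
whose flats sit at a 39.7 mm apothem; the derived facet width
(2 a tan(pi/14) = 18.12 mm) and maximum outer radius
(a / cos(pi/14) = 40.72 mm) agree with the nominal 18.2 mm / 41 mm
figures to better than 0.5%. The world frame puts +z on the bore axis and
facet 0's outward normal on +x; facet i sits at azimuth 2 pi i / 14.
Facet-local coordinates are u (transaxial, increasing azimuth), v = z,
and depth measured from the bore surface along the facet normal. Sector
assignment uses the maximum dot product with the facet normals, ties to
the lower index.

Each facet is in coincidence with the seven opposing facets at index
offsets 4-10 (mod 14) - the unique symmetric seven-set whose chords all
traverse the bore, so the coincidence volume spans the whole field of
view. Fourteen virtual pseudo-detector planes (16 x 84 elements of
0.84 mm) share the facet frames, tangent to the 30 mm circle.

## Photon-pair Monte Carlo

Emissions are sampled uniformly over each phantom's active region, with
times from an inhomogeneous Poisson process at the decay-corrected
positron rate (activity x branching; F-18 half-life 109.77 min,
branching 0.9686; Na-22 2.6018 y, 0.9060). Positron range is an
isotropic Gaussian blur (FWHM 0.54 mm for F-18, 1.0 mm for Na-22), and
the pair acollinearity a 0.25 degree FWHM Gaussian on the back-to-back
angle; both are toggleable.

The object is transported as a single homogeneous convex solid (the
phantom's dominant shape and material) with attenuation and up to two
Compton scatters; the attenuation *map* used for corrections is, by
contrast, fully voxelized from the analytic phantom geometry (water
0.0096/mm, polyethylene 0.0093/mm, acrylic 0.0112/mm at 511 keV).

In the crystal, free paths are exponential in the total LYSO attenuation
(built-in table over 50-511 keV, log-log interpolated; 0.087/mm total at
511 keV with a 0.33 photoelectric fraction). Each interaction is
photoelectric or Compton by the cross-section ratio; Compton angles
follow Klein-Nishina via rejection sampling; daughters are tracked until
absorption, escape, or the 50 keV cutoff (below which they are absorbed
at the vertex - at 511 keV a first scatter can never fall below the
cutoff, so this only affects long chains). Chains are labelled PE, CSE,
CS-PE, multi, or miss. Rayleigh scattering, fluorescence escape and
Doppler broadening are omitted as second-order for the positioning and
reconstruction chain under study.

Ray-solid intersections (polygon-prism hull minus bore cylinder, up to
two intervals per ray) are computed analytically and vectorized over
photons, which keeps the R-level Monte Carlo at roughly 10^5 event pairs
per second.

## Optical model

Expected sensor signals use a parametric light-spread model rather than
optical ray tracing. Each energy deposition radiates
`light_yield x E_dep` photons isotropically; a pixel's expectation is the
exact solid angle of its 4 mm active square (dead space between the
4.4 mm pitches is therefore modelled), times the collection efficiency,
times an exponential in the optical path length, plus a single
mirror-image term for the specular bore reflector. Three geometric
constraints shape the spread:

* direct paths whose transaxial segment dips inside the bore are blocked
  (light cannot cross the air bore) - that light is carried by the
  mirror term;
* the mirror term is restricted to the tangent-angle reach of a single
  reflection off a convex surface, with a cosine-squared specular lobe
  over a configurable fraction (default 0.7) of that reach;
* the mirror amplitude carries a convex-divergence factor
  1/(1 + 2 d/R), the leading-order intensity loss of a beam reflected
  off a convex cylinder from distance d.

Defaults: 29 photons/keV, 25% collection, 0.95 bore reflectance, and a
60 mm optical attenuation length. The attenuation length is an
*effective* parameter folding bulk absorption and accumulated surface
losses; it was chosen, together with the mirror-lobe shape, so that the
model reproduces the design constraint that >= 90% of an event's
collected light stays within the primary facet plus its two neighbours
(the measured default is about 92%). All parameters are exposed in
`optical_model()`.

Two boundary behaviours of the model are worth knowing. The three-facet
containment falls with distance from the sensor plane over the outer
three quarters of the crystal depth but rises again in the bore-adjacent
layer, where bore occlusion and the local mirror re-concentrate light;
the monotone-spread property is therefore asserted over the mid-depth
range. And within about a millimetre of the sensors, the dead space
between pixels makes the total collected signal non-monotone at
positions facing a gap, so the signal-versus-distance property is
checked at a pixel-aligned transaxial position.

Noise is per-sensor Poisson around the expectation, a fixed lognormal
gain per sensor (2% spread, reproducible per scanner seed), and an
additive Poisson dark floor (0.5 p.e. per sensor per event window).

## Trigger and coincidence logic

Per-array sums below the trigger threshold (default 5 p.e., the
digital stand-in for the hardware's analog threshold; comparisons are
inclusive) are excluded from the facet sums; no facet-level energy
threshold is applied. A single records its trigger time (first
interaction), the facet with the maximum facet sum, that facet's four
array sums, and the 12 x 16 distribution assembled from the triggering
facet and its two azimuthal neighbours (transaxial index 0-11 by
increasing azimuth, axial index 0-15 by increasing z).

The coincidence window (default 2 ns) is interpreted as the *full width*
of the signed time-difference acceptance: a prompt requires
|dt| <= window/2 on partner facets. Under this reading the
singles-product randoms rate is exactly `window x S_i x S_j`, and a
delayed-window measurement with the same acceptance width reproduces it;
the alternative max-|dt| reading would make those two disagree by a
factor of two. Groups of three or more in-window singles are discarded
outright - the simplest NU4-compatible policy. Dead time is not
modelled, so count-rate curves roll over only through randoms growth.

## Event positioning

Harmonization subtracts `f_factor` (default 0.0025) times the pixel sum
from every pixel, clamps negatives to zero, then scales the maximum to 1.
The subtract-clamp-normalize order is a package choice; harmonization is
scale-invariant and idempotent at f = 0, and both coincidence photons'
distributions are treated identically.

The centre-of-mass baseline takes the signal-weighted centroid of the
unfolded sensor coordinates across the three-facet span and reads depth
from a lookup, calibrated on simulated photoelectric events, that maps
the distribution's transaxial second moment to the mean distance below
the sensor plane (the centroid itself carries no depth information).

The trainable positioner is a dense residual network: a 192-input linear
layer, a configurable number of two-layer residual blocks (default 2,
width 64-96), and a linear 3-output head, trained with Adam on mean
squared error against the facet-local coordinates (u, z, w) of the
chain's *first* interaction - the correct LOR endpoint, which for CS-PE
chains is the Compton vertex. Targets are standardized internally;
training is bit-reproducible given the seed. Dense residual blocks stand
in for the reference ten-layer convolutional design: at the 192-pixel
input scale they train in minutes on a CPU while preserving the
properties under study (monotone improvement with light, the CS-PE
penalty, in-annulus clamping). Outputs are mapped through the primary
facet's frame and clamped to the nearest point of the scintillator
solid, with a flag when clamping fired.

On held-out photoelectric events from a 2 x 10^5-event simulated set the
network beats the centre of mass on every world axis; transaxially in
facet-local coordinates the centroid remains slightly sharper (it is a
near-optimal estimator for clean single peaks), but its depth error -
and the CS-PE twin-peak ambiguity - dominate its world-frame error.

## Projection and reconstruction

The line through the two position estimates is intersected with each
endpoint's virtual plane and binned with floor semantics (boundary to
the lower index); misses of either 16 x 84 grid are rejected with
reasons. Attenuation correction weights are exp(+ integral of mu) along
the chord between element centres, computed by exact voxel traversal
(Amanatides-Woo) in C++.

SSRB assigns each LOR to the slice at the sum of its two axial element
indices (2 x 84 - 1 = 167 slices on the doubled grid) and bins the
in-plane chord into 128 angles over pi and 0.42 mm radial bins. FBP
applies a frequency-space ramp (optional Hann apodization) per angle and
backprojects with linear interpolation; its absolute scale was verified
against the analytic sinogram of a unit-density disk (recovered within
1%).

List-mode MLEM ray-traces between element centres on the fly, with
multiplicative per-event survival factors and additive expected randoms
(ordinary-Poisson style, preserving non-negativity; FBP-side randoms
subtraction is not implemented since FBP serves the point-source
studies). The recorded log-likelihood is monotone non-decreasing and
zero-sensitivity voxels are masked.

The sensitivity image deserves its own note. An analytic version
(`mlem_sensitivity`) backprojects all allowed element pairs with
obliquity, inverse-square and crystal-interaction-probability factors.
It is retained, and is adequate for locating point sources, but it
cannot express one acceptance effect: an oblique photon's first
interaction may land in a *neighbouring* facet's sector, changing the
facet pair and sometimes dropping it out of the partner set. On a
uniform cylinder this leaves a 25-30% centre-versus-edge bias. The
default for quantitative work is therefore a Monte-Carlo normalization
(`mlem_sensitivity_mc`): a uniform emission cylinder is pushed through
the truth-level acceptance chain, and each accepted LOR is backprojected
with weight 1/(its analytic chord through the normalization region) -
the division removes the emission-chord bias of the normalization
phantom - times an analytic survival factor when an attenuation map is
supplied. With 10^7 normalization events a corrected uniform water
cylinder reconstructs with a centre-to-edge ratio of about 1.00-1.02,
and with the correction off it cups to about 0.88.

## NEMA NU4 analyses

Spatial resolution forms 1-D response functions along the radial,
tangential and axial axes by summing the orthogonal directions, in two
passes (the second restricted to +/- 2 x the provisional FWHM around the
peak); the peak is a parabolic fit through the three highest samples and
the widths come from linear interpolation at the half and tenth levels -
no function fitting. On an analytic Gaussian (sigma = 0.6 mm, 0.25 mm
grid) the estimator is within 0.2% of 2.3548 sigma and within 1% of the
1.8226 FWTM/FWHM ratio.

Sensitivity converts background-subtracted rates to S_i = (R_i - R_B)/A
and divides by the positron branching fraction for absolute values;
"integrated" values sum the fifteen measured axial positions (this
reading reproduces the 0.751 cps/Bq to 82.9% conversion exactly). The
background acquisition is a source-out run of equal duration, for which
the intrinsic-singles generator provides a stand-in.

Count rates follow the NU4 procedure: zero sinogram pixels more than
8 mm outside the phantom radius, centre each angular row on its maximum,
sum over angles, and take everything outside a centred 14 mm strip plus
the linearly interpolated background beneath it as scatter-plus-randoms;
randoms come from the singles-product estimate; NECR = T^2/Total with
the peak located by a parabolic fit over the activity sweep; the scatter
fraction averages acquisitions where randoms are below 1% of trues.

Image quality uses NU4 default regions: uniformity over a 22.5 mm x
10 mm cylindrical VOI; recovery coefficients from the 10 mm axial
average of the rod region, taking the maximum pixel in a 2 x diameter
ROI per rod and reading the axial profile at that position, with the
combined percent-standard-deviation formula; spillover as the mean in a
4 mm x 7.5 mm VOI inside each cold chamber over the uniform mean. The
phantom definition follows the NU4 drawings where the source text is
silent (30 mm body, 15 mm uniform chamber, rods 1-5 mm at a 7 mm offset,
8 mm cold chambers); every dimension is an argument.

## Problem sizes and what the studies show

The packaged studies run at desk scale by design: 10^4 events for the
light-containment measurement, 10^6 singles for the randoms cross-check,
2 x 10^4 noise-free pairs for MLEM point convergence on a 64^3 half-mm
grid, 10^6 decays plus 1.2 x 10^7 normalization events for the
attenuation-recovery study on a 1 mm grid, and 2 x 10^5 annihilations
for positioner training. These sizes make every study reproducible in
minutes on one CPU. They demonstrate internal consistency of the chain -
not hardware performance: the bench-measured resolution, sensitivity,
NECR and image-quality figures of a physical scanner depend on detector
physics (full optical transport, electronics, dead time, energy
resolution) that this reduced model deliberately replaces with
parametric stand-ins.

Known limitations, collected: no optical ray tracing (parametric spread
with a single mirror bounce); no object-scatter correction (scattered
pairs can be excluded at truth level for correction studies); no dead
time, ADC quantization or timing jitter; homogeneous convex object
transport; and the dense residual positioner stands in for the reference
convolutional design.
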