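# mapet — monolithic-annulus PET simulation, reconstruction and NU4 analysis

`mapet` models a preclinical PET scanner built from a *single monolithic
LYSO annulus*: a 72 mm-long crystal with a 60 mm bore, machined into
fourteen flat outer facets (apothem 39.7 mm), each read out by four
4 × 4 SiPM arrays at 4.4 mm pitch. Instead of discrete crystal elements,
event positions are decoded from the continuous scintillation-light
distribution spread across the facets — which makes the *computational*
chain (light model, trigger logic, distribution harmonization, learned
positioning, projection, reconstruction) the heart of the instrument.
This package implements that chain end-to-end as testable R code, for
researchers studying monolithic-scintillator PET designs and the
algorithms they require.

The pieces, in the order data flows through them:

* **Photon-pair Monte Carlo** — positron-range and acollinearity blur,
  object attenuation/Compton scatter, and interaction chains in LYSO
  (photoelectric vs Klein–Nishina Compton by cross-section ratio),
  labelled PE / CSE / CS-PE / multi.
* **Optical model** — exact solid angles of the 4 mm active pixel
  squares, bore occlusion, and a tangent-limited specular mirror term
  for the bore reflector; calibrated so that ≥ 90 % of an event's light
  stays within its primary facet ± 1.
* **DAQ** — per-array thresholds, facet sums, a 2 ns (full-width)
  coincidence window among the seven opposing facets, multiple-prompt
  rejection, and 12 × 16 photon-distribution assembly.
* **Positioning** — f-factor (0.0025) harmonization with
  max-normalization; a centre-of-mass baseline with a calibrated
  second-moment depth lookup; and a trainable dense residual network
  regressing the first-interaction position, always clamped to the
  crystal solid.
* **Reconstruction** — projection of each LOR onto fourteen virtual
  16 × 84 pseudo-detectors (0.84 mm elements) at the 30 mm radius;
  randoms from singles (`R = window · S_i · S_j`); attenuation weights by
  exact voxel traversal; SSRB + ramp-filtered backprojection; and
  list-mode MLEM (0.25 mm default voxels) with Monte-Carlo normalization
  and monotone log-likelihood.
* **NEMA NU4-2008 analyses** — point-source FWHM/FWTM (parabolic peak,
  linear-interpolated crossings), axial sensitivity profiles with
  branching-ratio conversion, count-rate/NECR/scatter-fraction sweeps
  (`NECR = T²/(T+S+R)`), and image-quality metrics (uniformity, recovery
  coefficients, spillover ratios).

## Worked example

Simulate a Na-22 point source 5 mm off-axis, run the trigger and
positioning chain, reconstruct with MLEM on a half-millimetre grid, and
measure NU4 spatial resolution:

```r
library(mapet)
g <- build_geometry()
cfg <- run_config(geometry = g,
                  phantom = point_source("Na22", activity = 2e6,
                                         position = c(5, 0, 0)),
                  n_events = 20000, seed = 1,
                  recon = list(method = "mlem", n_iter = 15,
                               dims = c(64, 64, 64), voxel_size = 0.5,
                               sens_stride = 3, attenuation = FALSE))
res <- run_pipeline(cfg)
str(res$manifest$counts)
#> List of 7
#>  $ annihilations: int 20000
#>  $ interactions : int 30757
#>  $ singles      : int 18902
#>  $ prompts      : int 5197
#>  $ positioned   : int 5197
#>  $ lors         : int 5023
#>  ...

resolution_metrics(res$volume, source_xy = c(5, 0))
#>    direction fwhm fwtm peak
#> 1     radial 1.59 3.95 4478
#> 2 tangential 1.77 3.90 4213
#> 3      axial 1.75 4.29 2145
```

Of 20 000 simulated annihilations, 18 902 photons trigger a facet,
5 197 survive the coincidence logic, and 5 023 project onto the virtual
detectors; the reconstructed point (here positioned with the
centre-of-mass baseline) comes back at 1.6–1.8 mm FWHM. Training the
network positioner (`make_positioning_dataset()` +
`train_positioner()`) and passing it as `positioner =` to
`run_pipeline()` sharpens all three axes.

A quick look at the optical model's headline property:

```r
optical_containment(g, optical_model(), n = 2000, seed = 1)$mean_percent
#> [1] 91.9
```

## Command line

A thin wrapper over the package functions lives at `inst/cli/mapet.R`:

```sh
Rscript inst/cli/mapet.R run --phantom point --events 20000 --seed 1 --out out/
Rscript inst/cli/mapet.R geometry --out geometry.json
```

## Layout

```
R/            geometry, phantoms, gamma_mc, optics, daq, positioning,
              recon, nema, pipeline modules
src/          C++ kernels: voxel traversal, line integrals, list-mode MLEM
tests/        testthat suite incl. the acceptance checks
scripts/      acceptance.R
vignettes/    methods.Rmd — models, assumptions, numerical choices
```
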