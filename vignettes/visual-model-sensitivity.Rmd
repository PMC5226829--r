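---
title: "Receptor-noise visual models and the sensitivity of dichromatism scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-noise visual models and the sensitivity of dichromatism scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichrosens)
library(dplyr)
```

## The problem

Most diurnal birds are tetrachromats: four single-cone classes (SWS1, SWS2,
MWS, LWS) feed an opponent colour system whose discrimination ability is
limited by receptor noise. A standard way to quantify how different two
colours look to such an eye is the receptor-noise limited distance, measured
in just-noticeable differences (JND): a distance of 1 JND is the
discrimination threshold under good light.

Sexual dichromatism of a species is commonly scored by measuring the
reflectance of a set of homologous plumage patches in males and females,
computing the male--female chromatic distance for each patch, and averaging
over patches. Every step of that computation depends on visual-system
parameters -- the light environment, the pigment peak sensitivities, the
oil-droplet and ocular-media filters, and the relative photoreceptor
densities -- which are measured in only a handful of species. This package
implements the full scoring pipeline and the machinery for asking how
sensitive the resulting scores, and the *ranking* of species by score, are
to each of those assumptions, both one parameter at a time and over the
exhaustive cross-product of plausible parameter values.

## The model

### Cone spectral sensitivities

Each cone's sensitivity is the product of three curves on the working grid
(300--700 nm at 1 nm; all spectral integrals are grid sums times the step):

1. **Pigment absorbance**, from a near-universal A1 visual-pigment template
   parameterized only by the peak wavelength $\lambda_{\max}$: an
   $\alpha$-band of the form
   $S(\lambda) = \left[e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D\right]^{-1}$
   with $x = \lambda_{\max}/\lambda$, $A = 69.7$, $B = 28$, $b = 0.922$,
   $C = -14.9$, $c = 1.104$, $D = 0.674$ and
   $a = 0.8795 + 0.0459\,e^{-(\lambda_{\max}-300)^2/11940}$, plus a Gaussian
   $\beta$-band with amplitude 0.26, centre $189 + 0.315\,\lambda_{\max}$
   and width $-40.5 + 0.195\,\lambda_{\max}$. The $\beta$-band is included
   by default and can be toggled (`beta_band = FALSE`), since published
   analyses exist with and without it. With the band on, the combined
   curve's maximum can sit one grid point short of $\lambda_{\max}$ for
   UV pigments, where the band merges with the $\alpha$ tail.
2. **Oil-droplet transmission**: C/Y/R droplets are long-pass cut-off
   filters $T(\lambda) = \exp(-e^{-b(\lambda - \lambda_o)})$ with decay rate
   $b = 2.89\,B_{mid}$ and 1/e point
   $\lambda_o = \lambda_{cut} + 1.08/(2.89\,B_{mid})$, so the curve passes
   exactly through $1/e$ at $\lambda_o$. T-type droplets (always paired
   with SWS1 here) are represented as an explicit non-filtering droplet
   rather than missing data, keeping the four-channel pipeline uniform.
   When a study reports the half-maximum wavelength $\lambda_{mid}$ instead
   of $B_{mid}$, we recover $B_{mid} = 0.5/(\lambda_{mid} - \lambda_{cut})$
   from the tangent-line geometry (the tangent at half-maximum absorbance
   reaches zero at $\lambda_{cut}$); the constants of this relation live in
   one configuration list so they can be revised without code changes.
3. **Ocular-media transmission**, a smooth long-pass filter summarized by
   its 50% wavelength T50. No closed form is standard across the
   literature, so we use a logistic sigmoid
   $T(\lambda) = 1/(1 + e^{-s(\lambda - T50)})$ with default slope
   $s = 0.08\ \mathrm{nm}^{-1}$ (a 10--90% rise over about 55 nm, matching
   published avian curves); the slope is an explicit argument
   (`ocular_slope`) for anyone wanting a steeper or shallower lens.

Sensitivities are renormalized to unit peak. The normalization is provably
irrelevant: the von Kries step divides it out, which the test suite checks
numerically.

### Quantum catches and chromatic distance

For reflectance $R$ (fractional), illuminant $I$ and sensitivity $S_i$, the
catch is $Q_i = \sum_\lambda R\,I\,S_i\,\Delta\lambda$ and the von
Kries-corrected relative catch is $q_i = Q_i / \sum_\lambda I\,S_i\,
\Delta\lambda$, the standard colour-constancy approximation. Contrast
between stimuli $A$ and $B$ uses $\Delta f_i = \ln(q_i^A/q_i^B)$ and the
four-receptor noise-limited distance with channel noises $e_i$ equal to the
Weber fractions:

$$\Delta S^2 =
\frac{\sum_{i<j} (e_k e_l)^2 (\Delta f_i - \Delta f_j)^2}
     {\sum_k \prod_{i\neq k} e_i^2},$$

where $(k, l)$ are the two channels not in the pair $(i, j)$. Weber
fractions derive from relative photoreceptor densities $\eta_i$ as
$\omega_i = \nu/\sqrt{\eta_i}$, with the noise scale $\nu$ fixed so the
most abundant channel has exactly the reference value (0.05 by default;
density ties resolve towards LWS, the conventional reference channel).
Hence for the Pekin robin ratios 1:2:2:4, $\omega = (0.100, 0.0707,
0.0707, 0.0500)$.

Consequences that the tests verify: $\Delta S$ is symmetric, zero exactly
when all $\Delta f_i$ are equal (so any two flat "grey" spectra are
indistinguishable), inversely proportional to a common rescaling of all
Weber fractions (6 JND at $\omega = 0.05$ becomes 3 at 0.10 and 1.5 at
0.20), invariant to illuminant intensity and per-channel sensitivity scale,
and equal to an independent generic-$n$ receptor-noise implementation at
$n = 4$ to machine precision.

### Scoring and comparing

Per-patch male--female distances below 1 JND are floored to zero (a
non-detectable difference should not inflate a species score), and the
species score is the floored sum divided by the number of *feathered*
patches -- bare facial patches, which lose their colour in museum skins,
are excluded from numerator and denominator via the bare-patch mask.
Species are ranked by score (rank 1 = most dichromatic; ties averaged; the
direction is a convention that cancels from all rank-change magnitudes).

Two parameterizations are compared by the Pearson correlation of species
scores and by rank statistics: how many species keep their rank, and the
mean, SD and maximum of the absolute rank change over all species (the
"over all species, absolute values" reading is our documented choice; the
source conventions are ambiguous). Patch-level reports for a focal species
count patches below threshold under each condition and patches whose *raw*
(un-floored) distance changed by more than 1 JND -- flooring applies to
scores only -- and give the largest single-patch change in JND and percent.
The percent change has no universal denominator convention; we compute it
for the patch with the largest JND change, defaulting to the smaller of the
two raw values (selectable to the larger value or condition A), and report
`NA` whenever that patch is sub-threshold on either side. Every report
records the convention used.

## Sensitivity analysis

`sweep_parameter()` rescores everything under each value of one parameter
and compares all condition pairs; the most divergent pair is the one with
the lowest Pearson r. `build_parameter_space()` assembles the exhaustive
per-eye-type space: 7 illuminants × 4 ocular T50 values (UVS 314--344 nm
in 10 nm steps; VS 335--395 nm in 20 nm steps) × 11 pigment sets (average,
each channel at its minimum or maximum, all-min, all-max) × 9 droplet sets
(average, each non-T droplet at min or max, all-min, all-max) × 9 density
ratios = 24,948 combinations. `permute_space()` evaluates all of them,
computing each sensitivity-curve set once per (pigment set, droplet set,
T50) triple and reusing it across illuminants and densities, which only
rescale catches and noise — a cached combination re-computed standalone
gives the identical score, which is tested. `summarize_permutations()`
reports the pooled range, the percent difference $100 \times
\max/\min$ (the convention implied by the field's own arithmetic; undefined
and reported `NA` when the minimum is zero), the overlap of the two eye
types' ranges as a fraction of the pooled range, and the ratio of grand
means (pairing scores across eye types is ill-defined because their
parameter values differ, so we do not average paired ratios).

### Physiology configuration

Average UVS and VS parameter sets are built in. The *extreme* pigment,
droplet and most density values in `inst/extdata/parameter_space.yaml` are
editable placeholders spanning literature ranges, flagged
`placeholder: true`; `build_parameter_space()` refuses them unless
`allow_placeholders = TRUE`, so nobody silently fabricates physiology. The
density sets include three published ratios: the Pekin robin 1:2:2:4 and
the strongly contrasting *Anous minutus* (1, 9.59, 16.82, 14.29) and
*Puffinus pacificus* (1, 0.68, 1.04, 1.44).

The six empirical illuminants are shipped as synthetic parametric
approximations (Planck photon-flux spectra at habitat-appropriate colour
temperatures, with Rayleigh or foliage weighting), clearly labelled in
their filenames and headers. They give the seven-illuminant machinery
realistic spectral diversity; they are not measured irradiance tables, and
none of the package's quantitative guarantees depends on their exact
shapes (the wavelength-independent "ideal" illuminant is the default
everywhere). Whether irradiance is treated as photon flux or energy only
matters for the empirical illuminants; the packaged tables declare photon
units, and users supplying energy spectra should convert (multiply by
$\lambda$) before use.

## The synthetic-data generator

`simulate_plumage()` produces per-sex mean reflectance curves -- the same
unit of data as a museum-skin spectral library -- with known ground truth:
each patch is a baseline plus Gaussian peaks (with an optional long-pass
sigmoid patch type for melanin-like spectra), the female curve shifts the
peak centres and/or changes amplitudes by a per-species effect multiplier,
and optional measurement noise is spectrally correlated (white noise
convolved with a 20 nm Gaussian kernel, the smoothness typical of
spectrometer output) rather than white. Reflectance is clipped to 0--100%
and everything is determined by the seed. `simulate_uv_contrast()` builds
the diagnostic case where the sexes differ only below 400 nm, which a UVS
eye resolves far better than a VS eye.

What passing synthetic tests does and does not show: the generator
exercises every pipeline contract (grid handling, sex pairing, bare-patch
masking, flooring, ranking, permutation bookkeeping) and realistic
smooth-spectra numerics, but real plumage reflectance has structure the
generator does not emulate (iridescence, sharp carotenoid shoulders,
correlated patch geometry across the body), so quantitative results on
real libraries will differ even when every synthetic check passes.

## Numerical choices and degenerate inputs

* Reflectance is floored at $10^{-4}$ (fractional) before catches, so no
  channel ever sees a zero catch from a dark patch; a genuinely zero or
  negative catch raises a typed error rather than being silently
  epsilon-padded, because silent epsilons distort JNDs unpredictably near
  the UV edge. The floor is configurable (`refl_floor`).
* Negative raw reflectances (instrument noise) are clipped to zero at read
  time; nothing else is altered.
* Resampling is linear interpolation onto the working grid; extrapolation
  outside the measured band is an error.
* Symmetry of $\Delta S$ holds to floating-point rounding of
  $\ln(a/b) = -\ln(b/a)$, i.e. to about $10^{-15}$ relative, not bitwise.
* Problem sizes in the test suite are chosen for fast feedback: reduced
  parameter spaces (2 values per axis, 32 combinations) stand in for the
  full 24,948-combination space in most tests, with the full space
  enumerated (and, in the acceptance script, fully evaluated for one
  synthetic species) to confirm the combinatorics and the cache
  correctness at scale.

## Known limitations

* Chromatic contrast only: no achromatic (double-cone) channel, no rod or
  dim-light (quantum-noise) regime, and no A2 chromophore or five-cone
  variants.
* The ocular-media sigmoid and the synthetic illuminants are parametric
  stand-ins; replace them with measured tables for species-level work.
* The supra-threshold meaning of large JND values is an open question in
  the field; scores built by summing many supra-threshold patch distances
  should be interpreted comparatively, not absolutely.
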