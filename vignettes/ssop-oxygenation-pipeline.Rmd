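---
title: "Methods: the SFDI/SSOP tissue-oxygenation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SFDI/SSOP tissue-oxygenation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssopr)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they rest on, the parameters that matter, and
the numerical and design choices made where the design was genuinely
open. Nothing stated here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The measurement model

### Forward model

Structured illumination at spatial frequency $f_x$ probes a turbid medium
whose diffuse reflectance we model with the standard spatial-frequency-
domain diffusion approximation for a semi-infinite homogeneous medium.
With $\mu_{tr} = \mu_a + \mu_s'$, reduced albedo $a' = \mu_s'/\mu_{tr}$
and

$$\mu_{eff}'(f_x) = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2},$$

the reflectance is

$$R_d(\mu_a, \mu_s', f_x) =
  \frac{3Aa'}{(\mu_{eff}'/\mu_{tr}+1)(\mu_{eff}'/\mu_{tr}+3A)},
  \qquad A = \frac{1-R_{eff}}{2(1+R_{eff})},$$

with $R_{eff} \approx 0.0636\,n + 0.668 + 0.710/n - 1.440/n^2$ the
effective internal Fresnel reflection for refractive index $n$ (default
1.4, soft tissue). Production instruments typically tabulate a Monte
Carlo forward model instead; the look-up-table interface here is forward-
model-agnostic (any table with the same schema inverts identically), and
the diffusion closed form is deterministic, desk-scale, and adequate over
the tissue-like range the pipeline targets ($\mu_a$ 0.005–0.05 mm⁻¹,
$\mu_s'$ 0.5–3 mm⁻¹, $f_x \le 0.2$ mm⁻¹). Its main assumptions —
scattering-dominated transport, semi-infinite homogeneous medium, no
specular component (the physical instrument rejects it with crossed
polarizers) — are exactly the conditions the renderer simulates, so
forward and inverse stages form a consistent pair.

One caveat the tests encode: $R_d$ is strictly decreasing in $\mu_a$ and
increasing in $\mu_s'$ at $f_x = 0$, but at $f_x = 0.2$ mm⁻¹ the closed
form loses strict $\mu_a$-monotonicity in the low-absorption,
low-scattering corner. Invertibility does not need it: it needs the
planar surface monotone (verified at table build time, failing loudly
otherwise) and the AC reflectance monotone in $\mu_s'$ along iso-$R_{DC}$
curves (verified numerically over the default ranges).

### Rendering

`render_frames()` images a ground-truth scene as

$$I(x,y) = G(x,y)\,\tfrac12\left[R_d(0) +
  R_d(f_x)\cos(2\pi f_x X + \phi + \Delta\phi_h)\right],$$

with three phase offsets $\phi \in \{0, 2\pi/3, 4\pi/3\}$ per frequency.
Planar illumination ($f_x = 0$) projects a uniform pattern, so its three
frames are identical and equal $G\,R_d(0)$. Two height effects are
simulated, mirroring standard fringe-projection geometry:

* a Lambertian shading factor $\cos\theta$ from the surface normal
  (computed from the height-map gradient), folded into the gain field
  $G$; and
* a fringe phase shift $\Delta\phi_h = 2\pi f_x\, h \tan\theta_{tri}$,
  with triangulation angle $\theta_{tri}$ (default 10°).

Not simulated: speckle, specular reflection (rejected by the instrument's
crossed polarizers), lens distortion, and working-distance irradiance
falloff (available as an option in the correction but off by default so
forward and inverse stay a matched pair).

### Noise

Default acquisition noise is additive Gaussian read noise at
$\sigma = 0.5\%$ of full scale (the illumination gain), applied per frame
and truncated at zero; `none` and Poisson shot-noise models are also
available. At this level, per-pixel StO2 estimates carry a standard
deviation of roughly 5 percentage points (the AC channel at 665 nm is a
small signal relative to full scale), while lobe means over $10^4$ pixels
are recovered to a fraction of a point. All noise derives from a single
seed through named per-module substreams, so identical configurations
reproduce byte-identical outputs.

## 2. Demodulation

**Three-phase SFDI.** The amplitude identity
$M_{AC} = \tfrac{\sqrt2}{3}\sqrt{(I_1-I_2)^2+(I_2-I_3)^2+(I_3-I_1)^2}$
is exact for a pure sinusoid; the tests hold it to $10^{-12}$ relative on
noiseless renders. The DC channel is taken as the three-frame mean of the
planar stack — mirroring the instrument's separate $f_x = 0$ acquisition —
rather than from the high-frequency stack.

**Single-frame SSOP.** The Fourier route estimates both channels from one
high-frequency frame: a radial raised-cosine low-pass (cutoff $f_x/2$,
cos² taper from half the cutoff) recovers the DC channel; a one-sided
raised-cosine band-pass of half-width $f_x/2$ centered on the carrier
recovers the analytic-signal magnitude, i.e. the AC amplitude. Outputs
are rescaled to the SFDI convention so the two methods are
interchangeable downstream. The instrument's original filter shapes are
not published; these defaults are declared, not inferred, and are fully
exposed in `ssop_filter_spec()`. Numerical details that matter:

* the frame is mirror-padded before the FFT; the *filter width* is taken
  as the spatial main lobe of the tapered band-pass, $\approx 2$ carrier
  periods, and pixels within one filter width of a border are flagged
  invalid (the padding seam is kept that far away as well);
* ringing at reflectance step edges is confined to within one filter
  width of the edge (a regression-tested property, not an accuracy
  claim);
* on smooth scenes the SSOP/SFDI ratio $M_{AC}/M_{DC}$ agrees within 5%
  on ≥95% of interior pixels, with sub-2% medians.

**Phase.** The three-step phase
$\phi = \operatorname{atan2}(\sqrt3(I_3-I_2),\, 2I_1-I_2-I_3)$ is
unwrapped with Itoh line-scan integration along the fringe direction plus
a column stitch. A residue-handling quality-guided unwrapper is not
needed here: the carrier advances well under $\pi$ per pixel at both
supported resolutions, and the renderer can only produce smooth,
carrier-dominant phase fields. Pixels with vanishing modulation are
flagged invalid.

## 3. Calibration, inversion, profilometry, unmixing

**Phantom calibration.**
$R(f_x) = M_{sample}/M_{phantom}\cdot R_d^{model}(\mu_a^{ph},
\mu_s'^{ph}, f_x)$ cancels any gain field shared between sample and
phantom exactly (tested with a random smooth ×2 field). Phantom and
sample must share method, wavelength, geometry and illumination; pixels
with phantom signal under 1% of its median are flagged invalid rather
than raising. The default virtual phantom ($\mu_a = 0.012$ mm⁻¹,
$\mu_s' = 1.5/1.2$ mm⁻¹ at 665/860 nm) sits mid-range; the phantom
acquisition carries the same noise model as the sample, which is the
dominant noise contribution to the AC channel.

**Look-up-table inversion.** The table stores the forward surfaces on a
64 × 64 grid — $\mu_a$ log-spaced (StO2 accuracy is driven by *relative*
absorption accuracy over a 10× dynamic range), $\mu_s'$ linear. Inversion
precomputes a dense inverse raster on a regular 512 × 512
$(R_{DC}, R_{AC})$ grid using three 1-D monotone interpolation passes
(spline refinement of the surfaces, then $\mu_a$ along iso-$\mu_s'$
columns, then $\mu_s'$ along iso-$R_{DC}$ rows), after which each pixel
is a bilinear lookup — vectorizable, no per-pixel optimization. Round-trip
recovery over an interior 20 × 20 sub-grid is ≈ 0.003% in $\mu_a$ and
≈ 0.0004% in $\mu_s'$, far inside the 1% / 0.5% contract, and doubling
the grid density moves mid-range inversions by < 0.5%. Out-of-hull pixels
are masked, never clamped: silent clamping would corrupt StO2 downstream
invisibly.

**Profilometry correction.** Height follows from the phase difference to
a flat reference, $h = \Delta\phi/(2\pi f_x\tan\theta_{tri})$, the exact
inverse of the renderer's convention. The correction divides both
channels by the modeled illumination factor — $\cos\theta$ from the
height gradient (centered differences at pixel-pitch scale, Gaussian
smoothing $\sigma = 2$ px to stabilize the normal), optionally an
inverse-square distance factor. Slopes beyond 75° are masked. Because the
factor is wavelength- and frequency-independent it never changes
$M_{AC}/M_{DC}$; it matters because a *flat* phantom cannot calibrate
away *sample* tilt. On a 20 mm curved-lobe scene the correction reduces
the mean StO2 error from ≈ 1.2 points to below 0.01 (noiseless), and the
strict corrected-vs-uncorrected inequality is part of the acceptance
suite. Correcting reflectance maps after calibration and correcting
modulation maps before it are multiplicatively identical;
`profile_correct()` accepts either map type, and the pipeline applies it
before calibration.

**Beer–Lambert unmixing.** With two chromophores at two wavelengths the
system $\mu_a(\lambda) = \ln 10\,(\epsilon_{HbO2}C_{HbO2} +
\epsilon_{Hb}C_{Hb})/10$ is exactly determined and solved in closed form;
no least squares, no baseline absorption offset, no water/fat terms (the
two-wavelength instrument design implies exactly this model). Extinction
coefficients (665 nm: 320 / 3151; 860 nm: 1070 / 710 cm⁻¹M⁻¹ for
HbO2/Hb) are interpolated from the Prahl/OMLC compilation; only their
ordering (deoxy-dominant red, oxy-dominant NIR) and conditioning affect
any result here, since the same table drives forward simulation and
unmixing. Negative concentrations — routine near the noise floor at deep
desaturation — are clipped to zero and *flagged*, not masked, preserving
map continuity with QC visibility; pixels with total hemoglobin below
$10^{-7}$ M are masked.

One design decision deserves emphasis: ROI summaries include clipped
pixels by default. Near StO2 = 0 the estimator's noise distribution is
one-sided after clipping; excluding clipped pixels truncates the low tail
and biases deep-ischemia lobe means upward by more than 2 percentage
points at default noise, while including them keeps the end-to-end error
below 1 point (with a small residual positive bias from the clipping
itself, visible as 7.0% recovered against a 6.4% truth). The
`include_clipped` argument exposes the stricter alternative.

## 4. The synthetic ischemia experiment

`liver_scene()` lays three vertical lobe territories (LL, LM, RM) across
a 15 × 15 cm field of view (256 × 320 px quarter resolution by default;
1024 × 1280 full). `make_ischemia_scene()` sets per-lobe StO2 targets by
occlusion group and timepoint: total vascular inflow occlusion drops the
left lobes deeply (46.0 → 16.2% LL, 42.7 → 6.4% LM) with a *narrow* (6 mm)
demarcation band; arterial-only occlusion drops them moderately
(32.7 → 19.1%, 35.3 → 15.5%) with a *wide* (20 mm) graded band; the right
medial lobe barely changes; reperfusion returns to baseline (T2 = T0).
Transitions use a cosine smoothstep that is exactly constant outside the
band, and the lobe ROI masks exclude the bands, so mask means equal the
targets exactly — the property the end-to-end criteria measure against.

Hemoglobin is parameterized so StO2 alone fixes the absorption pair given
total hemoglobin. Total hemoglobin defaults to 50 µM: the baseline value
for swine liver is not established in this context (a documented
placeholder), and the default is chosen so that the derived $\mu_a$ stays
inside the look-up-table range with ≥ 60% margin at both wavelengths over
the study's full StO2 span (0–60%) — without that margin, acquisition
noise pushes deep-ischemia pixels out of the inversion hull and the
one-sided masking biases lobe means. Reduced scattering defaults to 1.6 /
1.2 mm⁻¹ at 665 / 860 nm (mid-range, decreasing with wavelength, as
placeholder-documented as the hemoglobin value).

`simulate_study()` draws the lobe-level study table (2 groups × 6 animals
× 3 lobes × 3 timepoints) from normal cells at the reference means and
SDs. Lactate and the contact-oximeter reference are coupled to the same
observation's StO2 with within-cell correlations solved in *closed form*
(`calibrate_coupling()`) so the pooled Pearson correlations hit their
targets (−0.76 and 0.82): the pooled covariance decomposes into the
between-cell covariance of the means (fixed by the reference table,
contributing ≈ −0.60 on its own for lactate) plus the within-cell
coupling term, and the required within-cell correlations (≈ −0.89 and
≈ 0.79) follow by inverting the ratio. Monte Carlo checks (hundreds of
replicates) confirm the mean sample correlation lands within ±0.05 of the
target. Pooling crosses both groups and all timepoints by default; a
per-group option exists, and neither mode is claimed canonical.

**What passing tests do and do not show.** The generator reproduces the
*statistical structure* of the in-vivo experiment — cell means, SDs,
coupling, design balance — and the *physics* of the imaging chain as far
as the diffusion/Lambertian forward model goes. It does not emulate real
livers: heterogeneous parenchyma, specular wet surfaces, motion,
breathing, inter-animal covariance structure, or Monte-Carlo-level
radiative transport. Passing end-to-end tests therefore validates the
computation, not the instrument.

## 5. Statistics

`two_way_anova()` fits the classical two-factor model with interaction
(`stats::aov`; the design is balanced, so the sums of squares are the
textbook ones, and a hand-computed 2 × 2 × 2 example pins the F
arithmetic in the tests). Pairwise timepoint contrasts within each lobe
are estimated via `emmeans`, and Šidák adjustment is applied across the
*whole* family of pairwise comparisons (9 contrasts), the behavior of the
usual two-way-ANOVA multiple-comparison reports — with per-lobe families
of 3 the right-medial false-positive rate at the reference means/SDs
exceeds what the study design expects. Degenerate all-equal tables return
F = 0, p = 1 by contract; empty cells fail with the offending cells
named. Results are invariant to row order and animal relabeling.

At the reference means and SDs with n = 6, the T0-vs-T1 comparison is
significant in essentially 100% of replicates for the clamped lobes and
non-significant in ≈ 90% for the right medial lobe — the qualitative
pattern the acceptance suite checks over 500 seeds.

`detect_demarcation()` thresholds StO2 at an absolute 25% (a fixed
clinical-style ischemia cutoff, configurable; relative thresholds were
rejected as baseline-dependent), keeps the largest connected component
(`EBImage::bwlabel`), and scores sharpness as the median StO2 gradient
magnitude along the component's interior boundary (image-border pixels
are field-of-view artifacts and are excluded). On noiseless StO2 fields
the sharp TVIO band scores several-fold higher than the wide HAO band
(the smoothstep's peak slope is $\pi\Delta/2w$, ≈ 9.6 vs ≈ 1.8 %/mm);
at default acquisition noise the per-pixel noise gradient adds a common
floor to both scores and the TVIO > HAO ordering still holds, matching
the pronounced vs. faint demarcation the two occlusion modes produce.

## 6. Problem sizes and determinism

Defaults are sized for interactive use: quarter-resolution scenes
(256 × 320), 64² look-up tables with 512² inverse rasters, 300–500
simulation replicates for Monte Carlo checks. The full suite runs in well
under a minute; the complete virtual experiment in a few seconds. Every
stochastic step draws from a named substream derived from one master
seed; identical config + seed reproduce identical files, which the tests
assert byte-for-byte on the CSV outputs.

## 7. Known limitations

* The diffusion approximation under-models reflectance at high absorption
  and near sources; a Monte Carlo table can be substituted through the
  same schema.
* The deep-learning demodulation and profilometry used by real-time
  systems are out of scope; the classical algorithms they replaced are
  the implemented contract, and no video-rate claim is made.
* StO2 lobe means retain a small positive bias (≲ 0.7 points at default
  noise) at near-zero saturation from concentration clipping.
* The phase unwrapper assumes carrier-dominant smooth phase fields; it is
  not a general residue-handling unwrapper.
* Extinction coefficients are approximate interpolations of a published
  compilation; swapping in a lab's preferred values is a one-line change
  to `hb_extinction()`, and self-consistency of simulation and unmixing
  is preserved by construction either way.
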