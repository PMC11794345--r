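# ssopr — structured-light tissue oxygenation imaging (SFDI / SSOP)

`ssopr` implements the image-computation pipeline behind intraoperative
tissue oxygen saturation (StO2) mapping with **spatial frequency domain
imaging (SFDI)** and its real-time variant, **single snapshot imaging of
optical properties (SSOP)**, together with a fully synthetic
hemi-hepatic-ischemia experiment that exercises the pipeline end to end —
no camera, projector or animal required. It is aimed at biomedical-optics
researchers who want a tested, reusable reference implementation of the
classical SFDI/SSOP processing chain and of the lobe-wise statistical
analysis used to quantify liver ischemia.

## The method

A projector casts sinusoidal patterns of spatial frequency fx (here 0 and
0.2 mm⁻¹) at two wavelengths (665 and 860 nm) onto the tissue; a camera
records the diffusely backscattered light. The pipeline then:

1. **Demodulates** the frames into modulation amplitude maps
   M_DC (planar) and M_AC (high frequency) — either exactly, from three
   phase-shifted frames per frequency,

       M_AC = (√2/3) · √[(I₁−I₂)² + (I₂−I₃)² + (I₃−I₁)²],

   or in real-time SSOP style from a *single* high-frequency frame by
   Fourier-domain filtering (low-pass → DC, band-pass around the fringe
   carrier → AC).
2. **Calibrates** against a tissue-mimicking phantom of known optical
   properties: R(fx) = M_sample/M_phantom · R_d^model(µa, µ′s, fx),
   yielding diffuse reflectance maps R_DC and R_AC.
3. **Inverts** (R_DC, R_AC) per pixel through a look-up table built from a
   diffusion-approximation forward model of spatial-frequency-domain
   reflectance, giving absorption µa and reduced scattering µ′s maps per
   wavelength (µa 0.005–0.05 mm⁻¹, µ′s 0.5–3 mm⁻¹).
4. **Corrects for surface shape**: the fringe phase
   φ = atan2(√3(I₃−I₂), 2I₁−I₂−I₃), unwrapped and referenced to a flat
   plane, gives the surface height h = Δφ/(2π fx tan θ); the Lambertian
   tilt factor computed from h removes the illumination error on curved
   tissue.
5. **Unmixes** the two-wavelength absorption into oxy-/deoxyhemoglobin via
   Beer–Lambert and reports StO2 = 100·C_HbO2/(C_HbO2+C_Hb).

The package also ships a forward renderer (scene → structured-light frame
stacks, including height-induced fringe shifts and tilt shading), a
generator of virtual hemi-hepatic ischemia scenes — total vascular inflow
occlusion (TVIO) with a sharp demarcation line, hepatic artery occlusion
(HAO) with a faint one — a lobe-level study simulator with calibrated
StO2–lactate and StO2–oximeter couplings, and the statistics stage:
two-way ANOVA (lobe × timepoint) with Šidák-adjusted multiple
comparisons, pooled Pearson correlation matrices, and demarcation-line
detection on StO2 maps.

## Worked example

A complete virtual TVIO experiment at quarter resolution (256 × 320 px,
15 × 15 cm field of view), with 0.5% full-scale Gaussian read noise:

```r
library(ssopr)
cfg <- pipeline_config(seed = 1)
exp_tvio <- run_virtual_experiment("TVIO", cfg)
print(exp_tvio$lobe_table, digits = 3)
#>   roi timepoint mean_sto2 sd_sto2 n_valid empty
#> 1  LL        T0     45.89    5.10   25344 FALSE
#> 2  LM        T0     42.62    5.25   18432 FALSE
#> 3  RM        T0     47.85    4.95   20736 FALSE
#> 4  LL        T1     16.13    6.50   25344 FALSE
#> 5  LM        T1      7.03    5.80   18432 FALSE
#> 6  RM        T1     43.08    5.26   20736 FALSE
#> 7  LL        T2     45.90    5.08   25344 FALSE
#> 8  LM        T2     42.52    5.35   18432 FALSE
#> 9  RM        T2     47.87    4.98   20736 FALSE
```

The pipeline recovers the scene's ground-truth lobe means (LL 46.0 → 16.2%
from baseline to ischemia; the right medial lobe stays ≈ 48 → 43%) to
well under one percentage point at this noise level, and the left-lobe
ischemic territory segments cleanly:

```r
demarc <- detect_demarcation(exp_tvio$oxy_maps$T1)
#> demarcation: 52270 px below 25%, sharpness 16.10 %/mm
```

The study simulator reproduces the lobe-level statistical structure of
the two-group swine experiment (6 animals per group, 3 lobes, 3
timepoints):

```r
study <- simulate_study(study_spec(seed = 1))
cell_summaries(study)
#> Baseline - ischemia effect sizes per group and lobe:
#>   group lobe sto2_drop ref_sto2_drop lactate_rise
#> 1   HAO   LL     15.28         12.18       0.5264
#> 2  TVIO   LL     29.62         21.79       6.1959
#> 3   HAO   LM     21.79         13.45       0.0509
#> 4  TVIO   LM     36.73         20.64       7.0738
#> 5   HAO   RM      2.64         -2.81      -0.3521
#> 6  TVIO   RM      3.52         -3.33       1.3829
correlation_matrix(study)
#> Pearson correlations (pooled, pairwise-complete):
#>            sto2 lactate ref_sto2
#> sto2      1.000  -0.757    0.821
#> lactate  -0.757   1.000   -0.750
#> ref_sto2  0.821  -0.750    1.000
```

With noise disabled (`simulate_study(spec, noise = FALSE)`) the drops are
exactly 29.8 / 36.3 (TVIO LL/LM) and 13.6 / 19.8 (HAO) percentage points.
The two-way ANOVA finds the T0-vs-T1 desaturation significant in the
clamped left lobes and not in the right medial lobe:

```r
res <- two_way_anova(study, "sto2", group = "TVIO")
subset(res$comparisons, contrast == "T0 - T1")
#>   lobe contrast estimate   se     t df    p_raw    p_adj
#> 1   LL  T0 - T1    29.62 3.88 7.640 45 1.16e-09 1.04e-08
#> 4   LM  T0 - T1    36.73 3.88 9.472 45 2.77e-12 2.49e-11
#> 7   RM  T0 - T1     3.52 3.88 0.909 45 3.68e-01 9.84e-01
```

A thin command-line wrapper lives at `inst/cli/ssop.R`
(`Rscript inst/cli/ssop.R run --demo tvio --out results/`).

## Documentation

The methods vignette (`vignettes/ssop-oxygenation-pipeline.Rmd`) describes
the forward model and its assumptions, every tunable parameter with units
and defaults, what the synthetic generator does and does not emulate, and
the numerical choices behind the demodulators, the look-up-table
inversion and the statistics.
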