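# relaxcider

Mechanistic decomposition of the longitudinal relaxation of
[1-¹³C]pyruvate across magnetic fields, for hyperpolarized-MR sample
optimization.

Hyperpolarized [1-¹³C]pyruvate loses its signal with the time constant T1,
which depends on the magnetic field (microtesla fringe fields during
transport, tesla fields at detection) and on the sample chemistry. Because
rates of independent relaxation mechanisms add,

R₁(B) = R₁⁰ + R₁ᵢₙₜᵣₐᴰᴰ + R₁ᵢₙₜₑᵣᴰᴰ + R₁ᴾᴿᴱ:ᴼ²(B) + R₁ᴾᴿᴱ:ᴹ⁺(B) + R₁ᴾᴿᴱ:ʳᵃᵈ(B) + R₁ᶜˢᴬ(B),

each channel can be isolated by subtracting the T1-vs-field (NMRD) profiles
of two samples that differ in a single chemical feature — solvent
deuteration, degassing, chelation, radical content, methyl deuteration — and
fitting the difference with its field law: a quadratic
(2/15)(B·Δσ·γ)²τc for chemical shift anisotropy, Lorentzian dispersions
governed by the electron Larmor frequency for the paramagnetic channels,
field-flat rates for the dipolar couplings. The package implements:

* closed-form rate laws per mechanism and their additive combination for a
  sample composition (`r1_csa()`, `r1_pre()`, `total_r1()`);
* pairwise profile subtraction with uncertainty propagation, field-band
  statistics, weighted dispersion fits, and a full study decomposition
  (`subtract_rate_profiles()`, `band_statistics()`, `fit_csa()`,
  `fit_pre()`, `decompose_study()`);
* mono-exponential and flip-angle-corrected hyperpolarized decay fitting
  (`fit_monoexponential()`, `fit_hyperpolarized_decay()`);
* polarization-loss integration along a field-time trajectory and
  polarization quantification against a thermal reference
  (`retained_polarization()`, `snr_gain()`, `polarization_from_reference()`);
* a synthetic generator rebuilding the nine-sample composition study from
  tabulated component rates (`generate_study_bundle()`), so the whole
  pipeline is testable offline;
* CSV I/O for NMRD tables, decay series and field trajectories, and a
  one-call pipeline (`run_pipeline()`).

## Worked example

```r
library(relaxcider)

bundle <- generate_study_bundle(seed = 20260521, noise_rel = 0.03)
dec <- decompose_study(bundle$profiles)
dec
#> NMRD mechanism decomposition
#>   background  0.00449 +/- 4e-05 s^-1 (sample #A)
#>   intraDD     0.0007081 +/- 4.5e-05 s^-1 (pair #B - #A; raw diff 0.0006636)
#>   interDD     0.009556 +/- 0.00015 s^-1 (pair #E - #D; raw diff 0.008955)
#>   pre_o2        amp 0.006604 s^-1, tau_c 7.13 ps
#>   pre_metal_h2o amp 0.01325 s^-1, tau_c 180 ps
#>   pre_metal_d2o amp 0.01153 s^-1, tau_c 205 ps
#>   radical       amp 0.001784 s^-1, tau_c 308 ps
#>   CSA         delta_sigma 136.5 +/- 2.4 ppm (tau_c 7.3 ps fixed)
#>   RMS relative residual over 225 points: 0.0292
```

From nine simulated profiles at 3% noise, the decomposition recovers the
generating parameters: the background plateau (true 0.0044 s⁻¹), the methyl
and solvent dipolar rates (0.0008 / 0.0095 s⁻¹, reported after correcting
the raw pair differences for the ≈15.9× deuteration scaling), the O2 and
metal-ion PRE amplitudes and correlation times, and the shielding anisotropy
(true 136.5 ppm, with the rotational correlation time 7.3 ps held fixed —
only Δσ²τc is identifiable from quadratic data). The RMS relative residual
of the assembled model equals the injected noise level.

Transport consequences follow directly from the fitted model:

```r
m_g <- relaxation_map(sample_compositions("#G"), dec$registry)  # standard DNP sample
m_c <- relaxation_map(sample_compositions("#C"), dec$registry)  # optimized sample
hold <- constant_field_profile(1e-3, 19.5)                      # 19.5 s at 1 mT
retained_polarization(m_g, hold)  # 0.645
retained_polarization(m_c, hold)  # 0.904
snr_gain(0.904, 0.645)            # 1.40
```

A 19.5 s low-field transfer keeps ~65% of the polarization for the standard
radical-containing sample but ~90% for the optimized (degassed, deuterated,
filtered) one — a 1.4× SNR gain from sample chemistry alone. Polarization is
quantified from a thermal reference: an enhancement of 4.06×10⁵ over thermal
¹³C at 1 T and 293 K corresponds to
`polarization_from_reference(4.06e5, 1)` → 35.6%.

## Documentation

The methods vignette (`vignettes/nmrd-decomposition.Rmd`) describes the
additive model and its assumptions, the deuteration bookkeeping, the pairing
ledger, fitting and numerical choices, and what the synthetic generator does
and does not emulate.
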