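# dibkit

Quantifying how small amphipathic drugs — aspirin in particular — perturb
lipid bilayers, from three complementary bench measurements:

1. **Osmotic water permeability of droplet interface bilayers (DIBs).**
   Two lipid-monolayer-coated aqueous droplets in oil adhere to form a
   bilayer at their contact zone. With unequal osmolalities, water crosses
   the bilayer and the droplets measurably shrink or swell.  The volume
   flux follows the standard osmotic flow law
   *dV₁/dt = P_f · V_w · A · (c₁ − c₂)*, where *P_f* (µm/s) is the osmotic
   water permeability, *V_w* = 18.05 cm³/mol the molar volume of water,
   *A* the bilayer area and *c_i* the instantaneous osmotic
   concentrations.  `dibkit` forward-simulates this closed two-droplet
   system and inverts observed radius time series to *P_f* by initial-slope
   or full-trajectory least squares, then summarises drug effects as the
   whole-percent change 100·(P_f − P_f°)/P_f° against the drug-free
   reference P_f°.

2. **Interfacial energetics from droplet contact geometry.**  From the
   monolayer tension γ_m and the droplet contact angle θ:
   bilayer tension γ_B = 2γ_m·cosθ, Young–Dupré free energy of bilayer
   formation ΔF = 2γ_m(cosθ − 1) ≤ 0, and relative lateral pressure
   π = γ_m(1 − cosθ) = |ΔF|/2.  The contact angle itself comes from the
   sphere geometry, θ = ½[arcsin(r/R₁) + arcsin(r/R₂)].

3. **Thermotropic and structural perturbation.**  DSC heat-flow
   thermograms are normalised to molar excess heat capacity,
   baseline-corrected, and reduced to the main transition temperature *T*m
   (peak apex) and transition enthalpy ΔH (integrated peak area).  Raman
   spectra of supported bilayers are normalised to the 2849 cm⁻¹
   phospholipid band, aspirin bands are removed by reference subtraction
   scaled at the 1606 cm⁻¹ aromatic anchor, and the acyl-chain order
   ratios I(2848)/I(2890) and I(2930)/I(2890) are read out.

Because such studies publish summary values rather than raw traces, the
package ships seeded synthetic-data generators (`synth_config()`,
`gen_shrinkage()`, `gen_thermogram()`, `gen_raman()`, `gen_study()`) whose
defaults encode the published study conditions, so the entire pipeline is
testable end to end with recoverable ground truth.

## Worked example

```r
library(dibkit)

# Interfacial energetics from printed (gamma_m, theta) pairs
interfacial_params(
  data.frame(label   = c("1:0", "1:1"),     # DOPC:ASA mole ratio
             gamma_m = c(1.12, 0.92),       # mN/m
             theta   = c(36.7, 25.9)),      # degrees
  rounded = TRUE)
#> # A tibble: 2 × 8
#>   label gamma_m theta theta_deg gamma_B_mN_m delta_F_mJ_m2 abs_delta_F_mJ_m2
#> 1 1:0      1.12  36.7      36.7         1.8         -0.444             0.444
#> 2 1:1      0.92  25.9      25.9         1.66        -0.185             0.185
```

Aspirin at mole fraction 0.5 lowers the bilayer tension from 1.80 to
1.66 mN/m and shrinks the adhesion energy |ΔF| from ~0.445 to
0.185 mJ/m² — a weaker, more permeable membrane.

```r
# Simulate a shrinking droplet pair and recover its permeability
st  <- droplet_pair_state(V1 = 1.4137e7, V2 = 1.4137e7,     # um^3
                          osmolality1 = 300, osmolality2 = 100,
                          A = pi * 60^2)                    # um^2
ser <- simulate_droplet_pair(st, pf = 71, t_end = 1770, dt = 30,
                             noise_sd = 0.002, seed = 7)
pf_fit_trajectory(ser)
#> Osmotic water permeability estimate (trajectory-fit)
#>   Pf = 71.089 um/s (SE 0.279), residual norm 3.12, n = 60

relative_change(88, 71)   # percent change at chi_ASA = 0.5, pH 3
#> [1] 24
```

The fit recovers the generating *P_f* = 71 µm/s to 0.1 µm/s at 0.2 %
radius noise; an 88 µm/s aspirin-loaded membrane against a 71 µm/s
reference is a 24 % permeability increase.

Fitted objects support `tidy()`/`glance()`; series, heat-capacity curves
and spectra have `autoplot()` methods; `gen_study()` + `study_report()`
run the whole multi-condition pipeline from a directory of plain-text
fixtures.

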