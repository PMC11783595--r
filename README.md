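# barrelfret

Quantitative photophysics of small-molecule co-encapsulation in de novo
α-helical barrel (αHB) peptide assemblies.

αHBs are self-assembling coiled-coil oligomers (5+ helices) whose central,
solvent-accessible channels can bind hydrophobic small molecules. When two
different guests — a donor dye such as 1,6-diphenyl-1,3,5-hexatriene (DPH)
and an acceptor such as Nile red — occupy the *same* channel, Förster
resonance energy transfer (FRET) between them reports on their separation
with r⁻⁶ sensitivity. `barrelfret` implements the full analysis chain used
to establish and characterise such ternary complexes, for spectroscopists
and protein designers who need the fits, not the instruments:

- **Steady-state screening** — non-negative spectral unmixing of mixed
  emission spectra and a ratiometric apparent FRET efficiency
  E_app = sensitized / (sensitized + donor), used to rank a panel of
  barrels and call FRET positives; ligand-depletion (quadratic) binding
  isotherm fits for K_d; competitive-displacement detection.
- **Förster theory** — overlap integral
  J = ∫ F̄_D(λ) ε_A(λ) λ⁴ dλ, Förster radius
  R₀⁶ = 8.79×10⁻⁵ κ² n⁻⁴ Q_D J (Å⁶, J in M⁻¹ cm⁻¹ nm⁴), and the
  efficiency/rate/distance interconversions E = 1/(1+(r/R₀)⁶),
  r = R₀ (τ_T/τ_D)^{1/6}. Interval inputs (e.g. a κ² range) propagate to
  distance ranges.
- **TCSPC reconvolution** — multi-exponential decay models convolved
  analytically with a Gaussian instrument response
  (α/2)·exp(σ²/2τ² − u/τ)·erfc((σ/τ − u/σ)/√2), fitted by Poisson maximum
  likelihood with multi-start initialization; intensity-weighted average
  lifetimes Σαᵢτᵢ²/Σαᵢτᵢ, BIC model selection, and extraction of the
  sensitized-acceptor rise time constant (the FRET time).
- **Transient-absorption target analysis** — band-integrated
  stimulated-emission kinetics fitted to a two-population scheme: a
  dominant donor subpopulation transferring on a ~10 ps time scale and a
  minority subpopulation transferring at ~1 ns, with closed-form
  IRF-convolved populations.
- **Free-energy-profile analysis** — prominence-based basin detection with
  watershed boundaries on 1D profiles over inter-dye distance, Boltzmann
  populations p_b ∝ ∫_b e^{−F/RT} dd, and stacked / slipped / distal
  classification.
- **Photodimerization kinetics** — exponential-vs-linear model selection
  (AICc) on 365 nm irradiation time courses of encapsulated anthracene,
  with promoted / inhibited / ambiguous classification against controls.
- **Synthetic instruments** — seeded generators for every input: vibronic
  spectra, Poisson TCSPC histograms under a 170 ps Gaussian IRF, TA maps
  under a 280 fs IRF, depletion titrations, double-well free-energy
  profiles, and photolysis traces. Every generator is a pure function of
  its seed.

## Worked example

Simulate a donor decay at the heptamer reference lifetime and fit it by
reconvolution:

```r
library(barrelfret)

tr  <- simulate_tcspc(multiexp_model(1, 15.9),
                      noise = noise_spec("poisson", seed = 1))
fit <- fit_reconvolution(tr, n_components = 1)
fit
#> <tcspc_fit: 1 component(s), poisson_mle, reduced stat 1.019, converged>
#> <multiexp_model>
#>   tau =  15.9016 ns  amplitude = +2.03e+04
#>   baseline = 200.3, t0 = 2 ns
average_lifetime(fit$model)
#> [1] 15.90163
```

The fitted lifetime (15.90 ns) recovers the 15.9 ns ground truth; the
reduced Poisson deviance near 1 says the fit is statistically consistent
with counting noise. Screen the default 15-barrel panel and analyse a
free-energy profile:

```r
res <- screen_panel(simulate_screen_panels(seed = 1))
sum(res$positive)
#> [1] 10

prof <- simulate_fes(heptamer_fes_wells(), seed = 1)
b <- find_basins(prof)
b$population <- boltzmann_populations(prof, b)
b$state <- classify_states(b)
b
#>   position  depth  left right prominence population   state
#> 1     3.53 -92.35  1.50  5.94      89.29   4.51e-01 stacked
#> 2     9.99 -91.29  5.94 18.00      89.12   5.49e-01 slipped
#> 3    23.98  -8.87 18.00 40.00       9.73   1.31e-14  distal
```

Ten of fifteen barrels are called FRET-positive, and the heptamer profile
resolves its π-stacked (3.5 Å) and slipped-stacked (10 Å) basins, which
together hold essentially all of the room-temperature population — the
shallow 20–30 Å shelf is thermally negligible.

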