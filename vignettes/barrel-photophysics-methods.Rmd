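---
title: "Models and methods: photophysics of dye co-encapsulation in peptide barrels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: photophysics of dye co-encapsulation in peptide barrels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelfret)
```

`barrelfret` analyses the photophysics by which co-encapsulation of two
small molecules inside an α-helical barrel (αHB) channel is established:
steady-state FRET screening, Förster-theory distance inference, TCSPC
reconvolution, transient-absorption (TA) target analysis, free-energy-profile
basin analysis, and photodimerization kinetics. This vignette explains the
models behind each step, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate, and
the numerical choices that matter.

## The physical picture

A donor dye (DPH-like: absorption near 352 nm, vibronic emission near
450 nm, lifetime 15.9 ns in the heptamer channel) and an acceptor
(Nile-red-like: emission near 593 nm, lifetime 4.1 ns) can occupy one
barrel channel simultaneously. Two co-existing geometries explain the
kinetics: a dominant π-stacked population with sub-nm dye separation that
transfers energy on a ~10 ps time scale, visible only in TA; and a minority
population with the dyes ~3 nm apart transferring at ~1 ns, visible as a
small sensitized-emission rise in TCSPC. Free-energy profiles over the
inter-dye distance show the corresponding basins near 3.5 Å (fully
π-stacked) and 10 Å (slipped-stacked).

## Steady-state screening

Mixed emission spectra are decomposed against donor-only and acceptor-only
references by non-negative least squares on the mixed spectrum's grid. The
apparent FRET efficiency is operationalized ratiometrically:

$$E_\mathrm{app} = \frac{S_A}{S_A + S_D}, \qquad
S_A = c_A B_A - f_\mathrm{dir} B_A, \quad S_D = c_D B_D,$$

where $c_D, c_A$ are the unmixing coefficients, $B_D, B_A$ the reference
band areas integrated ±40 nm around 450 nm (donor) and 593 nm (acceptor),
and $f_\mathrm{dir}$ an optional direct-excitation correction. This
sensitized-acceptor form was a deliberate design choice: it is invariant to
uniform intensity rescaling, bounded in [0, 1], and reduces to the
constructed transfer fraction on mixtures built from known fractions. It is
documented prominently so it can be swapped if a different operational
definition is preferred; any monotone ratiometric proxy produces the same
screen ranking.

The positive-call threshold defaults to `0.1`. No printed threshold exists
for calling a screen hit; 0.1 was chosen once so that clearly
FRET-negative panels (E_app of a few percent, from noise and band overlap)
never cross it while genuine transfer fractions ≥ 0.25 always do, and it
was not revisited afterwards.

Binding titrations use the single-site **ligand-depletion** (quadratic)
isotherm rather than the hyperbolic approximation because the ligand
(0.5 µM) and the dissociation constants (low µM) are comparable — the free
ligand concentration is materially depleted by binding. The bound fraction
is the quadratic root of the mass balance, and the observable is
$F/F_\mathrm{max} = f_0 + (f_\mathrm{max} - f_0)\,\theta$. Fits are
Levenberg–Marquardt on (log K_d, f₀, f_max); a K_d standard error exceeding
the estimate flags an unidentifiable (flat) series. Displacement between a
single-dye and a with-competitor titration is called on the top quartile of
the concentration grid (the "saturating region"), with a default 50%
drop threshold — a "strong decrease".

## Förster theory

The overlap integral uses the wavelength-domain convention,
$J = \int \bar F_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4\,
d\lambda$ in M⁻¹ cm⁻¹ nm⁴, with the donor spectrum area-normalized and
trapezoidal quadrature on the union grid. The Förster radius follows
$R_0^6(\mathrm{Å}^6) = 8.79\times10^{-5}\, \kappa^2 n^{-4} Q_D J$; the
prefactor is fixed by the chosen λ-domain convention. Defaults: κ² = 2/3
(isotropic dynamic averaging), n = 1.4 (protein interior). Because
orientation factors inside a channel are genuinely uncertain, all
conversions vectorize: passing a κ² interval yields an R₀ interval and in
turn a distance **range**, which is how results such as "3.3–3.9 nm"
arise. R₀ enters as configuration, not as a derived quantity: the spectra
needed to derive it absolutely are instrument-specific, so the
distance-from-rate chain
$r = R_0(\tau_T/\tau_D)^{1/6}$ is exposed with R₀ as an explicit input and
the ~3.5 nm result treated as a consistency check.

## TCSPC reconvolution

The decay model is a signed-amplitude sum of exponentials; a negative
amplitude is a rise (sensitized emission). Each component is convolved
analytically with a Gaussian IRF:

$$h_i(t) = \frac{\alpha_i}{2}
  \exp\!\left(\frac{\sigma^2}{2\tau_i^2} - \frac{u}{\tau_i}\right)
  \mathrm{erfc}\!\left(\frac{\sigma/\tau_i - u/\sigma}{\sqrt 2}\right),
  \qquad u = t - t_0.$$

For σ ≪ τ the exponential prefactor overflows, so the implementation
switches to the scaled form
$\tfrac{\alpha}{2}\,\mathrm{erfcx}(B)\, e^{-u^2/2\sigma^2}$ (with
$B$ the erfc argument), using an asymptotic expansion of erfcx beyond
x = 25 where direct evaluation overflows. The IRF is handled through its
Gaussian σ (FWHM/2√(2 ln 2)) rather than an empirical histogram — only an
IRF width (170 ps FWHM) is specified for the instrument class being
emulated, not a measured shape.

Fitting minimizes the **Poisson deviance** (exact maximum likelihood for
counting data, correct at low counts in the decay tail) after a
Levenberg–Marquardt warm start on Pearson-weighted residuals; a pure
weighted-least-squares statistic is retained as a cross-check. Lifetimes
are fitted in log space; starts are log-spaced over
[channel width, t_max/2] (5 starts). Standard errors come from the inverse
Hessian of the deviance (covariance = 2 H⁻¹). Components below 0.1% of the
total amplitude are pruned post-fit. Model order is chosen by BIC with a
parsimony margin of 10: the smallest component count within 10 of the
minimum BIC wins — the flattest defensible rule given that no selection
criterion is printed for the reference fits.

The FRET time constant is extracted from the **acceptor channel** as a
negative-amplitude rise with the acceptor decay lifetime fixed from a
direct-excitation control. Both routes to a FRET time (donor quenching via
`efficiency_from_lifetimes`, acceptor rise via `extract_fret_time`) are
implemented; the reproduction driver uses the rise route. A rise amplitude
statistically indistinguishable from zero returns a "no resolvable rise"
outcome — the behaviour expected of a barrel that binds both dyes but
shows no FRET. The rise:decay amplitude ratio is reported as-is rather
than converted to a population fraction, because the observed rise
amplitude is an attribute of the minority slow-transfer population only.

Default acquisition design: 4096 channels, 0–100 ns window (120 ns for the
~20 ns donor control, 50 ns for acceptor-channel work), 2×10⁴ peak counts,
constant background 1% of peak, excitation at t₀ = 2 ns. None of these are
printed for the reference data; they are declared choices that make a
15.9 ns lifetime well-conditioned (window > 5× lifetime, flagged
otherwise) at a realistic photon budget.

## Transient-absorption target analysis

The two-population scheme has donor branches decaying at
$k_\mathrm{fast}+k_D$ (fraction $f_\mathrm{fast}$) and
$k_\mathrm{slow}+k_D$, both feeding the acceptor, which decays at $k_A$.
Populations are closed-form sums of IRF-convolved exponentials; the
removable singularity at $k_A = k_\mathrm{branch}$ is evaluated by a
central-difference limit. The closed form is property-tested against stiff
ODE integration with a Gaussian excitation source (1e−6 agreement over
random schemes), and excitation is conserved across excited species plus
cumulative ground-state returns.

`f_fast` defaults to **0.95**: the slow channel is described only as a
minority population, with no printed fraction, and at 0.95 the slow-rise
amplitude sits near the 1% noise floor of the TA fixtures — consistent
with a ~1 ns rise that is visible in TCSPC but not evident in TA. The
target fit therefore frees only the fast rate, an overall amplitude, and
time zero; the slow pathway stays fixed. Band integration over 575–605 nm
(not a single wavelength slice) defines the acceptor stimulated-emission
kinetics; stimulated emission is negative by convention. The default delay
grid is linear from −1 to +1 ps then logarithmic to 7 ns, standard
pump–probe practice. Fast constants below the IRF σ are flagged
unresolvable; recovery is unbiased once the constant exceeds a few IRF
widths.

## Free-energy-profile analysis

Profiles arrive as plain tables (CSV or whitespace dump; the package never
runs the biased sampling itself). Basin detection is **prominence-based**:
an interior minimum qualifies when the lower of its two enclosing barriers
is at least `min_prominence` (default 2 kJ mol⁻¹) above it — raw
sign-change detection would shatter on the few-kJ noise band that
accompanies such profiles. Boundaries are watershed (the separating
maxima; profile ends outermost). Populations are Boltzmann integrals with
the profile shifted to a zero global minimum (overflow guard), R = 8.314
J mol⁻¹ K⁻¹, T = 298 K default. Stacking classes use thresholds of 5 Å
(stacked) and 12 Å (slipped), bracketing the canonical 3.5/10.0 Å
geometries with margin.

For two Gaussian wells of equal width whose depths differ by exactly RT,
the population ratio is *not* exactly e : 1 — the integrand's curvature
scales with depth, giving the Laplace ratio
$e\sqrt{c_2/c_1}$ with $c_i = D_i/RT$; the test suite asserts the exact
quadrature value and the asymptotic e-ratio separately.

## Photodimerization kinetics

Anthracene photodimerization inside a barrel is modelled
**pseudo-first-order**, $F = p + (1-p)e^{-kt}$: encapsulation pre-pairs the
two anthracenes (1:2 barrel:ligand stoichiometry), so the bimolecular step
is not rate-limiting. This is an acknowledged approximation; free-solution
second-order kinetics are out of scope. The alternative is linear drift
$F = 1 - st$ through F(0) = 1 (slow photobleaching-like loss). Selection is
by AICc with a margin of 2 (AICc rather than an F-test because the models
are non-nested); completion means the exponential is selected and its
fitted end-of-run value is below 0.1. Panel classification compares each
sample's initial fractional loss rate ($k(1-p)$ or $s$) against controls:
promoted requires the exponential model *and* a rate above 3× the fastest
control; inhibited requires the linear model within twice the control
band (mean + 2 SD); anything else is ambiguous. A linear trace that is
modestly faster than controls therefore lands in ambiguous/inhibited,
never promoted.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the analyses assume:
Gaussian vibronic band shapes; channelwise Poisson counting under a
Gaussian 170 ps IRF with constant background; TA maps as population ×
spectrum outer products under a 280 fs IRF with relative Gaussian noise;
depletion-quadratic titrations; free-energy wells as negative Gaussians
with **spatially correlated** noise (white noise smoothed to a ~1 Å
correlation length — the sampling error of a converged biased-sampling
estimate is smooth, and white noise would manufacture spurious minima);
and exponential-vs-linear photolysis traces. Every generator takes a seed
and restores the caller's RNG state, so identical inputs give identical
outputs.

Not emulated: photon-by-photon detection artifacts (pile-up,
afterpulsing), a measured non-Gaussian IRF shape, probe chirp and coherent
artifacts in TA, excited-state absorption bands, 2D excitation–emission
cross-peak structure, and cooperativity in binding. Passing tests
therefore demonstrate correctness of the estimators under the stated
noise models, not robustness to these instrument non-idealities.

The default screen fixture builds 15 panels with 10 constructed positives
(transfer fractions 0.25–0.85, negatives at 0.01), mirroring a
10-of-15 screen outcome. The heptamer free-energy fixture uses wells at
3.5 Å (−93 kJ mol⁻¹, σ = 0.8 Å) and 10.0 Å (−92, σ = 1.5 Å) plus an
8 kJ mol⁻¹ shelf at 25 Å; widths are the generator's own choice (none are
printed) and are narrow enough that the wells do not shift each other's
minima.

## Problem sizes and determinism

The reproduction driver (`run_reproduction`, `scripts/acceptance.R`)
recovers each reference constant as the mean over 20 seeded replicates:
mono-exponential TCSPC recoveries at 4096 channels and 2×10⁴ peak counts,
acceptor-rise recoveries with a 0.15 rise:decay amplitude ratio, and TA
recoveries from full simulated maps (121 delays × 81 wavelengths, 1%
noise) band-integrated before fitting. Property suites run at reduced
sizes chosen for statistical adequacy: 200 seeds for Poisson-mean and
coverage checks (1024 channels or fewer), 100 random schemes/profiles for
the ODE and basin-scan oracle equivalences, 200 traces for
photodimerization accuracy. Per-replicate seeds derive linearly from the
global seed, so every reported number is a deterministic function of
`--seed`.

## Known limitations

- The apparent-efficiency estimator is an operational proxy; absolute
  efficiencies depend on band choices and direct-excitation corrections.
- R₀ is configuration, so inferred distances inherit its uncertainty
  (κ², n, Q_D) multiplicatively; report ranges, not points.
- The TCSPC information matrix gives asymptotic errors; coverage is
  validated (~68%) only at the default design.
- The TA model fixes the slow pathway; data in which the slow channel
  carries appreciable TA amplitude would need both rates freed.
- Basin populations assume the 1D profile is the relevant reaction
  coordinate; orthogonal degrees of freedom are integrated out by
  construction.
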