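---
title: "Models, estimators and design choices in quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

`quenchbind` implements the spectroscopic workflow used to characterise
small-molecule binding to serum albumins: fluorescence quenching
titrations, double-logarithm binding analysis, van't Hoff thermodynamics,
site-marker competition, and structural spectroscopy (synchronous scans,
excitation–emission matrices, UV/Vis, circular dichroism). This vignette
explains the underlying models, the estimators and numerical choices the
package makes where the literature conventions leave room, and what the
synthetic-data generator does and does not emulate.

## Quenching model and mechanism classification

Protein fluorescence quenched by a ligand at concentration $[Q]$ follows
the Stern–Volmer relation

$$\frac{F_0}{F} = 1 + K_{SV}[Q], \qquad K_q = K_{SV}/\tau_0 .$$

`stern_volmer_fit()` estimates $K_{SV}$ by unweighted ordinary least
squares of $F_0/F$ on $[Q]$, matching the linear-plot treatment standard
in this literature; no robust or weighted variant is offered. The
bimolecular rate constant $K_q$ uses $\tau_0 = 10^{-8}$ s by default —
the conventional average fluorescence lifetime of a biopolymer without
quencher; the value is configurable and always echoed in results, since
$K_q$ scales inversely with it. Values of $K_q$ far above the
diffusion-controlled limit ($\sim 2\times10^{10}$ L mol$^{-1}$ s$^{-1}$)
corroborate a static mechanism.

`classify_mechanism()` reads the mechanism off the temperature trend:
ground-state complexes destabilise on heating, so a strictly decreasing
$K_{SV}(T)$ is called *static*; diffusion accelerates on heating, so a
strictly increasing trend is called *dynamic*; anything non-monotone is
*indeterminate*. With only three temperatures spanning 12 K this is a
deliberately conservative rule — no significance test is attached,
because the decision in practice rests on the sign of a clearly monotone
trend.

Points with $F_0/F < 1$ (net fluorescence *enhancement*, seen when a
ligand first opens the protein structure before quenching sets in) are
excluded from the Stern–Volmer fit by default and reported in the
result's `excluded` field; they cannot carry quenching information and
would otherwise bias the slope.

## Reading intensities: the fixed-wavelength policy

$F$ is read at the emission peak of the free-protein spectrum for every
titration point (policy `"fixed"`), which is robust to the small
(≤ 3 nm) band shifts that occur during some titrations; a per-spectrum
maximum policy is selectable.

How the intensity at that fixed wavelength is *read* matters more than it
first appears. The downstream double-logarithm fit extrapolates its
intercept to $\log_{10}[Q] = 0$, roughly 4.5 decades beyond the titration
range, so a fractional bias $\epsilon$ in $F_0$ tilts the line and is
amplified into a $\sim 25\epsilon$ relative error in $K_A$. Reading a
single raw grid point at the argmax of the (noisy) free spectrum
introduces exactly such a bias: the argmax selects positive noise. The
package therefore reads intensities as the value at the reference
wavelength of a quadratic fit to the *log*-intensity over a ±12 nm
window. For a Gaussian band the log is exactly a parabola, so the
estimator is exact on noise-free data — including shifted bands — and it
has no selection bias under noise because the fitted value at a fixed
wavelength is a smooth functional of ~25 points. Stored spectra are never
altered; optional Savitzky–Golay smoothing (`smooth_spectrum()`) exists
for display or very noisy data but is off by default everywhere.

## Binding parameters

For static quenching the double-logarithm (Hill) relation

$$\log_{10}\frac{F_0 - F}{F} = \log_{10}K_A + n \log_{10}[Q]$$

is fitted by OLS; $K_A = 10^{\text{intercept}}$ (reported in L/mol, the
printed convention of the field even when $n \ne 1$) and $n$ is the
slope. Logarithms are base 10 throughout. Points with $F \ge F_0$ and the
$[Q]=0$ point are dropped (their transform is undefined) and recorded;
concentrations are total added ligand with no free-ligand correction, as
is conventional for these weakly-depleting titrations. For $n \approx 1$
the recovered $K_A$ agrees with the simple 1:1 static model
$F_0/F = 1 + K_A[Q]$ within 1 % on clean data, which the test suite
checks.

## Thermodynamics and force classification

`vant_hoff_fit()` regresses $\ln K_A$ on $1/T$:
$\Delta H = -\text{slope}\cdot R$, $\Delta S = \text{intercept}\cdot R$,
with $R = 8.314$ J mol$^{-1}$ K$^{-1}$. Two $\Delta G$ pathways are
always reported: $\Delta H - T\Delta S$ (the primary one — exact given
the fitted enthalpy and entropy, and the one that reproduces published
parameter tables cell-for-cell) and $-RT\ln K_A$, together with their
difference as a consistency diagnostic. The two agree exactly only when
$K_A$ lies exactly on the van't Hoff line; on published *rounded* values
they can differ by ~1 kJ/mol, and the package surfaces rather than hides
this. The same philosophy applies to the diagnostic in
`analysis/03_binding_thermodynamics.R`: refitting a published $K_A$
triple does not reproduce the published $(\Delta H, \Delta S)$ for these
complexes (e.g. −128.6 vs −105.74 kJ/mol for EPX/HSA), plausibly because
unrounded constants or a different point selection were used upstream;
the refit is reported as a diagnostic, not reconciled.

`classify_forces()` applies the two primary sign rules first —
$\Delta H<0 \wedge \Delta S<0 \Rightarrow$ hydrogen bond / van der Waals;
$\Delta H<0 \wedge \Delta S>0 \Rightarrow$ hydrophobic — and only then,
if enabled, the conventional extensions ($\Delta H>0 \wedge \Delta S>0
\Rightarrow$ hydrophobic; $|\Delta H|<5$ kJ/mol $\wedge\ \Delta S>0
\Rightarrow$ electrostatic), flagging extension calls in
`rule_applied`. The 5 kJ/mol half-width of the "$\Delta H \approx 0$"
band is configurable; it is of the order of a thermal energy scale times
the typical fit uncertainty and only affects the extended rules.

## Site-marker displacement

A marker *displaces* the ligand when the ratio $F_2/F_1$ at its highest
probe concentration falls below 0.8. The literature this workflow comes
from gives only a qualitative criterion ("decreasing" vs "little
impact"), so the threshold is an explicit, documented knob; the full
curves are always reported alongside the call so a reader can judge
borderline cases. The decision table is: only the site-I marker displaces
→ SudlowI; only site-II → SudlowII; both → ambiguous; neither →
surface_or_other. The call is invariant to uniform intensity rescaling
(only ratios enter), and the displaced set grows monotonically with the
threshold. No quantitative competitive-binding model (no $K_d$
partitioning between probe and ligand) is attempted — the analysis is the
ratio trend only.

## Structural spectroscopy

*Synchronous scans* are stored on the scanned excitation axis; because
conventions differ, peak tables report both $\lambda_{ex}$ and
$\lambda_{ex} + \Delta\lambda$. Offsets of 15 and 60 nm are attributed to
tyrosine and tryptophan respectively; other offsets are analysed but
unattributed. Quenching fractions are $1 - F/F_0$ at the free-protein
peak; shifts are measured against the free protein with the standard
2 nm classification threshold (sub-2 nm movements are treated as
unchanged, matching how ~1 nm movements are described as "almost
unchanged" while 3 nm is reported as a shift).

*Excitation–emission matrices*: the Rayleigh ridges are identified purely
geometrically ($|\lambda_{em} - \lambda_{ex}| \le 5$ nm first order,
$|\lambda_{em} - 2\lambda_{ex}| \le 5$ nm second order; tolerance
configurable) and masked before peak picking; fluorescence peaks are
strict local maxima of the remaining cells, refined by per-axis parabolic
interpolation, and assigned by excitation band: 260–300 nm for the
tryptophan/tyrosine peak (peak 1), 220–250 nm for the polypeptide
backbone peak (peak 2) — standard protein-EEM windows. No peak is ever
reported inside a ridge band, and no scattering correction beyond the
masking is attempted.

*UV/Vis*: per-concentration positions and intensities of the ~207 nm and
~280 nm bands with shifts measured against the free protein over fixed
search windows (200–230 and 255–310 nm).

*Circular dichroism*: observed millidegrees are converted to mean residue
ellipticity, $\mathrm{MRE} = \theta_{mdeg}/(10\,c\,n\,l)$ with $c$ in
mol/L (the only unit choice that makes the conventional $10cnl$
denominator dimensionally standard), $n$ the residue count (585 HSA, 583
BSA) and $l$ the path in cm. Helix content uses the 208 nm value only:
$\alpha(\%) = (-\mathrm{MRE}_{208} - 4000)/29000 \times 100$. The 222 nm
band is characterised but not used for a second estimate, and no CD
deconvolution (CONTIN/SELCON-style, or external β-strand estimators) is
attempted. Estimates outside $[0, 100]$ are clipped with a warning and
the raw value retained.

## The synthetic-data generator

The generator emulates the study design the analyses expect: a
$2\times10^{-6}$ mol/L albumin titrated with ligand from $2\times10^{-6}$
to $32\times10^{-6}$ mol/L (11 points, with the free protein as a
separate $[Q]=0$ scan) at 298/303/310 K, emission collected 300–500 nm
on a 1 nm grid at 295 nm excitation. The emission band is a single
Gaussian (centre 340 nm for HSA, 343 nm for BSA, σ = 25 nm) — adequate
because the analyses only use band height and position, not line shape.
Quenching is generated by exact inversion of the double-log model,
$F = F_0/(1 + K_A[Q]^n)$, with $K_A(T)$ either given per temperature or
derived exactly from a $(\Delta H, \Delta S)$ pair via the van't Hoff
relation, so that at zero noise every generator is the exact algebraic
inverse of its paired analysis. Modes: `static` (default), `dynamic`
(the enthalpy sign is flipped so $K$ rises with $T$ — a testing
construct, not a physical collisional model), `two_site` (70/30 mixture
of components at $K_A$ and $K_A/10$), and `enhancement_then_quench`
(+5 % intensity at the two lowest concentrations, emulating an initial
structural opening; the magnitude is a package choice, as only the
qualitative behaviour is reported in the literature). Noise is
multiplicative Gaussian per intensity sample with no wavelength jitter;
all generators are seeded and bit-reproducible, and every written file
embeds its ground truth in `#!` header lines so tests never hard-code
expected values.

What the generator does **not** emulate: real band asymmetry and Raman
scatter, inner-filter attenuation (a forward model is deliberately
omitted; `inner_filter_correct()` exists as a utility), detector
saturation, baseline drift, or correlated instrument noise. Passing the
round-trip suites therefore demonstrates correctness of the estimators
under the stated noise model, not robustness to every instrument
artefact.

## Problem sizes and numerical tolerances

The test and acceptance suites run: noise-free round trips over
$K_A \in [10^3, 10^7]$ L/mol and $n \in [0.8, 1.2]$ (recovery to
$10^{-6}$ relative or better); van't Hoff inversions exact to $10^{-9}$;
200 seeded replicates at 1 % noise on the 11-point design for the
stochastic claims (mean $K_A$ within 5 %, mean $n$ within 0.05, static
call rate ≥ 95 %); and single-scenario structural round trips (EEM peaks
within 1 nm, imposed intensity changes within 2 points, CD helix
contents to $10^{-6}$). These sizes keep the full suite under a minute
while leaving the stochastic means' standard errors several times
smaller than the tolerances they are checked against. Quantitative peak
*positions* on noisy broad bands are the least stable quantities
(single-scan location noise of a σ = 25 nm band at 1 % noise is a few
nm); direction calls are robust, and quantitative shift values should
come from low-noise or averaged scans, as instrument practice (3-scan
averaging) does.

## Known limitations

- The linearised double-log fit is the field's convention and is kept
  deliberately; no nonlinear isotherm or global multi-site fit is
  provided.
- The mechanism rule is a sign test on as few as two or three
  temperatures; it reports *indeterminate* rather than guessing on
  non-monotone input.
- $K_A$'s units are reported as L/mol even when $n \ne 1$, trading
  dimensional strictness for the field's reporting convention.
- Absorbance-based inner-filter correction is available but not applied
  automatically; the workflow assumes the low-absorbance regime in which
  these titrations are run.
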