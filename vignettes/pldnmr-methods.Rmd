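---
title: "Quantifying prion-like-domain structure, dynamics and phase behaviour with pldnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prion-like-domain structure, dynamics and phase behaviour with pldnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldnmr)
```

# Scope

`pldnmr` implements the quantitative analyses used to characterise
intrinsically disordered prion-like domains (PLDs) — the worked system
throughout is the C-terminal PLD of human TDP-43 (residues 274–414 of
UniProt Q13148) and its fragment PLD~309~ (309–350), whose methionine
sulfoxidation dismantles the helical elements that drive liquid–liquid
phase separation (LLPS) and chaperone recognition.  The package covers:

* sequence-derived biophysics (extinction coefficient, isoelectric point,
  hydrophobicity);
* secondary chemical shifts against a random-coil reference, with a
  helical-population estimate;
* chemical-shift perturbation (CSP) and intensity-broadening profiles;
* ^15^N R~1~/R~2~/het-NOE relaxation with Monte-Carlo errors and a
  rotational-correlation-time (τ~c~) estimator;
* CPMG relaxation-dispersion fits of two-state exchange;
* turbidity and thioflavin-T (ThT) aggregation-kinetics statistics and CD
  unit conversion;
* ensemble superposition with RMSD-to-mean convergence statistics;
* seeded generators that synthesise inputs for every stage, emitted through
  the package's own file writers.

Residue numbering is always full-length TDP-43 numbering (PLD = 274–414,
PLD~309~ = 309–350, helix 324–332), 1-based and inclusive, so every result
aligns with the numbering used for the intact protein.

# Sequence properties

The molar extinction coefficient follows the reduced-protein convention
ε~280~ = 5500·n~Trp~ + 1490·n~Tyr~ (no cystine term), which reproduces the
values used for concentration determination of TDP-43 (44,920 M^-1^cm^-1^)
and its PLD (17,990 M^-1^cm^-1^):

```{r}
extinctionCoefficient(tdp43Sequence("PLD"))
```

The isoelectric point is the bisection root (|charge| < 1e-4) of a
Henderson–Hasselbalch net-charge sum over D, E, C, Y, H, K, R and the
termini.  Two pK~a~ sets are shipped; the default "expasy" (Bjellqvist)
set reproduces the conventions of common web calculators, under which the
PLD computes to pI ≈ 10.0.  The pK~a~ table behind any published pI is
rarely stated, so pI comparisons should be read with ±0.2 pH tolerance —
the spread across common tables.  Hydrophobicity uses the Kyte–Doolittle
scale with a 7-residue window (ends shrink the window); the scale/window
behind any specific published figure is usually unstated, and this default
is the field's most common choice.  For the PLD the profile peaks inside
the self-association region 305–345.

# Random-coil reference and secondary shifts

Secondary shifts are defined as observed minus random-coil shifts,
ΔCα − ΔCβ being the standard helix/strand indicator.  The package ships
its own random-coil table for disordered chains (Cα, Cβ, N, H~N~) in the
style of the intrinsically-disordered-protein reference sets, with

* sparse neighbour corrections for the dominant Gly/Pro context effects
  (a following proline lowers Cα by ≈ 1.9 ppm; glycine neighbours mainly
  perturb the amide observables),
* per-atom linear temperature coefficients relative to 298.15 K (amide
  ^1^H at −4.7 ppb/K, ^15^N at −2.7 ppb/K, carbons nearly inert), and
* Henderson–Hasselbalch interpolation of the Asp/Glu/His protonation
  shifts for acidic samples (reference pH 6.5).

Conditions outside 273–333 K or pH 2–12 are clamped with a warning.
Methionine sulfoxide has no published random-coil table; the package
deliberately uses unmodified Met coefficients and offers
`maskOxidizedMet = TRUE` in `secondaryShifts()` so that MetO positions are
dropped from displays rather than misinterpreted — the same convention
used when plotting secondary shifts of oxidised PLD.

The helical population divides the mean ΔCα over a region by the +3.1 ppm
expected for a 100 % helical conformer, clamped to [0, 1].  ΔCα alone (not
ΔCα − ΔCβ) is used because the +3.1 ppm benchmark is defined on Cα.  The
region default is the short helix 324–332 of PLD~309~; published sentences
bracket it as 322–331 or Ala324–Ser332, and the accessor takes an explicit
region so either convention is one argument away.

# Peak-intensity analyses

CSP between two states is √(Δδ~1H~² + (Δδ~15N~/5)²); the 1/5 nitrogen
scaling is exposed (`nScale`) since it is a convention, not physics.
Broadening profiles divide state by reference intensities after scaling
each table by its median intensity over a normalisation region (default
400–414, the C-terminal tail that stays sharp in all states — published
intensity comparisons rarely state their normalisation, so it is explicit
and configurable here).  The "reverse decay" 1 − I~state~/I~ref~ (floored
at 0) is the binding/assembly fingerprint used for chaperone titrations.
Missing residues are reported as `NA`, never as zero.

HNHA cross/diagonal ratios invert the Vuister–Bax relation
I~cross~/I~diag~ = −tan²(2πJζ).  The dephasing delay ζ defaults to
13.05 ms (a common HNHA setting; configurable).  Couplings ≤ 5 Hz are
classed helix-leaning and ≥ 7 Hz strand-leaning, thresholds chosen to
bracket the 4 / 6 / 8 Hz anchors of helix, coil and strand.

# Relaxation

`fitMonoexponential()` fits I(t) = A·e^−Rt^ by least squares with a
log-linear seed plus three perturbed restarts, and propagates spectral
noise by refitting `nMc` Gaussian perturbations of the fitted curve
(parametric bootstrap, seeded).  Het-NOE is the saturated/unsaturated
intensity ratio with first-order error propagation from the spectral noise
(estimated as the intensity standard deviation of signal-less regions).

τ~c~ is estimated from the mean R~2~/R~1~ ratio as
τ~c~ ≈ √(6·R~2~/R~1~ − 7)/(4πν~N~), valid for residues without fast
internal motion or exchange broadening.  The subset filter therefore
excludes residue *i* iff T~2,i~ < mean(T~2~) − sd(T~2~) unless
T~1,i~ > mean(T~1~) + sd(T~1~).  Population standard deviation is the
default (`sdType` switches to sample sd; the choice is rarely stated in
published work).  Whether mean rates or mean times enter the ratio is
equally ambiguous in the field's phrasing; the default averages rates and
`average = "times"` averages times.  ν~N~ uses γ~N~/γ~H~ = 0.10136
(configurable).

# CPMG relaxation dispersion

R2eff = −ln(I/I~0~)/T~relax~ converts constant-time intensities.  Two
closed-form two-state models are provided: fast-exchange Luz–Meiboom and
the general Carver–Richards expression (equal intrinsic R~2~ in both
states).  A field of 0 Hz is kept as a data point and evaluated as the
ν→0 limit of each model (full R~ex~), matching acquisition schemes that
interleave a 0 Hz point.  Both forms are validated in the test suite
against an independent numerical Bloch–McConnell propagator
(`blochMcConnellR2eff()`), which explicitly evolves the two-site
magnetisation through the δ–180–2δ–180–δ pulse train and reports the
slowest-decaying mode of one CPMG cycle; agreement is better than 1 % over
k~ex~ ∈ 500–5000 s^−1^, p~B~ ∈ 0.01–0.2, Δω ∈ 0.5–3 ppm (Luz–Meiboom in
its fast-exchange regime only).

`fitDispersion()` uses the standard grouped topology — global (k~ex~,
p~B~), per-residue (Δω, R~2,0~) — with bounded L-BFGS-B on transformed
parameters, 7 independent starts by default, parametric-bootstrap errors
(`nMc` refits) and AICc model selection with a 2-unit preference for the
simpler model.  k~ex~ is bounded to [10, 2·10^4^] s^−1^; a fit at the
upper bound is flagged `kexLowerBound` and should be reported as a bound
(">2000 s^−1^"-style) rather than an estimate, avoiding over-interpretation
when the dispersion is flat on the accessible field range.  The per-curve
R~2~^RMSD^ statistic, √(Σ(R~2~^i,exp^ − R~2~^ave^)²/n), quantifies the
dispersion amplitude.

# Phase-separation and aggregation kinetics

Turbidity (A~600~) curves are integrated by the trapezoid rule over
[0, 24 h] as the LLPS readout; replicates are averaged point-wise for the
headline value and the SD across per-replicate AUCs is reported (published
panels rarely state which; both numbers are returned).  Raw A~600~ is
integrated by default, with an optional t = 0 baseline subtraction.  ThT
traces are fitted per replicate with a symmetric logistic
y~0~ + A/(1 + e^−k(t − t½)^) — the generic "sigmoidal curve" — reporting
mean t~½~ ± SD across replicates (fit-covariance SD for a single trace).
Mechanistic nucleation–elongation modelling is deliberately out of scope.
CD signals convert as Θ~mrw~ = θ·MRW/(10·l·c) with MRW defaulting to
98 g/mol.

# Ensemble geometry

`superposeEnsemble()` iterates: fit every conformer onto the current mean
of the selected atoms by the optimal least-squares (Kabsch) rotation,
recompute the mean, repeat until the mean moves < 10^−6^ Å RMS.  The
iteration is seeded with the first conformer because the raw coordinate
mean of arbitrarily oriented conformers can be degenerate.  "Heavy
backbone atoms" means N, Cα, C′, O; the default alignment region is the
short helix 324–332 (the structured element of the oxidised PLD~309~
ensemble), and scoring may use a different region or atom set.  The test
suite pins the Kabsch rotations to an independent quaternion (Horn)
superposition oracle at 10^−9^ Å.

# Synthetic data and what passing tests mean

Every generator is seeded and emits through the package's writers
(NMR-STAR, Sparky list, PDB, CSV), so file round-trips are exercised
wherever synthetic data are used.  Noise is Gaussian everywhere, matching
the Monte-Carlo error treatment of the analyses.  The generators emulate
the study conditions: 27 % helical population over 324–332 at 288 K /
pH 6.8; the seven R~1~ (20–1600 ms) and eight R~2~ delay schedules; the
nine CPMG fields (0–1000 Hz) with T~relax~ = 0.06 s at 800 MHz and
σ(R2eff) = 0.3 s^−1^ with truth k~ex~ = 3000 s^−1^, p~B~ = 0.05,
Δω = 2 ppm; 15-min/96-h plate-reader sampling; and 20-conformer ensembles
at 0.41 Å spread.  CPMG recovery uses three dispersion curves — the
smallest grouped fit in which the shared (k~ex~, p~B~) pair is clearly
identifiable; Monte-Carlo intervals on k~ex~ are reported as
normal-approximation intervals (estimate ± 1.96 · MC sd), which
calibrated best among percentile, basic-bootstrap and normal flavours in
seed-panel checks of this estimator.  Because the interval is itself a
Monte-Carlo product of a nonlinear fit, its coverage is near — not
exactly — nominal, so the recovery tests check coverage over a seed
panel rather than a single realisation.

What synthetic closure does *not* show: real spectra have non-Gaussian
artefacts (t~1~ noise, overlap), real random-coil references carry
systematic errors that partially cancel in ΔCα only when the same
reference is used on both sides, and real ensembles are restrained by
data, not isotropic displacement.  Closed-loop recoveries validate the
estimators, not the experimental accuracy of any particular deposit.
Where a quantity is pinned to a published number (ε exactly; pI ± 0.2;
27 % ± 5; 0.41 ± 0.10 Å; k~ex~ > 2000 s^−1^ with truth inside the 95 %
interval), the tolerance reflects that quantity's stated or conventional
uncertainty.

# Numerical choices and limitations

* Exponential, logistic and dispersion fits are deterministic given their
  seeds; restarts guard against local minima, and non-convergence raises
  an error rather than returning silently.
* The Carver–Richards implementation guards cosh overflow with its
  asymptotic form and clamps the acosh argument at 1; the ν = 0 limit is
  evaluated in closed form.
* Test and acceptance problem sizes (e.g. 100–500 Monte-Carlo refits,
  5 dispersion curves, 20-seed recovery sweeps) are chosen so the whole
  suite runs in minutes on a single core while keeping the statistical
  checks meaningful.
* Two-state exchange only; no ≥3-state models, no R1ρ, no model-free
  analysis, no structure calculation or dihedral prediction, no
  image-derived observables (FRAP/TEM/AFM), and no droplet-propensity
  prediction.
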