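# pldnmr

Quantitative analytics for intrinsically disordered prion-like domains
(PLDs), built around the C-terminal PLD of human TDP-43 (residues 274–414
of UniProt Q13148) — the region that drives liquid–liquid phase separation
(LLPS), amyloid aggregation and chaperone recognition in ALS/FTLD
proteinopathies, and whose behaviour is rewired by methionine
sulfoxidation.  The package is for structural biologists and biophysicists
who have chemical shifts, relaxation series, CPMG dispersions,
plate-reader kinetics or conformer ensembles for such a domain and want
the standard derived quantities with honest, seeded error estimates.

## What it computes

| Analysis | Core quantity |
|---|---|
| Sequence properties | ε₂₈₀ = 5500·n_W + 1490·n_Y; pI from the Henderson–Hasselbalch net charge; Kyte–Doolittle profiles |
| Secondary shifts | ΔCα − ΔCβ vs a neighbour/temperature-corrected random-coil reference; helix population = mean ΔCα / 3.1 ppm |
| Peak intensities | CSP = √(Δδ₁ᴴ² + (Δδ₁₅ₙ/5)²); broadening ratio and reverse decay 1 − I/I₀; Vuister–Bax ³J(HNHA) |
| ¹⁵N relaxation | R₁/R₂ monoexponential fits with Monte-Carlo errors; het-NOE; τc ≈ √(6·R₂/R₁ − 7)/(4πν_N) over a filtered residue subset |
| CPMG dispersion | global two-state fits (Luz–Meiboom / Carver–Richards, shared k_ex and p_B), validated against a numerical Bloch–McConnell propagator; R₂ᴿᴹˢᴰ amplitude statistic |
| Kinetics | turbidity AUC over 24 h; logistic ThT fits (t½ ± SD); Θ_mrw CD conversion |
| Ensembles | iterative Kabsch superposition; RMSD to mean coordinates |
| Synthetic data | seeded generators for every input type, emitted through the package's own NMR-STAR / Sparky / PDB / CSV writers |

File formats: FASTA, NMR-STAR v3.1 (BMRB-style shift loops), Sparky
`.list`, multi-model PDB and mmCIF, delimited time series.

## Worked example

```r
library(pldnmr)

pld <- tdp43Sequence("PLD")            # residues 274-414, Q13148 numbering
extinctionCoefficient(pld)
#> [1] 17990
isoelectricPoint(pld)$pI
#> [1] 9.978333

## plant a 27%-populated helix over 324-332 on the PLD_309 fragment,
## round-trip it through NMR-STAR, and recover the population
rec <- tdp43Sequence("PLD309")
f <- tempfile(fileext = ".str")
genShiftDataset(rec, c(324, 332), 0.27, seed = 1, path = f)
obs <- readNmrStarShifts(f)
ref <- randomCoilReference(rec, 288, 6.8, atoms = c("CA", "CB"))
helicalPopulation(secondaryShifts(obs, ref), c(324, 332))$population
#> [1] 0.2715027

## two-state exchange recovery at the nine CPMG fields (800 MHz, 60 ms)
cv <- genDispersionCurves(3000, 0.05, c(`321` = 2, `323` = 2, `331` = 2),
                          r20 = 8, sigma = 0.3, seed = 1)
fit <- fitDispersion(cv, model = "auto", nMc = 100, nRestarts = 7, seed = 1)
c(model = fit$model, kex = round(fit$kex), pB = signif(fit$pB, 2))
#>             model               kex                pB
#> "carver-richards"            "2531"           "0.029"
```

The extinction coefficient is exact by composition (3 Trp + 1 Tyr in the
PLD); the pI ≈ 10.0 explains why the cationic PLD avoids heterotypic
de-mixing with cationic chaperone regions; the recovered helical
population and exchange rate show the closed-loop consistency of the
generators and estimators (k_ex is recovered above the 2000 s⁻¹ reporting
bound with the truth inside the Monte-Carlo 95 % interval).

## Vignette

`vignettes/pldnmr-methods.Rmd` documents the models, the tunable
parameters and their defaults, the synthetic-data design, numerical
choices, and known limitations.
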