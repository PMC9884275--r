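Package: pldnmr
Title: NMR and Phase-Separation Analytics for Prion-Like Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Quantitative analysis of intrinsically disordered prion-like
        domains such as the C-terminal region of TDP-43. Provides readers for
        NMR-STAR chemical-shift deposits, Sparky peak lists, multi-model
        PDB/mmCIF ensembles and plate-reader time series; sequence-derived
        biophysical properties (extinction coefficient, isoelectric point,
        hydrophobicity); secondary chemical shifts against a neighbour- and
        temperature-corrected random-coil reference with helical-population
        estimates; chemical-shift perturbation and intensity-broadening
        profiles; 15N R1/R2/het-NOE relaxation fitting with Monte-Carlo
        errors and a rotational-correlation-time estimator; CPMG
        relaxation-dispersion analysis with Luz-Meiboom and Carver-Richards
        two-state models validated against a numerical Bloch-McConnell
        propagator; turbidity and thioflavin-T aggregation-kinetics
        statistics; Kabsch ensemble superposition with RMSD-to-mean
        convergence metrics; and seeded synthetic-data generators so every
        stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, Biostrings, bio3d, minpack.lm, pracma
Suggests: testthat (>= 3.0.0), withr, seqinr, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
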