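Package: RiboDesign
Title: Energy-Gap Guided Monte Carlo Design of Ribosomal RNA Secondary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for redesigning large structured RNAs (such as the bacterial
    16S and 23S ribosomal RNAs) toward a known target secondary structure. The
    central score is the energy gap ("delta") between the energy a sequence
    assigns to the target structure and the energy of its minimum free energy
    structure under a pair-additive nearest-pair model; designs are generated
    by constrained Metropolis Monte Carlo trajectories honouring mutation
    budgets, locked positions and IUPAC conservation masks derived from
    multiple alignments. Includes parsers for dot-bracket, CT and position-list
    formats, deterministic design operators (base-pair flips, AU/CG switches,
    wobble-to-Watson-Crick fixes, repeat breaking), mutation classifiers,
    design-pool selection and curation utilities, and a synthetic puzzle
    generator for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
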