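Package: il1evol
Title: Molecular Evolution Toolkit for the IL-1 Ligand Family
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the comparative molecular-evolution analysis of the
    interleukin-1 (IL-1) ligand family: JTT-model pairwise distances,
    neighbor-joining trees with bootstrap supports and low-support collapse,
    fixed-topology log-likelihood by Felsenstein pruning, modal-residue
    conservation profiling with domain partitions, Nei-Gojobori dN/dS with
    Jukes-Cantor correction, candidate nuclear-localisation-signal scanning
    and scoring, isoelectric-point computation, factorial domain-by-protein
    contrasts with Holm-Sidak adjustment, and a codon-alignment simulator
    with domain-specific selection intensities for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
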