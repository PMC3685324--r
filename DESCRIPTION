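Package: oscimhc
Title: Macroevolutionary Analysis of MHC Class I Exon 3 in Songbirds and
    Non-Passerine Birds
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for macroevolutionary analysis of major
    histocompatibility complex (MHC) class I exon 3 codon alignments:
    allele validity filtering, per-species polymorphism summaries,
    peptide-binding-region (PBR) partitioned dN/dS by the modified
    Nei-Gojobori counting method with Jukes-Cantor correction and codon
    bootstrap, neighbor-joining trees from TN93+Gamma or K2P distances,
    a Fitch-parsimony permutation test of species clustering, GC content
    by codon position with Welch tests, and maximum-likelihood
    Brownian-motion clade models of GC3 evolution compared by AIC with a
    stem-branch sensitivity analysis. Includes a seeded synthetic-data
    generator (two-clade allele trees, codon alignments with partitioned
    selection and third-position GC bias, Brownian traits) so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
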