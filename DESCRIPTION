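Package: uvspectra
Title: Mutation Spectra and Strand Asymmetry of UV-Induced Substitutions in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single and tandem base substitutions accumulated in
    UV-irradiated yeast genomes. Builds strand-collapsed 96-channel single-base and
    78-channel doublet substitution spectra in trinucleotide context, compares spectra
    (chi-squared, Pearson concordance, Mann-Whitney density tests), quantifies
    transcriptional strand asymmetry normalised by per-strand trinucleotide frequencies
    with Bonferroni-corrected goodness-of-fit tests, profiles leading/lagging replicative
    asymmetry between replication origins, and computes reversion-reporter and
    canavanine-resistance mutation frequencies from colony counts. A seeded synthetic-data
    generator produces toy genomes, annotations and mutation tables with controllable
    spectrum, transcriptional and replicative bias for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    rtracklayer,
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
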