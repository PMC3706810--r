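Package: popseqsim
Title: Simulation of Mapping-by-Sequencing Experiments in Plant Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of recombinant mutant mapping populations and
    their pooled whole-genome (or target-enriched) sequencing, for planning
    bulk-segregant mapping-by-sequencing experiments. Meioses are simulated
    from a configurable recombination landscape (trinomial crossover counts
    per chromosome, per-marker-interval placement frequencies, and
    gamma-modelled crossover interference); populations are bred under
    outcross and backcross schemes with phenotype selection and optional
    mis-scoring; sequencing of pooled genomes is simulated by multinomial
    coverage allocation over marker loci and per-read allele assignment with
    sequencing error. Downstream analyses include likelihood-ratio confidence
    mapping intervals for outcross pools, threshold-based homozygous
    candidate-mutation calling for backcross pools, foreground-genome
    quantification for direct sequencing of backcrossed mutants, and a
    single-end versus paired-end informative-read comparison. Synthetic
    species-like recombination landscapes (Arabidopsis-, rice- and
    barley-like) are generated in code, and experiment sweeps over pool size
    and coverage are orchestrated from YAML configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
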