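Package: gbcrispr
Title: In Silico GoldenBraid Assembly and CRISPR Multiplexing Toolbox
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale designer and simulator for GoldenBraid-style Type IIS
    modular cloning of CRISPR/Cas9 constructs. Models double-stranded DNA
    molecules with linear or circular topology, Type IIS enzyme geometry, sticky
    -end digestion and ligation-graph product enumeration, the GoldenBraid part
    grammar (level 0 domestication, alpha/omega binary braid), guide RNA target
    scanning and oligo-duplex design, polycistronic tRNA-gRNA multiplexing,
    restriction band prediction for clone validation, and assay arithmetic
    (restriction-site-loss mutation-rate correction, dual-luciferase reporter
    normalization). Ships a deterministic fixture generator for mock entry,
    alpha/omega destination and level -1 vectors plus synthetic genomes with
    planted targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils-seq.R'
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'enzymes.R'
    'core-digest.R'
    'core-ligate.R'
    'grammar.R'
    'crispr.R'
    'assay.R'
    'fixtures.R'
    'io.R'
    'workflow.R'
    'cli.R'
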