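Package: npscan
Title: Neuropeptide Precursor Discovery from Transcriptome Assemblies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for discovering and annotating neuropeptide precursor
    proteins in de novo transcriptome assemblies. Extracts open reading
    frames by six-frame translation, screens for N-terminal signal peptides,
    locates prohormone-convertase cleavage sites (mono-, di- and tribasic),
    predicts mature peptides with post-translational rules (C-terminal
    amidation of glycine-extended peptides, N-terminal pyroglutamate,
    disulfide capacity, tyrosine sulfation), classifies peptides into
    neuropeptide families via an extensible motif registry, screens
    candidate open reading frames by local-alignment homology against known
    precursors, and ranks de novo candidates with a composite
    precursor-likeness score. Includes a synthetic-fixture generator with
    ground-truth annotations for end-to-end validation, colourised
    annotation rendering, and GFF3/TSV/FASTA export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
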